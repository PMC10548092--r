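#' Read a BED file of intervals
#'
#' Thin wrapper over [rtracklayer::import()] returning a plain interval
#' data.frame in BED coordinates (0-based half-open starts).
#'
#' @param path BED file path.
#' @return Data.frame with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- as.data.frame(gr)
  data.frame(chrom = as.character(df$seqnames), start = df$start - 1,
             end = df$end)
}

#' Define a virtual-4C viewpoint
#'
#' The baited region of interest: a named set of genomic intervals
#' (overlapping intervals are merged per chromosome).
#'
#' @param name Viewpoint name.
#' @param intervals Data.frame `chrom`, `start`, `end` (0-based half-open),
#'   e.g. from [read_bed()].
#' @return An object of class `viewpoint`.
#' @export
viewpoint <- function(name, intervals) {
  stopifnot(nrow(intervals) >= 1)
  merged <- do.call(rbind, lapply(split(intervals, intervals$chrom), function(df) {
    df <- df[order(df$start), ]
    out <- df[1, ]
    if (nrow(df) > 1) for (i in 2:nrow(df)) {
      if (df$start[i] <= out$end[nrow(out)]) {
        out$end[nrow(out)] <- max(out$end[nrow(out)], df$end[i])
      } else out <- rbind(out, df[i, ])
    }
    out
  }))
  rownames(merged) <- NULL
  structure(list(name = name, intervals = merged,
                 chroms = unique(merged$chrom)), class = "viewpoint")
}

# does a 1-based position fall in any interval (0-based half-open)?
.in_intervals <- function(chrom, pos, intervals) {
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(intervals))) {
    hit <- hit | (chrom == intervals$chrom[i] &
                    pos - 1 >= intervals$start[i] & pos - 1 < intervals$end[i])
  }
  hit
}

#' Genome-wide trans counts for a viewpoint (virtual 4C)
#'
#' Extracts the "other ends" of read pairs with at least one end in the
#' baited viewpoint and the other end on a different chromosome (all cis
#' pairs, including bait-to-bait, are removed), and quantifies them in
#' fixed-grid 500-kb bins genome-wide.  Bins overlapping any exclusion —
#' the first `exclude_first` bp of every chromosome's centromeric end, the
#' blacklist, and any custom zones — by at least 1 bp are ineligible and
#' carry no counts.
#'
#' @param pairs Contact-pair data.frame (see [read_contact_pairs()]).
#' @param viewpoint A [viewpoint()].
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param bin_size Bin width, default 5e5.
#' @param exclude_first Bp excluded at every chromosome start (default 3e6).
#' @param blacklist,exclusions Optional interval data.frames
#'   (`chrom`, `start`, `end`).
#' @return Data.frame of class `trans_counts`: `chrom`, `start`, `bin_id`,
#'   `eligible`, `count`; with attributes `skipped` (pairs on unknown
#'   chromosomes) and `viewpoint`.
#' @export
virtual4c_bin_counts <- function(pairs, viewpoint, chrom_sizes, bin_size = 5e5,
                                 exclude_first = 3e6, blacklist = NULL,
                                 exclusions = NULL) {
  stopifnot(length(chrom_sizes) >= 1, !is.null(names(chrom_sizes)))
  bins <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    starts <- seq(0, chrom_sizes[[ch]] - 1, by = bin_size)
    data.frame(chrom = ch, start = starts)
  }))
  bins$bin_id <- paste0(bins$chrom, ":", format(bins$start, scientific = FALSE,
                                                trim = TRUE))
  eligible <- !(bins$chrom %in% viewpoint$chroms) &
    bins$start + bin_size > 0
  if (exclude_first > 0) {
    eligible <- eligible & (bins$start >= exclude_first)
  }
  excl <- rbind(if (!is.null(blacklist)) blacklist[, c("chrom", "start", "end")],
                if (!is.null(exclusions)) exclusions[, c("chrom", "start", "end")])
  if (!is.null(excl) && nrow(excl)) {
    for (i in seq_len(nrow(excl))) {
      hit <- bins$chrom == excl$chrom[i] & bins$start < excl$end[i] &
        bins$start + bin_size > excl$start[i]
      eligible[hit] <- FALSE
    }
  }
  bins$eligible <- eligible
  bins$count <- 0L

  a_in <- .in_intervals(pairs$chrom_a, pairs$pos_a, viewpoint$intervals)
  b_in <- .in_intervals(pairs$chrom_b, pairs$pos_b, viewpoint$intervals)
  other_chrom <- ifelse(a_in, pairs$chrom_b, pairs$chrom_a)
  other_pos <- ifelse(a_in, pairs$pos_b, pairs$pos_a)
  use <- (a_in | b_in) & !(other_chrom %in% viewpoint$chroms)
  known <- other_chrom %in% names(chrom_sizes)
  skipped <- sum(use & !known)
  if (skipped > 0) {
    warning(sprintf("%d trans pair(s) on unknown chromosomes skipped", skipped))
  }
  use <- use & known
  if (any(use)) {
    oc <- other_chrom[use]
    ob <- floor((other_pos[use] - 1) / bin_size) * bin_size
    ids <- paste0(oc, ":", format(ob, scientific = FALSE, trim = TRUE))
    tab <- table(ids)
    m <- match(names(tab), bins$bin_id)
    keep <- !is.na(m)
    bins$count[m[keep]] <- as.integer(tab[keep])
  }
  bins$count[!bins$eligible] <- NA_integer_
  attr(bins, "skipped") <- skipped
  attr(bins, "viewpoint") <- viewpoint$name
  class(bins) <- c("trans_counts", "data.frame")
  bins
}

#' Modified Z-score of a count vector
#'
#' The robust outlier score `0.6745 * (x - median(x)) / MAD` with
#' `MAD = median(|x - median(x)|)` (unscaled).  If the MAD is zero the
#' denominator falls back to `1.253314 * mean(|x - median|)`; if that is
#' also zero all scores are 0.  The score is invariant under positive
#' affine rescaling of the counts.
#'
#' @param x Counts over eligible bins (length >= 2).
#' @return Numeric vector of modified Z-scores.
#' @export
modified_zscore <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("need at least 2 eligible bins")
  med <- stats::median(x)
  mad0 <- stats::median(abs(x - med))
  if (mad0 > 0) return(0.6745 * (x - med) / mad0)
  meanad <- mean(abs(x - med))
  if (meanad > 0) return((x - med) / (1.253314 * meanad))
  rep(0, length(x))
}

#' Call significant trans interactions across replicates
#'
#' A bin is significant when its modified Z-score strictly exceeds the
#' threshold in every replicate; for those bins the replicate-average Z and
#' `log2(averageZ + 1)` are reported.
#'
#' @param count_tables List of `trans_counts` (one per replicate) sharing
#'   the same bins, or a list of plain count vectors over shared bins.
#' @param threshold Z cutoff (default 3.5, strict `>`).
#' @return Data.frame of class `zscore_result`: bin identifiers, per-replicate
#'   `z.<i>` columns, `significant`, `avg_z` (NA unless significant),
#'   `log2_avg_z1` = log2(avg over replicates of Z + 1) for all bins.
#' @export
call_significant <- function(count_tables, threshold = 3.5) {
  if (is.data.frame(count_tables)) count_tables <- list(count_tables)
  if (length(count_tables) == 1) {
    warning("single replicate: threshold applied to it alone")
  }
  first <- count_tables[[1]]
  if (is.data.frame(first)) {
    for (tb in count_tables[-1]) {
      if (!identical(tb$bin_id, first$bin_id)) stop("replicates must share bins")
    }
    elig <- first$eligible
    counts <- lapply(count_tables, function(tb) tb$count[elig])
    out <- first[, c("chrom", "start", "bin_id", "eligible")]
  } else {
    lens <- lengths(count_tables)
    if (length(unique(lens)) != 1) stop("replicates must share bins")
    elig <- rep(TRUE, lens[1])
    counts <- count_tables
    out <- data.frame(bin_id = seq_len(lens[1]),
                      eligible = TRUE)
  }
  if (!any(elig)) stop("no eligible bins")
  zmat <- vapply(counts, modified_zscore, numeric(sum(elig)))
  zfull <- matrix(NA_real_, nrow(out), length(counts))
  zfull[elig, ] <- zmat
  colnames(zfull) <- paste0("z.", seq_len(ncol(zfull)))
  sig <- rep(FALSE, nrow(out))
  sig[elig] <- apply(zmat > threshold, 1, all)
  avg <- rowMeans(zfull)
  out <- cbind(out, zfull)
  out$significant <- sig
  out$avg_z <- ifelse(sig, avg, NA_real_)
  l2 <- rep(NA_real_, nrow(out))
  ok <- elig & !is.na(avg) & avg > -1
  l2[ok] <- log2(avg[ok] + 1)
  out$log2_avg_z1 <- l2
  class(out) <- c("zscore_result", "data.frame")
  attr(out, "threshold") <- threshold
  out
}

#' Intersections of significant-hit sets
#'
#' Exact set algebra on bin identifiers: per-set sizes, all pairwise
#' intersection counts, and the k-way (all-sets) intersection.
#'
#' @param hit_sets Named list of character vectors of bin ids (e.g.
#'   `bin_id[significant]` from several viewpoints/conditions).
#' @return List: `sizes`, `pairwise` (data.frame set_a, set_b, n), `all_n`,
#'   `all_bins`.
#' @export
overlap_sets <- function(hit_sets) {
  stopifnot(length(hit_sets) >= 1, !is.null(names(hit_sets)))
  hit_sets <- lapply(hit_sets, unique)
  nm <- names(hit_sets)
  pw <- NULL
  if (length(nm) >= 2) {
    cmb <- utils::combn(nm, 2)
    pw <- data.frame(set_a = cmb[1, ], set_b = cmb[2, ],
                     n = apply(cmb, 2, function(p)
                       length(intersect(hit_sets[[p[1]]], hit_sets[[p[2]]]))))
  }
  all_bins <- Reduce(intersect, hit_sets)
  list(sizes = lengths(hit_sets), pairwise = pw,
       all_n = length(all_bins), all_bins = all_bins)
}

#' Hierarchical clustering of trans interaction profiles
#'
#' Clusters `log2(averageZ + 1)` profiles over the union of bins with
#' Euclidean distance and complete linkage (the defaults of the heatmap
#' tools this mirrors), applied to both rows (profiles) and columns (bins).
#'
#' @param profiles Named list of numeric vectors, each named by bin id;
#'   missing bins are imputed as 0.
#' @return List: `matrix` (profiles x bins), `row_hclust`, `col_hclust`,
#'   `row_labels` (cutree at k = 2 for convenience).
#' @export
cluster_profiles <- function(profiles) {
  if (length(profiles) < 2) stop("need at least 2 profiles")
  bins <- sort(unique(unlist(lapply(profiles, names))))
  m <- vapply(profiles, function(p) {
    v <- rep(0, length(bins))
    v[match(names(p), bins)] <- p
    v
  }, numeric(length(bins)))
  m <- t(m)
  colnames(m) <- bins
  row_hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                          method = "complete")
  col_hc <- stats::hclust(stats::dist(t(m), method = "euclidean"),
                          method = "complete")
  list(matrix = m, row_hclust = row_hc, col_hclust = col_hc,
       row_labels = stats::cutree(row_hc, k = min(2, nrow(m))))
}

#' Write a trans-interaction result table as TSV
#' @param result A `zscore_result`.
#' @param path Output path.
#' @export
write_zscore_result <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
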