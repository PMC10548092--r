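#' Binning scheme for a genomic region
#'
#' Defines a half-open, 0-based region `[start, end)` on one chromosome cut
#' into consecutive non-overlapping bins of `bin_size` base pairs.  A trailing
#' partial bin is kept, so the number of bins is `ceiling((end - start) /
#' bin_size)`.  A 1-based position `p` maps to bin `floor((p - 1 - start) /
#' bin_size) + 1`.
#'
#' @param chrom Chromosome name.
#' @param start,end Region bounds, 0-based half-open (BED convention).
#' @param bin_size Bin width in base pairs.
#' @return An object of class `binning_scheme`.
#' @examples
#' binning_scheme("chr12", 113090000, 116170000, 20000)
#' @export
binning_scheme <- function(chrom, start, end, bin_size) {
  stopifnot(is.character(chrom), nzchar(chrom))
  if (end <= start) stop("empty region: end must exceed start")
  if (bin_size <= 0) stop("bin_size must be positive")
  structure(
    list(chrom = chrom, start = as.numeric(start), end = as.numeric(end),
         bin_size = as.numeric(bin_size),
         n_bins = as.integer(ceiling((end - start) / bin_size))),
    class = "binning_scheme")
}

#' @export
print.binning_scheme <- function(x, ...) {
  cat(sprintf("binning_scheme: %s:%s-%s, %s bp bins, %d bins\n",
              x$chrom, format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE),
              format(x$bin_size, scientific = FALSE), x$n_bins))
  invisible(x)
}

#' Map 1-based positions to bin indices
#'
#' @param scheme A [binning_scheme()].
#' @param pos 1-based base-pair positions.
#' @return 1-based bin indices; `NA` for positions outside the region.
#' @export
bin_index <- function(scheme, pos) {
  idx <- floor((pos - 1 - scheme$start) / scheme$bin_size) + 1
  idx[pos - 1 < scheme$start | pos - 1 >= scheme$end] <- NA_integer_
  as.integer(idx)
}

#' Bin labels ("chrom:start-end") for a scheme
#' @param scheme A [binning_scheme()].
#' @return Character vector of length `n_bins`.
#' @export
bin_labels <- function(scheme) {
  s <- scheme$start + (seq_len(scheme$n_bins) - 1) * scheme$bin_size
  e <- pmin(s + scheme$bin_size, scheme$end)
  sprintf("%s:%s-%s", scheme$chrom, format(s, scientific = FALSE, trim = TRUE),
          format(e, scientific = FALSE, trim = TRUE))
}

new_contact_matrix <- function(values, mask, scheme, state) {
  dimnames(values) <- list(bin_labels(scheme), bin_labels(scheme))
  structure(list(values = values, mask = mask, scheme = scheme,
                 normalization_state = state),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix (%s): %d bins (%d masked), total mass %.4g\n",
              x$normalization_state, length(x$mask), sum(!x$mask),
              sum(x$values)))
  invisible(x)
}

#' Read contact-pair records from a TSV file
#'
#' Expects four tab-separated columns `chrom_a`, `pos_a`, `chrom_b`, `pos_b`
#' (1-based positions), with an optional header line and `#`-prefixed
#' comments.  Malformed records raise an error naming the offending line.
#'
#' @param path File path.
#' @return A data.frame with columns `chrom_a`, `pos_a`, `chrom_b`, `pos_b`.
#' @export
read_contact_pairs <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) && grepl("^chrom_a\\b", lines[1])) {
    lines <- lines[-1]
    lineno <- lineno[-1]
  }
  if (!length(lines)) {
    return(data.frame(chrom_a = character(), pos_a = numeric(),
                      chrom_b = character(), pos_b = numeric()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 4)
  if (length(bad)) stop(sprintf("malformed pair record at line %d of %s",
                                lineno[bad[1]], path))
  m <- matrix(unlist(lapply(parts, `[`, 1:4)), ncol = 4, byrow = TRUE)
  pa <- suppressWarnings(as.numeric(m[, 2]))
  pb <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(pa) | is.na(pb) | pa < 1 | pb < 1 |
                 !nzchar(m[, 1]) | !nzchar(m[, 3]))
  if (length(bad)) stop(sprintf("malformed pair record at line %d of %s",
                                lineno[bad[1]], path))
  data.frame(chrom_a = m[, 1], pos_a = pa, chrom_b = m[, 3], pos_b = pb)
}

#' Write contact pairs to TSV
#' @param pairs Data.frame as returned by [read_contact_pairs()].
#' @param path Output path.
#' @param comment Optional `#` comment line(s) written first.
#' @export
write_contact_pairs <- function(pairs, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines("chrom_a\tpos_a\tchrom_b\tpos_b", con)
  if (nrow(pairs)) {
    writeLines(sprintf("%s\t%.0f\t%s\t%.0f", pairs$chrom_a, pairs$pos_a,
                       pairs$chrom_b, pairs$pos_b), con)
  }
  invisible(path)
}

#' Bin contact pairs into a raw symmetric contact matrix
#'
#' Each pair with both ends inside the scheme's region increments one cell
#' (i, j) and its mirror; pairs with either end outside (or on another
#' chromosome) are ignored.  The sum over the upper triangle including the
#' diagonal therefore equals the number of accepted pairs.
#'
#' @param pairs Data.frame with columns `chrom_a`, `pos_a`, `chrom_b`,
#'   `pos_b` (1-based positions).
#' @param scheme A [binning_scheme()].
#' @return A `contact_matrix` in state `"raw"` with an all-valid mask.
#' @export
bin_contacts <- function(pairs, scheme) {
  n <- scheme$n_bins
  ia <- bin_index(scheme, pairs$pos_a)
  ib <- bin_index(scheme, pairs$pos_b)
  ok <- pairs$chrom_a == scheme$chrom & pairs$chrom_b == scheme$chrom &
    !is.na(ia) & !is.na(ib)
  ia <- ia[ok]; ib <- ib[ok]
  values <- matrix(0, n, n)
  if (length(ia)) {
    lo <- pmin(ia, ib); hi <- pmax(ia, ib)
    tab <- table(lo + n * (hi - 1))
    idx <- as.numeric(names(tab))
    values[idx] <- as.numeric(tab)
    values <- values + t(values)
    diag(values) <- diag(values) / 2
  }
  new_contact_matrix(values, rep(TRUE, n), scheme, "raw")
}

#' Mask low-coverage bins
#'
#' Marks as invalid the bins whose marginal (row sum) falls below
#' `min_fraction` times the median of the positive row sums — the "white
#' line" bins excluded from analysis — and zeroes their rows and columns.
#'
#' @param matrix A raw `contact_matrix`.
#' @param min_fraction Fraction of the median positive row sum below which a
#'   bin is masked (default 0.2).
#' @return The `contact_matrix` with its mask and values updated.
#' @export
mask_low_coverage <- function(matrix, min_fraction = 0.2) {
  rs <- rowSums(matrix$values)
  med <- stats::median(rs[rs > 0])
  valid <- is.finite(med) & rs >= min_fraction * med
  if (!any(valid)) stop("all bins masked: no usable coverage")
  matrix$mask <- valid
  matrix$values[!valid, ] <- 0
  matrix$values[, !valid] <- 0
  matrix
}

#' Balance a contact matrix by iterative correction
#'
#' Iterative proportional fitting: each sweep divides rows and columns by
#' their marginals and re-symmetrizes, until all unmasked row sums agree to a
#' relative tolerance.  The result is rescaled to preserve the input's total
#' mass.  Masked rows/columns stay zero.
#'
#' @param matrix A `contact_matrix` (raw, with mask applied).
#' @param max_iter Maximum sweeps (default 200).
#' @param tol Relative row-sum tolerance (default 1e-6).
#' @return The balanced `contact_matrix` (state `"balanced"`).
#' @export
ice_balance <- function(matrix, max_iter = 200, tol = 1e-6) {
  v <- matrix$values
  keep <- matrix$mask
  m <- v[keep, keep, drop = FALSE]
  mass <- sum(m)
  if (mass <= 0) stop("matrix has no mass on unmasked bins")
  resid <- Inf
  for (it in seq_len(max_iter)) {
    rs <- rowSums(m)
    if (any(rs == 0)) stop("unmasked bin with zero marginal; mask it first")
    m <- m / rs               # rows
    cs <- colSums(m)
    m <- sweep(m, 2, cs, "/") # columns
    m <- (m + t(m)) / 2       # keep symmetric
    rs <- rowSums(m)
    resid <- (max(rs) - min(rs)) / min(rs)
    if (resid <= tol) break
  }
  if (resid > tol) {
    stop(sprintf("iterative correction did not converge in %d sweeps (residual %.3g)",
                 max_iter, resid))
  }
  m <- m * (mass / sum(m))
  v[] <- 0
  v[keep, keep] <- m
  matrix$values <- v
  matrix$normalization_state <- "balanced"
  matrix
}

#' Observed-over-expected distance correction
#'
#' Divides every entry by the mean of the unmasked entries at the same
#' genomic separation `|i - j|`, removing the average contact-frequency decay
#' with distance.  Separations whose expected value is zero (or with no
#' unmasked entries) are flagged invalid rather than divided.
#'
#' @param matrix A balanced `contact_matrix`.
#' @return The `contact_matrix` in state `"distance_corrected"`, with an
#'   `invalid_diagonals` attribute listing the separations left undefined.
#' @export
distance_correct <- function(matrix) {
  v <- matrix$values
  n <- nrow(v)
  keep <- matrix$mask
  d <- abs(row(v) - col(v))
  eligible <- outer(keep, keep, "&")
  bad <- integer()
  for (s in 0:(n - 1)) {
    sel <- d == s & eligible
    if (!any(sel)) { bad <- c(bad, s); next }
    ex <- mean(v[sel])
    if (ex == 0) {
      bad <- c(bad, s)
      v[d == s] <- 0
    } else {
      v[d == s] <- v[d == s] / ex
    }
  }
  v[!eligible] <- 0
  matrix$values <- v
  matrix$normalization_state <- "distance_corrected"
  attr(matrix, "invalid_diagonals") <- bad
  matrix
}

#' Write / read a contact matrix as dense TSV
#'
#' The first row and column carry the bin labels `chrom:start-end`.  The
#' validity mask travels in a two-column sidecar TSV (label, valid flag).
#'
#' @param matrix A `contact_matrix`.
#' @param path Output TSV path.
#' @param mask_path Optional sidecar path (default `paste0(path, ".mask")`).
#' @export
write_contact_matrix <- function(matrix, path, mask_path = paste0(path, ".mask")) {
  lab <- bin_labels(matrix$scheme)
  m <- matrix$values
  out <- rbind(c("bin", lab), cbind(lab, format(m, digits = 10, trim = TRUE,
                                                scientific = FALSE)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(bin = lab, valid = as.integer(matrix$mask)),
                     mask_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_matrix
#' @param state Normalization state to stamp on the matrix read back.
#' @return `read_contact_matrix()` returns a `contact_matrix`.
#' @export
read_contact_matrix <- function(path, mask_path = paste0(path, ".mask"),
                                state = "raw") {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(tab)
  lab <- rownames(m)
  rng <- do.call(rbind, strsplit(sub("^.*:", "", lab), "-"))
  chrom <- sub(":.*$", "", lab[1])
  start <- as.numeric(rng[1, 1])
  end <- as.numeric(rng[nrow(rng), 2])
  size <- as.numeric(rng[1, 2]) - as.numeric(rng[1, 1])
  scheme <- binning_scheme(chrom, start, end, size)
  mask <- rep(TRUE, nrow(m))
  if (file.exists(mask_path)) {
    ms <- utils::read.table(mask_path, sep = "\t", header = TRUE)
    mask <- as.logical(ms$valid)[match(lab, ms$bin)]
  }
  new_contact_matrix(unname(m), mask, scheme, state)
}
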