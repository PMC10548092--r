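#' Per-bead annotation of the modeled locus
#'
#' Builds/validates the per-bead annotation table used by the ensemble
#' statistics: 1-based bead index, element class, CTCF level, and (for VH
#' beads) a recombination score.
#'
#' @param bead_index 1-based bead indices (unique).
#' @param element_class One of `"VH"`, `"DH"`, `"JH"`, `"Emu"`,
#'   `"CBE3prime"`, `"IGCR1"`, `"constant"`, `"RR3prime"`, `"none"`.
#' @param ctcf_level Non-negative CTCF binding level (default 0).
#' @param recombination_score Numeric or `NA` (default `NA`).
#' @return A data.frame of class `bead_annotation`.
#' @export
bead_annotation <- function(bead_index, element_class, ctcf_level = 0,
                            recombination_score = NA_real_) {
  classes <- c("VH", "DH", "JH", "Emu", "CBE3prime", "IGCR1", "constant",
               "RR3prime", "none")
  stopifnot(!anyDuplicated(bead_index), all(element_class %in% classes))
  df <- data.frame(bead_index = as.integer(bead_index),
                   element_class = element_class,
                   ctcf_level = ctcf_level,
                   recombination_score = recombination_score)
  df <- df[order(df$bead_index), ]
  class(df) <- c("bead_annotation", "data.frame")
  df
}

#' Synthetic Igh-like bead annotation
#'
#' A packaged annotation for a 156-bead Igh-locus model in the mm10
#' orientation used throughout: the 3' CTCF-binding elements (superanchor)
#' at bead 6, the constant/Emu block over beads 9-16, IGCR1 at bead 19, DH
#' genes over beads 18-21 (bead 19 carries D genes in addition to IGCR1),
#' and VH genes over beads 24-146.  CTCF levels and recombination scores are
#' synthetic placeholders (seeded), not measured values; the exact DH bead
#' span is an interpolation between the stated landmarks.
#'
#' @param n_beads Number of beads (default 156).
#' @param seed Seed for the synthetic CTCF levels and recombination scores.
#' @return A `bead_annotation` data.frame.
#' @export
igh_annotation <- function(n_beads = 156, seed = 1) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  stopifnot(n_beads >= 25)  # landmark layout needs the 3' block plus VH beads
  set.seed(seed)
  cls <- rep("none", n_beads)
  cls[6] <- "CBE3prime"
  cls[9:16] <- "constant"   # constant genes / Emu block
  cls[14] <- "Emu"
  cls[c(18, 20, 21)] <- "DH"
  cls[19] <- "IGCR1"        # carries D genes as well; DH set includes it
  vh <- 24:min(146, n_beads)
  cls[vh] <- "VH"
  ctcf <- stats::runif(n_beads, 0, 1)
  ctcf[c(6, 19)] <- stats::runif(2, 4, 6)  # anchors are strong CTCF sites
  score <- rep(NA_real_, n_beads)
  score[vh] <- stats::rexp(length(vh), 1)
  ann <- bead_annotation(seq_len(n_beads), cls, ctcf, score)
  attr(ann, "dh_beads") <- c(18, 19, 20, 21)
  ann
}

#' Beads of a given element class
#' @param annotation A `bead_annotation`.
#' @param class Element class; `"DH"` includes IGCR1's bead when flagged via
#'   the `dh_beads` attribute.
#' @return Integer bead indices.
#' @export
beads_of_class <- function(annotation, class) {
  if (class == "DH" && !is.null(attr(annotation, "dh_beads"))) {
    return(sort(attr(annotation, "dh_beads")))
  }
  annotation$bead_index[annotation$element_class == class]
}

#' Read / write bead annotation TSV
#' @param path File path.
#' @export
read_bead_annotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  bead_annotation(df$bead_index, df$element_class, df$ctcf_level,
                  df$recombination_score)
}

#' @rdname read_bead_annotation
#' @param annotation A `bead_annotation`.
#' @export
write_bead_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# per-conformation full distance matrices are the workhorse; returns the
# (S x npairs) stack from the compiled helper
.pair_dists <- function(ensemble) .pair_distances_cpp(ensemble$coords)

# column-major upper-triangle column index: pairs ordered (1,2),(1,3),(2,3),...
.ut_col <- function(i, j) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  (hi - 1) * (hi - 2) / 2 + lo
}

#' Mean number of interacting partners per bead
#'
#' For each bead, the number of other beads within `contact_radius`
#' (strict), averaged over all conformations.
#'
#' @param ensemble A `polymer_ensemble`.
#' @param contact_radius Contact threshold (default 1.5a).
#' @return Numeric vector of length `n_beads`.
#' @export
partners_per_bead <- function(ensemble, contact_radius = 1.5) {
  cmap <- ensemble_contact_map(ensemble, contact_radius)
  diag(cmap) <- 0
  rowSums(cmap)
}

#' V-D contact statistics over an ensemble
#'
#' For each conformation, the fraction of VH beads contacting at least one
#' DH bead; and, summed over conformations, the number of V-D bead-pair
#' contact events per DH bead and per VH bead.  Event conservation holds by
#' construction: the per-D counts and per-V counts sum to the same total.
#'
#' @param ensemble A `polymer_ensemble`.
#' @param annotation A `bead_annotation` with at least one VH and one DH bead.
#' @param contact_radius Contact threshold (default 1.5a).
#' @return List: `vh_fraction` (per conformation), `per_d` (named counts),
#'   `per_v` (named counts).
#' @export
vd_stats <- function(ensemble, annotation, contact_radius = 1.5) {
  vh <- beads_of_class(annotation, "VH")
  dh <- beads_of_class(annotation, "DH")
  if (!length(vh) || !length(dh)) stop("annotation must contain VH and DH beads")
  D <- .pair_dists(ensemble)
  S <- nrow(D)
  grid <- expand.grid(v = vh, d = dh)
  cols <- .ut_col(grid$v, grid$d)
  contact <- D[, cols, drop = FALSE] < contact_radius  # S x (|VH|*|DH|)
  dim(contact) <- c(S, length(vh), length(dh))
  any_d <- apply(contact, c(1, 2), any)                # S x |VH|
  vh_fraction <- rowMeans(any_d)
  per_v <- apply(contact, 2, sum)
  per_d <- apply(contact, 3, sum)
  names(per_v) <- vh
  names(per_d) <- dh
  list(vh_fraction = vh_fraction, per_d = per_d, per_v = per_v)
}

#' Center of mass of a conformation
#'
#' The arithmetic mean of the bead coordinates (avg x, avg y, avg z);
#' restricted to a subset of beads if given.  The VH-bead subset gives the
#' V-domain center of mass (CMv).
#'
#' @param coords n x 3 coordinate matrix.
#' @param subset Bead indices, or `"all"`.
#' @return Length-3 numeric vector.
#' @export
center_of_mass <- function(coords, subset = "all") {
  if (identical(subset, "all")) subset <- seq_len(nrow(coords))
  if (!length(subset)) stop("empty bead subset")
  colMeans(coords[subset, , drop = FALSE])
}

#' Per-bead mean distance from the CM and from the CMv
#'
#' For every bead, the distance to the whole-structure center of mass (CM)
#' and to the VH-only center of mass (CMv), averaged over conformations.
#'
#' @param ensemble A `polymer_ensemble`.
#' @param annotation A `bead_annotation` with VH beads.
#' @return Data.frame: `bead_index`, `dist_cm`, `dist_cmv` (units of a).
#' @export
cm_distance_profiles <- function(ensemble, annotation) {
  vh <- beads_of_class(annotation, "VH")
  if (!length(vh)) stop("annotation has no VH beads")
  S <- n_conformations(ensemble)
  n <- dim(ensemble$coords)[2]
  acc_cm <- acc_cmv <- numeric(n)
  for (s in seq_len(S)) {
    cm <- conformation(ensemble, s)
    c1 <- colMeans(cm)
    c2 <- colMeans(cm[vh, , drop = FALSE])
    acc_cm <- acc_cm + sqrt(rowSums(sweep(cm, 2, c1)^2))
    acc_cmv <- acc_cmv + sqrt(rowSums(sweep(cm, 2, c2)^2))
  }
  data.frame(bead_index = seq_len(n), dist_cm = acc_cm / S,
             dist_cmv = acc_cmv / S)
}

#' Conditional distance from CMv given a contact
#'
#' Mean distance of bead `b` from the VH center of mass over the subset of
#' conformations in which `b` is in contact with bead `q`.  An empty
#' conditioning subset yields an explicit `NA` with `n_subset = 0`, never a
#' silent zero.
#'
#' @param ensemble A `polymer_ensemble`.
#' @param annotation A `bead_annotation` with VH beads.
#' @param bead,partner Bead indices.
#' @param contact_radius Contact threshold (default 1.5a).
#' @return List: `mean_dist` (`NA` if undefined), `n_subset`.
#' @export
conditional_cmv_distance <- function(ensemble, annotation, bead, partner,
                                     contact_radius = 1.5) {
  vh <- beads_of_class(annotation, "VH")
  S <- n_conformations(ensemble)
  d <- numeric(S)
  sel <- logical(S)
  for (s in seq_len(S)) {
    cm <- conformation(ensemble, s)
    if (sqrt(sum((cm[bead, ] - cm[partner, ])^2)) < contact_radius) {
      sel[s] <- TRUE
      cmv <- colMeans(cm[vh, , drop = FALSE])
      d[s] <- sqrt(sum((cm[bead, ] - cmv)^2))
    }
  }
  if (!any(sel)) return(list(mean_dist = NA_real_, n_subset = 0L))
  list(mean_dist = mean(d[sel]), n_subset = sum(sel))
}

#' Mean fraction of VH beads contacted by each bead
#'
#' For bead b in conformation c, the fraction of VH beads (excluding b
#' itself) within `contact_radius`; averaged over conformations.
#'
#' @inheritParams vd_stats
#' @return Numeric vector of length `n_beads`, values in `[0, 1]`.
#' @export
vh_contact_fraction <- function(ensemble, annotation, contact_radius = 1.5) {
  vh <- beads_of_class(annotation, "VH")
  if (!length(vh)) stop("annotation has no VH beads")
  n <- dim(ensemble$coords)[2]
  cmap <- ensemble_contact_map(ensemble, contact_radius)  # mean contact freq
  diag(cmap) <- 0
  vapply(seq_len(n), function(b) {
    denom <- length(setdiff(vh, b))
    if (denom == 0) return(0)
    sum(cmap[b, setdiff(vh, b)]) / denom
  }, numeric(1))
}

#' Cluster conformations by structural similarity
#'
#' Dissimilarity between two conformations is either the root-mean-square
#' difference of their bead-to-bead distance matrices (`"rmsd"`; invariant
#' to rigid motion) or one minus the Jaccard overlap of their contact sets
#' (pairs closer than 1.5a with `|i - j| >= 2`; `"contact_overlap"`).
#' Agglomerative hierarchical clustering (average linkage by default) is cut
#' into `k` groups.
#'
#' @param ensemble A `polymer_ensemble` with >= 2 conformations.
#' @param method `"rmsd"` or `"contact_overlap"`.
#' @param linkage Passed to [stats::hclust()] (default `"average"`).
#' @param k Number of clusters (default 2).
#' @param contact_radius Contact threshold for `"contact_overlap"`.
#' @return List: `labels`, `sizes`, `largest` (index of the largest
#'   cluster), `largest_map` (contact map of the largest cluster),
#'   `dissimilarity` (a `dist`), `hclust`.
#' @export
cluster_conformations <- function(ensemble, method = c("rmsd", "contact_overlap"),
                                  linkage = "average", k = 2,
                                  contact_radius = 1.5) {
  method <- match.arg(method)
  S <- n_conformations(ensemble)
  if (S < 2) stop("need at least 2 conformations")
  if (k > S) stop("k exceeds the number of conformations")
  D <- .pair_dists(ensemble)
  if (method == "rmsd") {
    diss <- stats::dist(D) / sqrt(ncol(D))
  } else {
    n <- dim(ensemble$coords)[2]
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    longrange <- abs(pairs[, 1] - pairs[, 2]) >= 2
    C <- (D < contact_radius)[, longrange, drop = FALSE]
    inter <- tcrossprod(C * 1)
    sizes <- rowSums(C)
    uni <- outer(sizes, sizes, "+") - inter
    jac <- ifelse(uni > 0, inter / uni, 1)
    diss <- stats::as.dist(1 - jac)
  }
  hc <- stats::hclust(diss, method = linkage)
  labels <- stats::cutree(hc, k = k)
  sizes <- table(labels)
  largest <- as.integer(names(sizes)[which.max(sizes)])
  sub <- ensemble
  sub$coords <- ensemble$coords[labels == largest, , , drop = FALSE]
  list(labels = labels, sizes = sizes, largest = largest,
       largest_map = ensemble_contact_map(sub, contact_radius),
       dissimilarity = diss, hclust = hc)
}

#' Spearman rank correlation with pairwise NA removal
#'
#' Average ranks are used for ties; the two-sided p-value comes from the
#' t approximation (appropriate in the presence of ties).  A correlation of
#' magnitude above 0.4 is conventionally read as moderately strong.
#'
#' @param x,y Equal-length numeric vectors; pairs with any `NA` are dropped.
#' @return List: `rho`, `p`, `n`.  Constant input gives `rho = NA`.
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}
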