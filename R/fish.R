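#' Read a 3D FISH spot table
#'
#' Tab-separated columns `nucleus_id`, `channel`, `x`, `y`, `z` (micrometers)
#' and optionally `diameter` (nuclear diameter, micrometers); `#` comments
#' allowed.
#'
#' @param path File path.
#' @return Data.frame of spots.
#' @export
read_fish_spots <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  stopifnot(all(c("nucleus_id", "channel", "x", "y", "z") %in% names(df)))
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    stop("non-finite spot coordinates")
  }
  df
}

#' @rdname read_fish_spots
#' @param spots Spot data.frame.
#' @export
write_fish_spots <- function(spots, path) {
  utils::write.table(spots, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter nuclei by spot count per channel
#'
#' Keeps only nuclei with exactly `spots_per_channel` spots in every
#' channel present in the table (a diploid nucleus shows two spots per
#' probe; anything else indicates a segmentation or hybridization artifact).
#'
#' @param spots Spot data.frame (see [read_fish_spots()]).
#' @param spots_per_channel Required spots per channel (default 2).
#' @param channels Channels that must be present (default: all observed).
#' @return The filtered data.frame, with attribute `rejected` = number of
#'   nuclei removed.
#' @export
select_nuclei <- function(spots, spots_per_channel = 2,
                          channels = unique(spots$channel)) {
  tab <- table(spots$nucleus_id, factor(spots$channel, levels = channels))
  good <- rownames(tab)[apply(tab == spots_per_channel, 1, all)]
  out <- spots[spots$nucleus_id %in% good, , drop = FALSE]
  attr(out, "rejected") <- length(unique(spots$nucleus_id)) - length(good)
  out
}

# spots of one channel in one nucleus as a matrix
.channel_xyz <- function(spots, nucleus, channel) {
  sel <- spots$nucleus_id == nucleus & spots$channel == channel
  if (!any(sel)) stop(sprintf("nucleus %s has no spots in channel %s",
                              nucleus, channel))
  as.matrix(spots[sel, c("x", "y", "z")])
}

#' Closest cross-channel spot-pair distance in a nucleus
#'
#' The minimum Euclidean distance over all pairs of one spot from each
#' channel (with two spots per channel, 4 candidates); this is the
#' "shortest distance in each cell" used downstream.
#'
#' @param spots Spot data.frame (selected nuclei).
#' @param nucleus Nucleus id.
#' @param channel_a,channel_b Channel labels.
#' @return Distance in micrometers.
#' @export
closest_pair_distance <- function(spots, nucleus, channel_a, channel_b) {
  a <- .channel_xyz(spots, nucleus, channel_a)
  b <- .channel_xyz(spots, nucleus, channel_b)
  dd <- outer(seq_len(nrow(a)), seq_len(nrow(b)), Vectorize(function(i, j)
    sqrt(sum((a[i, ] - b[j, ])^2))))
  min(dd)
}

#' Closest-pair distances for all nuclei
#' @inheritParams closest_pair_distance
#' @return Data.frame `nucleus_id`, `distance`.
#' @export
closest_pair_distances <- function(spots, channel_a, channel_b) {
  ids <- unique(spots$nucleus_id)
  data.frame(nucleus_id = ids,
             distance = vapply(ids, function(nu)
               closest_pair_distance(spots, nu, channel_a, channel_b),
               numeric(1)))
}

#' Volume-adjust distances
#'
#' Multiplies distances by a scalar factor, used to normalize distances
#' measured in nuclei of a different average volume (a factor above one
#' enlarges distances measured in smaller nuclei).  Rank order is preserved.
#'
#' @param distances Numeric distances (micrometers).
#' @param factor Positive scale factor (e.g. 1.0601699 for thymocytes).
#' @return Scaled distances.
#' @export
adjust_volume <- function(distances, factor) {
  stopifnot(factor > 0)
  distances * factor
}

#' Nuclear volume from a diameter
#' @param diameter Diameter in micrometers.
#' @return Volume `(4/3) * pi * (d/2)^3` in cubic micrometers.
#' @export
nuclear_volume <- function(diameter) (4 / 3) * pi * (diameter / 2)^3

#' Random association probability of two loci
#'
#' The probability that two independently, uniformly positioned loci in a
#' spherical nucleus of volume `V` fall within radius `r` of each other is
#' approximated by the volume ratio `(4/3) * pi * r^3 / V` (boundary
#' truncation ignored, as in the standard calculation).  With `r` = 1 um
#' and `V` = 60 um^3 this gives ~0.069; the probability that three loci
#' associate simultaneously is the square of the pairwise probability.
#'
#' @param r Association radius (micrometers), positive.
#' @param V Nuclear volume (cubic micrometers), positive.
#' @return Probability (capped at 1).
#' @export
random_association_probability <- function(r = 1, V = 60) {
  if (r <= 0 || V <= 0) stop("r and V must be positive")
  min(1, (4 / 3) * pi * r^3 / V)
}

#' @rdname random_association_probability
#' @param p Pairwise association probability.
#' @export
tripartite_probability <- function(p) {
  stopifnot(p >= 0, p <= 1)
  p^2
}

#' Distance bracket distribution
#'
#' Counts distances in the four conventional brackets `[0, b1)`, `[b1, b2)`,
#' `[b2, b3)`, `[b3, Inf)` (half-open on the left edge of each bracket;
#' defaults 0.5, 0.8, 1.0 um).
#'
#' @param distances Non-negative distances (micrometers).
#' @param brackets Increasing cut points (default `c(0.5, 0.8, 1.0)`).
#' @return Named integer vector of counts summing to `length(distances)`.
#' @export
bracket_distribution <- function(distances, brackets = c(0.5, 0.8, 1.0)) {
  if (any(distances < 0)) stop("negative distance")
  stopifnot(all(diff(brackets) > 0))
  cuts <- c(0, brackets, Inf)
  cnt <- table(cut(distances, cuts, right = FALSE, include.lowest = FALSE))
  lab <- c(sprintf("<%g", brackets[1]),
           sprintf("%g-%g", brackets[-length(brackets)], brackets[-1]),
           sprintf(">%g", brackets[length(brackets)]))
  stats::setNames(as.integer(cnt), lab)
}

#' Association tests between cell types or against the random model
#'
#' `association_test()` compares the proportions of nuclei with
#' closest-pair distance below the radius in two groups by a two-sided
#' Fisher's exact test, Bonferroni-corrected for `m_tests` comparisons.
#' `association_vs_random()` tests an observed count against the analytic
#' random-association probability with an exact binomial test.
#'
#' @param k_a,n_a Associated count and total in group A.
#' @param k_b,n_b Associated count and total in group B.
#' @param m_tests Number of tests in the Bonferroni family (default 1).
#' @return List: `p` (raw), `p_corrected` (`min(1, m_tests * p)`),
#'   `odds_ratio`.
#' @export
association_test <- function(k_a, n_a, k_b, n_b, m_tests = 1) {
  if (n_a <= 0 || n_b <= 0) stop("zero group totals")
  stopifnot(k_a <= n_a, k_b <= n_b)
  tab <- matrix(c(k_a, n_a - k_a, k_b, n_b - k_b), 2, 2)
  ft <- stats::fisher.test(tab)
  list(p = ft$p.value, p_corrected = min(1, m_tests * ft$p.value),
       odds_ratio = unname(ft$estimate))
}

#' @rdname association_test
#' @param k,n Observed associated count and total.
#' @param p0 Analytic random probability (e.g. from
#'   [random_association_probability()]).
#' @export
association_vs_random <- function(k, n, p0, m_tests = 1) {
  if (n <= 0) stop("zero total")
  bt <- stats::binom.test(k, n, p = p0)
  list(p = bt$p.value, p_corrected = min(1, m_tests * bt$p.value),
       proportion = k / n)
}

#' Compare distance distributions across groups
#'
#' Omnibus Kruskal-Wallis test (with tie correction) followed by Dunn's
#' pairwise z-tests on the pooled ranks, Bonferroni-corrected.
#'
#' @param groups Named list of numeric distance vectors (>= 2 groups, each
#'   with >= 2 values).
#' @return List: `kruskal_p`, `kruskal_statistic`, `pairwise` (data.frame
#'   group_a, group_b, z, p, p_corrected).  If every value is identical the
#'   p-values are `NA` (flagged undefined).
#' @export
distribution_test <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  vals <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  if (length(unique(vals)) == 1) {
    return(list(kruskal_p = NA_real_, kruskal_statistic = NA_real_,
                pairwise = NULL))
  }
  kw <- stats::kruskal.test(vals, g)
  # Dunn's test on pooled ranks with tie correction
  N <- length(vals)
  rk <- rank(vals)
  ties <- table(vals)
  tiecor <- sum(ties^3 - ties) / (12 * (N - 1))
  meanrk <- tapply(rk, g, mean)
  ns <- tapply(rk, g, length)
  cmb <- utils::combn(levels(g), 2)
  m <- ncol(cmb)
  pw <- data.frame(group_a = cmb[1, ], group_b = cmb[2, ], z = NA_real_,
                   p = NA_real_, p_corrected = NA_real_)
  for (i in seq_len(m)) {
    a <- cmb[1, i]; b <- cmb[2, i]
    se <- sqrt((N * (N + 1) / 12 - tiecor) * (1 / ns[[a]] + 1 / ns[[b]]))
    z <- (meanrk[[a]] - meanrk[[b]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    pw$z[i] <- z
    pw$p[i] <- p
    pw$p_corrected[i] <- min(1, m * p)
  }
  list(kruskal_p = kw$p.value, kruskal_statistic = unname(kw$statistic),
       pairwise = pw)
}

#' Three-signal (tripartite) nucleus selection
#'
#' Picks the closest cross-channel signal trio — the triple (one spot per
#' channel) minimizing the sum of its three pairwise distances — and keeps
#' the nucleus only if at least two of those three distances are below the
#' radius.
#'
#' @param spots Spot data.frame (selected nuclei).
#' @param nucleus Nucleus id.
#' @param channels Three channel labels.
#' @param radius Association radius in micrometers (default 1.0).
#' @return List: `keep` (logical), `distances` (the trio's three pairwise
#'   distances), `trio` (spot row indices within each channel).
#' @export
three_way_select <- function(spots, nucleus, channels, radius = 1.0) {
  stopifnot(length(channels) == 3)
  xyz <- lapply(channels, function(ch) .channel_xyz(spots, nucleus, ch))
  best <- NULL
  for (i in seq_len(nrow(xyz[[1]]))) {
    for (j in seq_len(nrow(xyz[[2]]))) {
      for (k in seq_len(nrow(xyz[[3]]))) {
        d12 <- sqrt(sum((xyz[[1]][i, ] - xyz[[2]][j, ])^2))
        d13 <- sqrt(sum((xyz[[1]][i, ] - xyz[[3]][k, ])^2))
        d23 <- sqrt(sum((xyz[[2]][j, ] - xyz[[3]][k, ])^2))
        tot <- d12 + d13 + d23
        if (is.null(best) || tot < best$total) {
          best <- list(total = tot, distances = c(d12, d13, d23),
                       trio = c(i, j, k))
        }
      }
    }
  }
  list(keep = sum(best$distances < radius) >= 2, distances = best$distances,
       trio = best$trio)
}
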