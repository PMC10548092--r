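# Seeded generators that emulate the statistical structure of each input the
# pipeline consumes, so every stage is testable without external data.  All
# generators restore the caller's RNG state and are bit-reproducible for a
# given (seed, parameters).

.with_seed <- function(seed, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  expr
}

#' Ground-truth energy matrix with anchor stripes and a distal block
#'
#' Builds a synthetic well-depth matrix mimicking the pro-B-like locus
#' architecture: a small number of anchor beads attracting every other bead
#' (the stripes produced by CTCF-bound loop anchors), one distally located
#' attractive block (a compacted subdomain), and a uniform background.
#' Where specifications overlap, the deeper (more negative) value wins.
#'
#' @param n_beads Number of beads.
#' @param anchors Anchor bead indices (may be empty).
#' @param anchor_depth Well depth (kT) on anchor rows (default -1.5).
#' @param block `c(start, end)` bead range of the attractive block, or
#'   `NULL`.
#' @param block_depth Well depth inside the block (default -0.6).
#' @param background_depth Depth elsewhere (default 0).
#' @return Symmetric n x n matrix with zero diagonal, entries <= 0.
#' @export
synth_energy_truth <- function(n_beads, anchors = integer(), anchor_depth = -1.5,
                               block = NULL, block_depth = -0.6,
                               background_depth = 0) {
  stopifnot(all(anchors >= 1 & anchors <= n_beads))
  eps <- matrix(min(background_depth, 0), n_beads, n_beads)
  if (!is.null(block)) {
    b <- block[1]:block[2]
    eps[b, b] <- pmin(eps[b, b], block_depth)
  }
  for (a in anchors) {
    eps[a, ] <- pmin(eps[a, ], anchor_depth)
    eps[, a] <- pmin(eps[, a], anchor_depth)
  }
  eps <- pmin((eps + t(eps)) / 2, 0)
  diag(eps) <- 0
  eps
}

#' Simulate a target contact map from a known energy matrix
#'
#' Ground truth for inverse-fit recovery experiments: samples an ensemble
#' under the given energies and returns its contact-probability map
#' together with the generating ensemble.
#'
#' @param truth Energy matrix (kT).
#' @param params A [model_params()] (default sized to `truth`).
#' @param n_structures Ensemble size (default 600).
#' @param seed Seed.
#' @return List: `map` (contact probabilities), `ensemble`.
#' @export
synth_target_map <- function(truth, params = model_params(nrow(truth)),
                             n_structures = 600, seed = 1) {
  ens <- mc_sample(truth, params, n_structures = n_structures, seed = seed)
  list(map = ensemble_contact_map(ens, params$interaction_radius),
       ensemble = ens)
}

#' Synthetic genome-wide trans count tables
#'
#' Independent negative-binomial background counts per replicate over
#' `n_bins` eligible bins, with chosen bins "spiked" to `fold` times the
#' background mean in every replicate (frequent-contact bins a caller
#' should recover).  Ground-truth labels are attached.
#'
#' @param n_bins Number of eligible bins.
#' @param mean Background NB mean (> 0, default 20).
#' @param dispersion NB size parameter (default 5; smaller = more
#'   overdispersed).
#' @param spikes Data.frame `bin`, `fold` (or `NULL`).
#' @param n_replicates Number of replicates (default 2).
#' @param seed Seed.
#' @return List: `counts` (matrix n_bins x n_replicates), `is_spike`
#'   (logical ground truth).
#' @export
synth_trans_counts <- function(n_bins, mean = 20, dispersion = 5,
                               spikes = NULL, n_replicates = 2, seed = 1) {
  if (mean <= 0) stop("background mean must be positive")
  if (!is.null(spikes)) stopifnot(all(spikes$bin >= 1 & spikes$bin <= n_bins))
  .with_seed(seed, {
    counts <- matrix(stats::rnbinom(n_bins * n_replicates, mu = mean,
                                    size = dispersion),
                     n_bins, n_replicates)
    is_spike <- rep(FALSE, n_bins)
    if (!is.null(spikes) && nrow(spikes)) {
      for (i in seq_len(nrow(spikes))) {
        b <- spikes$bin[i]
        counts[b, ] <- stats::rnbinom(n_replicates,
                                      mu = mean * spikes$fold[i],
                                      size = dispersion)
        is_spike[b] <- TRUE
      }
    }
    list(counts = counts, is_spike = is_spike)
  })
}

# uniform points in a ball of radius R centered at the origin
.runif_ball <- function(n, R) {
  u <- stats::runif(n)^(1 / 3)
  v <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - v^2))
  R * u * cbind(s * cos(phi), s * sin(phi), v)
}

#' Synthetic FISH nuclei with controlled association frequency
#'
#' Generates spherical nuclei of the given volume, each with two spots per
#' channel.  The focal channel's first spot sits at the nucleus center (so
#' the analytic sphere-volume association probability applies exactly,
#' without boundary truncation); the partner channel's first spot is
#' uniform in the nucleus, except that with probability
#' `association_fraction` it is placed uniformly within
#' `association_radius` of the focal spot.  Second-allele spots of every
#' channel are uniform in the nucleus.  Spot 1 of each channel is the
#' designated primary spot (`spot` column).
#'
#' @param n_nuclei Number of nuclei.
#' @param nuclear_volume Volume in cubic micrometers (default 60).
#' @param association_fraction Fraction of nuclei with a true association
#'   (in `[0, 1]`).
#' @param association_radius Radius in micrometers (default 1.0; must be
#'   smaller than the nuclear radius).
#' @param channels Channel labels (>= 2; first is focal).
#' @param seed Seed.
#' @return Spot data.frame (`nucleus_id`, `channel`, `spot`, `x`, `y`, `z`)
#'   with attribute `associated` (ground-truth logical per nucleus).
#' @export
synth_fish_nuclei <- function(n_nuclei, nuclear_volume = 60,
                              association_fraction = 0,
                              association_radius = 1.0,
                              channels = c("green", "red"), seed = 1) {
  stopifnot(association_fraction >= 0, association_fraction <= 1,
            length(channels) >= 2)
  R <- (3 * nuclear_volume / (4 * pi))^(1 / 3)
  if (association_radius >= R) stop("association radius exceeds nuclear radius")
  .with_seed(seed, {
    assoc <- stats::runif(n_nuclei) < association_fraction
    rows <- vector("list", length(channels) * 2)
    ri <- 1
    for (ci in seq_along(channels)) {
      for (sp in 1:2) {
        if (ci == 1 && sp == 1) {
          xyz <- matrix(0, n_nuclei, 3)          # focal spot at the center
        } else {
          xyz <- .runif_ball(n_nuclei, R)
        }
        rows[[ri]] <- data.frame(nucleus_id = seq_len(n_nuclei),
                                 channel = channels[ci], spot = sp,
                                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
        ri <- ri + 1
      }
    }
    # overwrite the primary spot of every partner channel for associated
    # nuclei: uniform in the r-ball around the (centered) focal spot
    for (ch in channels[-1]) {
      prim <- which(vapply(rows, function(df)
        df$channel[1] == ch && df$spot[1] == 1, logical(1)))
      rows[[prim]][assoc, c("x", "y", "z")] <- .runif_ball(sum(assoc),
                                                           association_radius)
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$nucleus_id, out$channel, out$spot), ]
    rownames(out) <- NULL
    attr(out, "associated") <- assoc
    out
  })
}

#' Synthetic contact-pair records from a probability map
#'
#' Draws `n_pairs` bin pairs with probability proportional to the map's
#' upper triangle (diagonal included) and places each end uniformly within
#' its bin, producing records that re-bin to the map's relative frequencies
#' within multinomial error.
#'
#' @param probability_map Symmetric non-negative matrix over the scheme's
#'   bins.
#' @param n_pairs Number of pairs to draw.
#' @param scheme A [binning_scheme()].
#' @param seed Seed.
#' @return Contact-pair data.frame (`chrom_a`, `pos_a`, `chrom_b`, `pos_b`).
#' @export
synth_contact_pairs <- function(probability_map, n_pairs, scheme, seed = 1) {
  m <- as.matrix(probability_map)
  n <- nrow(m)
  stopifnot(n == scheme$n_bins)
  w <- m
  w[lower.tri(w)] <- 0
  if (sum(w) <= 0) stop("all-zero probability map")
  idx <- which(w > 0)
  .with_seed(seed, {
    draw <- idx[sample.int(length(idx), n_pairs, replace = TRUE,
                           prob = w[idx])]
    i <- ((draw - 1) %% n) + 1
    j <- ((draw - 1) %/% n) + 1
    pos_in_bin <- function(b) {
      lo <- scheme$start + (b - 1) * scheme$bin_size
      hi <- pmin(lo + scheme$bin_size, scheme$end)
      floor(stats::runif(length(b), lo, hi)) + 1
    }
    data.frame(chrom_a = scheme$chrom, pos_a = pos_in_bin(i),
               chrom_b = scheme$chrom, pos_b = pos_in_bin(j))
  })
}
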