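#' Coarse-grained polymer model parameters
#'
#' Beads-on-a-string chain in which each bead stands for one 20-kb chromatin
#' bin.  Lengths are expressed in units of the bond length `a`; the thermal
#' energy is fixed at kT = 1.  Nonbonded beads interact through a spherical
#' well: infinitely repulsive below `hardcore_radius`, constant depth
#' `eps[i, j]` up to (but excluding) `interaction_radius`, zero beyond.
#' Consecutive beads are joined by stiff harmonic bonds
#' `U = bond_stiffness * (d - a)^2`.
#'
#' @param n_beads Number of beads (>= 2).
#' @param interaction_radius Well outer radius, default 1.5 (units of a).
#' @param hardcore_radius Hard-core radius, default 0.6.
#' @param bond_stiffness Harmonic bond constant in kT/a^2, default 100.
#' @return An object of class `model_params`.
#' @export
model_params <- function(n_beads, interaction_radius = 1.5,
                         hardcore_radius = 0.6, bond_stiffness = 100) {
  n_beads <- as.integer(n_beads)
  stopifnot(n_beads >= 2)
  if (!(hardcore_radius < 1 && 1 < interaction_radius)) {
    stop("require hardcore_radius < bond length (1) < interaction_radius")
  }
  structure(list(n_beads = n_beads, interaction_radius = interaction_radius,
                 hardcore_radius = hardcore_radius,
                 bond_stiffness = bond_stiffness),
            class = "model_params")
}

#' Spherical-well pair potential
#'
#' @param d Distance(s) in units of a (non-negative).
#' @param eps Well depth(s) in kT (<= 0 for attraction).
#' @param params A [model_params()].
#' @return Energy in kT: `Inf` below the hard core, `eps` inside the well
#'   `[hardcore, interaction)`, 0 at or beyond the interaction radius.
#' @export
pair_potential <- function(d, eps, params) {
  if (any(d < 0)) stop("distance must be non-negative")
  out <- ifelse(d < params$hardcore_radius, Inf,
                ifelse(d < params$interaction_radius, eps, 0))
  out
}

#' Total energy of a conformation
#'
#' Sum of the spherical-well energy over all pairs with `|i - j| >= 2` plus
#' harmonic bond energy over consecutive pairs.  Any hard-core violation
#' (any pair, bonded included) yields `Inf`.
#'
#' @param coords n x 3 coordinate matrix (units of a).
#' @param eps n x n symmetric well-depth matrix (kT).
#' @param params A [model_params()].
#' @return Energy in kT.
#' @export
total_energy <- function(coords, eps, params) {
  n <- nrow(coords)
  dm <- as.matrix(stats::dist(coords))
  if (any(dm[upper.tri(dm)] < params$hardcore_radius)) return(Inf)
  sep <- abs(row(dm) - col(dm))
  ut <- upper.tri(dm)
  well <- ut & sep >= 2 & dm < params$interaction_radius
  bond <- ut & sep == 1
  sum(eps[well]) + params$bond_stiffness * sum((dm[bond] - 1)^2)
}

#' Sample a conformational ensemble by Metropolis Monte Carlo
#'
#' Runs a single Markov chain with 1:1 single-bead Gaussian displacements
#' (width tuned toward ~40% acceptance during the first half of burn-in) and
#' crankshaft rotations of short internal segments, then records snapshots at
#' a fixed thinning interval.  All randomness uses R's RNG, so a given
#' `seed` yields a bit-identical ensemble.
#'
#' @param energies n x n symmetric well-depth matrix (kT, entries <= 0).
#' @param params A [model_params()]; defaults to `model_params(nrow(energies))`.
#' @param n_structures Number of conformations to record (default 5001, the
#'   ensemble size used for locus-scale analyses).
#' @param seed Integer seed; recorded in the ensemble's provenance.
#' @param burnin_sweeps Equilibration sweeps (default `200 * n_beads`).
#' @param thin_sweeps Sweeps between snapshots (default `20 * n_beads`).
#' @param max_segment Longest crankshaft segment, in beads (default 8).
#' @return An object of class `polymer_ensemble`: list with `coords` (array
#'   `n_structures x n_beads x 3`), `params`, `seed`, and sampler
#'   diagnostics in `provenance`.
#' @export
mc_sample <- function(energies, params = model_params(nrow(energies)),
                      n_structures = 5001, seed = 1,
                      burnin_sweeps = 200 * params$n_beads,
                      thin_sweeps = 20 * params$n_beads,
                      max_segment = 8) {
  energies <- as.matrix(energies)
  n <- params$n_beads
  stopifnot(nrow(energies) == n, ncol(energies) == n, n_structures >= 1)
  if (max(abs(energies - t(energies))) > 1e-9) stop("energies must be symmetric")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  res <- .mc_sample_cpp(energies, as.integer(n_structures),
                        as.integer(burnin_sweeps), as.integer(thin_sweeps),
                        params$hardcore_radius, params$interaction_radius,
                        params$bond_stiffness, 0.3, as.integer(max_segment))
  for (nm in c("accept_displacement", "accept_crankshaft")) {
    r <- res[[nm]]
    if (is.finite(r) && (r < 0.05 || r > 0.95)) {
      warning(sprintf("%s acceptance rate %.2f outside [0.05, 0.95]", nm, r))
    }
  }
  structure(list(coords = res$coords, params = params, seed = seed,
                 provenance = list(accept_displacement = res$accept_displacement,
                                   accept_crankshaft = res$accept_crankshaft,
                                   sigma = res$sigma,
                                   burnin_sweeps = burnin_sweeps,
                                   thin_sweeps = thin_sweeps)),
            class = "polymer_ensemble")
}

#' @export
print.polymer_ensemble <- function(x, ...) {
  cat(sprintf("polymer_ensemble: %d conformations of %d beads (seed %s)\n",
              dim(x$coords)[1], dim(x$coords)[2], format(x$seed)))
  invisible(x)
}

#' Number of conformations in an ensemble
#' @param x A `polymer_ensemble`.
#' @export
n_conformations <- function(x) dim(x$coords)[1]

#' Extract one conformation's coordinate matrix
#' @param ensemble A `polymer_ensemble`.
#' @param i Conformation index.
#' @return n x 3 matrix.
#' @export
conformation <- function(ensemble, i) {
  matrix(ensemble$coords[i, , ], ncol = 3)
}

#' Ensemble contact-probability map
#'
#' Entry (i, j) is the fraction of conformations in which beads i and j lie
#' closer than `contact_radius` (strict inequality); the diagonal is 1.
#' Bonded neighbours are included — the contact definition is the bare
#' distance rule.
#'
#' @param ensemble A `polymer_ensemble`.
#' @param contact_radius Contact distance threshold (default 1.5a).
#' @return Symmetric matrix of contact probabilities in `[0, 1]`.
#' @export
ensemble_contact_map <- function(ensemble, contact_radius = 1.5) {
  stopifnot(n_conformations(ensemble) >= 1)
  .contact_map_cpp(ensemble$coords, contact_radius)
}

#' Write / read an ensemble as multi-frame XYZ-like text
#'
#' Each frame is: a line with the bead count, a comment line
#' `frame <i> seed <seed>`, then one `x y z` line per bead with 9
#' significant digits (so write/read round-trips are exact at that
#' precision).
#'
#' @param ensemble A `polymer_ensemble`.
#' @param path Output path.
#' @export
write_ensemble_xyz <- function(ensemble, path) {
  S <- n_conformations(ensemble)
  n <- dim(ensemble$coords)[2]
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seq_len(S)) {
    writeLines(c(format(n), sprintf("frame %d seed %s", s,
                                    format(ensemble$seed))), con)
    cm <- conformation(ensemble, s)
    writeLines(sprintf("%.9g %.9g %.9g", cm[, 1], cm[, 2], cm[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_ensemble_xyz
#' @param params Optional [model_params()] to attach (defaults to bead count
#'   read from the file).
#' @return `read_ensemble_xyz()` returns a `polymer_ensemble`.
#' @export
read_ensemble_xyz <- function(path, params = NULL) {
  lines <- readLines(path)
  pos <- 1
  frames <- list()
  seed <- NA
  while (pos <= length(lines)) {
    n <- as.integer(lines[pos])
    cm <- lines[pos + 1]
    if (grepl("seed", cm)) seed <- sub(".*seed\\s+", "", cm)
    block <- lines[(pos + 2):(pos + 1 + n)]
    xyz <- matrix(as.numeric(unlist(strsplit(block, "\\s+"))), ncol = 3,
                  byrow = TRUE)
    frames[[length(frames) + 1]] <- xyz
    pos <- pos + 2 + n
  }
  S <- length(frames)
  n <- nrow(frames[[1]])
  coords <- array(0, c(S, n, 3))
  for (s in seq_len(S)) coords[s, , ] <- frames[[s]]
  if (is.null(params)) params <- model_params(n)
  sd <- suppressWarnings(as.numeric(seed))
  structure(list(coords = coords, params = params,
                 seed = if (is.na(sd)) NA else sd,
                 provenance = list(source = path)),
            class = "polymer_ensemble")
}
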