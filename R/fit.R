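#' Rescale a balanced contact matrix to contact probabilities
#'
#' Experimental interaction frequencies are on an arbitrary scale; the
#' polymer model works in contact probabilities.  The target is obtained by
#' one global scale factor, chosen so that the mean of the unmasked entries
#' at separation `|i - j| = 2` matches the mean simulated by the neutral
#' (all well depths zero) homopolymer at the same separation; entries are
#' then clipped at 1.  Short-range geometry is fixed by the bonds, which is
#' why the nearest free separation anchors the scale.
#'
#' @param matrix A balanced `contact_matrix` (with mask).
#' @param params A [model_params()] matching the matrix's bin count.
#' @param seed Seed for the homopolymer calibration ensemble.
#' @param n_structures Size of the calibration ensemble (default 400).
#' @param reference_map Optional precomputed homopolymer contact map (skips
#'   the calibration simulation).
#' @return List of class `target_map`: `p` (probability matrix), `eligible`
#'   (logical matrix: unmasked pairs with `|i - j| >= 2`), `scale`.
#' @export
prepare_target <- function(matrix, params, seed = 1, n_structures = 400,
                           reference_map = NULL) {
  v <- matrix$values
  n <- nrow(v)
  stopifnot(params$n_beads == n)
  keep <- matrix$mask
  sep <- abs(row(v) - col(v))
  sel <- sep == 2 & outer(keep, keep, "&")
  if (!any(sel) || mean(v[sel]) == 0) {
    stop("no unmasked entries at separation 2 to anchor the probability scale")
  }
  if (is.null(reference_map)) {
    ref <- mc_sample(matrix(0, n, n), params, n_structures = n_structures,
                     seed = seed)
    reference_map <- ensemble_contact_map(ref, params$interaction_radius)
  }
  scale <- mean(reference_map[sep == 2]) / mean(v[sel])
  p <- pmin(v * scale, 1)
  eligible <- sep >= 2 & outer(keep, keep, "&")
  p[!outer(keep, keep, "&")] <- 0
  structure(list(p = p, eligible = eligible, scale = scale),
            class = "target_map")
}

#' Goodness of fit between simulated and target contact maps
#'
#' Pearson correlation over the eligible upper-triangle entries (unmasked,
#' `|i - j| >= 2`; bonded and self pairs are fixed by the chain geometry and
#' carry no information about the wells).
#'
#' @param sim_map,target_p Matrices of identical shape.
#' @param eligible Logical matrix of eligible entries.
#' @return Pearson r.
#' @export
goodness_of_fit <- function(sim_map, target_p, eligible) {
  sel <- eligible & upper.tri(sim_map)
  if (sum(sel) < 3) stop("fewer than 3 eligible entries")
  stats::cor(sim_map[sel], target_p[sel])
}

#' Fit spherical-well depths to a target contact map
#'
#' Inverse modeling by iterative-Boltzmann-style updates: at each iteration
#' an ensemble is simulated under the current energies, its contact map
#' `p_sim` is measured, and every eligible pair is moved by
#' `eps <- clip(eps + eta * log((p_sim + delta) / (p_target + delta)),
#' c(eps_min, 0))`.  Pairs observed less often than targeted get deeper
#' (more attractive) wells.  Each iteration uses a fresh sub-seed so the
#' optimization cannot overfit one sample.
#'
#' @param target A `target_map` from [prepare_target()], or a plain
#'   probability matrix (all `|i - j| >= 2` pairs then eligible).
#' @param params A [model_params()].
#' @param n_iterations Maximum iterations (default 40).
#' @param ensemble_size Structures per iteration (default 300).
#' @param eta Learning rate in kT per log-unit (default 0.3).
#' @param delta Pseudocount; default `1 / (2 * ensemble_size)`.
#' @param eps_min Lower bound on well depths in kT (default -5).
#' @param convergence_r Stop once the fit reaches this Pearson r (default
#'   0.98).
#' @param seed Base seed; iteration i simulates with `seed + i`.
#' @param burnin_sweeps,thin_sweeps Per-iteration sampling schedule
#'   (defaults `100 * n_beads` and `10 * n_beads`; lighter than the
#'   standalone [mc_sample()] defaults because each iteration only needs a
#'   rough probability estimate).
#' @param mask Optional logical vector of valid beads; masked beads' rows
#'   stay at zero.
#' @return An object of class `polymer_fit` with components `energies`,
#'   `trace` (per-iteration data.frame: r, mean |change|, acceptance),
#'   `target`, `params`, `config`, and the final iteration's simulated map
#'   `fitted_map`.
#' @seealso [coef.polymer_fit()], [predict.polymer_fit()],
#'   [simulate.polymer_fit()], [residuals.polymer_fit()]
#' @export
fit_polymer <- function(target, params, n_iterations = 40, ensemble_size = 300,
                        eta = 0.3, delta = 1 / (2 * ensemble_size),
                        eps_min = -5, convergence_r = 0.98, seed = 1,
                        burnin_sweeps = 100 * params$n_beads,
                        thin_sweeps = 10 * params$n_beads, mask = NULL) {
  if (!inherits(target, "target_map")) {
    p <- as.matrix(target)
    sep <- abs(row(p) - col(p))
    target <- structure(list(p = p, eligible = sep >= 2, scale = 1),
                        class = "target_map")
  }
  n <- params$n_beads
  stopifnot(nrow(target$p) == n, eta > 0, delta > 0, eps_min < 0)
  eligible <- target$eligible
  if (!is.null(mask)) {
    eligible <- eligible & outer(mask, mask, "&")
  }
  if (!any(eligible)) stop("no eligible pairs to fit")
  eps <- matrix(0, n, n)
  trace <- data.frame(iteration = integer(), r = numeric(),
                      mean_abs_step = numeric(), accept = numeric())
  sim_map <- NULL
  worse <- 0L
  best_r <- -Inf
  for (it in seq_len(n_iterations)) {
    ens <- mc_sample(eps, params, n_structures = ensemble_size,
                     seed = seed + it, burnin_sweeps = burnin_sweeps,
                     thin_sweeps = thin_sweeps)
    sim_map <- ensemble_contact_map(ens, params$interaction_radius)
    r <- goodness_of_fit(sim_map, target$p, eligible)
    step <- eta * log((sim_map + delta) / (target$p + delta))
    step[!eligible] <- 0
    new_eps <- pmin(pmax(eps + step, eps_min), 0)
    new_eps <- (new_eps + t(new_eps)) / 2
    diag(new_eps) <- 0
    trace <- rbind(trace, data.frame(
      iteration = it, r = r,
      mean_abs_step = mean(abs(new_eps - eps)[eligible]),
      accept = ens$provenance$accept_displacement))
    prev_r <- if (it > 1) trace$r[it - 1] else -Inf
    worse <- if (it > 1 && r < prev_r) worse + 1L else 0L
    best_r <- max(best_r, r)
    # sustained deterioration, not Monte-Carlo wobble around a plateau
    if (worse >= 5L && r < best_r - 0.05) {
      err <- simpleError("fit diverging: r decreased for 5 consecutive iterations")
      err$trace <- trace
      stop(err)
    }
    eps <- new_eps
    if (r >= convergence_r) break
  }
  structure(list(energies = eps, trace = trace, target = target,
                 params = params, fitted_map = sim_map,
                 config = list(n_iterations = n_iterations,
                               ensemble_size = ensemble_size, eta = eta,
                               delta = delta, eps_min = eps_min,
                               convergence_r = convergence_r, seed = seed)),
            class = "polymer_fit")
}

#' @export
print.polymer_fit <- function(x, ...) {
  k <- nrow(x$trace)
  cat(sprintf("polymer_fit: %d beads, %d iteration(s), final r = %.3f\n",
              x$params$n_beads, k, x$trace$r[k]))
  cat(sprintf("well depths in [%.2f, %.2f] kT (eps_min = %g)\n",
              min(x$energies), max(x$energies), x$config$eps_min))
  invisible(x)
}

#' @export
summary.polymer_fit <- function(object, ...) {
  k <- nrow(object$trace)
  el <- object$target$eligible & upper.tri(object$energies)
  out <- list(
    n_beads = object$params$n_beads,
    iterations = k,
    final_r = object$trace$r[k],
    eps_quantiles = stats::quantile(object$energies[el],
                                    c(0, .05, .25, .5, .75, .95, 1)),
    trace = object$trace)
  class(out) <- "summary.polymer_fit"
  out
}

#' @export
print.summary.polymer_fit <- function(x, ...) {
  cat(sprintf("Inverse polymer fit over %d beads (%d iterations)\n",
              x$n_beads, x$iterations))
  cat(sprintf("Final goodness of fit (Pearson r, |i-j| >= 2): %.4f\n", x$final_r))
  cat("Fitted well depths (kT), eligible pairs:\n")
  print(round(x$eps_quantiles, 3))
  invisible(x)
}

#' Fitted well-depth matrix
#' @param object A `polymer_fit`.
#' @param ... Ignored.
#' @return The n x n energy matrix (kT).
#' @export
coef.polymer_fit <- function(object, ...) object$energies

#' Simulate an ensemble from a fitted model
#' @param object A `polymer_fit`.
#' @param nsim Number of conformations (default 5001).
#' @param seed Seed for the simulation (default the fit's base seed).
#' @param ... Passed to [mc_sample()].
#' @return A `polymer_ensemble`.
#' @export
simulate.polymer_fit <- function(object, nsim = 5001, seed = object$config$seed,
                                 ...) {
  mc_sample(object$energies, object$params, n_structures = nsim, seed = seed,
            ...)
}

#' Predicted contact-probability map of a fitted model
#'
#' Either returns the last fitting iteration's simulated map (fast) or
#' simulates a fresh, larger ensemble.
#'
#' @param object A `polymer_fit`.
#' @param nsim If `NULL` (default), reuse the final iteration's map;
#'   otherwise simulate `nsim` fresh conformations.
#' @param seed Seed for a fresh simulation.
#' @param ... Passed to [mc_sample()].
#' @return Contact-probability matrix.
#' @export
predict.polymer_fit <- function(object, nsim = NULL, seed = object$config$seed,
                                ...) {
  if (is.null(nsim)) return(object$fitted_map)
  ensemble_contact_map(simulate(object, nsim = nsim, seed = seed, ...),
                       object$params$interaction_radius)
}

#' Residual map (target minus fitted contact probabilities)
#' @param object A `polymer_fit`.
#' @param ... Ignored.
#' @return Matrix of residuals, `NA` on ineligible entries.
#' @export
residuals.polymer_fit <- function(object, ...) {
  r <- object$target$p - object$fitted_map
  r[!object$target$eligible] <- NA
  r
}

#' Plot a fitted polymer model
#'
#' Side-by-side image of the target and fitted contact maps plus the fitting
#' trace.
#'
#' @param x A `polymer_fit`.
#' @param ... Ignored.
#' @export
plot.polymer_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  graphics::image(x$target$p, main = "target", col = pal, axes = FALSE)
  graphics::image(x$fitted_map, main = "fitted", col = pal, axes = FALSE)
  graphics::plot(x$trace$iteration, x$trace$r, type = "b", xlab = "iteration",
                 ylab = "Pearson r", main = "fit trace")
  invisible(x)
}

#' Write / read a dense numeric matrix TSV (energies, probability maps)
#'
#' Plain dense TSV with `bead_<i>` row/column labels.
#'
#' @param m Numeric matrix.
#' @param path File path.
#' @export
write_matrix_tsv <- function(m, path) {
  lab <- sprintf("bead_%d", seq_len(nrow(m)))
  df <- data.frame(bead = lab, m)
  names(df) <- c("bead", lab)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  unname(as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                     row.names = 1, check.names = FALSE)))
}
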