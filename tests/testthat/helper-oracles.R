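# Independent oracles used by the tests.  These deliberately do not share
# code with the package: the quadrature oracle integrates the two-bond
# chain's Boltzmann weight on a grid, and the balancing oracle is a plain
# fixed-point iteration written directly from the definition.

# Boltzmann statistics of a 3-bead chain (bonds harmonic, hard core on all
# pairs, optional well of depth eps on the 1-3 pair), by direct numerical
# integration over (r1, r2, cos theta) with measure r1^2 r2^2 dr1 dr2 dcos.
# Returns the 1-3 contact probability and an interpolated CDF of d13.
quadrature_3bead <- function(eps = 0, kb = 100, hardcore = 0.6, well = 1.5,
                             nr = 301, nc = 801, nd = 2881) {
  r1 <- seq(hardcore, 1.8, length.out = nr)
  cth <- seq(-1, 1, length.out = nc)
  g <- function(r) r^2 * exp(-kb * (r - 1)^2)
  W <- outer(g(r1), g(r1))
  dgrid <- seq(0, 3.6, length.out = nd)
  hist_w <- numeric(nd + 1)
  tot <- 0
  inwell <- 0
  for (ci in seq_along(cth)) {
    d <- sqrt(pmax(0, outer(r1^2, r1^2, "+") - 2 * outer(r1, r1) * cth[ci]))
    ok <- d >= hardcore
    wl <- ok & d < well
    w <- W * ok * exp(-eps * wl)
    tot <- tot + sum(w)
    inwell <- inwell + sum(w * wl)
    bins <- findInterval(as.vector(d), dgrid) + 1
    rs <- rowsum(as.vector(w), bins)
    hist_w[as.integer(rownames(rs))] <- hist_w[as.integer(rownames(rs))] + rs[, 1]
  }
  list(p_contact = inwell / tot,
       cdf = approxfun(dgrid, cumsum(hist_w)[seq_len(nd)] / tot,
                       yleft = 0, yright = 1))
}

# plain alternating row/column scaling run to a tight fixed point; returns
# the balanced matrix rescaled to the input mass
ice_oracle <- function(m, tol = 1e-10, max_iter = 10000) {
  mass <- sum(m)
  for (i in seq_len(max_iter)) {
    m <- m / rowSums(m)
    m <- sweep(m, 2, colSums(m), "/")
    m <- (m + t(m)) / 2
    rs <- rowSums(m)
    if ((max(rs) - min(rs)) / min(rs) < tol) break
  }
  m * mass / sum(m)
}

# build a polymer_ensemble object directly from a list of n x 3 matrices,
# bypassing the sampler, for hand-computed fixtures
frozen_ensemble <- function(conformations, params = NULL) {
  S <- length(conformations)
  n <- nrow(conformations[[1]])
  coords <- array(0, c(S, n, 3))
  for (s in seq_len(S)) coords[s, , ] <- conformations[[s]]
  if (is.null(params)) params <- ighfold::model_params(max(n, 2))
  structure(list(coords = coords, params = params, seed = NA,
                 provenance = list(source = "frozen")),
            class = "polymer_ensemble")
}

# straight chain along x at unit spacing
straight_chain <- function(n) cbind(seq_len(n) - 1, 0, 0)

# exhaustive two-sided Fisher p for a 2x2 table by hypergeometric enumeration
fisher_enum <- function(k_a, n_a, k_b, n_b) {
  k <- k_a + k_b
  supp <- max(0, k - n_b):min(n_a, k)
  pr <- dhyper(supp, n_a, n_b, k)
  sum(pr[pr <= dhyper(k_a, n_a, n_b, k) * (1 + 1e-7)])
}
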