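toy_annotation <- function(n, vh, dh) {
  cls <- rep("none", n)
  cls[vh] <- "VH"
  cls[dh] <- "DH"
  bead_annotation(seq_len(n), cls)
}

test_that("partners_per_bead counts neighbours within the contact radius", {
  ens <- frozen_ensemble(list(straight_chain(6)))
  pp <- partners_per_bead(ens)
  expect_equal(pp, c(1, 2, 2, 2, 2, 1))
  expect_true(all(pp <= 5))
  # hand-averaged over two conformations: chain, and chain with bead 4
  # moved within 1.5a of bead 1
  bent <- straight_chain(6); bent[4, ] <- c(1, 1, 0)
  # bent distances from bead 4: to 1 sqrt(2)<1.5, 2 1<1.5, 3 sqrt(2)<1.5,
  # to 5 sqrt(10)>1.5 -> bead-1 partners: chain 1, bent 2 -> mean 1.5
  ens2 <- frozen_ensemble(list(straight_chain(6), bent))
  expect_equal(partners_per_bead(ens2)[1], 1.5)
})

test_that("vd_stats computes VH fractions and conserves contact events", {
  # toy: DH = {1}, VH = {3,4,5}; bead 3 within radius of 1, beads 4,5 not
  conf <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0), c(3, 1, 0))
  ens <- frozen_ensemble(list(conf))
  ann <- toy_annotation(5, vh = 3:5, dh = 1)
  vs <- vd_stats(ens, ann)
  expect_equal(vs$vh_fraction, 1 / 3)
  expect_equal(sum(vs$per_d), sum(vs$per_v))
  expect_equal(unname(vs$per_v), c(1, 0, 0))

  # no V-D contact anywhere
  far <- straight_chain(8)
  ens0 <- frozen_ensemble(list(far))
  ann0 <- toy_annotation(8, vh = 6:8, dh = 1)
  vs0 <- vd_stats(ens0, ann0)
  expect_equal(vs0$vh_fraction, 0)
  expect_true(all(vs0$per_d == 0) && all(vs0$per_v == 0))

  # conservation on a random ensemble
  ensr <- suppressWarnings(mc_sample(matrix(-0.4, 12, 12) + diag(0.4, 12),
                                     model_params(12), n_structures = 150,
                                     seed = 3))
  annr <- toy_annotation(12, vh = 7:12, dh = 2:4)
  vsr <- vd_stats(ensr, annr)
  expect_equal(sum(vsr$per_d), sum(vsr$per_v))
  expect_true(all(vsr$vh_fraction >= 0 & vsr$vh_fraction <= 1))

  expect_error(vd_stats(ens, toy_annotation(5, vh = 3:5, dh = integer())),
               "DH")
})

test_that("center_of_mass is the coordinate average and is equivariant", {
  cm <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(center_of_mass(cm), c(1, 0, 0))
  expect_equal(center_of_mass(cm, subset = 2), c(2, 0, 0))
  t3 <- c(-1, 5, 2)
  shifted <- sweep(cm, 2, -t3)
  expect_equal(center_of_mass(shifted), center_of_mass(cm) + t3)
  expect_error(center_of_mass(cm, subset = integer()), "empty")
})

test_that("cm_distance_profiles averages distances to CM and CMv", {
  # single conformation, beads at (+-1, 0, 0): both 1 from the CM
  conf <- rbind(c(-1, 0, 0), c(1, 0, 0))
  ann <- toy_annotation(2, vh = 1:2, dh = integer())
  ann$element_class[1:2] <- "VH"
  prof <- cm_distance_profiles(frozen_ensemble(list(conf)), ann)
  expect_equal(prof$dist_cm, c(1, 1))
  # VH = all beads: the two profiles coincide
  expect_equal(prof$dist_cm, prof$dist_cmv)

  # two-conformation hand oracle with a proper VH subset
  c1 <- straight_chain(4)
  c2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  ann2 <- toy_annotation(4, vh = 3:4, dh = 1)
  prof2 <- cm_distance_profiles(frozen_ensemble(list(c1, c2)), ann2)
  hand <- sapply(1:4, function(b) {
    mean(sapply(list(c1, c2), function(cc) {
      sqrt(sum((cc[b, ] - colMeans(cc))^2))
    }))
  })
  expect_equal(prof2$dist_cm, hand)
  hand_v <- sapply(1:4, function(b) {
    mean(sapply(list(c1, c2), function(cc) {
      sqrt(sum((cc[b, ] - colMeans(cc[3:4, , drop = FALSE]))^2))
    }))
  })
  expect_equal(prof2$dist_cmv, hand_v)
})

test_that("conditional CMv distances flag empty conditioning subsets", {
  c1 <- straight_chain(4)
  c2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  c3 <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 1, 0), c(2, 2, 0))
  ann <- toy_annotation(4, vh = 3:4, dh = 1)
  ens <- frozen_ensemble(list(c1, c2, c3))
  # bead 2 and bead 3 in contact in c2 (d=1) and c3 (d=sqrt(2)) but not c1 (d=1? no: c1 d(2,3)=1 -> contact!)
  # use beads 1 and 4 instead: c1 d=3 no; c2 d=1 yes; c3 d=sqrt(8) no
  res <- conditional_cmv_distance(ens, ann, bead = 1, partner = 4)
  expect_equal(res$n_subset, 1L)
  cmv2 <- colMeans(c2[3:4, ])
  expect_equal(res$mean_dist, sqrt(sum((c2[1, ] - cmv2)^2)))
  # never-in-contact partner: explicit undefined, not silent zero
  far <- conditional_cmv_distance(frozen_ensemble(list(c1)), ann, 1, 4)
  expect_true(is.na(far$mean_dist))
  expect_equal(far$n_subset, 0L)
  # always-in-contact partner equals the unconditional mean
  always <- conditional_cmv_distance(ens, ann, bead = 1, partner = 2)
  expect_equal(always$n_subset, 3L)
  uncond <- mean(sapply(list(c1, c2, c3), function(cc)
    sqrt(sum((cc[1, ] - colMeans(cc[3:4, ]))^2))))
  expect_equal(always$mean_dist, uncond)
})

test_that("vh_contact_fraction is a bounded per-bead average", {
  # frozen straight chain, all beads VH: interior bead touches 2 of n-1
  n <- 7
  cls <- rep("VH", n)
  ann <- bead_annotation(seq_len(n), cls)
  ens <- frozen_ensemble(list(straight_chain(n)))
  fr <- vh_contact_fraction(ens, ann)
  expect_equal(fr[4], 2 / (n - 1))
  expect_equal(fr[1], 1 / (n - 1))
  expect_true(all(fr >= 0 & fr <= 1))

  # two-conformation hand computation on a mixed annotation
  c1 <- straight_chain(5)
  c2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0), c(-1, 1, 0))
  ann2 <- toy_annotation(5, vh = c(2, 4, 5), dh = 1)
  fr2 <- vh_contact_fraction(frozen_ensemble(list(c1, c2)), ann2)
  hand_b1 <- mean(sapply(list(c1, c2), function(cc) {
    mean(sqrt(rowSums(sweep(cc[c(2, 4, 5), , drop = FALSE], 2, cc[1, ])^2)) < 1.5)
  }))
  expect_equal(fr2[1], hand_b1)
})

test_that("conformation clustering separates structure classes", {
  # 5 copies of one structure + 1 distinct: two clusters, largest of size 5
  a <- straight_chain(6)
  b <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0), c(0, 2, 0),
             c(1, 2, 0))
  ens <- frozen_ensemble(c(replicate(5, a, simplify = FALSE), list(b)))
  cl <- cluster_conformations(ens, method = "rmsd", k = 2)
  expect_equal(max(cl$sizes), 5)
  expect_equal(length(unique(cl$labels[1:5])), 1)
  expect_error(cluster_conformations(ens, k = 10), "exceeds")

  # rigid rotation+translation has zero rmsd dissimilarity
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0), c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  a_rot <- a %*% R + matrix(c(5, 5, 5), 6, 3, byrow = TRUE)
  ens2 <- frozen_ensemble(list(a, a_rot))
  cl2 <- cluster_conformations(ens2, method = "rmsd", k = 1)
  expect_lt(max(cl2$dissimilarity), 1e-8)

  # dissimilarity matches the direct formula on 3 hand structures
  c3 <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0.5, 0), c(2.5, 1.5, 0),
              c(2, 2.5, 0), c(1, 2.5, 0))
  ens3 <- frozen_ensemble(list(a, b, c3))
  dd <- as.matrix(cluster_conformations(ens3, method = "rmsd", k = 1)$dissimilarity)
  direct <- function(x, y) {
    dx <- as.vector(dist(x)); dy <- as.vector(dist(y))
    sqrt(mean((dx - dy)^2))
  }
  expect_equal(dd[1, 2], direct(a, b), tolerance = 1e-12)
  expect_equal(dd[1, 3], direct(a, c3), tolerance = 1e-12)
  expect_equal(dd[2, 3], direct(b, c3), tolerance = 1e-12)

  # contact-overlap flavour runs and respects invariance too
  cl4 <- cluster_conformations(ens2, method = "contact_overlap", k = 1)
  expect_lt(max(cl4$dissimilarity), 1e-12)
})

test_that("clustering a 50/50 mixture of energy regimes recovers the labels", {
  # open homopolymer vs collapsed globule, 30 structures each
  n <- 16
  p <- model_params(n)
  open_e <- suppressWarnings(mc_sample(matrix(0, n, n), p,
                                       n_structures = 30, seed = 11))
  compact <- matrix(-1.2, n, n); diag(compact) <- 0
  closed_e <- suppressWarnings(mc_sample(compact, p, n_structures = 30,
                                         seed = 12))
  mix <- open_e
  mix$coords <- array(0, c(60, n, 3))
  mix$coords[1:30, , ] <- open_e$coords
  mix$coords[31:60, , ] <- closed_e$coords
  truth <- rep(1:2, each = 30)
  cl <- cluster_conformations(mix, method = "rmsd", linkage = "ward.D2",
                              k = 2)
  purity <- max(mean(cl$labels == truth), mean(cl$labels == 3 - truth))
  expect_gte(purity, 0.9)
})

test_that("spearman_cor handles ties, direction, and degenerate input", {
  expect_equal(spearman_cor(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)
  # tied example against exhaustive average-rank computation
  x <- c(1, 2, 2, 3, 5, 5, 5, 8)
  y <- c(2, 1, 4, 4, 6, 7, 7, 9)
  got <- spearman_cor(x, y)
  rho_direct <- cor(rank(x), rank(y))
  expect_equal(got$rho, rho_direct)
  expect_true(got$p >= 0 && got$p <= 1)
  # NA pairs dropped pairwise
  xna <- c(x, NA); yna <- c(y, 3)
  expect_equal(spearman_cor(xna, yna)$n, 8)
  # constant input: undefined, flagged
  expect_true(is.na(spearman_cor(rep(1, 5), 1:5)$rho))
})

test_that("the Igh annotation fixture matches the locus landmarks", {
  ann <- igh_annotation()
  expect_equal(nrow(ann), 156)
  expect_equal(beads_of_class(ann, "VH"), 24:146)
  expect_equal(beads_of_class(ann, "CBE3prime"), 6)
  expect_equal(beads_of_class(ann, "IGCR1"), 19)
  expect_equal(beads_of_class(ann, "DH"), c(18, 19, 20, 21))
  expect_identical(igh_annotation(seed = 2), igh_annotation(seed = 2))
  # round-trips through TSV
  f <- withr::local_tempfile(fileext = ".tsv")
  write_bead_annotation(ann, f)
  back <- read_bead_annotation(f)
  expect_equal(back$element_class, ann$element_class)
})
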