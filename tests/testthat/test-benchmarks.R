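# Conformer and free-energy benchmark statistics.

test_that("superposition RMSD is zero for rigid motions and symmetric", {
  x <- toy_mols$alkane4$conformers[[1]]
  expect_equal(conformer_rmsd(x, x), 0)
  expect_lt(conformer_rmsd(x, rigid_motion(x)), 1e-8)
  y <- x + matrix(rnorm(length(x), 0, 0.1), nrow(x), 3)
  expect_equal(conformer_rmsd(x, y), conformer_rmsd(y, x),
               tolerance = 1e-10)
})

test_that("Kabsch RMSD matches the closed-form quaternion solution", {
  set.seed(13)
  for (rep in 1:5) {
    a <- matrix(rnorm(12), 4, 3)
    b <- rigid_motion(a) + matrix(rnorm(12, 0, 0.2), 4, 3)
    expect_equal(conformer_rmsd(a, b), quaternion_rmsd(a, b),
                 tolerance = 1e-8)
  }
})

test_that("TFD matches the reference implementation on toy cases", {
  # expected values computed with the reference TFD implementation
  # (RDKit 2024.09.2 TorsionFingerprints) on identically-built conformer
  # pairs; the driven dihedral and angle are regenerated here in code
  mols <- make_toy_molecules(list(list(template = "alkane", n = 4),
                                  list(template = "alkane", n = 5),
                                  list(template = "alkane", n = 6),
                                  "glycol"))
  drive_all <- function(m, dihs, deltas) {
    x <- m$conformers[[1]]
    for (i in seq_along(dihs)) {
      d <- dihs[[i]]
      phi0 <- oracle_dihedral(x, d[1], d[2], d[3], d[4]) * pi / 180
      x <- smirfit:::.drive_dihedral(m, x, d, phi0 + deltas[i] * pi / 180)
    }
    x
  }
  cases <- list(
    list("alkane4", list(c(1, 2, 3, 4)), 60, 0.3333333333, 0.3333333333),
    list("alkane4", list(c(1, 2, 3, 4)), 120, 0.6666666667, 0.6666666667),
    list("alkane4", list(c(1, 2, 3, 4)), 170, 0.9444444444, 0.9444444444),
    list("alkane5", list(c(1, 2, 3, 4)), 80, 0.4040404040, 0.2222222222),
    list("alkane5", list(c(2, 3, 4, 5)), 80, 0.0404040404, 0.2222222222),
    list("alkane5", list(c(1, 2, 3, 4), c(2, 3, 4, 5)), c(50, -110),
         0.3080808081, 0.4444444444),
    list("alkane6", list(c(2, 3, 4, 5)), 95, 0.4398148148, 0.1759259259),
    list("alkane6", list(c(1, 2, 3, 4), c(3, 4, 5, 6)), c(40, 140),
         0.0833333333, 0.3333333333),
    list("glycol", list(c(1, 2, 3, 4)), 100, 0.5555555556, 0.5555555556),
    list("glycol", list(c(1, 2, 3, 4)), -35, 0.1944444444, 0.1944444444))
  for (cs in cases) {
    m <- mols[[cs[[1]]]]
    x1 <- drive_all(m, cs[[2]], cs[[3]])
    tw <- tfd(m, m$conformers[[1]], x1, use_weights = TRUE)
    tn <- tfd(m, m$conformers[[1]], x1, use_weights = FALSE)
    expect_true(tw$defined)
    expect_equal(tw$tfd, cs[[4]], tolerance = 1e-8,
                 label = paste(cs[[1]], "weighted"))
    expect_equal(tn$tfd, cs[[5]], tolerance = 1e-8,
                 label = paste(cs[[1]], "unweighted"))
    expect_true(tw$tfd >= 0 && tw$tfd <= 1)
  }
})

test_that("TFD of identical conformers is zero and bounded in [0,1]", {
  m <- toy_mols$alkane4
  out <- tfd(m, 1, 1)
  expect_true(out$defined)
  expect_equal(out$tfd, 0)
})

test_that("TFD is undefined without nonterminal rotatable bonds", {
  # ethane: the only C-C bond has no heavy neighbors on either side
  ethane <- make_toy_molecules(list(list(template = "alkane", n = 2)))[[1]]
  out <- tfd(ethane, 1, 1)
  expect_false(out$defined)
  expect_true(is.na(out$tfd))
})

test_that("relative conformer-energy errors exclude the QM minimum", {
  en <- data.frame(
    molecule = rep("m1", 3), conformer = 1:3,
    e_qm = c(2.0, 0.5, 3.0),   # conformer 2 is the QM minimum
    e_mm = c(2.4, 1.0, 3.1))
  out <- ddE_stats(en)
  ref <- out$per_conformer[out$per_conformer$is_reference, ]
  expect_equal(ref$conformer, 2)
  expect_equal(ref$ddE, 0)
  # hand-computed: ddE_i = (e_mm_i - 1.0) - (e_qm_i - 0.5)
  expect_equal(out$per_conformer$ddE, c(-0.1, 0, -0.4))
  expect_equal(unname(out$summary["rmse"]),
               sqrt(mean(c(0.1, 0.4)^2)))
  # identical energy sets give all-zero deviations
  same <- ddE_stats(transform(en, e_mm = e_qm))
  expect_true(all(same$per_conformer$ddE == 0))
  # single-conformer molecules are excluded with a reason
  single <- ddE_stats(data.frame(molecule = "m2", conformer = 1,
                                 e_qm = 1, e_mm = 1))
  expect_equal(single$excluded, "m2")
})

test_that("bond/angle RMSDs match single-coordinate perturbations", {
  m <- diatomic(1.5)
  x1 <- m$conformers[[1]]; x1[2, 1] <- x1[2, 1] + 0.1
  out <- internal_coord_rmsd(m, m$conformers[[1]], x1)
  expect_equal(out$bond_rmsd, 0.1, tolerance = 1e-12)
  m2 <- toy_mols$amide
  same <- internal_coord_rmsd(m2, 1, 1)
  expect_equal(same$bond_rmsd, 0)
  expect_equal(same$angle_rmsd, 0)
  expect_true(all(same$improper_deviations == 0))
})

test_that("mean shift is zero against itself and closed-form for offsets", {
  recs <- data.frame(system = paste0("s", 1:6),
                     o_exp = c(-3, -5, -1, -7, -2, -4))
  recs$o_sim <- recs$o_exp + c(0.2, -0.4, 0.1, 0.6, -0.1, 0.3)
  self <- mean_shift(recs, recs, n_boot = 200, seed = 4)
  expect_equal(self$mean_shift, 0)
  expect_true(self$ci[1] <= 0 && self$ci[2] >= 0)
  # new exact, ref off by +c everywhere -> shift = -c
  perfect <- transform(recs, o_sim = o_exp)
  offset <- transform(recs, o_sim = o_exp + 0.8)
  ms <- mean_shift(perfect, offset, n_boot = 200, seed = 4)
  expect_equal(ms$mean_shift, -0.8, tolerance = 1e-12)
  # hand computation on the 6-row table
  hand <- mean(abs(recs$o_sim - recs$o_exp) - abs(offset$o_sim - offset$o_exp))
  ms2 <- mean_shift(recs, offset, n_boot = 500, seed = 9)
  expect_equal(ms2$mean_shift, hand, tolerance = 1e-12)
  expect_true(ms2$ci[1] <= hand && hand <= ms2$ci[2])
  # bootstrap reproducibility under a fixed seed
  ms3 <- mean_shift(recs, offset, n_boot = 500, seed = 9)
  expect_identical(ms2$ci, ms3$ci)
  expect_error(mean_shift(recs, transform(recs, system = paste0("x", 1:6))),
               "no paired")
})

test_that("transfer free energies compose exactly", {
  expect_equal(transfer_free_energy(-5, -5), 0)
  dg_aq <- c(-5.2, -3.1, -7.4)
  dg_s1 <- c(-4.0, -2.5, -6.8)
  dg_s2 <- c(-6.1, -1.9, -7.0)
  # additivity identity: trans(aq->s1) - trans(aq->s2) = dG(s1) - dG(s2)
  lhs <- transfer_free_energy(dg_aq, dg_s1) -
    transfer_free_energy(dg_aq, dg_s2)
  expect_identical(lhs, dg_s1 - dg_s2)
  expect_error(transfer_free_energy(c(1, NA), c(1, 2)), "missing")
})

test_that("parameter enrichment among TFD outliers counts correctly", {
  cc <- data.frame(molecule = paste0("m", 1:8),
                   tfd = c(0.5, 0.3, 0.05, 0.02, 0.15, 0.01, NA, 0.2))
  cc$params <- list(c("t1"), c("t1"), c("t1"), c("t1"), c("t1"),
                    c("t1"), c("t1"), c("t1"))
  # parameter applied everywhere -> ratio 1 (undefined TFD row excluded)
  out <- enrichment_ratio(cc, "t1")
  expect_equal(out$ratio, 1)
  expect_equal(unname(out$counts["total"]), 7)
  # parameter only on high-TFD molecules -> ratio n_total / n_high
  cc$params <- list(c("t2"), c("t2"), character(0), character(0),
                    c("t2"), character(0), c("t2"), c("t2"))
  out2 <- enrichment_ratio(cc, "t2")  # defined rows: high = {1,2,5,8}
  expect_equal(out2$ratio, 7 / 4)
  # literal (unnormalized) ratio
  out3 <- enrichment_ratio(cc, "t2", normalized = FALSE)
  expect_equal(out3$ratio, 1)
  # degenerate: no outliers at a high threshold
  out4 <- enrichment_ratio(cc, "t2", tfd_threshold = 0.9)
  expect_false(out4$defined)
})

test_that("variance deconvolution clamps and recovers known fractions", {
  shifts <- c(-0.2, 0.3, 0.1, -0.4, 0.25)
  expect_equal(variance_deconvolution(shifts, 0)$fraction, 1)
  big <- variance_deconvolution(shifts, 10)
  expect_equal(big$fraction, 0)
  set.seed(21)
  a <- 0.5; b <- 0.3  # signal and noise SDs
  n <- 10000
  sim <- rnorm(n, 0, a) + rnorm(n, 0, b)
  out <- variance_deconvolution(sim, b)
  expect_equal(out$fraction, a^2 / (a^2 + b^2), tolerance = 0.05)
  # about 4.6% of points fall outside 2 sigma of the fitted Gaussian
  expect_equal(length(out$outliers) / n, 0.046, tolerance = 0.35)
})

test_that("RMSE with bootstrap CIs matches closed forms", {
  recs <- data.frame(o_exp = c(-3, -5, -1, -7, -2))
  perfect <- transform(recs, o_sim = o_exp)
  out0 <- rmse_with_ci(perfect, n_boot = 100, seed = 2)
  expect_equal(out0$rmse, 0)
  expect_equal(out0$mse, 0)
  off <- transform(recs, o_sim = o_exp + 1.3)
  out <- rmse_with_ci(off, n_boot = 500, seed = 2)
  expect_equal(out$rmse, 1.3, tolerance = 1e-12)
  expect_equal(out$mse, 1.3, tolerance = 1e-12)
  expect_true(out$rmse_ci[1] <= 1.3 && 1.3 <= out$rmse_ci[2])
  # reproducible under the recorded seed
  expect_identical(out$rmse_ci,
                   rmse_with_ci(off, n_boot = 500, seed = 2)$rmse_ci)
})
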