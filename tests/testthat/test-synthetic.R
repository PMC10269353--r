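# Synthetic-data generator: toy molecules, ground truth, surrogate backend
# and free-energy tables.

test_that("alkane templates have the right topology", {
  m <- make_toy_molecules(list(list(template = "alkane", n = 4)))[[1]]
  expect_equal(sum(m$elements == 6L), 4)
  expect_equal(sum(m$elements == 1L), 10)
  expect_equal(nrow(m$bonds), 13)  # n-1 C-C + 2n+2 C-H
  expect_error(make_toy_molecules(list("nonexistent")), "unknown template")
})

test_that("generation is deterministic", {
  a <- make_toy_molecules()
  b <- make_toy_molecules()
  for (nm in names(a))
    expect_identical(a[[nm]]$conformers, b[[nm]]$conformers)
  expect_identical(make_qm_targets(a["alkane3"], toy_ff, seed = 4,
                                   grid_spacing = 90)$optgeo,
                   make_qm_targets(b["alkane3"], toy_ff, seed = 4,
                                   grid_spacing = 90)$optgeo)
})

test_that("toy charges are neutral and geometry is chemically sane", {
  for (m in toy_mols) {
    expect_equal(sum(m$charges), 0, tolerance = 1e-12)
    ic <- internal_coordinates(m, 1)
    bonds <- ic$value[ic$type == "bond"]
    expect_true(all(bonds > 0.9 & bonds < 1.9))
  }
})

test_that("the toy set exercises every parameter class of the ground truth", {
  classes_seen <- character(0)
  for (m in toy_mols) {
    asg <- assign_parameters(m, toy_ff)
    for (cl in names(asg$by_class))
      if (length(asg$by_class[[cl]]) > 0)
        classes_seen <- union(classes_seen, cl)
  }
  expect_setequal(classes_seen,
                  c("bond", "angle", "proper_torsion", "improper_torsion",
                    "vdw"))
})

test_that("noiseless QM targets have zero loss at the ground truth", {
  tg <- make_qm_targets(toy_mols[c("alkane3", "alcohol", "amine")],
                        toy_ff, seed = 1, grid_spacing = 45)
  targets <- c(tg$optgeo, tg$torsion)
  obj <- total_valence_objective(targets, toy_ff)
  expect_lt(obj$data_term, 1e-6)
  for (t in tg$torsion) expect_equal(min(t$e_qm), 0)
})

test_that("profile noise produces the analytically expected loss at truth", {
  # independent oracle: apply the stated noise model directly to the
  # noiseless profile and average the loss formula over many draws
  tg0 <- make_qm_targets(toy_mols["alcohol"], toy_ff, seed = 1,
                         grid_spacing = 45)
  base <- tg0$torsion[[1]]
  sigma <- 0.2
  set.seed(99)
  oracle <- mean(replicate(3000, {
    noisy <- base$e_qm + rnorm(length(base$e_qm), 0, sigma)
    noisy <- noisy - min(noisy)
    w <- torsion_weight(noisy)
    mean(w * (noisy - base$e_qm)^2)
  }))
  # generator route: losses of noisy targets against the clean MM profile,
  # averaged over 50 seeds
  losses <- vapply(1:50, function(s) {
    tg <- make_qm_targets(toy_mols["alcohol"], toy_ff, seed = s,
                          grid_spacing = 45, sigma_energy = sigma)
    torsion_profile_loss(tg$torsion[[1]], base$e_qm)$loss
  }, numeric(1))
  expect_equal(mean(losses), oracle, tolerance = 0.25)
})

test_that("the surrogate produces zero LJ data term at the ground truth", {
  pd <- make_property_dataset(toy_mols, toy_ff,
                              noise_sd = c(rho = 0, hmix = 0), seed = 1)
  vec <- vectorize_parameters(toy_ff, counts = NULL, classes = "vdw")
  out <- lj_objective(pd$datapoints, pd$backend, vec$theta, vec$theta,
                      vec$map$sigma, map = vec$map)
  expect_equal(out$data_term, 0, tolerance = 1e-12)
})

test_that("surrogate gradients match finite differences", {
  pd <- make_property_dataset(toy_mols[c("alkane3", "alcohol")], toy_ff,
                              seed = 2)
  vec <- vectorize_parameters(toy_ff, counts = NULL, classes = "vdw")
  est <- pd$backend$estimate(vec$theta, vec$map, pd$datapoints)
  h <- 1e-6
  for (p in seq_along(vec$theta)) {
    tp <- vec$theta; tp[p] <- tp[p] + h
    tm <- vec$theta; tm[p] <- tm[p] - h
    fd <- (pd$backend$estimate(tp, vec$map, pd$datapoints)$values -
           pd$backend$estimate(tm, vec$map, pd$datapoints)$values) / (2 * h)
    expect_lt(max(abs(est$gradients[, p] - fd)), 1e-6)
  }
})

test_that("densities respond with the declared monotonicities", {
  mols <- toy_mols[c("alkane3", "alcohol")]
  be <- surrogate_backend(mols, toy_ff)
  dp <- data.frame(kind = "rho_pure", comp1 = c("alkane3", "alcohol"),
                   comp2 = NA, x1 = 1)
  base <- be$estimate(NULL, NULL, dp)$values
  # +5% R_min/2 on the generic hydrogen type -> all densities decrease
  ff_up <- ff_set_attr(toy_ff, "vdw", "n1", "rmin_half",
                       ff_get_parameter(toy_ff, "vdw", "n1")$attrs$rmin_half *
                         1.05)
  up <- surrogate_backend(mols, ff_up)$estimate(NULL, NULL, dp)$values
  expect_true(all(up < base))
  # +5% epsilon -> all densities increase
  ff_e <- ff_set_attr(toy_ff, "vdw", "n1", "epsilon",
                      ff_get_parameter(toy_ff, "vdw", "n1")$attrs$epsilon *
                        1.05)
  upe <- surrogate_backend(mols, ff_e)$estimate(NULL, NULL, dp)$values
  expect_true(all(upe > base))
})

test_that("free-energy tables have closed-form expected shifts", {
  # identical biases and shared noise draw structure -> expected shift 0
  t0 <- make_fe_tables(50, bias_ref = 0.7, bias_new = 0.7, noise_sd = 0.2,
                       seed = 5)
  expect_equal(t0$true_mean_shift, 0)
  # noiseless: shift is exactly the bias difference
  t1 <- make_fe_tables(10, bias_ref = 1, bias_new = 0, noise_sd = 0,
                       seed = 5)
  ms <- mean_shift(t1$new, t1$ref, n_boot = 100, seed = 5)
  expect_equal(ms$mean_shift, -1, tolerance = 1e-12)
  expect_equal(t1$true_mean_shift, -1)
  # large-sample agreement with the folded-normal expectation
  t2 <- make_fe_tables(500, bias_ref = 1, bias_new = 0.3, noise_sd = 0.5,
                       seed = 11)
  ms2 <- mean_shift(t2$new, t2$ref, n_boot = 500, seed = 11)
  boot_se <- diff(ms2$ci) / (2 * 1.96)
  expect_lt(abs(ms2$mean_shift - t2$true_mean_shift), 3 * boot_se)
})

test_that("the property design includes points destined for curation", {
  pd <- make_property_dataset(toy_mols, toy_ff, seed = 1)
  df <- pd$datapoints
  expect_true(any(df$temperature > 318.15))
  expect_true(any(df$pressure < 99.9))
  expect_true(any(pmin(df$x1, df$x2) < 0.05 & !is.na(df$comp2)))
  out <- filter_property_data(df, min_group_measurements = 0)
  expect_lt(out$report$retained, out$report$input)
})
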