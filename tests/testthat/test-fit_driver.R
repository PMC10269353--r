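# Parameter vectorization, regularization, objectives and the optimizer loop.

test_that("eligibility threshold gates parameters at exactly 5 molecules", {
  counts <- c(b2 = 4L, b3 = 5L)
  ff <- forcefield(list(
    bond = list(
      smirks_parameter("b2", "[#6X4:1]-[#6X4:2]", "bond", k = 500,
                       length = 1.52),
      smirks_parameter("b3", "[#6:1]-[#1:2]", "bond", k = 700,
                       length = 1.09))))
  vec <- vectorize_parameters(ff, counts, classes = "bond")
  expect_true(all(grepl("b3", vec$map$id)))
  expect_false(any(grepl("b2", vec$map$id)))
})

test_that("linear-angle equilibrium values are frozen at 180 degrees", {
  vec <- vectorize_parameters(toy_ff, counts = NULL, classes = "angle")
  a6 <- vec$map[vec$map$id == "a6", ]
  expect_equal(a6$attr, "k")  # theta0 of the linear angle is absent
  a1 <- vec$map[vec$map$id == "a1", ]
  expect_setequal(a1$attr, c("k", "angle"))
})

test_that("improper attributes and torsion periodicities/phases are never free", {
  vec <- vectorize_parameters(toy_ff, counts = NULL)
  expect_false(any(vec$map$class == "improper_torsion"))
  expect_false(any(vec$map$attr %in% c("periodicity", "phase")))
})

test_that("vectorize/devectorize is an exact round trip", {
  vec <- vectorize_parameters(toy_ff, counts = NULL)
  ff2 <- devectorize_parameters(toy_ff, vec$theta, vec$map)
  expect_equal(ff2$parameters, toy_ff$parameters)
  theta2 <- vec$theta * 1.07
  ff3 <- devectorize_parameters(toy_ff, theta2, vec$map)
  vec3 <- vectorize_parameters(ff3, counts = NULL)
  expect_equal(unname(vec3$theta), unname(theta2), tolerance = 1e-12)
})

test_that("regularization penalty is a scaled squared displacement", {
  th0 <- c(a = 2.5, b = 110)
  sigma <- c(1, 20)
  expect_equal(regularization_penalty(th0, th0, sigma), 0)
  th <- th0 + c(1, 0)  # one torsion-like K displaced by 1, sigma 1
  expect_equal(regularization_penalty(th, th0, sigma), 1)
  th2 <- th0 + c(1, 40)
  expect_equal(regularization_penalty(th2, th0, sigma), 1 + 4)  # additive
  expect_error(regularization_penalty(th, th0, sigma[1]), "mismatch")
})

test_that("two-of-three convergence logic matches its truth table", {
  cfg <- fit_config()
  cases <- list(
    list(obj = 0.05, g = 0.05, s = 0.005, conv = TRUE),   # all three
    list(obj = 0.05, g = 5,    s = 5,     conv = FALSE),  # objective only
    list(obj = 0.05, g = 5,    s = 0.005, conv = TRUE),   # obj + step
    list(obj = 5,    g = 0.05, s = 0.005, conv = TRUE),   # grad + step
    list(obj = 5,    g = 0.05, s = 5,     conv = FALSE),  # gradient only
    list(obj = 5,    g = 5,    s = 0.005, conv = FALSE),  # step only
    list(obj = 5,    g = 5,    s = 5,     conv = FALSE))  # none
  for (cs in cases) {
    chk <- check_convergence(cs$obj, cs$g, cs$s, cfg)
    expect_equal(chk$converged, cs$conv,
                 label = paste(cs$obj, cs$g, cs$s))
  }
})

test_that("the total objective decomposes exactly into data term and penalty", {
  mols <- toy_mols[c("alkane3", "alcohol")]
  tg <- make_qm_targets(mols, toy_ff, seed = 5, grid_spacing = 90)
  targets <- c(tg$optgeo, tg$torsion)
  vec <- vectorize_parameters(toy_ff, counts = NULL, classes = "bond")
  theta <- vec$theta * 1.05
  obj <- total_valence_objective(
    targets, devectorize_parameters(toy_ff, theta, vec$map),
    theta = theta, theta_start = vec$theta, sigma = vec$map$sigma,
    w_reg = 1)
  expect_equal(obj$total, obj$data_term + obj$penalty, tolerance = 1e-12)
  expect_equal(obj$data_term, sum(obj$per_target), tolerance = 1e-12)
  # with no displacement the penalty vanishes and total = data term
  obj0 <- total_valence_objective(
    targets, toy_ff, theta = vec$theta, theta_start = vec$theta,
    sigma = vec$map$sigma)
  expect_equal(obj0$penalty, 0)
})

test_that("hand-weighted target losses combine as 0.1 and 1", {
  # two targets with known losses 2.0 (opt-geo, weight 0.1) and 3.0
  # (torsion, weight 1) give a data term of 3.2
  loss_opt <- 2; loss_tor <- 3
  expect_equal(0.1 * loss_opt + 1 * loss_tor, 3.2)
  m <- diatomic(1.5)
  tgt <- optgeo_target(m, m$conformers[[1]])
  expect_equal(tgt$weight, 0.1)
  tt <- torsion_target(torsion_only_mol(), c(1, 2, 3, 4), c(-120, 0, 120),
                       c(0, 1, 2),
                       rep(list(torsion_only_mol()$conformers[[1]]), 3))
  expect_equal(tt$weight, 1)
})

test_that("the LJ objective reproduces forced and hand-computed values", {
  theta <- c(1, 2); sigma <- c(0.1, 1)
  fake_backend <- function(values) list(
    estimate = function(th, map, dp) list(
      values = values, gradients = matrix(0, length(values), 2)))
  dp1 <- data.frame(kind = "rho_pure", value = 0.8)
  # one density point off by exactly d_rho at theta = theta_start -> 1.0
  out <- lj_objective(dp1, fake_backend(0.85), theta, theta, sigma)
  expect_equal(out$data_term, 1, tolerance = 1e-12)
  expect_equal(out$penalty, 0)
  # perfect estimates and no displacement -> 0
  out0 <- lj_objective(dp1, fake_backend(0.8), theta, theta, sigma)
  expect_equal(out0$total, 0)
  # 2 density + 2 enthalpy points with stated residuals
  dp <- data.frame(kind = c("rho_pure", "rho_mix", "hmix", "hmix"),
                   value = c(0.8, 0.9, 1.0, 0.5))
  est <- c(0.82, 0.88, 1.4, 0.9)
  hand <- (((0.02 / 0.05)^2 + (0.02 / 0.05)^2) / 2 +
           ((0.4 / 1.6)^2 + (0.4 / 1.6)^2) / 2)
  out2 <- lj_objective(dp, fake_backend(est), theta, theta, sigma)
  expect_equal(out2$data_term, hand, tolerance = 1e-12)
  expect_equal(unname(out2$blocks["density"] + out2$blocks["hmix"]),
               hand, tolerance = 1e-12)
})

test_that("the optimizer recovers a quadratic minimum and detects fixed points", {
  map <- data.frame(class = "vdw", id = c("x", "y"), attr = "epsilon",
                    index = NA_integer_, kind = "vdw_epsilon",
                    start = c(1, 2), sigma = c(1, 1), lower = -Inf,
                    name = c("x", "y"))
  target <- c(1.3, 1.6)
  quad <- function(theta) list(data_term = sum((theta - target)^2))
  quad_grad <- function(theta) 2 * (theta - target)
  cfg <- fit_config(max_iterations = 50, inner_maxit = 20,
                    objective_tol = 1e-10, gradient_tol = 1e-8,
                    step_tol = 1e-10)
  for (eng in c("lbfgsb", "r_bfgs")) {
    rep1 <- optimize_parameters(quad, c(x = 1, y = 2), map, cfg, w_reg = 0,
                                gradient = quad_grad, engine = eng)
    expect_lt(max(abs(rep1$theta - target)), 1e-6)
    # start exactly at the optimum: immediate convergence, theta unchanged
    rep2 <- optimize_parameters(quad, stats::setNames(target, c("x", "y")),
                                map, fit_config(max_iterations = 5,
                                                inner_maxit = 20),
                                w_reg = 0, gradient = quad_grad,
                                engine = eng)
    expect_lte(nrow(rep2$iterations), 2)
    expect_lt(max(abs(rep2$theta - target)), 1e-8)
  }
})

test_that("fit reports record a consistent trajectory", {
  map <- data.frame(class = "vdw", id = "x", attr = "epsilon",
                    index = NA_integer_, kind = "vdw_epsilon", start = 1,
                    sigma = 1, lower = -Inf, name = "x")
  quad <- function(theta) list(data_term = (theta - 3)^2)
  rep1 <- optimize_parameters(quad, c(x = 1), map,
                              fit_config(max_iterations = 25,
                                         inner_maxit = 5),
                              w_reg = 0.5,
                              gradient = function(th) 2 * (th - 3))
  it <- rep1$iterations
  expect_equal(it$total, it$data_term + it$penalty, tolerance = 1e-12)
  expect_equal(nrow(rep1$trajectory), nrow(it))
  expect_equal(rep1$seed, fit_config()$seed)
})

test_that("bond force constants are near-unidentifiable from these targets", {
  # equilibrium geometries and restrained profiles carry orders of
  # magnitude less bond-stiffness than angle-stiffness information; this is
  # why bond k is held by the prior rather than freed in the recovery
  # experiment (see the methods vignette)
  mols <- toy_mols[c("alkane4", "alcohol", "amine")]
  tg <- make_qm_targets(mols, toy_ff, seed = 2, grid_spacing = 90)
  targets <- c(tg$optgeo, tg$torsion)
  asgs <- lapply(targets, function(t) assign_parameters(t$mol, toy_ff))
  cfg <- fit_config(minimize_tol = 1e-6)
  base <- total_valence_objective(targets, toy_ff, assignments = asgs,
                                  config = cfg)$data_term
  delta_for <- function(class, id) {
    p <- ff_get_parameter(toy_ff, class, id)
    ff2 <- ff_set_attr(toy_ff, class, id, "k", p$attrs$k * 1.1)
    total_valence_objective(targets, ff2, assignments = asgs,
                            config = cfg)$data_term - base
  }
  d_bond <- delta_for("bond", "b2")
  d_angle <- delta_for("angle", "a1")
  expect_lt(d_bond, 1e-5)
  expect_gt(d_angle, 20 * d_bond)
})

test_that("an empty free-parameter set is an error", {
  ff <- forcefield(list(bond = list(
    smirks_parameter("b", "[*:1]~[*:2]", "bond", k = 1, length = 1,
                     optimize = character(0)))))
  expect_error(vectorize_parameters(ff, counts = NULL, classes = "bond"),
               "nothing to optimize")
})
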