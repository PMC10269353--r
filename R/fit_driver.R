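# Regularized fitting driver for valence and Lennard-Jones parameters.
#
# Parameters are optimized in prior-scaled coordinates s = (theta -
# theta_start) / sigma_p, so the regularization penalty is w_reg * |s|^2 and
# the convergence thresholds on gradient norm and step size are dimensionless
# regardless of the mix of force constants, lengths and angles in the vector.

#' Regularization scheme
#'
#' Gaussian-prior widths per attribute kind. The defaults are the scales used
#' for SMIRKS-typed force-field optimization: bond k 100 kcal/mol/A^2, bond
#' length 0.1 A, angle k 100 kcal/mol/rad^2, equilibrium angle 20 deg,
#' torsion barrier 1 kcal/mol, vdW epsilon 0.1 kcal/mol, R_min/2 1 A.
#'
#' @param sigma named numeric vector of prior widths by kind.
#' @param w_reg regularization weight multiplying the summed squared scaled
#'   displacements.
#' @return a `smirfit_regularization`.
#' @export
regularization_scheme <- function(sigma = c(bond_k = 100, bond_length = 0.1,
                                            angle_k = 100, angle_angle = 20,
                                            torsion_k = 1,
                                            vdw_epsilon = 0.1,
                                            vdw_rmin_half = 1),
                                  w_reg = 1) {
  stopifnot(all(sigma > 0), w_reg >= 0)
  structure(list(sigma = sigma, w_reg = w_reg),
            class = "smirfit_regularization")
}

#' Fitting configuration
#'
#' @param eligibility_threshold minimum number of molecules a parameter must
#'   be applied to before its attributes enter the fit (default 5).
#' @param objective_tol,gradient_tol,step_tol convergence thresholds; the fit
#'   converges when at least `required_criteria` of {objective <=
#'   objective_tol, gradient norm <= gradient_tol, step size <= step_tol}
#'   hold (defaults 0.1, 0.1, 0.01, 2 of 3).
#' @param required_criteria how many criteria must hold (default 2).
#' @param max_iterations outer optimization iterations (default 50; the LJ
#'   loop conventionally uses 15).
#' @param inner_maxit L-BFGS-B iterations per outer iteration.
#' @param fd_step named finite-difference steps in parameter units by kind
#'   (k: force constants kcal/mol..., length A, angle deg, epsilon kcal/mol,
#'   rmin_half A).
#' @param minimize_tol gradient-RMS tolerance for per-target minimizations.
#' @param seed RNG seed recorded in reports (for stochastic backends).
#' @return a `smirfit_fit_config`.
#' @export
fit_config <- function(eligibility_threshold = 5, objective_tol = 0.1,
                       gradient_tol = 0.1, step_tol = 0.01,
                       required_criteria = 2, max_iterations = 50,
                       inner_maxit = 8,
                       fd_step = c(bond_k = 0.5, bond_length = 1e-3,
                                   angle_k = 0.5, angle_angle = 5e-2,
                                   torsion_k = 1e-2, vdw_epsilon = 1e-3,
                                   vdw_rmin_half = 1e-3),
                       minimize_tol = 1e-5, seed = 1L) {
  stopifnot(objective_tol > 0, gradient_tol > 0, step_tol > 0,
            max_iterations >= 1)
  structure(list(eligibility_threshold = eligibility_threshold,
                 objective_tol = objective_tol, gradient_tol = gradient_tol,
                 step_tol = step_tol, required_criteria = required_criteria,
                 max_iterations = max_iterations, inner_maxit = inner_maxit,
                 fd_step = fd_step, minimize_tol = minimize_tol,
                 seed = as.integer(seed)),
            class = "smirfit_fit_config")
}

.attr_kind <- function(class, attr) {
  if (class == "bond" && attr == "k") return("bond_k")
  if (class == "bond" && attr == "length") return("bond_length")
  if (class == "angle" && attr == "k") return("angle_k")
  if (class == "angle" && attr == "angle") return("angle_angle")
  if (class %in% c("proper_torsion", "improper_torsion") && attr == "k")
    return("torsion_k")
  if (class == "vdw" && attr == "epsilon") return("vdw_epsilon")
  if (class == "vdw" && attr == "rmin_half") return("vdw_rmin_half")
  stop("no kind for ", class, "/", attr)
}

#' Vectorize the optimizable force-field parameters
#'
#' Collects into a flat vector every attribute that is (i) flagged for
#' optimization on its parameter, (ii) belongs to a parameter applied to at
#' least `eligibility_threshold` molecules, and (iii) is not excluded by
#' convention: equilibrium angles of linear angle parameters (theta0 = 180
#' deg) stay frozen, torsion periodicities and phases are never free, and
#' improper torsions are not optimized by default. The returned map inverts
#' the operation exactly.
#'
#' @param ff force field.
#' @param counts named molecule counts from [applied_parameter_counts()]
#'   (NULL disables the eligibility filter).
#' @param config a [fit_config()].
#' @param scheme a [regularization_scheme()] supplying prior widths.
#' @param classes restrict to these parameter classes (e.g. "vdw" for an LJ
#'   fit; default all).
#' @return list(theta, map) where map is a data.frame with one row per free
#'   attribute (class, id, attr, index, kind, start, sigma, lower).
#' @export
vectorize_parameters <- function(ff, counts = NULL, config = fit_config(),
                                 scheme = regularization_scheme(),
                                 classes = .PARAM_CLASSES) {
  rows <- list()
  for (cl in classes) {
    for (p in ff$parameters[[cl]]) {
      if (!is.null(counts)) {
        cnt <- counts[p$id]
        if (is.na(cnt) || cnt < config$eligibility_threshold) next
      }
      for (attr in p$optimize) {
        if (cl %in% c("proper_torsion", "improper_torsion") &&
            attr %in% c("periodicity", "phase")) next
        if (cl == "angle" && attr == "angle" &&
            isTRUE(all.equal(p$attrs$angle, 180))) next
        vals <- p$attrs[[attr]]
        kind <- .attr_kind(cl, attr)
        lower <- switch(kind,
          bond_k = 0, angle_k = 0, torsion_k = 0, vdw_epsilon = 0,
          vdw_rmin_half = 0.1, -Inf)
        for (idx in seq_along(vals)) {
          rows[[length(rows) + 1L]] <- data.frame(
            class = cl, id = p$id, attr = attr,
            index = if (length(vals) > 1) idx else NA_integer_,
            kind = kind, start = vals[idx],
            sigma = scheme$sigma[[kind]], lower = lower,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) stop("nothing to optimize")
  map <- do.call(rbind, rows)
  map$name <- paste0(map$class, "/", map$id, "/", map$attr,
                     ifelse(is.na(map$index), "", paste0("/", map$index)))
  theta <- stats::setNames(map$start, map$name)
  list(theta = theta, map = map)
}

#' Write a parameter vector back into a force field
#' @param ff force field.
#' @param theta parameter vector aligned with `map`.
#' @param map map from [vectorize_parameters()].
#' @return updated force field.
#' @export
devectorize_parameters <- function(ff, theta, map) {
  if (length(theta) != nrow(map)) stop("theta/map length mismatch")
  for (r in seq_len(nrow(map))) {
    idx <- if (is.na(map$index[r])) NULL else map$index[r]
    ff <- ff_set_attr(ff, map$class[r], map$id[r], map$attr[r],
                      unname(theta[r]), index = idx)
  }
  ff
}

#' Regularization penalty
#'
#' w_reg * sum_p ((theta_p - theta_start_p) / sigma_p)^2: the Gaussian-prior
#' harmonic penalty on parameter displacement from the fit's starting point.
#'
#' @param theta,theta_start aligned parameter vectors.
#' @param sigma per-parameter prior widths (aligned; e.g. `map$sigma`).
#' @param w_reg penalty weight.
#' @return nonnegative scalar.
#' @export
regularization_penalty <- function(theta, theta_start, sigma, w_reg = 1) {
  if (length(theta) != length(theta_start) ||
      length(theta) != length(sigma)) stop("mismatched lengths")
  w_reg * sum(((theta - theta_start) / sigma)^2)
}

#' Two-of-three convergence test
#'
#' @param objective total objective value (data + penalty).
#' @param grad_norm norm of the objective gradient in prior-scaled
#'   coordinates.
#' @param step_size norm of the last parameter step in prior-scaled
#'   coordinates.
#' @param config a [fit_config()].
#' @return list(converged, criteria) with the named logical triple.
#' @export
check_convergence <- function(objective, grad_norm, step_size,
                              config = fit_config()) {
  criteria <- c(objective = objective <= config$objective_tol,
                gradient = grad_norm <= config$gradient_tol,
                step = step_size <= config$step_tol)
  list(converged = sum(criteria) >= config$required_criteria,
       criteria = criteria)
}

#' Total valence objective
#'
#' Weighted sum of per-target normalized losses plus the regularization
#' penalty: sum_i w_i L_i + w_reg sum_p (dtheta_p / sigma_p)^2. Target
#' weights default to 0.1 for opt-geo and 1 for torsion-profile targets (set
#' on the targets themselves).
#'
#' @param targets list of targets.
#' @param ff force field holding the current parameter values.
#' @param theta,theta_start,sigma aligned vectors for the penalty (all NULL
#'   for an unregularized evaluation).
#' @param w_reg penalty weight.
#' @param assignments optional list of precomputed assignments (one per
#'   target, cached across evaluations since SMIRKS matching is independent
#'   of parameter values).
#' @param config fit configuration (minimizer tolerance).
#' @param cache optional environment carrying warm-start geometries across
#'   evaluations at nearby parameter values.
#' @return list(data_term, penalty, total, per_target).
#' @export
total_valence_objective <- function(targets, ff, theta = NULL,
                                    theta_start = NULL, sigma = NULL,
                                    w_reg = 1, assignments = NULL,
                                    config = fit_config(), cache = NULL) {
  per <- numeric(length(targets))
  for (ti in seq_along(targets)) {
    t <- targets[[ti]]
    asg <- if (is.null(assignments)) NULL else assignments[[ti]]
    ctx <- energy_context(t$mol, ff, asg)
    starts <- if (!is.null(cache)) cache$starts[[ti]] else NULL
    res <- tryCatch(
      evaluate_target(t, ff, context = ctx, tol = config$minimize_tol,
                      starts = starts),
      error = function(e) stop("target '", t$id, "' failed: ",
                               conditionMessage(e)))
    # warm-start geometries are committed only when the caller asks (at
    # accepted iterates), keeping the objective a deterministic function of
    # the parameters during line searches and finite differencing
    if (!is.null(cache) && isTRUE(cache$commit))
      cache$starts[[ti]] <- res$starts
    per[ti] <- t$weight * res$loss
  }
  penalty <- if (is.null(theta)) 0 else
    regularization_penalty(theta, theta_start, sigma, w_reg)
  list(data_term = sum(per), penalty = penalty,
       total = sum(per) + penalty,
       per_target = stats::setNames(per, vapply(targets, function(t) t$id,
                                                character(1))))
}

#' Lennard-Jones objective
#'
#' Weighted least-squares objective over physical-property data:
#' (1/N_rho) sum ((rho_est - rho_exp)/d_rho)^2 (pure and mixture densities
#' pooled) + (1/N_dHmix) sum ((dH_est - dH_exp)/d_hmix)^2 + sum
#' ((dtheta_p/sigma_p)^2) with sigma 0.1 kcal/mol for epsilon and 1 A for
#' R_min/2.
#'
#' @param datapoints property data.frame (see [property_dataset()]).
#' @param backend property backend with an `estimate(theta, map, datapoints)`
#'   method returning list(values, gradients).
#' @param theta,theta_start,sigma aligned parameter vectors.
#' @param d_rho density divisor (g/mL), default 0.05.
#' @param d_hmix enthalpy-of-mixing divisor (kJ/mol), default 1.6.
#' @param map parameter map (passed through to the backend).
#' @param gradient also return the analytic objective gradient in unscaled
#'   parameter units.
#' @param w_prior scale on the regularization penalty (default 1; 0 gives
#'   the pure data term, e.g. for noiseless recovery validation).
#' @return list(data_term, penalty, total, blocks, gradient?).
#' @export
lj_objective <- function(datapoints, backend, theta, theta_start, sigma,
                         map = NULL, d_rho = 0.05, d_hmix = 1.6,
                         gradient = FALSE, w_prior = 1) {
  est <- backend$estimate(theta, map, datapoints)
  if (length(est$values) != nrow(datapoints) || anyNA(est$values))
    stop("backend failed to estimate points: ",
         paste(which(is.na(est$values)), collapse = ","))
  is_rho <- datapoints$kind %in% c("rho_pure", "rho_mix")
  is_h <- datapoints$kind == "hmix"
  resid <- est$values - datapoints$value
  n_rho <- sum(is_rho); n_h <- sum(is_h)
  block_rho <- if (n_rho) sum((resid[is_rho] / d_rho)^2) / n_rho else 0
  block_h <- if (n_h) sum((resid[is_h] / d_hmix)^2) / n_h else 0
  penalty <- regularization_penalty(theta, theta_start, sigma,
                                    w_reg = w_prior)
  out <- list(data_term = block_rho + block_h, penalty = penalty,
              total = block_rho + block_h + penalty,
              blocks = c(density = block_rho, hmix = block_h,
                         regularization = penalty))
  if (gradient) {
    G <- est$gradients  # n_points x n_params
    g <- numeric(length(theta))
    if (n_rho) g <- g + as.numeric((2 / (n_rho * d_rho^2)) *
                                   crossprod(G[is_rho, , drop = FALSE],
                                             resid[is_rho]))
    if (n_h) g <- g + as.numeric((2 / (n_h * d_hmix^2)) *
                                 crossprod(G[is_h, , drop = FALSE],
                                           resid[is_h]))
    g <- g + 2 * w_prior * (theta - theta_start) / sigma^2
    out$gradient <- g
  }
  out
}

# Projected BFGS with Armijo backtracking, pure R. Used when the objective
# itself runs L-BFGS-B minimizations internally: R's L-BFGS-B C routine is
# not reentrant, so the outer parameter loop must not call it.
.projected_bfgs <- function(fn, gr, s0, lower, maxit = 100, pgtol = 1e-10,
                            state = NULL) {
  n <- length(s0)
  s <- pmax(s0, lower)
  if (!is.null(state) && isTRUE(all.equal(state$s, s)) &&
      !isTRUE(state$stale)) {
    f <- state$f; g <- state$g; H <- state$H
  } else {
    f <- fn(s); g <- gr(s)
    H <- if (is.null(state)) diag(n) else state$H
  }
  for (it in seq_len(maxit)) {
    d <- as.numeric(-H %*% g)
    active <- s <= lower + 1e-12 & d < 0
    d[active] <- 0
    if (sum(d * g) >= 0) { d <- -g; d[active] <- 0 }  # reset on bad curvature
    if (all(d == 0)) break
    alpha <- 1; f_new <- Inf; s_new <- s
    repeat {
      s_try <- pmax(s + alpha * d, lower)
      f_try <- fn(s_try)
      if (is.finite(f_try) && f_try <= f + 1e-4 * sum(g * (s_try - s))) {
        s_new <- s_try; f_new <- f_try; break
      }
      alpha <- alpha / 2
      if (alpha < 1e-8) { s_new <- s; f_new <- f; break }
    }
    if (identical(s_new, s)) break
    g_new <- gr(s_new)
    dvec <- s_new - s; y <- g_new - g
    sy <- sum(dvec * y)
    if (sy > 1e-12) {
      rho <- 1 / sy
      V <- diag(n) - rho * outer(dvec, y)
      H <- V %*% H %*% t(V) + rho * outer(dvec, dvec)
    }
    s <- s_new; f <- f_new; g <- g_new
    pg <- g; pg[s <= lower + 1e-12 & g > 0] <- 0
    if (max(abs(pg)) < pgtol) break
  }
  list(par = s, value = f, state = list(s = s, f = f, g = g, H = H))
}

# central finite-difference gradient in prior-scaled coordinates
.fd_gradient_scaled <- function(fn_s, s, h_scaled) {
  g <- numeric(length(s))
  for (p in seq_along(s)) {
    sp <- s; sp[p] <- sp[p] + h_scaled[p]
    sm <- s; sm[p] <- sm[p] - h_scaled[p]
    g[p] <- (fn_s(sp) - fn_s(sm)) / (2 * h_scaled[p])
  }
  g
}

#' Iteratively optimize a parameter vector
#'
#' Mirrors the production loop: each outer iteration evaluates the objective
#' and its gradient at the current parameters and takes an L-BFGS-B step
#' (box-constrained, in prior-scaled coordinates), until the two-of-three
#' convergence test passes or `max_iterations` is reached. The full
#' trajectory is recorded.
#'
#' @param objective function(theta) returning list(data_term); the penalty is
#'   added internally.
#' @param theta0 starting parameter vector (also the regularization center).
#' @param map parameter map from [vectorize_parameters()].
#' @param config fit configuration.
#' @param w_reg regularization weight.
#' @param gradient optional function(theta) returning the data-term gradient
#'   in unscaled parameter units; finite differences when NULL.
#' @param engine inner step engine: "lbfgsb" (stats::optim, default) or
#'   "r_bfgs" (an R-level projected BFGS, required when the objective itself
#'   runs geometry minimizations, since R's L-BFGS-B is not reentrant).
#' @param on_iterate optional callback invoked with theta after each
#'   accepted outer iteration (e.g. to commit warm-start caches).
#' @return a `smirfit_fit_report`: data.frame `iterations`, matrix
#'   `trajectory` (one row per iteration), final `theta`, `converged`,
#'   `criteria`, `seed`.
#' @export
optimize_parameters <- function(objective, theta0, map,
                                config = fit_config(), w_reg = 1,
                                gradient = NULL,
                                engine = c("lbfgsb", "r_bfgs"),
                                on_iterate = NULL) {
  engine <- match.arg(engine)
  sigma <- map$sigma
  to_theta <- function(s) theta0 + s * sigma
  data_fn <- function(s) objective(to_theta(s))$data_term
  fn_s <- function(s) data_fn(s) + w_reg * sum(s^2)
  h_scaled <- config$fd_step[map$kind] / sigma
  gr_s <- if (is.null(gradient)) {
    function(s) .fd_gradient_scaled(fn_s, s, h_scaled)
  } else {
    function(s) gradient(to_theta(s)) * sigma + 2 * w_reg * s
  }
  lower_s <- (map$lower - theta0) / sigma

  s <- rep(0, length(theta0))
  rows <- list(); traj <- list()
  converged <- FALSE; criteria <- NULL
  bfgs_state <- NULL
  for (it in seq_len(config$max_iterations)) {
    res <- if (engine == "lbfgsb") {
      stats::optim(s, fn_s, gr_s, method = "L-BFGS-B", lower = lower_s,
                   control = list(maxit = config$inner_maxit,
                                  factr = 1e2, pgtol = 1e-12))
    } else {
      .projected_bfgs(fn_s, gr_s, s, lower_s, maxit = config$inner_maxit,
                      state = bfgs_state)
    }
    if (engine == "r_bfgs") bfgs_state <- res$state
    s_new <- res$par
    step <- sqrt(sum((s_new - s)^2))
    if (engine == "r_bfgs") {
      # the BFGS state already holds f and g at s_new
      g <- res$state$g
      data_term <- res$state$f - w_reg * sum(s_new^2)
    } else {
      g <- gr_s(s_new)
      data_term <- objective(to_theta(s_new))$data_term
    }
    total <- data_term + w_reg * sum(s_new^2)
    rows[[it]] <- data.frame(
      iteration = it, data_term = data_term,
      penalty = w_reg * sum(s_new^2), total = total,
      grad_norm = sqrt(sum(g^2)), step_norm = step)
    traj[[it]] <- to_theta(s_new)
    s <- s_new
    # committing warm-start caches shifts the objective by less than the
    # convergence resolution, so the BFGS state is kept as-is
    if (!is.null(on_iterate)) on_iterate(to_theta(s_new))
    chk <- check_convergence(total, sqrt(sum(g^2)), step, config)
    criteria <- chk$criteria
    if (chk$converged) { converged <- TRUE; break }
  }
  iterations <- do.call(rbind, rows)
  structure(list(iterations = iterations,
                 trajectory = do.call(rbind, traj),
                 theta = to_theta(s), theta_start = theta0, map = map,
                 converged = converged, criteria = criteria,
                 seed = config$seed),
            class = "smirfit_fit_report")
}

#' @export
print.smirfit_fit_report <- function(x, ...) {
  last <- x$iterations[nrow(x$iterations), ]
  cat(sprintf(paste0("<fit report: %d iteration(s), %sconverged; final ",
                     "objective %.4g (data %.4g + penalty %.4g)>\n"),
              nrow(x$iterations), if (x$converged) "" else "NOT ",
              last$total, last$data_term, last$penalty))
  invisible(x)
}

#' Fit valence parameters against QM-style targets
#'
#' End-to-end valence fit: counts parameter applications over the target
#' molecules, vectorizes eligible attributes, and minimizes the regularized
#' total objective with finite-difference gradients.
#'
#' @param targets list of opt-geo and torsion-profile targets.
#' @param ff starting force field (also the regularization center).
#' @param config fit configuration.
#' @param scheme regularization scheme; `scheme$w_reg` weights the penalty.
#' @param classes parameter classes to free (default bonds, angles, proper
#'   torsions).
#' @return list(ff: fitted force field, report, map).
#' @export
fit_valence <- function(targets, ff, config = fit_config(),
                        scheme = regularization_scheme(),
                        classes = c("bond", "angle", "proper_torsion")) {
  mols <- lapply(targets, function(t) t$mol)
  unique_mols <- mols[!duplicated(vapply(mols, function(m) m$name,
                                         character(1)))]
  counts <- applied_parameter_counts(unique_mols, ff)
  vec <- vectorize_parameters(ff, counts, config, scheme, classes = classes)
  assignments <- lapply(targets, function(t) assign_parameters(t$mol, ff))
  cache <- new.env(parent = emptyenv())
  cache$starts <- vector("list", length(targets))
  cache$commit <- FALSE
  objective <- function(theta) {
    ff_cur <- devectorize_parameters(ff, theta, vec$map)
    total_valence_objective(targets, ff_cur, assignments = assignments,
                            config = config, cache = cache)
  }
  commit_at <- function(theta) {
    cache$commit <- TRUE
    on.exit(cache$commit <- FALSE)
    objective(theta)
  }
  # seed the warm-start cache once at the starting parameters
  commit_at(vec$theta)
  report <- optimize_parameters(objective, vec$theta, vec$map, config,
                                w_reg = scheme$w_reg, engine = "r_bfgs",
                                on_iterate = commit_at)
  list(ff = devectorize_parameters(ff, report$theta, vec$map),
       report = report, map = vec$map)
}

#' Fit Lennard-Jones parameters against physical-property data
#'
#' Frees (epsilon, R_min/2) of the vdW types passed in `refit_ids` (from
#' [eligible_lj_types()]) and minimizes the property objective through the
#' supplied backend with analytic gradients.
#'
#' @param datapoints property data.frame.
#' @param backend property backend (e.g. [surrogate_backend()]).
#' @param ff starting force field.
#' @param refit_ids vdW parameter ids to refit.
#' @param config fit configuration (`max_iterations` defaults to 15 here).
#' @param scheme regularization scheme (Eq-style sigmas: epsilon 0.1
#'   kcal/mol, R_min/2 1 A).
#' @param d_rho,d_hmix data-type divisors.
#' @param w_prior scale on the regularization penalty (default 1).
#' @return list(ff, report, map).
#' @export
fit_lj <- function(datapoints, backend, ff, refit_ids,
                   config = fit_config(max_iterations = 15,
                                       inner_maxit = 1),
                   scheme = regularization_scheme(),
                   d_rho = 0.05, d_hmix = 1.6, w_prior = 1) {
  ff_sub <- ff
  for (k in seq_along(ff_sub$parameters$vdw)) {
    if (!ff_sub$parameters$vdw[[k]]$id %in% refit_ids)
      ff_sub$parameters$vdw[[k]]$optimize <- character(0)
  }
  vec <- vectorize_parameters(ff_sub, counts = NULL, config, scheme,
                              classes = "vdw")
  theta0 <- vec$theta
  objective <- function(theta)
    lj_objective(datapoints, backend, theta, theta0, vec$map$sigma,
                 map = vec$map, d_rho = d_rho, d_hmix = d_hmix,
                 w_prior = w_prior)
  gradient <- function(theta)
    lj_objective(datapoints, backend, theta, theta0, vec$map$sigma,
                 map = vec$map, d_rho = d_rho, d_hmix = d_hmix,
                 gradient = TRUE, w_prior = 0)$gradient
  report <- optimize_parameters(objective, theta0, vec$map, config,
                                w_reg = w_prior, gradient = gradient)
  list(ff = devectorize_parameters(ff, report$theta, vec$map),
       report = report, map = vec$map)
}
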