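# End-to-end parameter-recovery experiments on noiseless synthetic data.
# These are the package's self-validation workflows: generate targets under
# the ground-truth force field, perturb the identifiable parameters by a
# fixed fraction, refit, and measure the relative recovery error.

#' Valence parameter-recovery experiment
#'
#' Generates noiseless opt-geo and torsion-profile targets for the toy
#' molecule set under the ground-truth force field, perturbs all eligible
#' identifiable valence attributes (bond equilibrium lengths, angle force
#' constants and equilibrium angles, torsion barrier heights) by
#' `perturbation`, refits without regularization, and reports per-parameter
#' relative errors. Bond force constants are held fixed: equilibrium
#' geometries and restrained torsion profiles carry almost no bond-stiffness
#' signal once vibrational targets are absent, so they are constrained by
#' the prior in production fits rather than by this data (see the methods
#' vignette).
#'
#' @param seed RNG seed (targets are noiseless; the seed still namespaces
#'   the generator).
#' @param perturbation relative perturbation of the starting values
#'   (default 0.10).
#' @param grid_spacing scan grid spacing in degrees for the torsion targets
#'   (default 45; a desk-scale reduction of the production 15-degree grid).
#' @param molecules names of toy molecules used (default: a seven-molecule
#'   H/C/N/O subset giving every freed parameter >= 5 molecules).
#' @param config fit configuration; the default runs up to 45 iterations
#'   with recovery-grade convergence thresholds.
#' @return list(fit, errors, truth, fitted) where errors is the named
#'   vector of relative errors in percent.
#' @export
recover_valence_parameters <- function(seed = 1, perturbation = 0.10,
                                       grid_spacing = 45,
                                       molecules = c("alkane3", "alkane4",
                                                     "methanol", "ether",
                                                     "glycol", "alcohol",
                                                     "amine"),
                                       config = fit_config(
                                         max_iterations = 45,
                                         inner_maxit = 1,
                                         minimize_tol = 1e-6,
                                         objective_tol = 1e-5,
                                         gradient_tol = 5e-4,
                                         step_tol = 1e-4, seed = seed)) {
  mols <- make_toy_molecules()[molecules]
  ff <- make_toy_forcefield()
  tg <- make_qm_targets(mols, ff, seed = seed, grid_spacing = grid_spacing)
  targets <- c(tg$optgeo, tg$torsion)
  ff_exp <- ff
  for (k in seq_along(ff_exp$parameters$bond))
    ff_exp$parameters$bond[[k]]$optimize <- "length"
  counts <- applied_parameter_counts(mols, ff)
  scheme <- regularization_scheme(w_reg = 0)
  vec <- vectorize_parameters(ff_exp, counts, config, scheme,
                              classes = c("bond", "angle",
                                          "proper_torsion"))
  start_ff <- devectorize_parameters(ff_exp, vec$theta * (1 + perturbation),
                                     vec$map)
  fit <- fit_valence(targets, start_ff, config = config, scheme = scheme)
  fitted <- stats::setNames(fit$report$theta, fit$map$name)
  truth <- vec$theta
  errors <- 100 * abs(fitted[names(truth)] - truth) / abs(truth)
  list(fit = fit, errors = errors, truth = truth, fitted = fitted)
}

#' Lennard-Jones parameter-recovery experiment
#'
#' Generates a noiseless surrogate property dataset for the toy substances,
#' curates it with the production filters, determines the data-eligible vdW
#' types, perturbs their (epsilon, R_min/2) by `perturbation`, and refits
#' them through the surrogate backend without the prior (a prior centered
#' on the perturbed start would bias the recovery by construction).
#'
#' @param seed RNG seed.
#' @param perturbation relative perturbation (default 0.10).
#' @param config fit configuration (a single long quasi-Newton run; the
#'   surrogate is deterministic so the iterate-and-re-estimate loop of a
#'   simulation backend is unnecessary).
#' @return list(fit, errors, eligible) with per-attribute relative errors in
#'   percent over the refit (non-frozen) types.
#' @export
recover_lj_parameters <- function(seed = 1, perturbation = 0.10,
                                  config = fit_config(
                                    max_iterations = 4,
                                    inner_maxit = 20000,
                                    objective_tol = 1e-9,
                                    gradient_tol = 1e-8,
                                    step_tol = 1e-10, seed = seed)) {
  mols <- make_toy_molecules()
  ff <- make_toy_forcefield()
  pd <- make_property_dataset(mols, ff, noise_sd = c(rho = 0, hmix = 0),
                              seed = seed)
  cur <- filter_property_data(pd$datapoints, min_group_measurements = 0)
  coverage <- lapply(rownames(pd$backend$type_counts), function(nm)
    colnames(pd$backend$type_counts)[pd$backend$type_counts[nm, ] > 0])
  names(coverage) <- rownames(pd$backend$type_counts)
  eligible <- eligible_lj_types(cur$retained, coverage)
  pert <- ff
  for (k in seq_along(pert$parameters$vdw)) {
    p <- pert$parameters$vdw[[k]]
    if (p$id %in% eligible && length(p$optimize)) {
      pert$parameters$vdw[[k]]$attrs$epsilon <-
        p$attrs$epsilon * (1 + perturbation)
      pert$parameters$vdw[[k]]$attrs$rmin_half <-
        p$attrs$rmin_half * (1 + perturbation)
    }
  }
  fit <- fit_lj(cur$retained, pd$backend, pert, refit_ids = eligible,
                config = config, w_prior = 0)
  errors <- numeric(0)
  for (id in eligible) {
    pt <- ff_get_parameter(ff, "vdw", id)
    if (length(pt$optimize) == 0) next
    pf <- ff_get_parameter(fit$ff, "vdw", id)
    errors[paste0(id, "/epsilon")] <-
      100 * abs(pf$attrs$epsilon - pt$attrs$epsilon) / pt$attrs$epsilon
    errors[paste0(id, "/rmin_half")] <-
      100 * abs(pf$attrs$rmin_half - pt$attrs$rmin_half) /
        pt$attrs$rmin_half
  }
  list(fit = fit, errors = errors, eligible = eligible)
}
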