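# Gas-phase classical potential with analytic gradients. Functional form
# (AMBER-family / SMIRNOFF conventions):
#   bonds     k/2 (r - r0)^2
#   angles    k/2 (theta - theta0)^2            (theta in radians internally)
#   torsions  sum_n K_n (1 + cos(n*phi - gamma_n))
#   vdW       12-6 from (R_min/2, epsilon), Lorentz-Berthelot combining
#   Coulomb   332.0637 q_i q_j / r_ij
# with 1-2 and 1-3 exclusions, configurable 1-4 scaling, no cutoffs and no
# periodicity.

#' Coulomb constant in kcal/mol * Angstrom / e^2
#' @export
COULOMB_CONSTANT <- 332.0637

#' Hartree to kcal/mol conversion factor
#'
#' Used e.g. for the in-ring torsion-scan energy cutoff of 0.05 hartree
#' (about 31.4 kcal/mol).
#' @export
HARTREE_TO_KCALMOL <- 627.5094740631

#' Precompile an energy context
#'
#' Expands a parameter assignment into flat term tables (one row per bond,
#' angle, torsion Fourier term and nonbonded pair) so that repeated energy
#' and gradient evaluations are vectorized. Parameter *values* are read at
#' build time: rebuild the context after changing the force field.
#'
#' @param mol molecule.
#' @param ff force field.
#' @param assignment output of [assign_parameters()]; recomputed when `NULL`.
#' @param electrostatics "auto" (default: Coulomb on iff partial charges are
#'   present), TRUE (required: error when charges are missing) or FALSE.
#' @return a `smirfit_energy_context`.
#' @export
energy_context <- function(mol, ff, assignment = NULL,
                           electrostatics = "auto") {
  if (identical(electrostatics, TRUE) && is.null(mol$charges))
    stop("electrostatics requested but molecule '", mol$name,
         "' has no partial charges")
  elec_on <- !identical(electrostatics, FALSE) && !is.null(mol$charges)
  if (is.null(assignment)) assignment <- assign_parameters(mol, ff)
  n <- n_atoms(mol)

  grab <- function(cl) assignment$by_class[[cl]]

  bonds <- grab("bond")
  bond_tab <- if (length(bonds)) {
    do.call(rbind, lapply(bonds, function(e) {
      p <- ff_get_parameter(ff, "bond", e$id)
      c(e$tuple, p$attrs$k, p$attrs$length)
    }))
  } else matrix(numeric(0), ncol = 4)

  angles <- grab("angle")
  angle_tab <- if (length(angles)) {
    do.call(rbind, lapply(angles, function(e) {
      p <- ff_get_parameter(ff, "angle", e$id)
      c(e$tuple, p$attrs$k, p$attrs$angle * pi / 180)
    }))
  } else matrix(numeric(0), ncol = 5)

  expand_torsions <- function(cl) {
    entries <- grab(cl)
    rows <- list()
    for (e in entries) {
      p <- ff_get_parameter(ff, cl, e$id)
      for (t in seq_along(p$attrs$periodicity)) {
        rows[[length(rows) + 1L]] <- c(e$tuple, p$attrs$k[t],
                                       p$attrs$periodicity[t],
                                       p$attrs$phase[t] * pi / 180)
      }
    }
    if (length(rows)) do.call(rbind, rows) else matrix(numeric(0), ncol = 7)
  }
  proper_tab <- expand_torsions("proper_torsion")
  improper_tab <- expand_torsions("improper_torsion")

  # nonbonded pair list with exclusions from topological distance
  topo <- topological_distances(mol)
  vdw_ids <- vapply(grab("vdw"), function(e) e$id, character(1))
  eps <- numeric(n); rmh <- numeric(n)
  for (e in grab("vdw")) {
    p <- ff_get_parameter(ff, "vdw", e$id)
    eps[e$tuple] <- p$attrs$epsilon
    rmh[e$tuple] <- p$attrs$rmin_half
  }
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- topo[pairs] >= 3
  pairs <- pairs[keep, , drop = FALSE]
  sep14 <- topo[pairs] == 3
  svdw <- ifelse(sep14, ff$scale14_vdw, 1)
  selec <- ifelse(sep14, ff$scale14_elec, 1)
  eps_ij <- sqrt(eps[pairs[, 1]] * eps[pairs[, 2]])
  rmin_ij <- rmh[pairs[, 1]] + rmh[pairs[, 2]]
  qq <- if (!is.null(mol$charges))
    COULOMB_CONSTANT * mol$charges[pairs[, 1]] * mol$charges[pairs[, 2]]
  else NULL

  structure(list(
    n = n, bond = bond_tab, angle = angle_tab, proper = proper_tab,
    improper = improper_tab,
    nb_i = pairs[, 1], nb_j = pairs[, 2],
    nb_eps = eps_ij * svdw, nb_rmin = rmin_ij, nb_qq = if (is.null(qq)) NULL
      else qq * selec,
    electrostatics = elec_on
  ), class = "smirfit_energy_context")
}

.dihedral_angle <- function(x, i, j, k, l) {
  b1 <- x[j, ] - x[i, ]; b2 <- x[k, ] - x[j, ]; b3 <- x[l, ] - x[k, ]
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# row-wise cross products of two N x 3 matrices
.cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# scatter-add rows of `vals` into g at atom indices idx
.scatter_add <- function(g, idx, vals) {
  o <- rowsum(vals, idx)
  rows <- as.integer(rownames(o))
  g[rows, ] <- g[rows, ] + o
  g
}

# cosine-series torsion energy + gradient, vectorized over term-table rows
.torsion_eval <- function(tab, x, grad) {
  keep <- tab[, 5] != 0
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) == 0)
    return(list(e = 0, g = if (grad) matrix(0, nrow(x), 3) else NULL))
  i <- tab[, 1]; j <- tab[, 2]; k <- tab[, 3]; l <- tab[, 4]
  K <- tab[, 5]; nper <- tab[, 6]; gamma <- tab[, 7]
  b1 <- x[j, , drop = FALSE] - x[i, , drop = FALSE]
  b2 <- x[k, , drop = FALSE] - x[j, , drop = FALSE]
  b3 <- x[l, , drop = FALSE] - x[k, , drop = FALSE]
  n1 <- .cross_rows(b1, b2); n2 <- .cross_rows(b2, b3)
  n1sq <- rowSums(n1^2); n2sq <- rowSums(n2^2)
  # colinear arms (e.g. nitriles) have undefined dihedrals; skip those rows
  ok <- n1sq > 1e-10 & n2sq > 1e-10
  if (!all(ok)) {
    tab <- tab[ok, , drop = FALSE]
    return(.torsion_eval(tab, x, grad))
  }
  b2sq <- rowSums(b2^2); b2n <- sqrt(b2sq)
  m1 <- .cross_rows(n1, b2 / b2n)
  phi <- atan2(rowSums(m1 * n2), rowSums(n1 * n2))
  e <- sum(K * (1 + cos(nper * phi - gamma)))
  g <- NULL
  if (grad) {
    dEdphi <- -K * nper * sin(nper * phi - gamma)
    gi <- n1 * (b2n / n1sq)
    gl <- -n2 * (b2n / n2sq)
    p <- rowSums(b1 * b2) / b2sq
    q <- rowSums(b3 * b2) / b2sq
    gj <- -(1 + p) * gi + q * gl
    gk <- p * gi - (1 + q) * gl
    g <- matrix(0, nrow(x), 3)
    g <- .scatter_add(g, i, gi * dEdphi)
    g <- .scatter_add(g, j, gj * dEdphi)
    g <- .scatter_add(g, k, gk * dEdphi)
    g <- .scatter_add(g, l, gl * dEdphi)
  }
  list(e = e, g = g)
}

# analytic dihedral-angle gradient (standard cross-product formulation)
.dihedral_gradient <- function(x, i, j, k, l) {
  b1 <- x[j, ] - x[i, ]; b2 <- x[k, ] - x[j, ]; b3 <- x[l, ] - x[k, ]
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  n1sq <- sum(n1^2); n2sq <- sum(n2^2)
  b2sq <- sum(b2^2); b2n <- sqrt(b2sq)
  gi <- b2n / n1sq * n1
  gl <- -b2n / n2sq * n2
  p <- sum(b1 * b2) / b2sq
  q <- sum(b3 * b2) / b2sq
  gj <- -(1 + p) * gi + q * gl
  gk <- p * gi - (1 + q) * gl
  list(gi = gi, gj = gj, gk = gk, gl = gl)
}

#' Potential energy of a conformer
#'
#' @param mol molecule.
#' @param conformer conformer index (or an N x 3 matrix of coordinates).
#' @param ff force field.
#' @param assignment optional precomputed assignment.
#' @param context optional precompiled [energy_context()] (fastest path).
#' @param terms character vector restricting which energy terms are
#'   evaluated (default all).
#' @return a `smirfit_energy` breakdown: bond, angle, proper_torsion,
#'   improper_torsion, vdw, electrostatic, restraint (0 here) and
#'   `total_without_restraint`, all kcal/mol.
#' @export
potential_energy <- function(mol, conformer = 1L, ff = NULL,
                             assignment = NULL, context = NULL,
                             terms = NULL) {
  x <- if (is.matrix(conformer)) conformer else mol$conformers[[conformer]]
  if (is.null(context)) context <- energy_context(mol, ff, assignment)
  .energy_eval(context, x, grad = FALSE, terms = terms)$breakdown
}

#' Analytic energy gradient of a conformer
#'
#' @inheritParams potential_energy
#' @return N x 3 matrix of dE/dx (kcal/mol/A).
#' @export
energy_gradient <- function(mol, conformer = 1L, ff = NULL,
                            assignment = NULL, context = NULL, terms = NULL) {
  x <- if (is.matrix(conformer)) conformer else mol$conformers[[conformer]]
  if (is.null(context)) context <- energy_context(mol, ff, assignment)
  .energy_eval(context, x, grad = TRUE, terms = terms)$gradient
}

.ALL_TERMS <- c("bond", "angle", "proper_torsion", "improper_torsion",
                "vdw", "electrostatic")

# hot path: compiled kernel over the precompiled term tables
.energy_eval <- function(ctx, x, grad = FALSE, terms = NULL) {
  term_on <- if (is.null(terms)) rep(TRUE, 6) else .ALL_TERMS %in% terms
  if (!ctx$electrostatics) term_on[6] <- FALSE
  res <- .energy_eval_cpp(x, ctx$bond, ctx$angle, ctx$proper, ctx$improper,
                          ctx$nb_i, ctx$nb_j, ctx$nb_eps, ctx$nb_rmin,
                          if (is.null(ctx$nb_qq)) numeric(0) else ctx$nb_qq,
                          term_on, grad)
  e <- stats::setNames(res$e, .ALL_TERMS)
  breakdown <- structure(as.list(e), class = "smirfit_energy")
  breakdown$restraint <- 0
  breakdown$total_without_restraint <- sum(e)
  list(breakdown = breakdown, gradient = if (grad) res$g else NULL,
       total = sum(e))
}

# reference R implementation of the same kernel (kept for cross-checking in
# the test suite; identical contract to .energy_eval)
.energy_eval_r <- function(ctx, x, grad = FALSE, terms = NULL) {
  if (is.null(terms)) terms <- .ALL_TERMS
  e <- stats::setNames(numeric(length(.ALL_TERMS)), .ALL_TERMS)
  g <- if (grad) matrix(0, ctx$n, 3) else NULL

  if ("bond" %in% terms && nrow(ctx$bond)) {
    i <- ctx$bond[, 1]; j <- ctx$bond[, 2]
    d <- x[i, , drop = FALSE] - x[j, , drop = FALSE]
    r <- sqrt(rowSums(d^2))
    dr <- r - ctx$bond[, 4]
    e[["bond"]] <- sum(0.5 * ctx$bond[, 3] * dr^2)
    if (grad) {
      gv <- d * (ctx$bond[, 3] * dr / r)
      g <- .scatter_add(g, i, gv)
      g <- .scatter_add(g, j, -gv)
    }
  }

  if ("angle" %in% terms && nrow(ctx$angle)) {
    i <- ctx$angle[, 1]; j <- ctx$angle[, 2]; k <- ctx$angle[, 3]
    kth <- ctx$angle[, 4]; th0 <- ctx$angle[, 5]
    u <- x[i, , drop = FALSE] - x[j, , drop = FALSE]
    v <- x[k, , drop = FALSE] - x[j, , drop = FALSE]
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    cth <- pmax(-1, pmin(1, rowSums(u * v) / (nu * nv)))
    th <- acos(cth)
    e[["angle"]] <- sum(0.5 * kth * (th - th0)^2)
    if (grad) {
      sth <- sqrt(pmax(1 - cth^2, 1e-12))
      dEdth <- kth * (th - th0)
      dthdu <- -(v / (nu * nv) - u * (cth / nu^2)) / sth
      dthdv <- -(u / (nu * nv) - v * (cth / nv^2)) / sth
      g <- .scatter_add(g, i, dthdu * dEdth)
      g <- .scatter_add(g, k, dthdv * dEdth)
      g <- .scatter_add(g, j, -(dthdu + dthdv) * dEdth)
    }
  }

  if ("proper_torsion" %in% terms && nrow(ctx$proper)) {
    res <- .torsion_eval(ctx$proper, x, grad)
    e[["proper_torsion"]] <- res$e
    if (grad) g <- g + res$g
  }
  if ("improper_torsion" %in% terms && nrow(ctx$improper)) {
    res <- .torsion_eval(ctx$improper, x, grad)
    e[["improper_torsion"]] <- res$e
    if (grad) g <- g + res$g
  }

  if (length(ctx$nb_i) &&
      (("vdw" %in% terms) ||
       ("electrostatic" %in% terms && ctx$electrostatics))) {
    d <- x[ctx$nb_i, , drop = FALSE] - x[ctx$nb_j, , drop = FALSE]
    r2 <- rowSums(d^2); r <- sqrt(r2)
    if ("vdw" %in% terms) {
      s6 <- (ctx$nb_rmin^2 / r2)^3
      e[["vdw"]] <- sum(ctx$nb_eps * (s6^2 - 2 * s6))
      if (grad) {
        gv <- d * (ctx$nb_eps * 12 * (s6 - s6^2) / r2)
        g <- .scatter_add(g, ctx$nb_i, gv)
        g <- .scatter_add(g, ctx$nb_j, -gv)
      }
    }
    if ("electrostatic" %in% terms && ctx$electrostatics) {
      e[["electrostatic"]] <- sum(ctx$nb_qq / r)
      if (grad) {
        gv <- d * (-ctx$nb_qq / (r2 * r))
        g <- .scatter_add(g, ctx$nb_i, gv)
        g <- .scatter_add(g, ctx$nb_j, -gv)
      }
    }
  }

  breakdown <- structure(as.list(e), class = "smirfit_energy")
  breakdown$restraint <- 0
  breakdown$total_without_restraint <- sum(e)
  list(breakdown = breakdown, gradient = g,
       total = sum(e))
}

#' @export
print.smirfit_energy <- function(x, ...) {
  terms <- setdiff(names(x), c("restraint", "total_without_restraint"))
  for (t in terms) cat(sprintf("  %-18s %12.6f kcal/mol\n", t, x[[t]]))
  cat(sprintf("  %-18s %12.6f kcal/mol\n", "restraint", x$restraint))
  cat(sprintf("  %-18s %12.6f kcal/mol\n", "total (no restr.)",
              x$total_without_restraint))
  invisible(x)
}
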