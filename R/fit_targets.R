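# Valence fitting targets: optimized-geometry (internal-coordinate) loss and
# weighted torsion-profile loss.
#
# The opt-geo loss penalizes deviations of an MM-minimized geometry's
# internal coordinates from the QM reference, each scaled by a
# coordinate-type divisor (0.05 A bonds, 8 deg angles, 20 deg impropers);
# proper torsion angles are deliberately excluded (they are fit through
# torsion profiles). The torsion-profile loss penalizes weighted deviations
# between MM and QM relative energy profiles on a dihedral grid, with an
# energy-dependent weight that prioritizes the region near the minima.

.OPTGEO_DIVISORS <- c(bond = 0.05, angle = 8, improper = 20)

#' Internal coordinates of a conformer
#'
#' One entry per bonded pair (length, Angstrom), per bonded triple (angle,
#' degrees) and per trivalent center (improper dihedral of the canonical
#' center-sorted-neighbor tuple, degrees). Near-colinear angle triples are
#' evaluated with a clamped cosine and flagged in the `degenerate` column.
#'
#' @param mol molecule.
#' @param conformer conformer index or N x 3 coordinate matrix.
#' @return data.frame with columns type ("bond", "angle", "improper"),
#'   i, j, k, l (NA where unused), value, degenerate.
#' @export
internal_coordinates <- function(mol, conformer = 1L) {
  x <- if (is.matrix(conformer)) conformer else mol$conformers[[conformer]]
  tuples <- enumerate_tuples(mol)
  rows <- list()
  for (t in tuples$bond) {
    rows[[length(rows) + 1L]] <- data.frame(
      type = "bond", i = t[1], j = t[2], k = NA_integer_, l = NA_integer_,
      value = sqrt(sum((x[t[1], ] - x[t[2], ])^2)), degenerate = FALSE)
  }
  for (t in tuples$angle) {
    u <- x[t[1], ] - x[t[2], ]; v <- x[t[3], ] - x[t[2], ]
    cth <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    degen <- abs(cth) > 1
    rows[[length(rows) + 1L]] <- data.frame(
      type = "angle", i = t[1], j = t[2], k = t[3], l = NA_integer_,
      value = acos(max(-1, min(1, cth))) * 180 / pi, degenerate = degen)
  }
  for (t in tuples$improper_torsion) {
    # canonical tuple is (center, n1, n2, n3) with sorted neighbors; the
    # improper dihedral is taken over (n1, center, n2, n3) and folded to
    # (-90, 90] so an exactly planar center reads 0 on either branch
    phi <- wrap_angle(.dihedral_angle(x, t[2], t[1], t[3], t[4]) * 180 / pi)
    if (phi > 90) phi <- phi - 180
    if (phi <= -90) phi <- phi + 180
    rows[[length(rows) + 1L]] <- data.frame(
      type = "improper", i = t[2], j = t[1], k = t[3], l = t[4],
      value = phi, degenerate = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(type = character(0), i = integer(0), j = integer(0),
                      k = integer(0), l = integer(0), value = numeric(0),
                      degenerate = logical(0)))
  do.call(rbind, rows)
}

#' Construct an optimized-geometry fitting target
#'
#' @param mol molecule (its topology defines the internal-coordinate list).
#' @param qm_conformer reference QM-minimized coordinates (N x 3, Angstrom).
#' @param divisors named numeric vector of scaling factors: bond (A), angle
#'   (deg), improper (deg).
#' @param weight target weight in the total objective (default 0.1).
#' @param id target identifier.
#' @return a `smirfit_optgeo_target`.
#' @export
optgeo_target <- function(mol, qm_conformer, divisors = .OPTGEO_DIVISORS,
                          weight = 0.1, id = mol$name) {
  stopifnot(all(divisors > 0))
  qm_conformer <- as.matrix(qm_conformer)
  if (nrow(qm_conformer) != n_atoms(mol))
    stop("QM conformer atom count mismatch")
  ref <- internal_coordinates(mol, qm_conformer)
  structure(list(mol = mol, qm_conformer = qm_conformer, reference = ref,
                 divisors = divisors, weight = weight, id = id),
            class = "smirfit_optgeo_target")
}

#' Optimized-geometry loss
#'
#' Mean over internal coordinates of ((x_QM - x_MM) / d_i)^2, with angular
#' deviations wrapped to (-180, 180] degrees. Proper torsions never enter.
#'
#' @param target an [optgeo_target()].
#' @param mm_conformer MM-minimized coordinates (caller's duty to minimize).
#' @return list(loss, contributions) where contributions is the per-
#'   coordinate data.frame of squared scaled deviations (unnormalized).
#' @export
optgeo_loss <- function(target, mm_conformer) {
  mm <- internal_coordinates(target$mol, as.matrix(mm_conformer))
  ref <- target$reference
  if (nrow(mm) != nrow(ref) || !all(mm$type == ref$type))
    stop("internal-coordinate list mismatch")
  dev <- ref$value - mm$value
  ang <- ref$type %in% c("angle", "improper")
  dev[ang] <- wrap_angle(dev[ang])
  d <- target$divisors[ref$type]
  contrib <- (dev / d)^2
  out <- ref[, c("type", "i", "j", "k", "l")]
  out$contribution <- contrib
  list(loss = mean(contrib), contributions = out)
}

#' Torsion-profile weight as a function of QM relative energy
#'
#' Maximal (1) at and near the profile minimum, smoothly decreasing in an
#' intermediate regime, and exactly 0 at and above the upper cutoff, so
#' high-barrier regions do not dominate the fit:
#' w = 1 for E < lower; 1/sqrt(1 + (E - lower)^2) for lower <= E < upper;
#' 0 for E >= upper (E, lower, upper in kcal/mol).
#'
#' @param e_qm nonnegative QM relative energy (kcal/mol), vectorized.
#' @param lower,upper regime boundaries (kcal/mol), defaults 1 and 5.
#' @return weight(s) in [0, 1].
#' @export
torsion_weight <- function(e_qm, lower = 1, upper = 5) {
  if (any(e_qm < 0)) stop("QM relative energies must be >= 0")
  ifelse(e_qm < lower, 1,
         ifelse(e_qm < upper, 1 / sqrt(1 + (e_qm - lower)^2), 0))
}

#' Construct a torsion-profile fitting target
#'
#' @param mol molecule.
#' @param dihedral four bonded atom indices.
#' @param grid grid angles (degrees).
#' @param e_qm QM relative energies on the grid (kcal/mol, minimum 0).
#' @param start_conformers list of per-grid-point starting coordinates (the
#'   QM scan frames); MM evaluation minimizes from these with the four
#'   torsion atoms frozen.
#' @param d_e energy divisor (kcal/mol), default 1.
#' @param weight target weight (default 1).
#' @param weight_lower,weight_upper regime boundaries of [torsion_weight()].
#' @param id target identifier.
#' @return a `smirfit_torsion_target`.
#' @export
torsion_target <- function(mol, dihedral, grid, e_qm, start_conformers,
                           d_e = 1, weight = 1, weight_lower = 1,
                           weight_upper = 5, id = mol$name) {
  grid <- as.numeric(grid); e_qm <- as.numeric(e_qm)
  if (length(grid) != length(e_qm)) stop("grid and energies differ in length")
  if (length(start_conformers) != length(grid))
    stop("one starting conformer per grid point required")
  if (abs(min(e_qm)) > 1e-9) stop("QM profile must be referenced to 0")
  e_qm <- e_qm - min(e_qm)
  structure(list(mol = mol, dihedral = as.integer(dihedral), grid = grid,
                 e_qm = e_qm, start_conformers = start_conformers, d_e = d_e,
                 weight = weight, weight_lower = weight_lower,
                 weight_upper = weight_upper, id = id),
            class = "smirfit_torsion_target")
}

#' Torsion-profile loss
#'
#' Mean over grid points of w(E_QM) * ((dE_MM - dE_QM)/d_E)^2 where both
#' profiles are referenced to their own grid minimum, making the loss
#' invariant under additive shifts of either absolute-energy profile.
#'
#' @param target a [torsion_target()].
#' @param mm_energies MM energies on the target grid (kcal/mol; absolute or
#'   relative, re-referenced internally).
#' @return list(loss, contributions) with per-point weighted squared scaled
#'   deviations (unnormalized).
#' @export
torsion_profile_loss <- function(target, mm_energies) {
  if (length(mm_energies) != length(target$grid))
    stop("MM profile grid mismatch")
  e_mm <- mm_energies - min(mm_energies)
  w <- torsion_weight(target$e_qm, target$weight_lower, target$weight_upper)
  contrib <- w * ((e_mm - target$e_qm) / target$d_e)^2
  list(loss = mean(contrib),
       contributions = data.frame(angle = target$grid, e_qm = target$e_qm,
                                  e_mm = e_mm, weight = w,
                                  contribution = contrib))
}

#' Evaluate a target's loss under a force field
#'
#' Dispatches on target type: opt-geo targets minimize from the QM geometry
#' under the current parameters, then score internal-coordinate deviations;
#' torsion-profile targets re-minimize each stored scan frame with the four
#' torsion atoms frozen and positional restraints (k = 1 kcal/mol/A^2)
#' on all other atoms, then score the restraint-free relative profile.
#'
#' @param target opt-geo or torsion-profile target.
#' @param ff force field.
#' @param context optional precompiled energy context for `target$mol`
#'   under `ff` (rebuild after changing parameter values).
#' @param tol,maxit minimizer settings.
#' @param starts optional warm-start coordinates from a previous evaluation
#'   at nearby parameters (opt-geo: a conformer; torsion: list of frames).
#'   The minimization result is returned in the output for reuse.
#' @return list(loss, detail, starts).
#' @export
evaluate_target <- function(target, ff, context = NULL, tol = 1e-5,
                            maxit = 2000, starts = NULL) {
  UseMethod("evaluate_target")
}

#' @export
evaluate_target.smirfit_optgeo_target <- function(target, ff, context = NULL,
                                                  tol = 1e-5, maxit = 2000,
                                                  starts = NULL) {
  if (is.null(context)) context <- energy_context(target$mol, ff)
  x0 <- if (is.null(starts)) target$qm_conformer else starts
  res <- minimize_conformer(target$mol, x0, context = context, tol = tol,
                            maxit = maxit)
  out <- optgeo_loss(target, res$coordinates)
  list(loss = out$loss, detail = out$contributions,
       mm_conformer = res$coordinates, converged = res$converged,
       starts = res$coordinates)
}

#' @export
evaluate_target.smirfit_torsion_target <- function(target, ff,
                                                   context = NULL,
                                                   tol = 1e-5, maxit = 2000,
                                                   starts = NULL) {
  if (is.null(context)) context <- energy_context(target$mol, ff)
  others <- setdiff(seq_len(n_atoms(target$mol)), target$dihedral)
  energies <- numeric(length(target$grid))
  conv <- logical(length(target$grid))
  frames <- vector("list", length(target$grid))
  for (gi in seq_along(target$grid)) {
    ref <- target$start_conformers[[gi]]
    xstart <- if (is.null(starts)) ref else starts[[gi]]
    restr <- if (length(others))
      list(list(type = "position", atoms = others,
                ref = ref[others, , drop = FALSE], k = 1))
    else list()
    res <- minimize_conformer(target$mol, xstart, context = context,
                              frozen_atoms = target$dihedral,
                              restraints = restr, tol = tol, maxit = maxit)
    energies[gi] <- res$energy$total_without_restraint
    conv[gi] <- res$converged
    frames[[gi]] <- res$coordinates
  }
  out <- torsion_profile_loss(target, energies)
  list(loss = out$loss, detail = out$contributions, mm_energies = energies,
       converged = all(conv), starts = frames)
}

## ---- target file I/O -------------------------------------------------------

#' Write fitting targets to a JSON file
#'
#' Molecules are stored inline (topology + conformers) so a target file is
#' self-contained.
#'
#' @param targets list of opt-geo / torsion-profile targets.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_targets_json <- function(targets, path) {
  ser_mol <- function(m) list(
    elements = m$elements, formal_charges = m$formal_charges,
    bonds = m$bonds, conformers = m$conformers, charges = m$charges,
    name = m$name)
  objs <- lapply(targets, function(t) {
    if (inherits(t, "smirfit_optgeo_target")) {
      list(kind = "optgeo", id = t$id, molecule = ser_mol(t$mol),
           qm_conformer = t$qm_conformer, divisors = as.list(t$divisors),
           weight = t$weight)
    } else if (inherits(t, "smirfit_torsion_target")) {
      list(kind = "torsion_profile", id = t$id, molecule = ser_mol(t$mol),
           dihedral = t$dihedral, grid = t$grid, e_qm = t$e_qm,
           start_conformers = t$start_conformers, d_e = t$d_e,
           weight = t$weight, weight_lower = t$weight_lower,
           weight_upper = t$weight_upper)
    } else stop("unknown target type")
  })
  writeLines(jsonlite::toJSON(objs, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' Read fitting targets from a JSON file
#' @param path file written by [write_targets_json()].
#' @return list of targets.
#' @export
read_targets_json <- function(path) {
  objs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  de_mol <- function(o) molecule(
    unlist(o$elements),
    matrix(unlist(o$bonds), ncol = 3, byrow = TRUE),
    lapply(o$conformers, function(cc)
      matrix(unlist(cc), ncol = 3, byrow = TRUE)),
    charges = if (is.null(o$charges)) NULL else unlist(o$charges),
    formal_charges = unlist(o$formal_charges), name = o$name %||% "")
  lapply(objs, function(o) {
    mol <- de_mol(o$molecule)
    if (o$kind == "optgeo") {
      optgeo_target(mol,
                    matrix(unlist(o$qm_conformer), ncol = 3, byrow = TRUE),
                    divisors = unlist(o$divisors), weight = o$weight,
                    id = o$id)
    } else {
      torsion_target(mol, unlist(o$dihedral), unlist(o$grid),
                     unlist(o$e_qm),
                     lapply(o$start_conformers, function(cc)
                       matrix(unlist(cc), ncol = 3, byrow = TRUE)),
                     d_e = o$d_e, weight = o$weight,
                     weight_lower = o$weight_lower,
                     weight_upper = o$weight_upper, id = o$id)
    }
  })
}
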