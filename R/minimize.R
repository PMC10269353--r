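# Constrained minimization and restrained torsion scans.

#' Wrap an angle difference into (-180, 180] degrees
#' @param x angle(s) in degrees.
#' @return wrapped angle(s).
#' @export
wrap_angle <- function(x) {
  w <- (x + 180) %% 360 - 180
  ifelse(w == -180, 180, w)
}

.wrap_rad <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  ifelse(w == -pi, pi, w)
}

# restraints: list of entries
#   list(type="position", atoms=, ref=<matrix over those atoms>, k=)
#   list(type="dihedral", atoms=c(i,j,k,l), target=<radians>, k=)   (k per rad^2)
# energy convention k/2 * deviation^2, matching the harmonic valence terms
.restraint_eval <- function(restraints, x, grad = FALSE) {
  e <- 0
  g <- if (grad) matrix(0, nrow(x), 3) else NULL
  for (rs in restraints) {
    if (rs$type == "position") {
      d <- x[rs$atoms, , drop = FALSE] - rs$ref
      e <- e + 0.5 * rs$k * sum(d^2)
      if (grad) g[rs$atoms, ] <- g[rs$atoms, ] + rs$k * d
    } else if (rs$type == "dihedral") {
      a <- rs$atoms
      phi <- .dihedral_angle(x, a[1], a[2], a[3], a[4])
      dphi <- .wrap_rad(phi - rs$target)
      e <- e + 0.5 * rs$k * dphi^2
      if (grad) {
        dg <- .dihedral_gradient(x, a[1], a[2], a[3], a[4])
        f <- rs$k * dphi
        g[a[1], ] <- g[a[1], ] + f * dg$gi
        g[a[2], ] <- g[a[2], ] + f * dg$gj
        g[a[3], ] <- g[a[3], ] + f * dg$gk
        g[a[4], ] <- g[a[4], ] + f * dg$gl
      }
    } else stop("unknown restraint type ", rs$type)
  }
  list(e = e, g = g)
}

#' Minimize a conformer's energy
#'
#' Quasi-Newton (L-BFGS-B) minimization over the Cartesian coordinates of the
#' non-frozen atoms, with optional harmonic positional/dihedral restraints.
#' Convergence is declared when the gradient root-mean-square over free
#' coordinates (restraints included) falls below `tol`; hitting the step
#' budget flags the result rather than raising an error.
#'
#' @param mol molecule.
#' @param conformer conformer index or N x 3 coordinate matrix.
#' @param ff force field (ignored when `context` given).
#' @param assignment optional precomputed assignment.
#' @param frozen_atoms integer atom indices held fixed.
#' @param restraints list of restraints (see Details in the package vignette).
#' @param tol gradient-RMS convergence tolerance (kcal/mol/A).
#' @param maxit maximum optimizer steps.
#' @param context optional precompiled [energy_context()].
#' @return list with `coordinates`, `energy` (breakdown, restraint energy in
#'   the `restraint` slot), `converged`, `grad_rms`, `counts`.
#' @export
minimize_conformer <- function(mol, conformer = 1L, ff = NULL,
                               assignment = NULL, frozen_atoms = integer(0),
                               restraints = list(), tol = 1e-5, maxit = 2000,
                               context = NULL) {
  x0 <- if (is.matrix(conformer)) conformer else mol$conformers[[conformer]]
  if (is.null(context)) context <- energy_context(mol, ff, assignment)
  n <- nrow(x0)
  free <- setdiff(seq_len(n), frozen_atoms)

  full_grad_rms <- function(x) {
    ev <- .energy_eval(context, x, grad = TRUE)
    rg <- .restraint_eval(restraints, x, grad = TRUE)
    g <- ev$gradient + if (is.null(rg$g)) 0 else rg$g
    sqrt(mean(g[free, , drop = FALSE]^2))
  }

  if (length(free) == 0) {
    ev <- .energy_eval(context, x0, grad = FALSE)
    rE <- .restraint_eval(restraints, x0)$e
    ev$breakdown$restraint <- rE
    return(list(coordinates = x0, energy = ev$breakdown, converged = TRUE,
                grad_rms = NA_real_, counts = c(0, 0)))
  }

  xcur <- x0
  fn <- function(par) {
    x <- xcur; x[free, ] <- matrix(par, ncol = 3)
    .energy_eval(context, x, grad = FALSE)$total +
      .restraint_eval(restraints, x)$e
  }
  gr <- function(par) {
    x <- xcur; x[free, ] <- matrix(par, ncol = 3)
    ev <- .energy_eval(context, x, grad = TRUE)
    rg <- .restraint_eval(restraints, x, grad = TRUE)
    g <- ev$gradient + if (is.null(rg$g)) 0 else rg$g
    as.numeric(g[free, , drop = FALSE])
  }

  par <- as.numeric(x0[free, , drop = FALSE])
  total_counts <- c(0, 0)
  converged <- FALSE
  prev_rms <- Inf
  for (round in 1:4) {
    res <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = maxit, factr = 10,
                                       pgtol = tol / 10))
    par <- res$par
    total_counts <- total_counts + res$counts
    xcur[free, ] <- matrix(par, ncol = 3)
    rms <- full_grad_rms(xcur)
    if (rms <= tol) { converged <- TRUE; break }
    if (rms >= prev_rms * 0.5) break  # stalled (machine-precision floor)
    prev_rms <- rms
  }
  x <- xcur
  ev <- .energy_eval(context, x, grad = FALSE)
  ev$breakdown$restraint <- .restraint_eval(restraints, x)$e
  list(coordinates = x, energy = ev$breakdown, converged = converged,
       grad_rms = full_grad_rms(x), counts = total_counts)
}

#' Torsion scan grid
#'
#' Half-open grid over `[range[1], range[2])` at the given spacing (degrees).
#' The default reproduces the 24-point, 15-degree grid used for
#' one-dimensional torsion drives.
#'
#' @param spacing grid spacing in degrees (must divide the range width).
#' @param range two-element degree range, default c(-180, 180).
#' @return numeric vector of grid angles (degrees).
#' @export
make_torsion_grid <- function(spacing = 15, range = c(-180, 180)) {
  width <- range[2] - range[1]
  if (spacing <= 0 || width <= 0) stop("spacing and range must be positive")
  if (abs(width / spacing - round(width / spacing)) > 1e-9)
    stop("spacing ", spacing, " does not divide the range width ", width)
  seq(range[1], range[2] - spacing, by = spacing)
}

# atoms on the k-side of bond j-k (reachable from k without crossing j),
# excluding k itself; error if the bond lies in a ring
.bond_side <- function(mol, j, k) {
  nb <- mol_neighbors(mol)
  seen <- c(j, k)
  queue <- setdiff(nb[[k]], j)
  side <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v == j) stop("bond ", j, "-", k, " is in a ring; rigid driving ",
                     "is not possible (use mode = 'restrain')")
    if (v %in% seen) next
    seen <- c(seen, v); side <- c(side, v)
    queue <- c(queue, setdiff(nb[[v]], seen))
  }
  if (j %in% side) stop("bond in ring")
  side
}

# rigidly rotate the l-side of dihedral (i,j,k,l) so the dihedral equals
# `target` radians, exactly
.drive_dihedral <- function(mol, x, dihedral, target) {
  i <- dihedral[1]; j <- dihedral[2]; k <- dihedral[3]; l <- dihedral[4]
  side <- .bond_side(mol, j, k)
  phi <- .dihedral_angle(x, i, j, k, l)
  delta <- .wrap_rad(target - phi)
  axis <- x[k, ] - x[j, ]
  axis <- axis / sqrt(sum(axis^2))
  rot <- function(theta) {
    K <- matrix(c(0, -axis[3], axis[2],
                  axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
  }
  apply_rot <- function(theta) {
    R <- rot(theta)
    xs <- x
    rel <- sweep(x[side, , drop = FALSE], 2, x[j, ])
    xs[side, ] <- sweep(rel %*% t(R), 2, x[j, ], `+`)
    xs
  }
  x1 <- apply_rot(delta)
  if (abs(.wrap_rad(.dihedral_angle(x1, i, j, k, l) - target)) > 1e-9)
    x1 <- apply_rot(-delta)
  x1
}

#' Restrained torsion scan
#'
#' Drives a dihedral over a grid of angles and minimizes the rest of the
#' molecule at each point, reproducing the constrained-scan protocol used to
#' evaluate torsion-profile targets: the four torsion atoms are held at the
#' driven geometry and every other atom carries a harmonic positional
#' restraint (default force constant 1 kcal/mol/A^2) about its starting
#' position. Reported profile energies exclude all restraint contributions
#' and are referenced to the grid minimum (which is therefore exactly 0).
#'
#' @param mol molecule.
#' @param ff force field.
#' @param assignment optional precomputed assignment.
#' @param dihedral integer vector (i,j,k,l); must be a bonded path.
#' @param grid grid angles in degrees, from [make_torsion_grid()].
#' @param restraint_k positional restraint force constant (kcal/mol/A^2).
#' @param energy_cutoff optional cutoff (kcal/mol): grid points whose
#'   re-referenced energy exceeds it are dropped (the in-ring drive protocol
#'   uses 0.05 hartree, `0.05 * HARTREE_TO_KCALMOL`).
#' @param mode "freeze" (default): dihedral set exactly by rigid rotation,
#'   then the four torsion atoms Cartesian-frozen during minimization.
#'   "restrain": stiff harmonic dihedral restraint of `dihedral_k`
#'   kcal/mol/rad^2 instead of freezing; the residual angle error is checked
#'   against 0.1 degrees and flagged.
#' @param dihedral_k dihedral restraint force constant for mode "restrain".
#' @param conformer starting conformer index or coordinate matrix.
#' @param context optional precompiled energy context.
#' @param tol,maxit minimizer settings per grid point.
#' @return a `smirfit_scan`: `angles`, `energies` (kcal/mol, min 0),
#'   `coordinates` (list), `converged`, `dropped` (angles removed by the
#'   cutoff), `dihedral`.
#' @export
torsion_scan <- function(mol, ff = NULL, assignment = NULL, dihedral, grid,
                         restraint_k = 1, energy_cutoff = NULL,
                         mode = c("freeze", "restrain"), dihedral_k = 1000,
                         conformer = 1L, context = NULL, tol = 1e-5,
                         maxit = 2000) {
  mode <- match.arg(mode)
  dihedral <- as.integer(dihedral)
  if (length(dihedral) != 4) stop("dihedral must have 4 atom indices")
  nbmat <- mol_neighbors(mol)
  for (t in 1:3) {
    if (!dihedral[t + 1] %in% nbmat[[dihedral[t]]])
      stop("dihedral atoms are not bonded i-j-k-l: ",
           paste(dihedral, collapse = "-"))
  }
  if (is.null(context)) context <- energy_context(mol, ff, assignment)
  x0 <- if (is.matrix(conformer)) conformer else mol$conformers[[conformer]]
  grid <- as.numeric(grid)
  ng <- length(grid)

  phi0 <- .dihedral_angle(x0, dihedral[1], dihedral[2], dihedral[3],
                          dihedral[4]) * 180 / pi
  start_idx <- which.min(abs(wrap_angle(grid - phi0)))
  order_idx <- c(seq(start_idx, ng), if (start_idx > 1) seq(start_idx - 1, 1))

  coords <- vector("list", ng)
  energies <- numeric(ng)
  converged <- logical(ng)

  run_point <- function(xstart, angle_deg) {
    target <- angle_deg * pi / 180
    others <- setdiff(seq_len(nrow(x0)), dihedral)
    if (mode == "freeze") {
      xd <- .drive_dihedral(mol, xstart, dihedral, target)
      restr <- if (length(others))
        list(list(type = "position", atoms = others,
                  ref = xd[others, , drop = FALSE], k = restraint_k))
      else list()
      res <- minimize_conformer(mol, xd, context = context,
                                frozen_atoms = dihedral, restraints = restr,
                                tol = tol, maxit = maxit)
    } else {
      xd <- xstart
      restr <- c(
        list(list(type = "dihedral", atoms = dihedral, target = target,
                  k = dihedral_k)),
        if (length(others))
          list(list(type = "position", atoms = others,
                    ref = xd[others, , drop = FALSE], k = restraint_k))
      )
      res <- minimize_conformer(mol, xd, context = context,
                                restraints = restr, tol = tol, maxit = maxit)
      resid <- abs(wrap_angle(.dihedral_angle(res$coordinates, dihedral[1],
                                              dihedral[2], dihedral[3],
                                              dihedral[4]) * 180 / pi -
                              angle_deg))
      if (resid > 0.1) res$converged <- FALSE
    }
    res
  }

  xprev_up <- x0
  for (pos in seq_along(order_idx)) {
    gidx <- order_idx[pos]
    if (pos == 1 || gidx > order_idx[pos - 1]) xstart <- xprev_up
    else if (gidx == start_idx - 1) xstart <- coords[[start_idx]]
    else xstart <- coords[[gidx + 1]]
    res <- run_point(xstart, grid[gidx])
    coords[[gidx]] <- res$coordinates
    energies[gidx] <- res$energy$total_without_restraint
    converged[gidx] <- res$converged
    if (gidx >= start_idx) xprev_up <- res$coordinates
  }

  rel <- energies - min(energies)
  dropped <- numeric(0)
  keep <- rep(TRUE, ng)
  if (!is.null(energy_cutoff)) {
    keep <- rel <= energy_cutoff
    dropped <- grid[!keep]
  }
  rel <- rel[keep] - min(rel[keep])
  structure(list(angles = grid[keep], energies = rel,
                 coordinates = coords[keep], converged = converged[keep],
                 dropped = dropped, dihedral = dihedral),
            class = "smirfit_scan")
}

#' @export
print.smirfit_scan <- function(x, ...) {
  cat(sprintf("<torsion scan %s: %d points, barrier %.3f kcal/mol%s>\n",
              paste(x$dihedral, collapse = "-"), length(x$angles),
              max(x$energies),
              if (length(x$dropped)) paste0(", ", length(x$dropped),
                                            " dropped by cutoff") else ""))
  invisible(x)
}

#' Serialize a torsion scan to JSON
#' @param scan a `smirfit_scan`.
#' @param path optional output file.
#' @return JSON string (invisibly when `path` is given).
#' @export
scan_to_json <- function(scan, path = NULL) {
  obj <- list(dihedral = scan$dihedral, angles = scan$angles,
              energies = scan$energies, converged = scan$converged,
              dropped = scan$dropped)
  txt <- jsonlite::toJSON(obj, digits = NA)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}
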