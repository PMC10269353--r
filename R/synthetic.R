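# Synthetic data with known ground truth: toy molecules built from explicit
# internal-coordinate templates, a ground-truth toy force field, "QM"-style
# fitting targets generated by running the package's own engine under the
# ground truth, a surrogate physical-property backend, and paired
# free-energy benchmark tables. Everything is seed-deterministic.

## ---- z-matrix construction -------------------------------------------------

# rows: list(bond=c(ref, r), angle=c(ref, deg), dihedral=c(ref, deg))
# (angle needed from atom 3 on, dihedral from atom 4 on)
.zmat_build <- function(rows) {
  n <- length(rows)
  x <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    row <- rows[[k]]
    if (k == 1) next
    if (k == 2) { x[2, ] <- c(row$bond[2], 0, 0); next }
    j <- row$bond[1]; r <- row$bond[2]
    i <- row$angle[1]; theta <- row$angle[2] * pi / 180
    if (k == 3 || is.null(row$dihedral)) {
      u <- x[i, ] - x[j, ]; u <- u / sqrt(sum(u^2))
      # any perpendicular
      p <- if (abs(u[1]) < 0.9) .cross3(u, c(1, 0, 0)) else
        .cross3(u, c(0, 1, 0))
      p <- p / sqrt(sum(p^2))
      x[k, ] <- x[j, ] + r * (cos(theta) * u + sin(theta) * p)
    } else {
      # natural-extension (NeRF) placement: distance r to j, angle theta at
      # j w.r.t. i, dihedral phi w.r.t. h-i-j
      h <- row$dihedral[1]; phi <- row$dihedral[2] * pi / 180
      b1 <- x[i, ] - x[h, ]; b2 <- x[j, ] - x[i, ]
      bc <- b2 / sqrt(sum(b2^2))
      nrm <- .cross3(b1, b2); nrm <- nrm / sqrt(sum(nrm^2))
      m <- .cross3(nrm, bc)
      d <- r * (-cos(theta) * bc +
                sin(theta) * (cos(phi) * m - sin(phi) * nrm))
      x[k, ] <- x[j, ] + d
    }
  }
  x
}

# toy partial charges: element/environment-based, then neutralized exactly
.toy_charges <- function(elements, bonds) {
  n <- length(elements)
  base <- c("1" = 0.06, "6" = -0.1, "7" = -0.6, "8" = -0.5, "16" = 0.6)
  q <- unname(base[as.character(elements)])
  q[is.na(q)] <- 0
  # hydrogens on N/O are more positive
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    if (elements[i] == 1L && elements[j] %in% c(7L, 8L)) q[i] <- 0.35
    if (elements[j] == 1L && elements[i] %in% c(7L, 8L)) q[j] <- 0.35
  }
  q - sum(q) / n
}

.zr <- function(ref, r, aref = NULL, a = NULL, dref = NULL, d = NULL) {
  out <- list(bond = c(ref, r))
  if (!is.null(aref)) out$angle <- c(aref, a)
  if (!is.null(dref)) out$dihedral <- c(dref, d)
  out
}

.toy_alkane <- function(n) {
  stopifnot(n >= 2)
  rows <- list(list())                      # C1
  rows[[2]] <- .zr(1, 1.53)                 # C2
  if (n >= 3) rows[[3]] <- .zr(2, 1.53, 1, 112)
  if (n >= 4) for (k in 4:n)
    rows[[k]] <- .zr(k - 1, 1.53, k - 2, 112, k - 3, 180)
  elements <- rep(6L, n)
  bonds <- if (n >= 2) cbind(seq_len(n - 1), 2:n, 1L) else NULL
  # hydrogens: terminal carbons get 3, inner get 2
  hidx <- n
  for (c0 in seq_len(n)) {
    prev <- if (c0 == 1) 2L else c0 - 1L
    aux <- if (c0 == 1) (if (n >= 3) 3L else n + 1L) else
      if (c0 < n) c0 + 1L else c0 - 2L
    nh <- if (c0 == 1 || c0 == n) 3L else 2L
    if (n == 2) aux <- if (c0 == 1) 3L else 3L  # first H placed on C1
    phis <- if (nh == 3) c(60, 180, 300) else c(115, 245)
    for (t in seq_len(nh)) {
      hidx <- hidx + 1L
      if (c0 == 1 && n == 2 && t == 1) {
        rows[[hidx]] <- .zr(1, 1.09, 2, 109.5)       # defines the frame
      } else if (c0 == 1 && n == 2) {
        rows[[hidx]] <- .zr(1, 1.09, 2, 109.5, n + 1L, phis[t] - 60)
      } else {
        rows[[hidx]] <- .zr(c0, 1.09, prev, 109.5, aux, phis[t])
      }
      elements <- c(elements, 1L)
      bonds <- rbind(bonds, c(c0, hidx, 1L))
    }
  }
  list(rows = rows, elements = elements, bonds = bonds)
}

.toy_templates <- function() {
  ald <- function(...) list(...)
  list(
    methanol = function() {
      rows <- list(list(), .zr(1, 1.43), .zr(2, 0.96, 1, 108),
                   .zr(1, 1.09, 2, 109.5, 3, 60),
                   .zr(1, 1.09, 2, 109.5, 3, 180),
                   .zr(1, 1.09, 2, 109.5, 3, 300))
      list(rows = rows, elements = c(6L, 8L, 1L, 1L, 1L, 1L),
           bonds = rbind(c(1, 2, 1), c(2, 3, 1), c(1, 4, 1), c(1, 5, 1),
                         c(1, 6, 1)))
    },
    ether = function() {
      # dimethyl ether: C1 O2 C3 (divalent O without H)
      rows <- list(list(), .zr(1, 1.41), .zr(2, 1.41, 1, 111),
                   .zr(1, 1.09, 2, 109.5, 3, 60),
                   .zr(1, 1.09, 2, 109.5, 3, 180),
                   .zr(1, 1.09, 2, 109.5, 3, 300),
                   .zr(3, 1.09, 2, 109.5, 1, 60),
                   .zr(3, 1.09, 2, 109.5, 1, 180),
                   .zr(3, 1.09, 2, 109.5, 1, 300))
      list(rows = rows, elements = c(6L, 8L, 6L, 1L, 1L, 1L, 1L, 1L, 1L),
           bonds = rbind(c(1, 2, 1), c(2, 3, 1), c(1, 4, 1), c(1, 5, 1),
                         c(1, 6, 1), c(3, 7, 1), c(3, 8, 1), c(3, 9, 1)))
    },
    glycol = function() {
      # ethylene glycol: O1 C2 C3 O4 (gauche backbone)
      rows <- list(list(), .zr(1, 1.43), .zr(2, 1.53, 1, 108),
                   .zr(3, 1.43, 2, 108, 1, 60),
                   .zr(1, 0.96, 2, 108, 3, 180),
                   .zr(4, 0.96, 3, 108, 2, 180),
                   .zr(2, 1.09, 1, 109.5, 3, 120),
                   .zr(2, 1.09, 1, 109.5, 3, 240),
                   .zr(3, 1.09, 4, 109.5, 2, 120),
                   .zr(3, 1.09, 4, 109.5, 2, 240))
      list(rows = rows,
           elements = c(8L, 6L, 6L, 8L, 1L, 1L, 1L, 1L, 1L, 1L),
           bonds = rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(1, 5, 1),
                         c(4, 6, 1), c(2, 7, 1), c(2, 8, 1), c(3, 9, 1),
                         c(3, 10, 1)))
    },
    alcohol = function() {
      # ethanol: C1 C2 O3 H(O) + 5 H(C)
      rows <- list(list(), .zr(1, 1.53), .zr(2, 1.43, 1, 108),
                   .zr(3, 0.96, 2, 108, 1, 180),          # hydroxyl H
                   .zr(1, 1.09, 2, 109.5, 3, 60),
                   .zr(1, 1.09, 2, 109.5, 3, 180),
                   .zr(1, 1.09, 2, 109.5, 3, 300),
                   .zr(2, 1.09, 1, 109.5, 3, 120),
                   .zr(2, 1.09, 1, 109.5, 3, 240))
      list(rows = rows, elements = c(6L, 6L, 8L, 1L, 1L, 1L, 1L, 1L, 1L),
           bonds = rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(1, 5, 1),
                         c(1, 6, 1), c(1, 7, 1), c(2, 8, 1), c(2, 9, 1)))
    },
    amine = function() {
      # ethylamine: C1 C2 N3 + H
      rows <- list(list(), .zr(1, 1.53), .zr(2, 1.47, 1, 110),
                   .zr(3, 1.01, 2, 108, 1, 60),
                   .zr(3, 1.01, 2, 108, 1, 300),
                   .zr(1, 1.09, 2, 109.5, 3, 60),
                   .zr(1, 1.09, 2, 109.5, 3, 180),
                   .zr(1, 1.09, 2, 109.5, 3, 300),
                   .zr(2, 1.09, 1, 109.5, 3, 120),
                   .zr(2, 1.09, 1, 109.5, 3, 240))
      list(rows = rows,
           elements = c(6L, 6L, 7L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
           bonds = rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(3, 5, 1),
                         c(1, 6, 1), c(1, 7, 1), c(1, 8, 1), c(2, 9, 1),
                         c(2, 10, 1)))
    },
    amide = function() {
      # acetamide: C1(methyl) C2(carbonyl) O3 N4
      rows <- list(list(), .zr(1, 1.52), .zr(2, 1.23, 1, 121),
                   .zr(2, 1.35, 1, 115, 3, 180),
                   .zr(4, 1.01, 2, 120, 3, 0),
                   .zr(4, 1.01, 2, 120, 3, 180),
                   .zr(1, 1.09, 2, 109.5, 3, 0),
                   .zr(1, 1.09, 2, 109.5, 3, 120),
                   .zr(1, 1.09, 2, 109.5, 3, 240))
      list(rows = rows,
           elements = c(6L, 6L, 8L, 7L, 1L, 1L, 1L, 1L, 1L),
           bonds = rbind(c(1, 2, 1), c(2, 3, 2), c(2, 4, 1), c(4, 5, 1),
                         c(4, 6, 1), c(1, 7, 1), c(1, 8, 1), c(1, 9, 1)))
    },
    sulfonamide = function() {
      # methanesulfonamide: C1 S2 O3 O4 N5
      rows <- list(list(), .zr(1, 1.78), .zr(2, 1.45, 1, 108),
                   .zr(2, 1.45, 1, 108, 3, 120),
                   .zr(2, 1.68, 1, 102, 3, 240),
                   .zr(5, 1.01, 2, 111, 1, 60),
                   .zr(5, 1.01, 2, 111, 1, 300),
                   .zr(1, 1.09, 2, 109.5, 3, 60),
                   .zr(1, 1.09, 2, 109.5, 3, 180),
                   .zr(1, 1.09, 2, 109.5, 3, 300))
      list(rows = rows,
           elements = c(6L, 16L, 8L, 8L, 7L, 1L, 1L, 1L, 1L, 1L),
           bonds = rbind(c(1, 2, 1), c(2, 3, 2), c(2, 4, 2), c(2, 5, 1),
                         c(5, 6, 1), c(5, 7, 1), c(1, 8, 1), c(1, 9, 1),
                         c(1, 10, 1)))
    },
    nitrile = function() {
      # acetonitrile: C1 C2 N3 (linear angle at C2)
      rows <- list(list(), .zr(1, 1.46), .zr(2, 1.16, 1, 179.5),
                   .zr(1, 1.09, 2, 109.5, 3, 60),
                   .zr(1, 1.09, 2, 109.5, 3, 180),
                   .zr(1, 1.09, 2, 109.5, 3, 300))
      list(rows = rows, elements = c(6L, 6L, 7L, 1L, 1L, 1L),
           bonds = rbind(c(1, 2, 1), c(2, 3, 3), c(1, 4, 1), c(1, 5, 1),
                         c(1, 6, 1)))
    }
  )
}

#' Build deterministic toy molecules
#'
#' Templates are explicit internal-coordinate constructions (no conformer
#' embedder involved), so geometries are bit-reproducible. Available
#' templates: "alkane" (chain length `n`), "alcohol" (ethanol), "amine"
#' (ethylamine), "amide" (acetamide), "sulfonamide" (methanesulfonamide) and
#' "nitrile" (acetonitrile; exercises linear angles). Partial charges follow
#' a fixed element/environment scheme and are exactly neutralized.
#'
#' @param spec list of template requests: either template names or
#'   list(template=, n=) entries. Default: one of each template plus butane.
#' @return named list of `smirfit_molecule`.
#' @export
make_toy_molecules <- function(spec = NULL) {
  if (is.null(spec))
    spec <- list(list(template = "alkane", n = 3),
                 list(template = "alkane", n = 4), "methanol", "ether",
                 "glycol", "alcohol", "amine", "amide", "sulfonamide",
                 "nitrile")
  templates <- .toy_templates()
  out <- list()
  for (s in spec) {
    if (is.character(s)) s <- list(template = s)
    tname <- s$template
    if (tname == "alkane") {
      n <- s$n %||% 4
      def <- .toy_alkane(n)
      name <- paste0("alkane", n)
    } else {
      if (!tname %in% names(templates)) stop("unknown template: ", tname)
      def <- templates[[tname]]()
      name <- tname
    }
    xyz <- .zmat_build(def$rows)
    q <- .toy_charges(def$elements, def$bonds)
    out[[name]] <- molecule(def$elements, def$bonds, xyz, charges = q,
                            name = name)
  }
  out
}

#' Ground-truth toy force field
#'
#' A small ordered SMIRKS-typed force field covering every interaction class
#' of the toy templates, with generic-to-specific parameter hierarchies so
#' last-match-wins assignment is exercised. Values are physically plausible
#' but synthetic; they serve as the known ground truth for parameter
#' recovery.
#'
#' @return a `smirfit_forcefield`.
#' @export
make_toy_forcefield <- function() {
  bp <- function(id, smirks, k, length)
    smirks_parameter(id, smirks, "bond", k = k, length = length)
  ap <- function(id, smirks, k, angle)
    smirks_parameter(id, smirks, "angle", k = k, angle = angle)
  tp <- function(id, smirks, k, periodicity, phase)
    smirks_parameter(id, smirks, "proper_torsion", k = k,
                     periodicity = periodicity, phase = phase)
  vp <- function(id, smirks, epsilon, rmin_half)
    smirks_parameter(id, smirks, "vdw", epsilon = epsilon,
                     rmin_half = rmin_half)
  forcefield(list(
    bond = list(
      bp("b1", "[*:1]~[*:2]", 600, 1.5),
      bp("b2", "[#6X4:1]-[#6X4:2]", 529, 1.526),
      bp("b3", "[#6:1]-[#1:2]", 680, 1.092),
      bp("b4", "[#6X4:1]-[#8X2:2]", 640, 1.43),
      bp("b5", "[#8:1]-[#1:2]", 1100, 0.962),
      bp("b6", "[#6X4:1]-[#7:2]", 620, 1.47),
      bp("b7", "[#6X3:1]-[#7:2]", 840, 1.352),
      bp("b8", "[#7:1]-[#1:2]", 1000, 1.012),
      bp("b9", "[#6X3:1]=[#8X1:2]", 1200, 1.229),
      bp("b10", "[#16:1]=[#8:2]", 1100, 1.452),
      bp("b11", "[#16:1]-[#7:2]", 700, 1.68),
      bp("b12", "[#6:1]-[#16:2]", 480, 1.78),
      bp("b13", "[#6:1]#[#7:2]", 2100, 1.157),
      bp("b14", "[#6X4:1]-[#6X2:2]", 700, 1.46)),
    angle = list(
      ap("a1", "[*:1]~[*:2]~[*:3]", 120, 110.5),
      ap("a2", "[#1:1]-[#6X4:2]-[#1:3]", 70, 107.9),
      ap("a3", "[*:1]~[#6X3:2]~[*:3]", 140, 120.2),
      ap("a4", "[*:1]~[#8X2:2]~[*:3]", 110, 107.5),
      ap("a5", "[*:1]~[#16X4:2]~[*:3]", 130, 108.5),
      ap("a6", "[*:1]~[#6X2:2]~[*:3]", 80, 180)),
    proper_torsion = list(
      tp("t1", "[*:1]~[*:2]~[*:3]~[*:4]", 0.15, 3, 0),
      tp("t2", "[*:1]~[#6X4:2]-[#6X4:3]~[*:4]", 0.25, 3, 0),
      tp("t3", "[*:1]~[#6X4:2]-[#8X2:3]~[*:4]", 0.35, 3, 0),
      tp("t4", "[*:1]~[#6X3:2]-[#7X3:3]~[*:4]", 2.4, 2, 180),
      tp("t5", "[*:1]~[#6X4:2]-[#7X3:3]~[*:4]", 0.4, 3, 0),
      tp("t6", "[*:1]~[#16X4:2]-[#7X3:3]~[*:4]", 0.6, 3, 0),
      tp("t7", "[*:1]~[#6X4:2]-[#6X2:3]~[*:4]", 0, 3, 0)),
    improper_torsion = list(
      smirks_parameter("i1", "[*:1]~[#6X3:2](~[*:3])~[*:4]",
                       "improper_torsion", k = 1.1, periodicity = 2,
                       phase = 180),
      smirks_parameter("i2", "[*:1]~[#7X3:2](~[*:3])~[*:4]",
                       "improper_torsion", k = 1.0, periodicity = 2,
                       phase = 180)),
    vdw = list(
      vp("n1", "[#1:1]", 0.0157, 0.60),
      # hydroxyl hydrogen: vestigial well buried in the host oxygen's
      # envelope and perfectly correlated with it (1:1 co-occurrence in any
      # liquid), so its LJ attributes are held fixed, as production force
      # fields do
      smirks_parameter("n2", "[#1:1]-[#8]", "vdw", epsilon = 0.005,
                       rmin_half = 0.30, optimize = character(0)),
      vp("n3", "[#1:1]-[#7]", 0.01, 0.55),
      vp("n4", "[#6:1]", 0.1094, 1.908),
      vp("n5", "[#6X4:1]", 0.1088, 1.896),
      vp("n6", "[#8:1]", 0.2100, 1.661),
      vp("n7", "[#8X2H1+0:1]", 0.2104, 1.721),
      vp("n8", "[#7:1]", 0.1700, 1.824),
      vp("n9", "[#16:1]", 0.2500, 2.000))
  ), name = "toy-ground-truth", version = "1.0")
}

#' Pick a representative scan dihedral for a molecule
#'
#' First bond whose two atoms both have another heavy (or any, as fallback)
#' neighbor, avoiding colinear triple-bond arms; returns NULL when the
#' molecule has no scannable torsion.
#'
#' @param mol molecule.
#' @return integer 4-vector (i, j, k, l) or NULL.
#' @export
select_scan_dihedral <- function(mol) {
  nb <- mol_neighbors(mol)
  flag <- logical(n_atoms(mol))
  for (r in seq_len(nrow(mol$bonds)))
    if (mol$bonds[r, 3] == 3L) flag[mol$bonds[r, 1:2]] <- TRUE
  for (r in seq_len(nrow(mol$bonds))) {
    j <- mol$bonds[r, 1]; k <- mol$bonds[r, 2]
    if (flag[j] || flag[k]) next
    cand_i <- setdiff(nb[[j]], k)
    cand_l <- setdiff(nb[[k]], j)
    if (length(cand_i) == 0 || length(cand_l) == 0) next
    pick <- function(cands) {
      heavy <- cands[mol$elements[cands] != 1L & !flag[cands]]
      ok <- cands[!flag[cands]]
      if (length(heavy)) heavy[1] else if (length(ok)) ok[1] else NA_integer_
    }
    i <- pick(cand_i); l <- pick(cand_l)
    if (!is.na(i) && !is.na(l)) return(c(i, j, k, l))
  }
  NULL
}

#' Generate synthetic QM-style fitting targets
#'
#' Opt-geo references are geometries minimized under the ground-truth force
#' field plus optional Gaussian coordinate noise; torsion-profile targets
#' are restrained scans under the ground truth plus optional Gaussian energy
#' noise, re-referenced to the grid minimum. With zero noise the total
#' valence data term at the ground truth is zero by construction.
#'
#' @param mols named list of molecules.
#' @param ff ground-truth force field.
#' @param sigma_coord coordinate noise SD (A), default 0.
#' @param sigma_energy profile energy noise SD (kcal/mol), default 0.
#' @param seed RNG seed.
#' @param grid_spacing scan grid spacing (degrees), default 15.
#' @param scan_molecules names of molecules to build torsion targets for
#'   (default: all with a scannable dihedral).
#' @return list(optgeo = list of targets, torsion = list of targets,
#'   skipped = character vector).
#' @export
make_qm_targets <- function(mols, ff, sigma_coord = 0, sigma_energy = 0,
                            seed = 1, grid_spacing = 15,
                            scan_molecules = NULL) {
  set.seed(seed)
  optgeo <- list(); torsion <- list(); skipped <- character(0)
  grid <- make_torsion_grid(grid_spacing)
  for (nm in names(mols)) {
    mol <- mols[[nm]]
    asg <- assign_parameters(mol, ff)
    ctx <- energy_context(mol, ff, asg)
    res <- minimize_conformer(mol, 1L, context = ctx)
    ref <- res$coordinates
    if (sigma_coord > 0)
      ref <- ref + matrix(stats::rnorm(length(ref), 0, sigma_coord),
                          nrow(ref), 3)
    optgeo[[nm]] <- optgeo_target(mol, ref, id = paste0("optgeo-", nm))
    do_scan <- is.null(scan_molecules) || nm %in% scan_molecules
    dih <- select_scan_dihedral(mol)
    if (do_scan && !is.null(dih)) {
      sc <- tryCatch(
        torsion_scan(mol, context = ctx, dihedral = dih, grid = grid,
                     conformer = res$coordinates),
        error = function(e) NULL)
      if (is.null(sc) || !all(sc$converged)) {
        skipped <- c(skipped, nm)
      } else {
        e <- sc$energies
        if (sigma_energy > 0) {
          e <- e + stats::rnorm(length(e), 0, sigma_energy)
          e <- e - min(e)
        }
        torsion[[nm]] <- torsion_target(mol, dih, sc$angles, e,
                                        sc$coordinates,
                                        id = paste0("torsion-", nm))
      }
    }
  }
  list(optgeo = optgeo, torsion = torsion, skipped = skipped)
}

## ---- surrogate property backend -------------------------------------------

#' Surrogate physical-property backend
#'
#' Maps vdW parameters analytically to densities and enthalpies of mixing,
#' standing in for condensed-phase simulation in the LJ fitting loop.
#' Per-substance effective molar volume V = sum_atoms c_v * (R_min/2)^3 *
#' (1 - 0.5 * eps/(eps + 0.2)) (mL/mol) makes density M/V decrease with
#' growing R_min/2 and increase with growing epsilon; mixtures mix volumes
#' ideally for density, and the enthalpy of mixing combines a regular-
#' solution term dH = (x1 V1 + x2 V2) phi1 phi2 (delta1 - delta2)^2 with
#' solubility parameter delta = sqrt(c_e * E_coh / V), E_coh = sum_atoms
#' eps, and a type-resolved cross-interaction term c_x * x1 x2 * sum_t
#' f_t(1) f_t(2) eps_t (f_t = fraction of atoms of vdW type t), which makes
#' the well depths of individual types identifiable from mixture data
#' rather than only their per-substance sums. Gradients are exact
#' (complex-step differentiation).
#'
#' @param mols named list of molecules (the substances).
#' @param ff force field providing vdW typing and default values.
#' @param c_v volume prefactor (mL/mol/A^3), default 3.5.
#' @param c_e cohesion prefactor (kJ/mol per kcal/mol), default 40.
#' @param c_x cross-interaction prefactor (kJ/mol per kcal/mol), default 50.
#' @return backend list with `estimate(theta, map, datapoints)` and
#'   `type_counts`.
#' @export
surrogate_backend <- function(mols, ff, c_v = 3.5, c_e = 40, c_x = 50) {
  vdw_ids <- vapply(ff$parameters$vdw, function(p) p$id, character(1))
  counts <- matrix(0L, length(mols), length(vdw_ids),
                   dimnames = list(names(mols), vdw_ids))
  masses <- stats::setNames(numeric(length(mols)), names(mols))
  for (nm in names(mols)) {
    asg <- assign_parameters(mols[[nm]], ff)
    for (e in asg$by_class$vdw) counts[nm, e$id] <- counts[nm, e$id] + 1L
    masses[nm] <- sum(.ATOMIC_MASSES[as.character(mols[[nm]]$elements)])
  }
  base_eps <- vapply(ff$parameters$vdw, function(p) p$attrs$epsilon,
                     numeric(1))
  base_rmh <- vapply(ff$parameters$vdw, function(p) p$attrs$rmin_half,
                     numeric(1))
  names(base_eps) <- names(base_rmh) <- vdw_ids

  fracs <- counts / rowSums(counts)
  storage.mode(counts) <- "double"

  value_fn <- function(eps, rmh, datapoints) {
    # eps/rmh: (possibly complex) vectors over vdw ids; fully vectorized
    pervol <- c_v * rmh^3 * (1 - 0.7 * eps / (eps + 0.05))
    vols <- as.vector(counts %*% pervol)
    cohs <- as.vector(counts %*% eps)
    names(vols) <- names(cohs) <- rownames(counts)
    i1 <- match(datapoints$comp1, rownames(counts))
    i2 <- match(datapoints$comp2, rownames(counts))
    x1 <- datapoints$x1; x2 <- 1 - x1
    out <- if (is.complex(eps)) complex(nrow(datapoints)) else
      numeric(nrow(datapoints))
    pure <- datapoints$kind == "rho_pure"
    out[pure] <- masses[i1[pure]] / vols[i1[pure]]
    mix <- datapoints$kind == "rho_mix"
    out[mix] <- (x1[mix] * masses[i1[mix]] + x2[mix] * masses[i2[mix]]) /
      (x1[mix] * vols[i1[mix]] + x2[mix] * vols[i2[mix]])
    hm <- datapoints$kind == "hmix"
    if (any(hm)) {
      v1 <- vols[i1[hm]]; v2 <- vols[i2[hm]]
      vm <- x1[hm] * v1 + x2[hm] * v2
      phi1 <- x1[hm] * v1 / vm; phi2 <- x2[hm] * v2 / vm
      d1 <- sqrt(c_e * cohs[i1[hm]] / v1)
      d2 <- sqrt(c_e * cohs[i2[hm]] / v2)
      cross <- c_x * x1[hm] * x2[hm] *
        as.vector((fracs[i1[hm], , drop = FALSE] *
                   fracs[i2[hm], , drop = FALSE]) %*% eps)
      out[hm] <- vm * phi1 * phi2 * (d1 - d2)^2 + cross
    }
    out
  }

  estimate <- function(theta, map, datapoints) {
    eps <- base_eps; rmh <- base_rmh
    if (!is.null(map)) {
      for (r in seq_len(nrow(map))) {
        if (map$attr[r] == "epsilon") eps[map$id[r]] <- theta[r]
        else if (map$attr[r] == "rmin_half") rmh[map$id[r]] <- theta[r]
      }
    }
    values <- Re(value_fn(eps + 0i, rmh + 0i, datapoints))
    gradients <- NULL
    if (!is.null(map)) {
      h <- 1e-20
      gradients <- matrix(0, nrow(datapoints), nrow(map))
      for (r in seq_len(nrow(map))) {
        epsc <- eps + 0i; rmhc <- rmh + 0i
        if (map$attr[r] == "epsilon")
          epsc[map$id[r]] <- epsc[map$id[r]] + h * 1i
        else rmhc[map$id[r]] <- rmhc[map$id[r]] + h * 1i
        gradients[, r] <- Im(value_fn(epsc, rmhc, datapoints)) / h
      }
    }
    list(values = values, gradients = gradients,
         uncertainty = rep(0, nrow(datapoints)))
  }

  list(estimate = estimate, type_counts = counts, masses = masses,
       c_v = c_v, c_e = c_e)
}

#' Generate a synthetic physical-property dataset
#'
#' "Experimental" values are the surrogate model evaluated at the
#' ground-truth force field plus Gaussian noise. The default design spans
#' pure densities for every substance and density/enthalpy curves for a few
#' binary pairs at near-ambient conditions, and deliberately includes
#' points that the curation filters must remove (off-ambient, sub-floor
#' mole fractions).
#'
#' @param mols named list of substances.
#' @param ff ground-truth force field.
#' @param backend optional prebuilt [surrogate_backend()].
#' @param noise_sd named noise SDs c(rho =, hmix =) in data units (defaults
#'   0.002 g/mL and 0.02 kJ/mol).
#' @param seed RNG seed.
#' @param include_filtered also emit points designed to be filtered out
#'   (default TRUE).
#' @return list(datapoints, backend).
#' @export
make_property_dataset <- function(mols, ff, backend = NULL,
                                  noise_sd = c(rho = 0.002, hmix = 0.02),
                                  seed = 1, include_filtered = TRUE) {
  set.seed(seed)
  if (is.null(backend)) backend <- surrogate_backend(mols, ff)
  subs <- names(mols)
  elem_str <- vapply(mols, function(m)
    paste(sort(unique(.ELEMENT_SYMBOLS[as.character(m$elements)])),
          collapse = ","), character(1))
  rows <- list()
  add <- function(kind, s1, s2, x1, temp, pres) {
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, comp1 = s1, comp2 = s2, x1 = x1,
      temperature = temp, pressure = pres, stringsAsFactors = FALSE)
  }
  for (s in subs) {
    for (temp in c(293.15, 298.15, 303.15, 308.15, 313.15))
      add("rho_pure", s, NA, 1, temp, 101.3)
  }
  pairs <- utils::combn(subs, 2)
  for (pc in seq_len(ncol(pairs))) {
    s1 <- pairs[1, pc]; s2 <- pairs[2, pc]
    for (x1 in c(0.25, 0.5, 0.75)) {
      add("rho_mix", s1, s2, x1, 298.15, 101.3)
      add("hmix", s1, s2, x1, 298.15, 101.3)
    }
  }
  if (include_filtered) {
    add("rho_pure", subs[1], NA, 1, 350, 101.3)       # off-ambient T
    add("rho_pure", subs[1], NA, 1, 298.15, 90)       # off-ambient P
    if (length(subs) >= 2) {
      add("rho_mix", subs[1], subs[2], 0.03, 298.15, 101.3)  # sub-floor x
      add("hmix", subs[1], subs[2], 0.97, 298.15, 101.3)     # sub-floor x2
    }
  }
  df <- do.call(rbind, rows)
  df$x2 <- ifelse(is.na(df$comp2), 0, 1 - df$x1)
  df$elements <- ifelse(is.na(df$comp2), elem_str[df$comp1],
                        paste(elem_str[df$comp1], elem_str[df$comp2],
                              sep = ","))
  df$groups <- df$comp1
  est <- backend$estimate(NULL, NULL, df)
  noise <- ifelse(df$kind == "hmix",
                  stats::rnorm(nrow(df), 0, noise_sd[["hmix"]]),
                  stats::rnorm(nrow(df), 0, noise_sd[["rho"]]))
  df$value <- est$values + noise
  df$uncertainty <- ifelse(df$kind == "hmix", noise_sd[["hmix"]],
                           noise_sd[["rho"]])
  list(datapoints = df, backend = backend)
}

#' Generate paired synthetic free-energy benchmark tables
#'
#' Experimental values are Gaussian; the "reference" and "new" predictions
#' add configurable biases and Gaussian noise. The analytic expected mean
#' shift E|b_new + e| - E|b_ref + e| (folded-normal means) is returned for
#' validation.
#'
#' @param n_systems number of paired systems (>= 2).
#' @param bias_ref,bias_new systematic biases (kcal/mol).
#' @param noise_sd prediction noise SD (kcal/mol).
#' @param exp_mean,exp_sd distribution of experimental values.
#' @param seed RNG seed.
#' @return list(new, ref, true_mean_shift) with record data.frames (system,
#'   o_sim, o_exp, uncertainty).
#' @export
make_fe_tables <- function(n_systems, bias_ref = 1, bias_new = 0.5,
                           noise_sd = 0.3, exp_mean = -5, exp_sd = 3,
                           seed = 1) {
  stopifnot(n_systems >= 2)
  set.seed(seed)
  ids <- sprintf("sys%04d", seq_len(n_systems))
  o_exp <- stats::rnorm(n_systems, exp_mean, exp_sd)
  mk <- function(bias) data.frame(
    system = ids, o_exp = o_exp,
    o_sim = o_exp + bias + stats::rnorm(n_systems, 0, noise_sd),
    uncertainty = noise_sd, stringsAsFactors = FALSE)
  folded <- function(b, s) {
    if (s == 0) return(abs(b))
    s * sqrt(2 / pi) * exp(-b^2 / (2 * s^2)) + b * (1 - 2 * stats::pnorm(-b / s))
  }
  list(new = mk(bias_new), ref = mk(bias_ref),
       true_mean_shift = folded(bias_new, noise_sd) -
         folded(bias_ref, noise_sd))
}
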