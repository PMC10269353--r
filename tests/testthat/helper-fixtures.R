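# Shared fixtures and independent oracle routines. Everything here is
# generated in code; oracles are deliberately written without reference to
# the implementation they check.

toy_mols <- make_toy_molecules()
toy_ff <- make_toy_forcefield()

# a minimal diatomic with a single bond parameter
diatomic <- function(r = 1.5) {
  molecule(c(6L, 6L), rbind(c(1, 2, 1)),
           rbind(c(0, 0, 0), c(r, 0, 0)), name = "diatomic")
}

diatomic_ff <- function(k = 500, r0 = 1.5) {
  forcefield(list(
    bond = list(smirks_parameter("b", "[*:1]~[*:2]", "bond", k = k,
                                 length = r0)),
    angle = list(smirks_parameter("a", "[*:1]~[*:2]~[*:3]", "angle",
                                  k = 0, angle = 109.5)),
    proper_torsion = list(smirks_parameter("t", "[*:1]~[*:2]~[*:3]~[*:4]",
                                           "proper_torsion", k = 0,
                                           periodicity = 3, phase = 0)),
    vdw = list(smirks_parameter("n", "[*:1]", "vdw", epsilon = 0,
                                rmin_half = 1))
  ), name = "diatomic")
}

# a 4-atom chain with only one torsion parameter active
torsion_only_mol <- function() {
  molecule(rep(6L, 4), rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1)),
           rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.0, 1.4, 0),
                 c(3.5, 1.5, 0.3)), name = "chain4")
}

torsion_only_ff <- function(K = 1.3, n = 3, phase = 30) {
  forcefield(list(
    bond = list(smirks_parameter("b", "[*:1]~[*:2]", "bond", k = 0,
                                 length = 1.5)),
    angle = list(smirks_parameter("a", "[*:1]~[*:2]~[*:3]", "angle",
                                  k = 0, angle = 109.5)),
    proper_torsion = list(smirks_parameter("t", "[*:1]~[*:2]~[*:3]~[*:4]",
                                           "proper_torsion", k = K,
                                           periodicity = n, phase = phase)),
    vdw = list(smirks_parameter("n", "[*:1]", "vdw", epsilon = 0,
                                rmin_half = 1))
  ), name = "torsion-only")
}

# rigid rotation + translation of a coordinate matrix
rigid_motion <- function(x, angles = c(0.3, -0.8, 1.2), shift = c(5, -2, 7)) {
  rx <- matrix(c(1, 0, 0, 0, cos(angles[1]), -sin(angles[1]),
                 0, sin(angles[1]), cos(angles[1])), 3, 3, byrow = TRUE)
  ry <- matrix(c(cos(angles[2]), 0, sin(angles[2]), 0, 1, 0,
                 -sin(angles[2]), 0, cos(angles[2])), 3, 3, byrow = TRUE)
  rz <- matrix(c(cos(angles[3]), -sin(angles[3]), 0,
                 sin(angles[3]), cos(angles[3]), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  sweep(x %*% t(rz %*% ry %*% rx), 2, shift, `+`)
}

# independent quaternion (Horn) closed-form RMSD oracle
quaternion_rmsd <- function(a, b) {
  a <- sweep(a, 2, colMeans(a)); b <- sweep(b, 2, colMeans(b))
  m <- crossprod(b, a)
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  K <- matrix(c(
    sxx + syy + szz, syz - szy, szx - sxz, sxy - syx,
    syz - szy, sxx - syy - szz, sxy + syx, szx + sxz,
    szx - sxz, sxy + syx, -sxx + syy - szz, syz + szy,
    sxy - syx, szx + sxz, syz + szy, -sxx - syy + szz), 4, 4, byrow = TRUE)
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(a^2) + sum(b^2) - 2 * lmax) / nrow(a)
  sqrt(max(msd, 0))
}

# independent vector-algebra internal-coordinate oracle
oracle_bond_length <- function(x, i, j) sqrt(sum((x[i, ] - x[j, ])^2))
oracle_angle <- function(x, i, j, k) {
  u <- x[i, ] - x[j, ]; v <- x[k, ] - x[j, ]
  acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
}
oracle_dihedral <- function(x, i, j, k, l) {
  b1 <- x[j, ] - x[i, ]; b2 <- x[k, ] - x[j, ]; b3 <- x[l, ] - x[k, ]
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  m <- cr(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m * n2), sum(n1 * n2)) * 180 / pi
}
# improper deviations are reported folded to (-90, 90] so that planarity
# reads 0 on either dihedral branch
oracle_improper <- function(x, i, j, k, l) {
  phi <- oracle_dihedral(x, i, j, k, l)
  phi <- (phi + 180) %% 360 - 180
  if (phi > 90) phi <- phi - 180
  if (phi <= -90) phi <- phi + 180
  phi
}

# brute-force max-min diverse subset (exhaustive over all subsets)
bruteforce_maxmin <- function(d, cap, seed_idx) {
  n <- nrow(d)
  best <- NULL; best_score <- -Inf
  combs <- utils::combn(setdiff(seq_len(n), seed_idx), cap - 1)
  for (ci in seq_len(ncol(combs))) {
    subset <- c(seed_idx, combs[, ci])
    score <- min(d[subset, subset][upper.tri(diag(length(subset)))])
    if (score > best_score) { best_score <- score; best <- subset }
  }
  list(subset = best, score = best_score)
}

perturbed_conformer <- function(mol, sd = 0.05, seed = 1) {
  set.seed(seed)
  mol$conformers[[1]] + matrix(rnorm(3 * n_atoms(mol), 0, sd),
                               n_atoms(mol), 3)
}
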