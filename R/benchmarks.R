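# Benchmark statistics for conformer geometries, energetics and free-energy
# result tables.

#' Optimal-superposition RMSD between two conformers
#'
#' Kabsch algorithm: both coordinate sets are centered and the rotation
#' minimizing the RMSD is found by SVD (with the proper-rotation sign
#' correction), so the metric is invariant under rigid motion of either
#' input and symmetric in its arguments.
#'
#' @param conf_a,conf_b N x 3 coordinate matrices.
#' @param subset optional atom indices to superimpose and score (e.g. heavy
#'   atoms); default all.
#' @return RMSD in Angstrom.
#' @export
conformer_rmsd <- function(conf_a, conf_b, subset = NULL) {
  a <- as.matrix(conf_a); b <- as.matrix(conf_b)
  if (nrow(a) != nrow(b)) stop("conformers have different atom counts")
  if (!is.null(subset)) {
    a <- a[subset, , drop = FALSE]
    b <- b[subset, , drop = FALSE]
  }
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(b, a))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((a - b %*% rot)^2)))
}

## ---- torsion fingerprint deviation ----------------------------------------

# Morgan-style iterative atom invariants (radius refinements of element,
# degree, H count, formal charge) used to detect locally symmetric neighbors.
.atom_invariants <- function(mol, radius = 2) {
  deg <- mol_degrees(mol)
  inv <- as.integer(factor(paste(mol$elements, deg$degree, deg$h_count,
                                 mol$formal_charges)))
  nb <- mol_neighbors(mol)
  for (r in seq_len(radius)) {
    sig <- vapply(seq_along(inv), function(i)
      paste(inv[i], paste(sort(inv[nb[[i]]]), collapse = ","), sep = "|"),
      character(1))
    inv <- as.integer(factor(sig))
  }
  inv
}

.heavy_neighbors <- function(mol, nb, atom, exclude = -1L) {
  ns <- nb[[atom]]
  ns[mol$elements[ns] != 1L & ns != exclude]
}

# reference-atom selection for one end of a torsion, following the cited
# fingerprint method: a single reference atom unless the neighbors are all
# topologically equivalent, in which case every one spawns a quartet
.torsion_reference <- function(mol, neighbors, inv) {
  if (length(neighbors) == 1) return(neighbors)
  iv <- inv[neighbors]
  if (length(unique(iv)) == 1) return(neighbors)          # all symmetric
  if (length(unique(iv)) == length(iv))                   # all different
    return(neighbors[order(iv)][1])
  if (length(neighbors) == 3) {                            # two same, one not
    tab <- table(iv)
    odd <- neighbors[iv == as.integer(names(tab)[tab == 1])]
    return(odd[1])
  }
  neighbors[order(iv)][1]
}

# acyclic test: a connected graph is acyclic iff edges = atoms - components
.count_rings <- function(mol) {
  n <- n_atoms(mol)
  nb <- mol_neighbors(mol)
  seen <- logical(n); comps <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in nb[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  nrow(mol$bonds) - n + comps
}

# torsion list for TFD: one entry per nonterminal acyclic rotatable bond,
# with the set of reference quartets and the normalization (180 under the
# "equal" convention used here)
.tfd_torsion_list <- function(mol) {
  nb <- mol_neighbors(mol)
  inv <- .atom_invariants(mol)
  # atoms that cannot be torsion centres: triple-bond partners (colinear)
  flag <- logical(n_atoms(mol))
  b <- mol$bonds
  for (r in seq_len(nrow(b))) {
    if (b[r, 3] == 3L) flag[b[r, 1:2]] <- TRUE
  }
  out <- list()
  for (r in seq_len(nrow(b))) {
    a1 <- b[r, 1]; a2 <- b[r, 2]
    nb1 <- .heavy_neighbors(mol, nb, a1, exclude = a2)
    nb2 <- .heavy_neighbors(mol, nb, a2, exclude = a1)
    if (length(nb1) == 0 || length(nb2) == 0) next  # terminal bond
    if (flag[a1] || flag[a2]) next                  # colinear centre
    d1 <- .torsion_reference(mol, nb1, inv)
    d2 <- .torsion_reference(mol, nb2, inv)
    quartets <- as.matrix(expand.grid(d1, d2))
    out[[length(out) + 1L]] <- list(
      bond = c(a1, a2),
      quartets = cbind(quartets[, 1], a1, a2, quartets[, 2]),
      maxdev = 180)
  }
  out
}

# per-torsion weights: exp(-beta d^2) with d the topological distance from
# the most central bond, beta calibrated so w(dmax/2) = 0.1
.tfd_weights <- function(mol, tors) {
  distmat <- topological_distances(mol)
  nb <- mol_neighbors(mol)
  n <- n_atoms(mol)
  nonterminal <- which(vapply(seq_len(n), function(i)
    length(.heavy_neighbors(mol, nb, i)) >= 2, logical(1)))
  stds <- vapply(nonterminal, function(i)
    stats::sd(distmat[i, -i]) * sqrt((n - 2) / (n - 1)), numeric(1))
  ord <- nonterminal[order(stds, nonterminal)]
  aid1 <- ord[1]
  aid2 <- NA_integer_
  for (cand in ord[-1]) {
    if (cand %in% nb[[aid1]]) { aid2 <- cand; break }
  }
  if (is.na(aid2)) aid2 <- nb[[aid1]][1]
  # beta from the most distant nonterminal bond
  dmax <- 0
  for (r in seq_len(nrow(mol$bonds))) {
    b1 <- mol$bonds[r, 1]; b2 <- mol$bonds[r, 2]
    if (length(.heavy_neighbors(mol, nb, b2)) <= 1) next
    dmax <- max(dmax, max(distmat[aid1, b1], distmat[aid1, b2]))
  }
  beta <- if (dmax > 0) -log(0.1) / (dmax / 2)^2 else 1
  vapply(tors, function(t) {
    if (setequal(t$bond, c(aid1, aid2))) return(1)
    d <- min(distmat[c(aid1, aid2), t$bond]) + 1
    exp(-beta * d^2)
  }, numeric(1))
}

.tfd_angles <- function(x, tors) {
  lapply(tors, function(t) {
    apply(t$quartets, 1, function(q) {
      a <- .dihedral_angle(x, q[1], q[2], q[3], q[4]) * 180 / pi
      if (a < 0) a + 360 else a
    })
  })
}

#' Torsion fingerprint deviation between two conformers
#'
#' Weighted, normalized deviation of torsion angles about the nonterminal
#' rotatable bonds, following the torsion-fingerprint method of Schulz-Gasch
#' et al. as realized in its reference implementation: per bond, reference
#' quartets are chosen by local-symmetry analysis, the deviation is the
#' minimal circular difference across equivalent quartets normalized by 180
#' degrees, and bonds are weighted by exp(-beta d^2) in the topological
#' distance d from the molecule's most central bond. Undefined (flagged, not
#' 0) when the molecule has no nonterminal rotatable bonds. Supports acyclic
#' molecules; ring systems are out of scope here and raise an error.
#'
#' @param mol molecule.
#' @param conf_a,conf_b conformer indices or N x 3 coordinate matrices.
#' @param use_weights weight torsions by centrality (default TRUE).
#' @return list(tfd, defined, n_torsions).
#' @export
tfd <- function(mol, conf_a, conf_b, use_weights = TRUE) {
  if (.count_rings(mol) > 0)
    stop("TFD for ring systems is not supported")
  xa <- if (is.matrix(conf_a)) conf_a else mol$conformers[[conf_a]]
  xb <- if (is.matrix(conf_b)) conf_b else mol$conformers[[conf_b]]
  tors <- .tfd_torsion_list(mol)
  if (length(tors) == 0)
    return(list(tfd = NA_real_, defined = FALSE, n_torsions = 0L))
  ta <- .tfd_angles(xa, tors)
  tb <- .tfd_angles(xb, tors)
  dev <- vapply(seq_along(tors), function(i) {
    diffs <- abs(outer(ta[[i]], tb[[i]], `-`))
    diffs <- pmin(diffs, 360 - diffs)
    min(diffs) / tors[[i]]$maxdev
  }, numeric(1))
  w <- if (use_weights) .tfd_weights(mol, tors) else rep(1, length(tors))
  list(tfd = sum(dev * w) / sum(w), defined = TRUE,
       n_torsions = length(tors))
}

## ---- conformer energetics --------------------------------------------------

#' Relative conformer-energy errors
#'
#' For each conformer i of a molecule, ddE_i = (E_MM,i - E_MM,0) - (E_QM,i -
#' E_QM,0), where conformer 0 is the QM minimum-energy conformer. The QM
#' minimum has ddE = 0 by construction and is excluded from summary
#' statistics so they are not skewed toward zero; single-conformer molecules
#' are excluded with a reason.
#'
#' @param energies data.frame with columns molecule, conformer, e_qm, e_mm
#'   (kcal/mol).
#' @return list(per_conformer, summary, excluded) where summary holds RMSE,
#'   MAE and mean signed error over the non-reference conformers.
#' @export
ddE_stats <- function(energies) {
  stopifnot(all(c("molecule", "conformer", "e_qm", "e_mm") %in%
                names(energies)))
  per <- list(); excluded <- character(0)
  for (m in unique(energies$molecule)) {
    sub <- energies[energies$molecule == m, , drop = FALSE]
    if (nrow(sub) < 2) {
      excluded <- c(excluded, m)
      next
    }
    ref <- which.min(sub$e_qm)
    dd <- (sub$e_mm - sub$e_mm[ref]) - (sub$e_qm - sub$e_qm[ref])
    per[[m]] <- data.frame(molecule = m, conformer = sub$conformer,
                           ddE = dd, is_reference = seq_len(nrow(sub)) == ref)
  }
  per <- if (length(per)) do.call(rbind, per) else
    data.frame(molecule = character(0), conformer = integer(0),
               ddE = numeric(0), is_reference = logical(0))
  rownames(per) <- NULL
  scored <- per$ddE[!per$is_reference]
  list(per_conformer = per,
       summary = c(rmse = sqrt(mean(scored^2)), mae = mean(abs(scored)),
                   mse = mean(scored)),
       excluded = excluded)
}

#' Bond/angle RMSD and improper deviations between two conformers
#'
#' @param mol molecule.
#' @param conf_qm,conf_mm conformer indices or coordinate matrices.
#' @return list(bond_rmsd (A), angle_rmsd (deg), improper_deviations (deg,
#'   wrapped to (-180, 180]), n_bonds, n_angles).
#' @export
internal_coord_rmsd <- function(mol, conf_qm, conf_mm) {
  icq <- internal_coordinates(mol, conf_qm)
  icm <- internal_coordinates(mol, conf_mm)
  dev <- icq$value - icm$value
  ang <- icq$type %in% c("angle", "improper")
  dev[ang] <- wrap_angle(dev[ang])
  bonds <- dev[icq$type == "bond"]
  angles <- dev[icq$type == "angle"]
  imps <- dev[icq$type == "improper"]
  list(bond_rmsd = if (length(bonds)) sqrt(mean(bonds^2)) else NA_real_,
       angle_rmsd = if (length(angles)) sqrt(mean(angles^2)) else NA_real_,
       improper_deviations = imps,
       n_bonds = length(bonds), n_angles = length(angles))
}

## ---- free-energy statistics ------------------------------------------------

.percentile_ci <- function(stats, level = 0.95) {
  alpha <- (1 - level) / 2
  stats::quantile(stats, c(alpha, 1 - alpha), names = FALSE, na.rm = TRUE)
}

#' Mean shift in unsigned error between two force fields
#'
#' For systems present in both record sets, the shift is |O_sim,new - O_exp|
#' - |O_sim,ref - O_exp|; negative means the new force field improved on the
#' reference. The mean shift is reported with a percentile-bootstrap 95%
#' confidence interval resampling paired systems.
#'
#' @param records_new,records_ref data.frames with columns system, o_sim,
#'   o_exp (and optionally uncertainty).
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed RNG seed (mandatory; recorded in the result).
#' @param level confidence level.
#' @return list(mean_shift, ci, shifts, n, seed).
#' @export
mean_shift <- function(records_new, records_ref, n_boot = 2000, seed,
                       level = 0.95) {
  common <- intersect(records_new$system, records_ref$system)
  if (length(common) == 0) stop("no paired systems between record sets")
  a <- records_new[match(common, records_new$system), ]
  b <- records_ref[match(common, records_ref$system), ]
  if (any(abs(a$o_exp - b$o_exp) > 1e-9))
    warning("experimental values differ between paired records")
  shifts <- abs(a$o_sim - a$o_exp) - abs(b$o_sim - b$o_exp)
  set.seed(seed)
  boot <- replicate(n_boot, {
    idx <- sample.int(length(shifts), replace = TRUE)
    mean(shifts[idx])
  })
  list(mean_shift = mean(shifts), ci = .percentile_ci(boot, level),
       shifts = stats::setNames(shifts, common), n = length(shifts),
       seed = seed)
}

#' Transfer free energy from solvation free energies
#'
#' dG_trans(aq -> nonaq) = dG_solv(nonaq) - dG_solv(aq): the free energy of
#' moving a solute from aqueous solution into a nonaqueous solvent, composed
#' from the two solvation free energies of the same solute.
#'
#' @param dg_solv_aq,dg_solv_nonaq solvation free energies (kcal/mol).
#' @return transfer free energy (kcal/mol).
#' @export
transfer_free_energy <- function(dg_solv_aq, dg_solv_nonaq) {
  if (length(dg_solv_aq) != length(dg_solv_nonaq))
    stop("component vectors differ in length")
  if (anyNA(dg_solv_aq) || anyNA(dg_solv_nonaq))
    stop("missing solvation free-energy component")
  dg_solv_nonaq - dg_solv_aq
}

#' Over-representation of a parameter among high-TFD molecules
#'
#' enrichment = [n(param & TFD > thr) / n(TFD > thr)] /
#'              [n(param) / n(total)]:
#' a value above 1 means molecules carrying the parameter are
#' over-represented among geometry outliers. Molecules with undefined TFD
#' are excluded from every count. `normalized = FALSE` gives the literal
#' fraction n(param & TFD > thr) / n(param) instead.
#'
#' @param comparisons data.frame with columns molecule, tfd and list-column
#'   params (character vectors of applied parameter ids).
#' @param parameter_id parameter of interest.
#' @param tfd_threshold outlier threshold (default 0.1).
#' @param normalized return the enrichment ratio (default) or the literal
#'   fraction.
#' @return list(ratio, defined, counts).
#' @export
enrichment_ratio <- function(comparisons, parameter_id, tfd_threshold = 0.1,
                             normalized = TRUE) {
  ok <- !is.na(comparisons$tfd)
  cc <- comparisons[ok, , drop = FALSE]
  has_p <- vapply(cc$params, function(p) parameter_id %in% p, logical(1))
  high <- cc$tfd > tfd_threshold
  counts <- c(total = nrow(cc), with_param = sum(has_p),
              high_tfd = sum(high), high_with_param = sum(high & has_p))
  if (normalized) {
    if (counts[["high_tfd"]] == 0 || counts[["with_param"]] == 0 ||
        counts[["total"]] == 0)
      return(list(ratio = NA_real_, defined = FALSE, counts = counts))
    ratio <- (counts[["high_with_param"]] / counts[["high_tfd"]]) /
      (counts[["with_param"]] / counts[["total"]])
  } else {
    if (counts[["with_param"]] == 0)
      return(list(ratio = NA_real_, defined = FALSE, counts = counts))
    ratio <- counts[["high_with_param"]] / counts[["with_param"]]
  }
  list(ratio = ratio, defined = TRUE, counts = counts)
}

#' Fraction of shift variance attributable to the force-field change
#'
#' Fits a Gaussian to the distribution of shifts and assumes the simulation
#' noise is zero-mean Gaussian with standard deviation equal to the mean
#' propagated uncertainty: fraction = max(0, s^2 - sigma_noise^2) / s^2.
#' Shifts beyond 2 standard deviations of the fitted Gaussian are reported
#' as outliers.
#'
#' @param shifts numeric vector of per-system shifts (>= 3 values).
#' @param sigma_noise mean propagated simulation uncertainty of a shift.
#' @return list(fraction, defined, sd_shifts, outliers (indices),
#'   outlier_fraction_expected = 0.046).
#' @export
variance_deconvolution <- function(shifts, sigma_noise) {
  if (length(shifts) < 3) stop("need at least 3 shifts")
  if (sigma_noise < 0) stop("uncertainty must be >= 0")
  s2 <- stats::var(shifts)
  if (s2 == 0) return(list(fraction = NA_real_, defined = FALSE,
                           sd_shifts = 0, outliers = integer(0)))
  frac <- max(0, s2 - sigma_noise^2) / s2
  mu <- mean(shifts); s <- sqrt(s2)
  outliers <- which(abs(shifts - mu) > 2 * s)
  list(fraction = frac, defined = TRUE, sd_shifts = s, outliers = outliers,
       outlier_fraction_expected = 2 * stats::pnorm(-2))
}

#' RMSE and mean signed error with bootstrap confidence intervals
#'
#' @param records data.frame with columns o_sim, o_exp.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed.
#' @param level confidence level.
#' @return list(rmse, rmse_ci, mse, mse_ci, n, seed).
#' @export
rmse_with_ci <- function(records, n_boot = 2000, seed, level = 0.95) {
  if (nrow(records) < 2) stop("need at least 2 records")
  err <- records$o_sim - records$o_exp
  set.seed(seed)
  boot <- replicate(n_boot, {
    idx <- sample.int(length(err), replace = TRUE)
    c(sqrt(mean(err[idx]^2)), mean(err[idx]))
  })
  list(rmse = sqrt(mean(err^2)), rmse_ci = .percentile_ci(boot[1, ], level),
       mse = mean(err), mse_ci = .percentile_ci(boot[2, ], level),
       n = length(err), seed = seed)
}
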