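# Small supporting interfaces: the functional-group library, scan-frame
# export, and RMSD-based conformer pairing for the matched ddE variant.

#' Load a functional-group SMARTS library
#'
#' Reads a YAML mapping of group label to SMARTS pattern. The package ships
#' a starter library covering the toy-template chemistry in
#' `inst/extdata/functional_groups.yaml`.
#'
#' @param path YAML file; default the shipped library.
#' @return named character vector (label -> SMARTS).
#' @export
load_group_library <- function(path = system.file("extdata",
                                                  "functional_groups.yaml",
                                                  package = "smirfit")) {
  lib <- yaml::read_yaml(path)
  unlist(lib)
}

#' Write torsion-scan frames as a multi-conformer SDF
#'
#' @param scan a `smirfit_scan`.
#' @param mol the scanned molecule (topology source).
#' @param path output SDF path.
#' @return `path`, invisibly.
#' @export
scan_to_sdf <- function(scan, mol, path) {
  m <- mol
  m$conformers <- scan$coordinates
  write_molecules_sdf(m, path)
}

#' Pair MM conformers with QM conformers by RMSD
#'
#' Front-end for the RMSD-matched variant of relative conformer-energy
#' scoring: instead of comparing each MM-minimized conformer directly to
#' the QM conformer it started from, each MM conformer is matched to the
#' nearest QM conformer within a cutoff (greedy, best matches first);
#' unmatched conformers are dropped from the comparison.
#'
#' @param mol molecule (for the atom subset convention).
#' @param qm_conformers,mm_conformers lists of N x 3 matrices.
#' @param cutoff maximum RMSD for a valid match (A), default 1.
#' @param heavy_only match on heavy atoms only (default TRUE).
#' @return data.frame (mm, qm, rmsd) of accepted pairs.
#' @export
match_conformers_by_rmsd <- function(mol, qm_conformers, mm_conformers,
                                     cutoff = 1, heavy_only = TRUE) {
  subset <- if (heavy_only) which(mol$elements != 1L) else NULL
  d <- matrix(Inf, length(mm_conformers), length(qm_conformers))
  for (a in seq_along(mm_conformers)) for (b in seq_along(qm_conformers))
    d[a, b] <- conformer_rmsd(mm_conformers[[a]], qm_conformers[[b]],
                              subset = subset)
  pairs <- list()
  repeat {
    best <- which(d == min(d), arr.ind = TRUE)[1, ]
    if (is.infinite(d[best[1], best[2]]) || d[best[1], best[2]] > cutoff)
      break
    pairs[[length(pairs) + 1L]] <- data.frame(
      mm = best[[1]], qm = best[[2]], rmsd = d[best[1], best[2]])
    d[best[1], ] <- Inf
    d[, best[2]] <- Inf
    if (all(is.infinite(d))) break
  }
  if (length(pairs) == 0)
    return(data.frame(mm = integer(0), qm = integer(0), rmsd = numeric(0)))
  out <- do.call(rbind, pairs)
  rownames(out) <- NULL
  out
}
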