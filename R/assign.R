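# Direct chemical perception: walk each ordered parameter list, match every
# SMIRKS against the molecule, and let the last matching parameter win for
# each canonical bonded tuple.

#' Canonical key for a bonded tuple
#'
#' Collapses the two traversal directions of a bond/angle/torsion (and the
#' neighbor orderings of an improper) onto a single representative so that a
#' parameter is applied exactly once per chemical tuple.
#'
#' @param tuple integer vector of atom indices; for impropers the *central*
#'   atom must be in the second position (SMIRNOFF convention).
#' @param class parameter class.
#' @return integer vector: bond (i,j) with i<j; angle (i,j,k) with i<k;
#'   proper torsion oriented so the inner pair (j,k) has j<k (ties broken on
#'   the outer pair); improper as (center, sorted neighbors).
#' @export
canonical_key <- function(tuple, class) {
  class <- match.arg(class, .PARAM_CLASSES)
  tuple <- as.integer(tuple)
  if (length(tuple) != .CLASS_ARITY[[class]])
    stop("tuple length ", length(tuple), " does not match class ", class)
  switch(class,
    vdw = tuple,
    bond = if (tuple[1] <= tuple[2]) tuple else rev(tuple),
    angle = if (tuple[1] <= tuple[3]) tuple else rev(tuple),
    proper_torsion = {
      rev_t <- rev(tuple)
      if (tuple[2] < tuple[3]) tuple
      else if (tuple[2] > tuple[3]) rev_t
      else if (tuple[1] <= tuple[4]) tuple else rev_t
    },
    improper_torsion = c(tuple[2], sort(tuple[-2]))
  )
}

.key_string <- function(tuple) paste(tuple, collapse = "-")

# Enumerate all bonded tuples of a molecule per class, already canonical.
enumerate_tuples <- function(mol) {
  nb <- mol_neighbors(mol)
  n <- n_atoms(mol)
  bonds <- lapply(seq_len(nrow(mol$bonds)), function(r)
    canonical_key(mol$bonds[r, 1:2], "bond"))
  angles <- list()
  for (j in seq_len(n)) {
    nbs <- nb[[j]]
    if (length(nbs) < 2) next
    for (a in seq_len(length(nbs) - 1)) for (b in (a + 1):length(nbs)) {
      angles[[length(angles) + 1L]] <-
        canonical_key(c(nbs[a], j, nbs[b]), "angle")
    }
  }
  propers <- list()
  for (r in seq_len(nrow(mol$bonds))) {
    j <- mol$bonds[r, 1]; k <- mol$bonds[r, 2]
    for (i in setdiff(nb[[j]], k)) for (l in setdiff(nb[[k]], j)) {
      if (i == l) next  # three-membered ring wrap-around
      propers[[length(propers) + 1L]] <-
        canonical_key(c(i, j, k, l), "proper_torsion")
    }
  }
  propers <- unique(propers)
  impropers <- list()
  for (c0 in seq_len(n)) {
    if (length(nb[[c0]]) == 3) {
      impropers[[length(impropers) + 1L]] <-
        canonical_key(c(nb[[c0]][1], c0, nb[[c0]][2], nb[[c0]][3]),
                      "improper_torsion")
    }
  }
  list(vdw = lapply(seq_len(n), identity), bond = bonds, angle = angles,
       proper_torsion = propers, improper_torsion = impropers)
}

#' Assign force-field parameters to a molecule
#'
#' For every bonded tuple of each interaction class, the id of the *last*
#' parameter in force-field list order whose SMIRKS matches the tuple wins
#' (SMIRNOFF hierarchy convention: later, more specific patterns override
#' earlier, generic ones). Atoms, bonds, angles and proper torsions must all
#' be covered; improper torsions apply only where a pattern matches.
#'
#' @param mol a `smirfit_molecule`.
#' @param ff a `smirfit_forcefield`.
#' @return a `smirfit_assignment`: per class, a named list mapping canonical
#'   tuple key (dash-joined indices) to list(tuple, id).
#' @export
assign_parameters <- function(mol, ff) {
  ctx <- .smarts_mol_ctx(mol)
  tuples <- enumerate_tuples(mol)
  out <- list()
  for (cl in .PARAM_CLASSES) {
    plist <- ff$parameters[[cl]]
    amap <- list()
    for (p in plist) {
      m <- .smarts_matches_ctx(ctx, smarts_parse(p$smirks), tagged_only = TRUE)
      for (r in seq_len(nrow(m))) {
        key <- canonical_key(m[r, ], cl)
        amap[[.key_string(key)]] <- list(tuple = key, id = p$id)
      }
    }
    required <- if (cl == "improper_torsion") list() else tuples[[cl]]
    missing <- required[!vapply(required, function(t)
      .key_string(t) %in% names(amap), logical(1))]
    if (length(missing) > 0)
      stop("unassigned chemistry in molecule '", mol$name, "', class ", cl,
           ": tuple(s) ",
           paste(vapply(missing, .key_string, character(1)), collapse = "; "))
    # keep only tuples that exist in the molecule's enumeration
    valid <- vapply(tuples[[cl]], .key_string, character(1))
    amap <- amap[names(amap) %in% valid]
    out[[cl]] <- if (length(amap)) amap[order(names(amap))] else amap
  }
  structure(list(by_class = out, molecule = mol$name),
            class = "smirfit_assignment")
}

#' @export
print.smirfit_assignment <- function(x, ...) {
  counts <- vapply(x$by_class, length, integer(1))
  cat(sprintf("<assignment for '%s': %s>\n", x$molecule,
              paste(names(counts), counts, sep = "=", collapse = " ")))
  invisible(x)
}

#' Parameter ids used by an assignment
#' @param assignment a `smirfit_assignment`.
#' @param class optional class filter.
#' @return character vector of distinct parameter ids.
#' @export
assigned_ids <- function(assignment, class = NULL) {
  classes <- if (is.null(class)) .PARAM_CLASSES else class
  unique(unlist(lapply(classes, function(cl)
    vapply(assignment$by_class[[cl]], function(e) e$id, character(1)))))
}

#' Count molecules to which each parameter applies
#'
#' A parameter counts once per molecule in which it is assigned to at least
#' one tuple; the result feeds the fitting-eligibility rule (parameters
#' applied to fewer molecules than a threshold are frozen).
#'
#' @param mols list of molecules.
#' @param ff force field.
#' @return named integer vector over all parameter ids (0 for unused).
#' @export
applied_parameter_counts <- function(mols, ff) {
  all_ids <- unlist(lapply(.PARAM_CLASSES, function(cl)
    vapply(ff$parameters[[cl]], function(p) p$id, character(1))))
  counts <- stats::setNames(integer(length(all_ids)), all_ids)
  for (mol in mols) {
    used <- assigned_ids(assign_parameters(mol, ff))
    counts[used] <- counts[used] + 1L
  }
  counts
}
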