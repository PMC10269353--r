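# Training-data selection and filtering rules for QM targets and
# physical-property datasets.

#' Greedy diverse conformer selection
#'
#' Keeps at most `cap` conformers per molecule so conformer-rich molecules do
#' not dominate the fit. When over the cap, a greedy max-min rule applies:
#' seed with the lowest-energy conformer (first conformer when energies are
#' missing), then repeatedly add the conformer whose minimum RMSD to the
#' already-selected set is largest.
#'
#' @param mol molecule whose conformers are selected.
#' @param cap maximum conformers retained (default 10).
#' @param energies optional per-conformer energies (kcal/mol) used to pick
#'   the seed.
#' @param heavy_only compute selection RMSD over heavy atoms only (default
#'   TRUE).
#' @return integer indices of the selected conformers, in selection order.
#' @export
cap_conformers <- function(mol, cap = 10, energies = NULL,
                           heavy_only = TRUE) {
  n <- length(mol$conformers)
  if (n == 0) stop("molecule has at least one conformer required")
  if (n <= cap) return(seq_len(n))
  subset <- if (heavy_only) which(mol$elements != 1L) else NULL
  d <- matrix(0, n, n)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    d[a, b] <- d[b, a] <- conformer_rmsd(mol$conformers[[a]],
                                         mol$conformers[[b]],
                                         subset = subset)
  }
  seed <- if (!is.null(energies)) which.min(energies) else 1L
  selected <- seed
  while (length(selected) < cap) {
    remaining <- setdiff(seq_len(n), selected)
    mindist <- vapply(remaining, function(r)
      min(d[r, selected]), numeric(1))
    best <- remaining[which.max(mindist)]
    selected <- c(selected, best)
  }
  selected
}

#' Detect connectivity changes between two geometries
#'
#' Bonds are perceived from interatomic distances: a pair is bonded iff its
#' distance is below `tolerance` times the sum of covalent radii. A target
#' whose perceived bond set differs between the initial and final geometry
#' (e.g. an intramolecular proton transfer during optimization) is dropped.
#'
#' @param mol molecule (supplies elements).
#' @param initial,final N x 3 coordinate matrices.
#' @param tolerance scaling of the covalent-radius sum (default 1.2).
#' @return list(keep, bonds_initial, bonds_final) where the bond sets are
#'   two-column matrices of perceived pairs.
#' @export
filter_connectivity_change <- function(mol, initial, final,
                                       tolerance = 1.2) {
  perceive <- function(x) {
    radii <- .COVALENT_RADII[as.character(mol$elements)]
    if (anyNA(radii))
      stop("unknown element for bond perception: ",
           paste(unique(mol$elements[is.na(radii)]), collapse = ","))
    n <- nrow(x)
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    dist <- sqrt(rowSums((x[pairs[, 1], , drop = FALSE] -
                          x[pairs[, 2], , drop = FALSE])^2))
    cut <- tolerance * (radii[pairs[, 1]] + radii[pairs[, 2]])
    pairs[dist < cut, , drop = FALSE]
  }
  b0 <- perceive(as.matrix(initial)); b1 <- perceive(as.matrix(final))
  key <- function(b) paste(b[, 1], b[, 2], sep = "-")
  keep <- setequal(key(b0), key(b1))
  list(keep = keep, bonds_initial = b0, bonds_final = b1)
}

#' Detect intramolecular hydrogen bonds (Baker-Hubbard style)
#'
#' Single-structure adaptation of the Baker-Hubbard criterion: a D-H...A
#' contact with donor and acceptor in {N, O}, H...A distance at most
#' `distance_cutoff` and D-H...A angle at least `angle_cutoff` counts as a
#' hydrogen bond. Targets with any hit are excluded from torsion-profile
#' training to avoid fitting against gas-phase-only internal H-bond
#' conformations.
#'
#' @param mol molecule (hydrogens explicit).
#' @param conformer conformer index or coordinate matrix.
#' @param distance_cutoff H...A distance cutoff (A), default 2.5.
#' @param angle_cutoff D-H...A angle cutoff (degrees), default 120.
#' @return list(keep, hbonds) where hbonds is a data.frame (donor, hydrogen,
#'   acceptor, distance, angle).
#' @export
filter_internal_hbonds <- function(mol, conformer = 1L,
                                   distance_cutoff = 2.5,
                                   angle_cutoff = 120) {
  x <- if (is.matrix(conformer)) conformer else mol$conformers[[conformer]]
  nb <- mol_neighbors(mol)
  donors_acceptors <- which(mol$elements %in% c(7L, 8L))
  hits <- list()
  for (d in donors_acceptors) {
    hs <- nb[[d]][mol$elements[nb[[d]]] == 1L]
    for (h in hs) {
      for (a in setdiff(donors_acceptors, d)) {
        if (a %in% nb[[h]]) next  # covalently bound, not an H-bond
        dist <- sqrt(sum((x[h, ] - x[a, ])^2))
        if (dist > distance_cutoff) next
        u <- x[d, ] - x[h, ]; v <- x[a, ] - x[h, ]
        ang <- acos(max(-1, min(1, sum(u * v) /
                                  sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
        if (ang < angle_cutoff) next
        hits[[length(hits) + 1L]] <- data.frame(
          donor = d, hydrogen = h, acceptor = a, distance = dist,
          angle = ang)
      }
    }
  }
  hb <- if (length(hits)) do.call(rbind, hits) else
    data.frame(donor = integer(0), hydrogen = integer(0),
               acceptor = integer(0), distance = numeric(0),
               angle = numeric(0))
  list(keep = nrow(hb) == 0, hbonds = hb)
}

#' Select torsion scans with minimal parameter overlap
#'
#' For each torsion parameter, prefer a candidate scan that exercises it
#' alone across the central bond (0 overlaps with other torsion parameters);
#' when none exists, the allowed overlap count is incremented until a
#' qualifying candidate is found. Ties break deterministically on candidate
#' identifier order.
#'
#' @param candidates data.frame with columns `candidate` (identifier) and a
#'   list-column `params` (character vectors of torsion parameter ids
#'   exercised across the candidate's central bond).
#' @return data.frame (parameter, candidate, overlaps); parameters with no
#'   candidate at any level are reported with NA candidate.
#' @export
select_torsions <- function(candidates) {
  stopifnot(all(c("candidate", "params") %in% names(candidates)))
  all_params <- sort(unique(unlist(candidates$params)))
  rows <- lapply(all_params, function(p) {
    containing <- which(vapply(candidates$params, function(ps) p %in% ps,
                               logical(1)))
    if (length(containing) == 0)
      return(data.frame(parameter = p, candidate = NA_character_,
                        overlaps = NA_integer_))
    overlaps <- vapply(containing, function(ci)
      length(setdiff(candidates$params[[ci]], p)), integer(1))
    lvl <- min(overlaps)
    pool <- containing[overlaps == lvl]
    pool <- pool[order(candidates$candidate[pool])]
    data.frame(parameter = p, candidate = candidates$candidate[pool[1]],
               overlaps = lvl)
  })
  do.call(rbind, rows)
}

#' Assemble a physical-property dataset
#'
#' @param kind "rho_pure", "rho_mix" or "hmix".
#' @param comp1,comp2 substance identifiers (comp2 NA for pure substances).
#' @param x1 mole fraction of component 1 (1 for pure substances).
#' @param temperature K.
#' @param pressure kPa.
#' @param value experimental value (g/mL for densities, kJ/mol for
#'   enthalpies of mixing).
#' @param uncertainty reported uncertainty, same units.
#' @param elements comma-joined element symbols present in the system.
#' @param groups comma-joined functional-group labels.
#' @return data.frame with the package's property-data columns.
#' @export
property_dataset <- function(kind, comp1, comp2 = NA_character_, x1 = 1,
                             temperature, pressure, value,
                             uncertainty = NA_real_, elements = "",
                             groups = "") {
  df <- data.frame(kind = kind, comp1 = comp1, comp2 = comp2, x1 = x1,
                   x2 = ifelse(is.na(comp2), 0, 1 - x1),
                   temperature = temperature, pressure = pressure,
                   value = value, uncertainty = uncertainty,
                   elements = elements, groups = groups,
                   stringsAsFactors = FALSE)
  bad <- abs(df$x1 + df$x2 - 1) > 1e-6
  if (any(bad)) stop("mole fractions must sum to 1")
  df
}

#' Curate physical-property data
#'
#' Applies, in order: element whitelist (H, C, N, O, Cl, Br); ambient window
#' (99.9-101.4 kPa, 288.15-318.15 K, boundaries inclusive); mole-fraction
#' floor (x_i >= 0.05, inclusive); for each binary system and data type,
#' retention of at most 3 points nearest to x1 in {0.25, 0.5, 0.75}; and
#' removal of functional groups left with fewer than `min_group_measurements`
#' measurements for a data type. Points missing required metadata are dropped
#' with a reason.
#'
#' @param datapoints property data.frame.
#' @param elements_allowed element whitelist.
#' @param pressure_window,temperature_window ambient windows (kPa, K).
#' @param min_mole_fraction mole-fraction floor.
#' @param target_fractions concentrations targeted for binary systems.
#' @param min_group_measurements group-coverage minimum (default 5).
#' @param exclusions optional character vector of named exclusion rules among
#'   "long_chain" (alkane/ether chains) and "13diketone", matched against the
#'   `groups` labels; off by default.
#' @return list(retained, report) where report is a `smirfit_curation_report`
#'   (input/retained counts and per-filter removals).
#' @export
filter_property_data <- function(datapoints,
                                 elements_allowed = c("H", "C", "N", "O",
                                                      "Cl", "Br"),
                                 pressure_window = c(99.9, 101.4),
                                 temperature_window = c(288.15, 318.15),
                                 min_mole_fraction = 0.05,
                                 target_fractions = c(0.25, 0.5, 0.75),
                                 min_group_measurements = 5,
                                 exclusions = character(0)) {
  df <- datapoints
  df$.row <- seq_len(nrow(df))
  removed <- list()
  drop <- function(mask, reason) {
    removed[[reason]] <<- c(removed[[reason]], df$.row[mask])
    df <<- df[!mask, , drop = FALSE]
  }

  has_meta <- !is.na(df$temperature) & !is.na(df$pressure) &
    !is.na(df$x1) & !is.na(df$value)
  drop(!has_meta, "missing_metadata")

  elem_ok <- vapply(strsplit(df$elements, ","), function(e)
    all(trimws(e) %in% c(elements_allowed, "")), logical(1))
  drop(!elem_ok, "element_whitelist")

  amb <- df$pressure >= pressure_window[1] & df$pressure <= pressure_window[2] &
    df$temperature >= temperature_window[1] &
    df$temperature <= temperature_window[2]
  drop(!amb, "ambient_window")

  binary <- !is.na(df$comp2)
  floor_ok <- !binary | (pmin(df$x1, df$x2) >= min_mole_fraction)
  drop(!floor_ok, "mole_fraction_floor")

  if ("long_chain" %in% exclusions)
    drop(grepl("long_chain", df$groups), "long_chain_exclusion")
  if ("13diketone" %in% exclusions)
    drop(grepl("13diketone", df$groups), "13diketone_exclusion")

  # 3-concentration selection per binary system and data type
  if (any(!is.na(df$comp2))) {
    keep_rows <- rep(TRUE, nrow(df))
    sysid <- paste(df$kind, df$comp1, df$comp2, sep = "|")
    for (sys in unique(sysid[!is.na(df$comp2)])) {
      idx <- which(sysid == sys)
      if (length(idx) <= length(target_fractions)) next
      chosen <- integer(0)
      for (tf in target_fractions) {
        avail <- setdiff(idx, chosen)
        if (length(avail) == 0) break
        chosen <- c(chosen, avail[which.min(abs(df$x1[avail] - tf))])
      }
      keep_rows[setdiff(idx, chosen)] <- FALSE
    }
    drop(!keep_rows, "concentration_selection")
  }

  # group-coverage minimum, applied last (per data type)
  repeat {
    gl <- strsplit(df$groups, ",")
    gl <- lapply(gl, function(g) trimws(g[nzchar(trimws(g))]))
    tab <- table(unlist(lapply(seq_len(nrow(df)), function(r)
      paste(df$kind[r], gl[[r]], sep = "|"))))
    weak <- names(tab)[tab < min_group_measurements]
    if (length(weak) == 0 || nrow(df) == 0) break
    bad <- vapply(seq_len(nrow(df)), function(r)
      any(paste(df$kind[r], gl[[r]], sep = "|") %in% weak), logical(1))
    if (!any(bad)) break
    drop(bad, "group_coverage")
  }

  report <- structure(list(
    input = nrow(datapoints), retained = nrow(df),
    removed = vapply(removed, length, integer(1)),
    removed_rows = removed,
    retained_rows = df$.row), class = "smirfit_curation_report")
  df$.row <- NULL
  list(retained = df, report = report)
}

#' @export
print.smirfit_curation_report <- function(x, ...) {
  cat(sprintf("<curation: %d in, %d retained, %d removed>\n", x$input,
              x$retained, x$input - x$retained))
  for (r in names(x$removed))
    cat(sprintf("  %-24s -%d\n", r, x$removed[[r]]))
  invisible(x)
}

#' vdW types eligible for Lennard-Jones refitting
#'
#' A vdW type qualifies only with at least `min_points` density points AND at
#' least `min_points` enthalpy-of-mixing points touching it; types under
#' either threshold keep their starting values.
#'
#' @param datapoints property data.frame.
#' @param type_coverage named list: substance id -> character vector of vdW
#'   parameter ids applied to that substance.
#' @param min_points threshold (default 5).
#' @return character vector of eligible vdW ids.
#' @export
eligible_lj_types <- function(datapoints, type_coverage, min_points = 5) {
  count_for <- function(kinds) {
    sub <- datapoints[datapoints$kind %in% kinds, , drop = FALSE]
    tab <- list()
    for (r in seq_len(nrow(sub))) {
      comps <- stats::na.omit(c(sub$comp1[r], sub$comp2[r]))
      ids <- unique(unlist(type_coverage[comps]))
      for (id in ids) tab[[id]] <- (tab[[id]] %||% 0L) + 1L
    }
    tab
  }
  rho <- count_for(c("rho_pure", "rho_mix"))
  hm <- count_for("hmix")
  ids <- union(names(rho), names(hm))
  ids[vapply(ids, function(id)
    (rho[[id]] %||% 0L) >= min_points && (hm[[id]] %||% 0L) >= min_points,
    logical(1))]
}

#' Functional-group co-occurrence graph
#'
#' Groups are nodes; an undirected edge connects two groups that occur
#' together in at least one molecule. Node and edge counts summarize the
#' combinatorial mixing of chemistries in a training set.
#'
#' @param mols list of molecules.
#' @param group_smarts named character vector: group label -> SMARTS.
#' @return list(graph: igraph object, nodes, edges, per_molecule: list of
#'   group labels found per molecule).
#' @export
coverage_graph <- function(mols, group_smarts) {
  parsed <- lapply(group_smarts, function(s)
    tryCatch(smarts_parse(s),
             error = function(e) stop("invalid group SMARTS '", s, "': ",
                                      conditionMessage(e))))
  per_mol <- lapply(mols, function(m) {
    names(group_smarts)[vapply(parsed, function(p)
      nrow(smarts_matches(m, p)) > 0, logical(1))]
  })
  present <- sort(unique(unlist(per_mol)))
  edges <- character(0)
  for (gs in per_mol) {
    gs <- sort(gs)
    if (length(gs) >= 2) {
      cmb <- utils::combn(gs, 2)
      edges <- c(edges, paste(cmb[1, ], cmb[2, ], sep = "\r"))
    }
  }
  edges <- unique(edges)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(present), name = present)
  if (length(edges)) {
    em <- do.call(rbind, strsplit(edges, "\r", fixed = TRUE))
    g <- igraph::add_edges(g, as.vector(t(em)))
  }
  list(graph = g, nodes = length(present), edges = length(edges),
       per_molecule = per_mol)
}
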