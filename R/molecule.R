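# Molecule container: explicit topology + conformers. All coordinates in
# Angstrom, partial charges in elementary charge units.

.ELEMENT_SYMBOLS <- c(
  "1" = "H", "6" = "C", "7" = "N", "8" = "O", "9" = "F", "15" = "P",
  "16" = "S", "17" = "Cl", "35" = "Br"
)
.ELEMENT_NUMBERS <- stats::setNames(as.integer(names(.ELEMENT_SYMBOLS)),
                                    .ELEMENT_SYMBOLS)

# Covalent radii (Angstrom, Cordero 2008) for distance-based bond perception.
.COVALENT_RADII <- c(
  "1" = 0.31, "6" = 0.76, "7" = 0.71, "8" = 0.66, "9" = 0.57,
  "15" = 1.07, "16" = 1.05, "17" = 1.02, "35" = 1.20
)

# Approximate atomic masses (g/mol) for the supported elements.
.ATOMIC_MASSES <- c(
  "1" = 1.008, "6" = 12.011, "7" = 14.007, "8" = 15.999, "9" = 18.998,
  "15" = 30.974, "16" = 32.06, "17" = 35.45, "35" = 79.904
)

#' Construct a molecule
#'
#' A molecule carries explicit topology (atoms with element and formal charge,
#' bonds with integer order), zero or more conformers, and optional fixed
#' partial charges. All parameter assignment and energy evaluation in the
#' package operates on this container.
#'
#' @param elements integer vector of atomic numbers.
#' @param bonds two- or three-column matrix/data.frame of 1-based atom index
#'   pairs and (optionally) integer bond orders (default 1).
#' @param conformers list of N x 3 coordinate matrices (Angstrom), or a single
#'   matrix.
#' @param charges optional numeric vector of partial charges (length N).
#' @param formal_charges optional integer vector of formal charges (default 0).
#' @param name molecule identifier.
#' @return an object of class `smirfit_molecule`.
#' @export
molecule <- function(elements, bonds, conformers = list(), charges = NULL,
                     formal_charges = NULL, name = "") {
  elements <- as.integer(elements)
  n <- length(elements)
  if (is.null(formal_charges)) formal_charges <- integer(n)
  stopifnot(length(formal_charges) == n)
  if (is.data.frame(bonds)) bonds <- as.matrix(bonds)
  if (is.null(bonds) || length(bonds) == 0) {
    bonds <- matrix(integer(0), ncol = 3)
  } else {
    bonds <- as.matrix(bonds)
    if (ncol(bonds) == 2) bonds <- cbind(bonds, 1L)
  }
  storage.mode(bonds) <- "integer"
  colnames(bonds) <- c("i", "j", "order")
  if (nrow(bonds) > 0) {
    if (any(bonds[, 1:2] < 1L) || any(bonds[, 1:2] > n))
      stop("bond indices out of atom range")
    if (any(bonds[, 1] == bonds[, 2])) stop("self-bond not allowed")
    ii <- pmin(bonds[, 1], bonds[, 2]); jj <- pmax(bonds[, 1], bonds[, 2])
    if (anyDuplicated(cbind(ii, jj))) stop("duplicate bonds")
    bonds[, 1] <- ii; bonds[, 2] <- jj
    bonds <- bonds[order(ii, jj), , drop = FALSE]
  }
  if (is.matrix(conformers)) conformers <- list(conformers)
  conformers <- lapply(conformers, function(x) {
    x <- as.matrix(x)
    if (nrow(x) != n || ncol(x) != 3)
      stop("conformer must be an N x 3 matrix with N = number of atoms")
    dimnames(x) <- NULL
    storage.mode(x) <- "double"
    x
  })
  if (!is.null(charges)) {
    charges <- as.numeric(charges)
    if (length(charges) != n) stop("partial-charge count must equal atom count")
  }
  structure(
    list(elements = elements, formal_charges = as.integer(formal_charges),
         bonds = bonds, conformers = conformers, charges = charges,
         name = name),
    class = "smirfit_molecule"
  )
}

#' @export
print.smirfit_molecule <- function(x, ...) {
  sym <- .ELEMENT_SYMBOLS[as.character(x$elements)]
  cat(sprintf("<molecule '%s': %d atoms (%s), %d bonds, %d conformer(s)%s>\n",
              x$name, length(x$elements),
              paste(names(table(sym)), table(sym), sep = "", collapse = " "),
              nrow(x$bonds), length(x$conformers),
              if (is.null(x$charges)) "" else ", charged"))
  invisible(x)
}

n_atoms <- function(mol) length(mol$elements)

# Neighbor list: integer vectors per atom, plus bond-order lookup.
mol_neighbors <- function(mol) {
  n <- n_atoms(mol)
  nb <- vector("list", n)
  for (k in seq_len(n)) nb[[k]] <- integer(0)
  b <- mol$bonds
  for (r in seq_len(nrow(b))) {
    i <- b[r, 1]; j <- b[r, 2]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  lapply(nb, sort)
}

# order of the bond between atoms i and j, or NA if not bonded
bond_order <- function(mol, i, j) {
  b <- mol$bonds
  lo <- pmin(i, j); hi <- pmax(i, j)
  hit <- which(b[, 1] == lo & b[, 2] == hi)
  if (length(hit) == 0) return(NA_integer_)
  b[hit[1], 3]
}

# per-atom degree and attached-hydrogen count (all hydrogens are explicit)
mol_degrees <- function(mol) {
  n <- n_atoms(mol)
  deg <- integer(n); hcount <- integer(n)
  b <- mol$bonds
  for (r in seq_len(nrow(b))) {
    i <- b[r, 1]; j <- b[r, 2]
    deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
    if (mol$elements[j] == 1L) hcount[i] <- hcount[i] + 1L
    if (mol$elements[i] == 1L) hcount[j] <- hcount[j] + 1L
  }
  list(degree = deg, h_count = hcount)
}

# all-pairs topological distance (small molecules; BFS per atom)
topological_distances <- function(mol) {
  n <- n_atoms(mol)
  nb <- mol_neighbors(mol)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in nb[[v]]) {
        if (is.infinite(d[s, w])) {
          d[s, w] <- d[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  d
}

#' Read molecules from an SDF (V2000) file
#'
#' Consecutive records sharing the same molecule title are merged into one
#' molecule with multiple conformers (topology taken from the first record).
#' Partial charges are read from the SDF data field named by `charge_field`
#' when present (whitespace-separated values, one per atom).
#'
#' @param path SDF file path.
#' @param charge_field name of the SDF property holding partial charges.
#' @return list of `smirfit_molecule`.
#' @export
read_molecules_sdf <- function(path, charge_field = "PARTIAL_CHARGES") {
  sdfs <- ChemmineR::read.SDFset(path)
  out <- list()
  for (k in seq_along(sdfs@SDF)) {
    sdf <- sdfs@SDF[[k]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elems <- sub("_.*$", "", rownames(ab))
    elements <- unname(.ELEMENT_NUMBERS[elems])
    if (anyNA(elements)) stop("unsupported element in SDF: ",
                              paste(unique(elems[is.na(elements)]), collapse = ","))
    coords <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
    bonds <- if (length(bb) == 0) NULL else
      unname(as.matrix(bb)[, 1:3, drop = FALSE])
    db <- ChemmineR::datablock(sdf)
    charges <- NULL
    if (charge_field %in% names(db)) {
      charges <- as.numeric(strsplit(trimws(db[[charge_field]]), "\\s+")[[1]])
    }
    nm <- ChemmineR::header(sdf)[["Molecule_Name"]]
    if (is.null(nm) || is.na(nm)) nm <- ""
    prev <- if (length(out)) out[[length(out)]] else NULL
    if (!is.null(prev) && identical(prev$name, nm) &&
        identical(prev$elements, as.integer(elements))) {
      prev$conformers <- c(prev$conformers, list(coords))
      out[[length(out)]] <- prev
    } else {
      out[[length(out) + 1L]] <- molecule(elements, bonds, list(coords),
                                          charges = charges, name = nm)
    }
  }
  out
}

#' Write molecules to an SDF (V2000) file
#'
#' Each conformer becomes one SDF record; partial charges, when present, are
#' written to the data field named by `charge_field`.
#'
#' @param mols list of `smirfit_molecule` (or a single molecule).
#' @param path output file path.
#' @param charge_field SDF property name for partial charges.
#' @return `path`, invisibly.
#' @export
write_molecules_sdf <- function(mols, path, charge_field = "PARTIAL_CHARGES") {
  if (inherits(mols, "smirfit_molecule")) mols <- list(mols)
  lines <- character(0)
  for (mol in mols) {
    confs <- mol$conformers
    if (length(confs) == 0) stop("molecule '", mol$name, "' has no conformer")
    for (xyz in confs) {
      lines <- c(lines, .sdf_record(mol, xyz, charge_field))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

.sdf_record <- function(mol, xyz, charge_field) {
  n <- n_atoms(mol); nb <- nrow(mol$bonds)
  head <- c(mol$name, "  smirfit", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb)
  atoms <- vapply(seq_len(n), function(i) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            xyz[i, 1], xyz[i, 2], xyz[i, 3],
            .ELEMENT_SYMBOLS[as.character(mol$elements[i])])
  }, character(1))
  bonds <- vapply(seq_len(nb), function(r) {
    sprintf("%3d%3d%3d  0  0  0  0", mol$bonds[r, 1], mol$bonds[r, 2],
            mol$bonds[r, 3])
  }, character(1))
  rec <- c(head, counts, atoms, bonds, "M  END")
  if (!is.null(mol$charges)) {
    rec <- c(rec, paste0(">  <", charge_field, ">"),
             paste(formatC(mol$charges, format = "g", digits = 10),
                   collapse = " "), "")
  }
  c(rec, "$$$$")
}
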