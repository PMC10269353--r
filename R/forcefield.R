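# SMIRKS-keyed force-field container. Parameters live in ordered lists per
# interaction class; list order is significant (later patterns override
# earlier ones during assignment) and is preserved by serialization.
#
# Units: distances Angstrom, angles degrees (in files), energies kcal/mol,
# bond k in kcal/mol/A^2, angle k in kcal/mol/rad^2, torsion barriers K in
# kcal/mol, vdW epsilon kcal/mol, R_min/2 Angstrom.

.PARAM_CLASSES <- c("bond", "angle", "proper_torsion", "improper_torsion", "vdw")

.CLASS_ARITY <- c(bond = 2L, angle = 3L, proper_torsion = 4L,
                  improper_torsion = 4L, vdw = 1L)

.DEFAULT_OPTIMIZE <- list(
  bond = c("k", "length"),
  angle = c("k", "angle"),
  proper_torsion = "k",
  improper_torsion = character(0),
  vdw = c("epsilon", "rmin_half")
)

#' Construct a SMIRKS-keyed force-field parameter
#'
#' @param id unique parameter id within its class (e.g. "b57", "a31", "t154",
#'   "n12").
#' @param smirks SMIRKS pattern; the number of tagged atoms must match the
#'   class (2 bond, 3 angle, 4 torsion/improper, 1 vdW).
#' @param class one of "bond", "angle", "proper_torsion", "improper_torsion",
#'   "vdw".
#' @param ... named attributes. Bonds: `k` (kcal/mol/A^2), `length` (A).
#'   Angles: `k` (kcal/mol/rad^2), `angle` (degrees). Torsions: vectors
#'   `periodicity`, `phase` (degrees), `k` (kcal/mol). vdW: `epsilon`
#'   (kcal/mol), `rmin_half` (A).
#' @param optimize character vector of attribute names whose values may be
#'   adjusted during fitting; class-specific defaults follow the convention
#'   that impropers are never optimized and torsion periodicities/phases are
#'   fixed.
#' @return a `smirfit_parameter`.
#' @export
smirks_parameter <- function(id, smirks, class, ..., optimize = NULL) {
  class <- match.arg(class, .PARAM_CLASSES)
  attrs <- list(...)
  nt <- smarts_n_tagged(smirks)
  if (nt != .CLASS_ARITY[[class]])
    stop("parameter ", id, ": SMIRKS has ", nt, " tagged atoms; class '",
         class, "' requires ", .CLASS_ARITY[[class]])
  if (class %in% c("proper_torsion", "improper_torsion")) {
    need <- c("periodicity", "phase", "k")
    if (!all(need %in% names(attrs)))
      stop("parameter ", id, ": torsion needs periodicity, phase, k")
    attrs$periodicity <- as.integer(attrs$periodicity)
    if (any(attrs$periodicity < 1L))
      stop("parameter ", id, ": periodicities must be positive integers")
    if (length(attrs$phase) != length(attrs$periodicity) ||
        length(attrs$k) != length(attrs$periodicity))
      stop("parameter ", id, ": periodicity/phase/k lengths differ")
  } else if (class == "vdw") {
    if (!all(c("epsilon", "rmin_half") %in% names(attrs)))
      stop("parameter ", id, ": vdw needs epsilon and rmin_half")
    if (attrs$epsilon < 0) stop("parameter ", id, ": epsilon must be >= 0")
    if (attrs$rmin_half <= 0) stop("parameter ", id, ": rmin_half must be > 0")
  } else if (class == "bond") {
    if (!all(c("k", "length") %in% names(attrs)))
      stop("parameter ", id, ": bond needs k and length")
  } else if (class == "angle") {
    if (!all(c("k", "angle") %in% names(attrs)))
      stop("parameter ", id, ": angle needs k and angle")
  }
  if (is.null(optimize)) optimize <- .DEFAULT_OPTIMIZE[[class]]
  canon <- switch(class,
    bond = c("k", "length"), angle = c("k", "angle"),
    proper_torsion = c("periodicity", "phase", "k"),
    improper_torsion = c("periodicity", "phase", "k"),
    vdw = c("epsilon", "rmin_half"))
  attrs <- attrs[c(canon, setdiff(names(attrs), canon))]
  structure(list(id = id, smirks = smirks, class = class, attrs = attrs,
                 optimize = optimize),
            class = "smirfit_parameter")
}

#' Construct a force field
#'
#' @param parameters named list with elements `bond`, `angle`,
#'   `proper_torsion`, `improper_torsion`, `vdw`, each an ordered list of
#'   [smirks_parameter()] objects (missing classes become empty lists).
#' @param name,version metadata strings.
#' @param scale14_vdw,scale14_elec 1-4 nonbonded scale factors (AMBER-family
#'   defaults 0.5 and 1/1.2).
#' @param combining_rule vdW combining rule tag (only "Lorentz-Berthelot" is
#'   implemented by the engine).
#' @param extras character vector of unknown serialized sections preserved
#'   verbatim on round-trip.
#' @return a `smirfit_forcefield`.
#' @export
forcefield <- function(parameters = list(), name = "forcefield",
                       version = "0.1", scale14_vdw = 0.5,
                       scale14_elec = 1 / 1.2,
                       combining_rule = "Lorentz-Berthelot",
                       extras = character(0)) {
  params <- stats::setNames(vector("list", length(.PARAM_CLASSES)),
                            .PARAM_CLASSES)
  for (cl in .PARAM_CLASSES) {
    plist <- if (cl %in% names(parameters)) parameters[[cl]] else list()
    ids <- vapply(plist, function(p) p$id, character(1))
    if (anyDuplicated(ids))
      stop("duplicate parameter id in class ", cl, ": ",
           paste(unique(ids[duplicated(ids)]), collapse = ","))
    bad <- vapply(plist, function(p) p$class != cl, logical(1))
    if (any(bad)) stop("parameter of wrong class in list ", cl)
    params[[cl]] <- plist
  }
  structure(list(parameters = params, name = name, version = version,
                 scale14_vdw = scale14_vdw, scale14_elec = scale14_elec,
                 combining_rule = combining_rule, extras = extras),
            class = "smirfit_forcefield")
}

#' @export
print.smirfit_forcefield <- function(x, ...) {
  counts <- vapply(x$parameters, length, integer(1))
  cat(sprintf("<forcefield '%s' v%s: %s>\n", x$name, x$version,
              paste(names(counts), counts, sep = "=", collapse = " ")))
  invisible(x)
}

# look up a parameter by class and id
ff_get_parameter <- function(ff, class, id) {
  for (p in ff$parameters[[class]]) if (p$id == id) return(p)
  stop("no parameter '", id, "' in class ", class)
}

ff_set_attr <- function(ff, class, id, attr, value, index = NULL) {
  plist <- ff$parameters[[class]]
  for (k in seq_along(plist)) {
    if (plist[[k]]$id == id) {
      if (is.null(index)) plist[[k]]$attrs[[attr]] <- value
      else plist[[k]]$attrs[[attr]][index] <- value
      ff$parameters[[class]] <- plist
      return(ff)
    }
  }
  stop("no parameter '", id, "' in class ", class)
}

## ---- XML dialect -----------------------------------------------------------

.XML_SECTION <- c(Bonds = "bond", Angles = "angle",
                  ProperTorsions = "proper_torsion",
                  ImproperTorsions = "improper_torsion", vdW = "vdw")
.XML_CHILD <- c(bond = "Bond", angle = "Angle", proper_torsion = "Proper",
                improper_torsion = "Improper", vdw = "Atom")

#' Parse a force field from XML or JSON text
#'
#' Accepts the package's SMIRNOFF-style XML subset or the equivalent JSON
#' form; the dialect is auto-detected. Round-tripping through
#' [serialize_forcefield()] reproduces the force field exactly, including
#' parameter list order and unknown XML sections.
#'
#' @param text a single string (or character vector of lines) containing the
#'   document, or a file path.
#' @return a `smirfit_forcefield`.
#' @export
parse_forcefield <- function(text) {
  if (length(text) == 1 && !grepl("[<{]", text) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  else text <- paste(text, collapse = "\n")
  first <- substring(trimws(text), 1, 1)
  if (first == "{") .parse_ff_json(text) else .parse_ff_xml(text)
}

.parse_ff_xml <- function(text) {
  doc <- xml2::read_xml(text)
  if (xml2::xml_name(doc) != "ForceField")
    stop("root element must be <ForceField>")
  name <- xml2::xml_attr(doc, "name"); if (is.na(name)) name <- "forcefield"
  version <- xml2::xml_attr(doc, "version"); if (is.na(version)) version <- "0.1"
  params <- list(); extras <- character(0)
  scale14_vdw <- 0.5; scale14_elec <- 1 / 1.2
  combining_rule <- "Lorentz-Berthelot"
  for (sec in xml2::xml_children(doc)) {
    secname <- xml2::xml_name(sec)
    if (secname == "Electrostatics") {
      s <- xml2::xml_attr(sec, "scale14")
      if (!is.na(s)) scale14_elec <- as.numeric(s)
      next
    }
    if (!secname %in% names(.XML_SECTION)) {
      extras <- c(extras, as.character(sec))
      next
    }
    cl <- .XML_SECTION[[secname]]
    if (cl == "vdw") {
      s <- xml2::xml_attr(sec, "scale14")
      if (!is.na(s)) scale14_vdw <- as.numeric(s)
      cr <- xml2::xml_attr(sec, "combining_rule")
      if (!is.na(cr)) combining_rule <- cr
    }
    plist <- lapply(xml2::xml_children(sec), function(node) {
      at <- xml2::xml_attrs(node)
      id <- at[["id"]]; smirks <- at[["smirks"]]
      opt <- if ("parameterize" %in% names(at)) {
        v <- trimws(strsplit(at[["parameterize"]], ",")[[1]])
        v[nzchar(v)]
      } else NULL
      rest <- at[setdiff(names(at), c("id", "smirks", "parameterize"))]
      if (cl %in% c("proper_torsion", "improper_torsion")) {
        idx <- sort(unique(as.integer(sub("^(periodicity|phase|k)", "",
                                          names(rest)))))
        smirks_parameter(id, smirks, cl,
          periodicity = as.integer(rest[paste0("periodicity", idx)]),
          phase = as.numeric(rest[paste0("phase", idx)]),
          k = as.numeric(rest[paste0("k", idx)]),
          optimize = opt)
      } else {
        args <- c(list(id = id, smirks = smirks, class = cl),
                  lapply(as.list(rest), as.numeric), list(optimize = opt))
        do.call(smirks_parameter, args)
      }
    })
    params[[cl]] <- plist
  }
  forcefield(params, name = name, version = version,
             scale14_vdw = scale14_vdw, scale14_elec = scale14_elec,
             combining_rule = combining_rule, extras = extras)
}

.parse_ff_json <- function(text) {
  obj <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  params <- list()
  for (cl in .PARAM_CLASSES) {
    if (is.null(obj$parameters[[cl]])) next
    params[[cl]] <- lapply(obj$parameters[[cl]], function(p) {
      args <- c(list(id = p$id, smirks = p$smirks, class = cl),
                lapply(p$attrs, unlist),
                list(optimize = as.character(unlist(p$optimize))))
      do.call(smirks_parameter, args)
    })
  }
  forcefield(params,
             name = obj$name %||% "forcefield",
             version = obj$version %||% "0.1",
             scale14_vdw = obj$scale14_vdw %||% 0.5,
             scale14_elec = obj$scale14_elec %||% (1 / 1.2),
             combining_rule = obj$combining_rule %||% "Lorentz-Berthelot",
             extras = as.character(unlist(obj$extras %||% list())))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a force field
#'
#' @param ff a `smirfit_forcefield`.
#' @param format "xml" (default) or "json".
#' @param path optional file path; when given the text is written there.
#' @return the document as a single string (invisibly when `path` is given).
#' @export
serialize_forcefield <- function(ff, format = c("xml", "json"), path = NULL) {
  format <- match.arg(format)
  out <- if (format == "xml") .serialize_ff_xml(ff) else .serialize_ff_json(ff)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

.num_attr <- function(x) formatC(x, format = "g", digits = 15)

.serialize_ff_xml <- function(ff) {
  lines <- c(sprintf('<ForceField name="%s" version="%s">', ff$name, ff$version))
  for (cl in .PARAM_CLASSES) {
    plist <- ff$parameters[[cl]]
    secname <- names(.XML_SECTION)[.XML_SECTION == cl]
    open <- if (cl == "vdw")
      sprintf('  <vdW combining_rule="%s" scale14="%s">', ff$combining_rule,
              .num_attr(ff$scale14_vdw))
    else sprintf("  <%s>", secname)
    lines <- c(lines, open)
    for (p in plist) {
      at <- character(0)
      if (cl %in% c("proper_torsion", "improper_torsion")) {
        for (t in seq_along(p$attrs$periodicity)) {
          at <- c(at, sprintf('periodicity%d="%d" phase%d="%s" k%d="%s"',
                              t, p$attrs$periodicity[t], t,
                              .num_attr(p$attrs$phase[t]), t,
                              .num_attr(p$attrs$k[t])))
        }
      } else {
        at <- sprintf('%s="%s"', names(p$attrs),
                      vapply(p$attrs, .num_attr, character(1)))
      }
      popt <- sprintf('parameterize="%s"', paste(p$optimize, collapse = ","))
      lines <- c(lines, sprintf('    <%s id="%s" smirks="%s" %s %s/>',
                                .XML_CHILD[[cl]], p$id,
                                .xml_escape(p$smirks),
                                paste(at, collapse = " "), popt))
    }
    lines <- c(lines, sprintf("  </%s>", secname))
  }
  lines <- c(lines, sprintf('  <Electrostatics scale14="%s"/>',
                            .num_attr(ff$scale14_elec)))
  lines <- c(lines, paste0("  ", ff$extras))
  lines <- c(lines, "</ForceField>")
  paste(lines, collapse = "\n")
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

.serialize_ff_json <- function(ff) {
  obj <- list(
    name = ff$name, version = ff$version,
    scale14_vdw = ff$scale14_vdw, scale14_elec = ff$scale14_elec,
    combining_rule = ff$combining_rule,
    parameters = lapply(ff$parameters, function(plist)
      lapply(plist, function(p)
        list(id = p$id, smirks = p$smirks, attrs = p$attrs,
             optimize = as.list(p$optimize)))),
    extras = as.list(ff$extras)
  )
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
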