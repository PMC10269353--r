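# A focused SMARTS/SMIRKS-subset parser and matcher.
#
# Supported dialect (sufficient for SMIRNOFF-style valence/vdW typing of the
# aliphatic C/H/N/O/P/S/halogen chemistry this package generates):
#   atoms:  [...] bracket expressions and bare *
#           primitives: * (any), #<n> (atomic number), X<n> (total degree),
#           H<n> or H (attached hydrogens), +<n>/+/-<n>/- (formal charge),
#           ! (negation); combined with & (and, high), , (or), ; (and, low);
#           juxtaposition binds like &. Trailing :<n> is the SMIRKS atom map.
#   bonds:  - (single), = (double), # (triple), : (order 4), ~ (any);
#           an omitted bond symbol means single.
#   structure: linear chains with parenthesised branches. Ring-closure digits,
#           aromaticity, chirality and recursive SMARTS are not supported and
#           raise a parse error.

smarts_parse <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  pos <- 1L
  n <- length(chars)
  nodes <- list()          # each: list(expr=, map=)
  edges <- list()          # each: c(a, b, bond) with bond a character
  stack <- integer(0)      # open-branch anchors
  prev <- 0L
  pending_bond <- NULL

  peek <- function() if (pos <= n) chars[pos] else ""
  advance <- function() { pos <<- pos + 1L }

  read_number <- function() {
    start <- pos
    while (pos <= n && grepl("[0-9]", chars[pos])) advance()
    if (pos == start) return(NA_integer_)
    as.integer(paste(chars[start:(pos - 1L)], collapse = ""))
  }

  read_bracket_atom <- function() {
    # positioned just after '['
    prims <- list()   # flat token list incl. operators
    map <- 0L
    repeat {
      ch <- peek()
      if (ch == "") stop("unterminated bracket atom in SMARTS: ", pattern)
      if (ch == "]") { advance(); break }
      if (ch == ":") {
        advance()
        m <- read_number()
        if (is.na(m)) stop("bad atom map in SMARTS: ", pattern)
        map <- m
        next
      }
      if (ch %in% c("&", ",", ";", "!")) {
        prims[[length(prims) + 1L]] <- list(op = ch)
        advance(); next
      }
      if (ch == "*") { prims[[length(prims) + 1L]] <- list(kind = "any"); advance(); next }
      if (ch == "A") { prims[[length(prims) + 1L]] <- list(kind = "any"); advance(); next }
      if (ch == "#") {
        advance(); v <- read_number()
        if (is.na(v)) stop("bad #element in SMARTS: ", pattern)
        prims[[length(prims) + 1L]] <- list(kind = "elem", value = v); next
      }
      if (ch == "X") {
        advance(); v <- read_number()
        if (is.na(v)) stop("bad X primitive in SMARTS: ", pattern)
        prims[[length(prims) + 1L]] <- list(kind = "degree", value = v); next
      }
      if (ch == "H") {
        advance(); v <- read_number()
        if (is.na(v)) v <- 1L
        prims[[length(prims) + 1L]] <- list(kind = "hcount", value = v); next
      }
      if (ch == "+" || ch == "-") {
        sign <- if (ch == "+") 1L else -1L
        advance()
        v <- read_number()
        if (is.na(v)) {
          v <- 1L
          while (peek() == ch) { v <- v + 1L; advance() }
        }
        prims[[length(prims) + 1L]] <- list(kind = "charge", value = sign * v)
        next
      }
      stop("unsupported SMARTS primitive '", ch, "' in: ", pattern)
    }
    list(expr = .smarts_build_expr(prims, pattern), map = map)
  }

  while (pos <= n) {
    ch <- peek()
    if (ch %in% c("-", "=", "#", ":", "~")) {
      if (ch == "#" && pos < n && grepl("[0-9]", chars[pos + 1L]))
        stop("bare #element outside brackets in SMARTS: ", pattern)
      pending_bond <- ch
      advance()
      next
    }
    if (ch == "(") {
      if (prev == 0L) stop("branch before first atom in SMARTS: ", pattern)
      stack <- c(stack, prev)
      advance(); next
    }
    if (ch == ")") {
      if (length(stack) == 0) stop("unbalanced ')' in SMARTS: ", pattern)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      advance(); next
    }
    if (grepl("[0-9]", ch)) stop("ring-closure digits not supported: ", pattern)
    if (ch == "[") {
      advance()
      at <- read_bracket_atom()
    } else if (ch == "*") {
      advance()
      at <- list(expr = list(list(list(kind = "any", neg = FALSE))), map = 0L)
    } else {
      stop("unsupported SMARTS syntax at '", ch, "' in: ", pattern)
    }
    nodes[[length(nodes) + 1L]] <- at
    this <- length(nodes)
    if (prev > 0L) {
      edges[[length(edges) + 1L]] <- list(a = prev, b = this,
                                          bond = if (is.null(pending_bond)) "-" else pending_bond)
    }
    pending_bond <- NULL
    prev <- this
  }
  if (length(stack)) stop("unbalanced '(' in SMARTS: ", pattern)
  if (length(nodes) == 0) stop("empty SMARTS pattern")
  maps <- vapply(nodes, function(x) x$map, integer(1))
  tagged <- maps[maps > 0L]
  if (anyDuplicated(tagged)) stop("duplicate atom map in SMARTS: ", pattern)
  structure(list(nodes = nodes, edges = edges, pattern = pattern),
            class = "smirfit_smarts")
}

# Build OR-of-ANDs expression from the flat primitive/operator token list.
# Precedence: ! > & (and juxtaposition) > , > ;  — ';' terms are distributed
# as additional AND factors into every OR alternative.
.smarts_build_expr <- function(prims, pattern) {
  if (length(prims) == 0) stop("empty bracket atom in SMARTS: ", pattern)
  # split on ';' first
  semi_groups <- list(); current <- list()
  for (p in prims) {
    if (!is.null(p$op) && p$op == ";") {
      semi_groups[[length(semi_groups) + 1L]] <- current; current <- list()
    } else current[[length(current) + 1L]] <- p
  }
  semi_groups[[length(semi_groups) + 1L]] <- current

  parse_group <- function(g) {
    # -> list of alternatives, each a list of primitives with 'neg'
    alts <- list(); cur <- list(); neg <- FALSE
    for (p in g) {
      if (!is.null(p$op)) {
        if (p$op == ",") {
          if (length(cur) == 0) stop("dangling ',' in SMARTS: ", pattern)
          alts[[length(alts) + 1L]] <- cur; cur <- list()
        } else if (p$op == "!") {
          neg <- TRUE
        }
        # '&' is implicit AND; nothing to do
      } else {
        p$neg <- neg; neg <- FALSE
        cur[[length(cur) + 1L]] <- p
      }
    }
    if (length(cur) == 0) stop("dangling operator in SMARTS: ", pattern)
    alts[[length(alts) + 1L]] <- cur
    alts
  }

  groups <- lapply(semi_groups, parse_group)
  # distribute: cartesian product of one alternative per ';' group
  expr <- list(list())
  for (alts in groups) {
    expr <- unlist(lapply(expr, function(e)
      lapply(alts, function(a) c(e, a))), recursive = FALSE)
  }
  expr
}

# Evaluate an atom expression against atom i of a prepared molecule context.
.smarts_atom_ok <- function(expr, ctx, i) {
  for (alt in expr) {
    ok <- TRUE
    for (p in alt) {
      v <- switch(p$kind,
        any    = TRUE,
        elem   = ctx$elements[i] == p$value,
        degree = ctx$degree[i] == p$value,
        hcount = ctx$h_count[i] == p$value,
        charge = ctx$formal[i] == p$value,
        stop("unknown primitive kind ", p$kind))
      if (p$neg) v <- !v
      if (!v) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

.smarts_bond_ok <- function(bond, order) {
  switch(bond,
    "~" = TRUE,
    "-" = order == 1L,
    "=" = order == 2L,
    "#" = order == 3L,
    ":" = order == 4L,
    stop("unknown bond symbol ", bond))
}

# Precompute per-molecule matching context.
.smarts_mol_ctx <- function(mol) {
  deg <- mol_degrees(mol)
  n <- n_atoms(mol)
  ord <- matrix(0L, n, n)
  b <- mol$bonds
  for (r in seq_len(nrow(b))) {
    ord[b[r, 1], b[r, 2]] <- b[r, 3]
    ord[b[r, 2], b[r, 1]] <- b[r, 3]
  }
  list(elements = mol$elements, degree = deg$degree, h_count = deg$h_count,
       formal = mol$formal_charges, order = ord,
       neighbors = mol_neighbors(mol))
}

#' Find all matches of a SMARTS/SMIRKS pattern in a molecule
#'
#' Performs injective subgraph matching of the (tree-shaped) pattern against
#' the molecular graph. Every embedding is returned, including symmetric
#' orientations; callers that need one parameter application per chemical
#' tuple should canonicalize with [canonical_key()].
#'
#' @param mol a `smirfit_molecule`.
#' @param pattern SMARTS/SMIRKS string, or a pre-parsed `smirfit_smarts`.
#' @param tagged_only if `TRUE` (default) return only atoms carrying SMIRKS
#'   atom maps, as a matrix with one column per map index in map order;
#'   otherwise return all pattern atoms.
#' @return integer matrix of atom indices, one row per match (0 rows if none).
#' @export
smarts_matches <- function(mol, pattern, tagged_only = TRUE) {
  pat <- if (inherits(pattern, "smirfit_smarts")) pattern else smarts_parse(pattern)
  ctx <- .smarts_mol_ctx(mol)
  .smarts_matches_ctx(ctx, pat, tagged_only)
}

.smarts_matches_ctx <- function(ctx, pat, tagged_only = TRUE) {
  np <- length(pat$nodes)
  # DFS order with parent pointers (pattern is a tree rooted at node 1)
  adj <- vector("list", np)
  for (e in pat$edges) {
    adj[[e$a]] <- c(adj[[e$a]], list(e))
    adj[[e$b]] <- c(adj[[e$b]], list(list(a = e$b, b = e$a, bond = e$bond)))
  }
  order_nodes <- integer(0); parent <- integer(np); pbond <- character(np)
  visited <- logical(np)
  stack <- 1L; visited[1L] <- TRUE; parent[1L] <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order_nodes <- c(order_nodes, v)
    for (e in adj[[v]]) {
      w <- e$b
      if (!visited[w]) {
        visited[w] <- TRUE
        parent[w] <- v; pbond[w] <- e$bond
        stack <- c(stack, w)
      }
    }
  }
  if (!all(visited)) stop("disconnected SMARTS pattern: ", pat$pattern)

  natoms <- length(ctx$elements)
  assignment <- integer(np)
  results <- list()

  recurse <- function(k) {
    if (k > np) {
      results[[length(results) + 1L]] <<- assignment
      return(invisible())
    }
    node_id <- order_nodes[k]
    node <- pat$nodes[[node_id]]
    cands <- if (parent[node_id] == 0L) {
      seq_len(natoms)
    } else {
      ctx$neighbors[[assignment[parent[node_id]]]]
    }
    for (a in cands) {
      if (a %in% assignment[order_nodes[seq_len(k - 1L)]]) next
      if (parent[node_id] != 0L) {
        ord <- ctx$order[assignment[parent[node_id]], a]
        if (!.smarts_bond_ok(pbond[node_id], ord)) next
      }
      if (!.smarts_atom_ok(node$expr, ctx, a)) next
      assignment[node_id] <<- a
      recurse(k + 1L)
      assignment[node_id] <<- 0L
    }
  }
  recurse(1L)

  maps <- vapply(pat$nodes, function(x) x$map, integer(1))
  cols <- if (tagged_only && any(maps > 0L)) order(maps[maps > 0L]) else NULL
  sel <- if (tagged_only && any(maps > 0L)) which(maps > 0L)[order(maps[maps > 0L])]
         else seq_len(np)
  if (length(results) == 0)
    return(matrix(integer(0), nrow = 0, ncol = length(sel)))
  m <- do.call(rbind, results)[, sel, drop = FALSE]
  unname(unique(m))
}

#' Number of tagged atoms in a SMIRKS pattern
#' @param pattern SMARTS/SMIRKS string or parsed pattern.
#' @return integer count of atom maps.
#' @export
smarts_n_tagged <- function(pattern) {
  pat <- if (inherits(pattern, "smirfit_smarts")) pattern else smarts_parse(pattern)
  sum(vapply(pat$nodes, function(x) x$map, integer(1)) > 0L)
}
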