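#' Substructure pattern matching (SMARTS subset)
#'
#' The feature-definition and pKa rule tables are written in a compact
#' subset of the SMARTS language, matched with a backtracking subgraph
#' search against the heavy-atom connection table. Supported syntax:
#'
#' * atoms: `C N O S P F Cl Br I B` (aliphatic), `c n o s` (aromatic),
#'   `*` (any), `A` (any aliphatic), `a` (any aromatic)
#' * bracket atoms `[...]` with primitives: element symbol or `#n`,
#'   `a`/`A`, charge `+` `-` `+1` `-2` ..., `Hn` (total hydrogen count),
#'   `Xn` (connectivity incl. hydrogens), `Dn` (heavy-atom degree),
#'   `R`/`R0` (ring membership), negation `!`, conjunction `&` or `;`
#'   (and implicit concatenation), disjunction `,`
#' * bonds: `-` `=` `#` `:` `~`; an unannotated bond means
#'   "single or aromatic"
#' * branches `(...)` and ring-closure digits `1`-`9`
#'
#' Recursive SMARTS, wildcard ring-bond counts and stereo primitives are
#' not supported; the shipped definitions only use the subset above.
#'
#' @param pattern pattern string.
#' @return `parse_smarts` returns a query-graph object used by
#'   [smarts_match()].
#' @export
parse_smarts <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  pos <- 1L
  natom <- 0L
  atoms <- list()
  bonds <- list()  # (a1, a2, type) type in single,double,triple,aromatic,any,default
  ring_open <- list()
  peek <- function() if (pos <= length(chars)) chars[pos] else ""
  advance <- function() { pos <<- pos + 1L }
  err <- function(msg) abort(sprintf("invalid pattern '%s': %s", pattern, msg))

  parse_bracket <- function() {
    # pos is at '['
    advance()
    alts <- list(); prims <- list(); neg <- FALSE
    flush_alt <- function() {
      alts[[length(alts) + 1]] <<- prims
      prims <<- list()
    }
    add <- function(p) {
      p$negate <- neg
      prims[[length(prims) + 1]] <<- p
      neg <<- FALSE
    }
    repeat {
      ch <- peek()
      if (ch == "") err("unterminated bracket atom")
      if (ch == "]") { advance(); break }
      if (ch == "!") { neg <- TRUE; advance(); next }
      if (ch %in% c("&", ";")) { advance(); next }
      if (ch == ",") { flush_alt(); advance(); next }
      if (ch == "#") {
        advance(); num <- ""
        while (grepl("[0-9]", peek())) { num <- paste0(num, peek()); advance() }
        if (num == "") err("'#' needs an atomic number")
        add(list(kind = "elem_num", value = as.integer(num)))
        next
      }
      if (ch %in% c("+", "-")) {
        sign <- if (ch == "+") 1L else -1L
        advance(); num <- ""
        while (grepl("[0-9]", peek())) { num <- paste0(num, peek()); advance() }
        reps <- 0L
        while (peek() == ch) { reps <- reps + 1L; advance() }
        mag <- if (num != "") as.integer(num) else 1L + reps
        add(list(kind = "charge", value = sign * mag))
        next
      }
      if (ch %in% c("H", "X", "D", "R")) {
        # H could be element hydrogen; in this subset H always means H-count
        prim_kind <- c(H = "hcount", X = "connect", D = "degree", R = "ring")[ch]
        advance(); num <- ""
        while (grepl("[0-9]", peek())) { num <- paste0(num, peek()); advance() }
        val <- if (num != "") as.integer(num) else
          if (ch == "R") NA_integer_ else 1L
        add(list(kind = prim_kind, value = val))
        next
      }
      if (ch == "a") { advance(); add(list(kind = "arom", value = TRUE)); next }
      if (ch == "A") { advance(); add(list(kind = "arom", value = FALSE)); next }
      if (ch == "*") { advance(); add(list(kind = "any")); next }
      if (grepl("[A-Z]", ch)) {
        sym <- ch; advance()
        if (grepl("[a-z]", peek()) && paste0(sym, peek()) %in%
            c("Cl", "Br", "Si", "Se")) { sym <- paste0(sym, peek()); advance() }
        if (!(sym %in% names(.ELEMENT_NUM)))
          err(sprintf("unknown element symbol '%s'", sym))
        # uppercase element in a bracket is aliphatic, as in full SMARTS
        add(list(kind = "elem", value = sym,
                 aromatic = if (sym %in% c("C", "N", "O", "S", "P")) FALSE else NA))
        next
      }
      if (grepl("[a-z]", ch)) {
        advance()
        add(list(kind = "elem", value = toupper(ch), aromatic = TRUE))
        next
      }
      err(sprintf("unsupported primitive '%s'", ch))
    }
    flush_alt()
    list(bracket = TRUE, alts = alts)
  }

  parse_atom <- function() {
    ch <- peek()
    if (ch == "[") return(parse_bracket())
    if (ch == "*") { advance(); return(list(bracket = FALSE, kind = "any")) }
    if (ch == "A") { advance(); return(list(bracket = FALSE, kind = "arom", value = FALSE)) }
    if (ch == "a") { advance(); return(list(bracket = FALSE, kind = "arom", value = TRUE)) }
    if (grepl("[A-Z]", ch)) {
      sym <- ch; advance()
      if (grepl("[a-z]", peek()) && paste0(sym, peek()) %in% c("Cl", "Br")) {
        sym <- paste0(sym, peek()); advance()
      }
      if (!(sym %in% names(.ELEMENT_NUM)))
        err(sprintf("unknown element symbol '%s'", sym))
      return(list(bracket = FALSE, kind = "elem", value = sym, aromatic = NA))
    }
    if (grepl("[a-z]", ch)) {
      advance()
      return(list(bracket = FALSE, kind = "elem", value = toupper(ch),
                  aromatic = TRUE))
    }
    err(sprintf("expected an atom at position %d", pos))
  }

  add_atom <- function(spec) {
    natom <<- natom + 1L
    atoms[[natom]] <<- spec
    natom
  }
  add_bond <- function(a, b, type) {
    bonds[[length(bonds) + 1]] <<- list(a1 = a, a2 = b, type = type)
  }

  recurse <- function(prev) {
    pending_bond <- "default"
    while (pos <= length(chars)) {
      ch <- peek()
      if (ch == ")") return(invisible(NULL))
      if (ch == "(") {
        advance()
        recurse(prev)
        if (peek() != ")") err("unbalanced parenthesis")
        advance()
        next
      }
      if (ch %in% c("-", "=", "#", ":", "~")) {
        pending_bond <- c(`-` = "single", `=` = "double", `#` = "triple",
                          `:` = "aromatic", `~` = "any")[ch]
        advance()
        next
      }
      if (grepl("[0-9]", ch)) {
        advance()
        if (!is.null(ring_open[[ch]])) {
          add_bond(ring_open[[ch]]$atom, prev, ring_open[[ch]]$bond)
          ring_open[[ch]] <<- NULL
        } else {
          ring_open[[ch]] <<- list(atom = prev, bond = pending_bond)
        }
        pending_bond <- "default"
        next
      }
      spec <- parse_atom()
      idx <- add_atom(spec)
      if (!is.null(prev)) add_bond(prev, idx, pending_bond)
      pending_bond <- "default"
      prev <- idx
    }
    invisible(NULL)
  }
  recurse(NULL)
  if (length(ring_open) > 0 && any(!vapply(ring_open, is.null, logical(1))))
    err("unclosed ring bond")
  if (natom == 0) err("empty pattern")
  structure(list(pattern = pattern, atoms = atoms, bonds = bonds,
                 n = natom), class = "smarts_query")
}

#' @export
print.smarts_query <- function(x, ...) {
  cat(sprintf("<pattern '%s': %d atoms, %d bonds>\n", x$pattern, x$n,
              length(x$bonds)))
  invisible(x)
}

.ELEMENT_NUM <- c(B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
                  Cl = 17, Se = 34, Br = 35, I = 53)

.prim_ok <- function(prim, env_row) {
  val <- switch(prim$kind,
    any = TRUE,
    elem = {
      m <- env_row$element == prim$value
      if (!is.na(prim$aromatic %||% NA))
        m <- m && (env_row$aromatic == prim$aromatic)
      m
    },
    elem_num = identical(unname(.ELEMENT_NUM[env_row$element]),
                         as.numeric(prim$value)),
    charge = env_row$charge == prim$value,
    hcount = env_row$nH == prim$value,
    connect = env_row$X == prim$value,
    degree = env_row$degree == prim$value,
    ring = if (is.na(prim$value)) env_row$in_ring else
      if (prim$value == 0) !env_row$in_ring else env_row$in_ring,
    arom = env_row$aromatic == prim$value,
    abort(paste("unknown primitive", prim$kind)))
  if (isTRUE(prim$negate)) !val else val
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.atom_ok <- function(spec, env_row) {
  if (isTRUE(spec$bracket)) {
    for (alt in spec$alts) {
      ok <- TRUE
      for (prim in alt) if (!.prim_ok(prim, env_row)) { ok <- FALSE; break }
      if (ok) return(TRUE)
    }
    return(FALSE)
  }
  switch(spec$kind,
    any = TRUE,
    arom = env_row$aromatic == spec$value,
    elem = {
      if (!is.na(spec$aromatic %||% NA)) {
        env_row$element == spec$value && env_row$aromatic == spec$aromatic
      } else {
        # plain organic-subset symbol outside brackets: aliphatic
        env_row$element == spec$value && !env_row$aromatic
      }
    })
}

.bond_ok <- function(type, binfo) {
  if (is.null(binfo)) return(FALSE)
  switch(type,
    any = TRUE,
    default = (binfo$order == 1 && !binfo$aromatic) || binfo$aromatic,
    single = binfo$order == 1 && !binfo$aromatic,
    double = binfo$order == 2 && !binfo$aromatic,
    triple = binfo$order == 3,
    aromatic = isTRUE(binfo$aromatic))
}

#' Match a substructure pattern against a molecule
#'
#' @param mol a `phmol`.
#' @param pattern pattern string or a parsed `smarts_query`.
#' @param unique_sets drop matches that cover an atom set already returned
#'   (default `FALSE`: all distinct mappings are returned).
#' @return list of integer vectors; element `i` of a vector is the molecule
#'   atom matched by query atom `i`.
#' @rdname parse_smarts
#' @export
smarts_match <- function(mol, pattern, unique_sets = FALSE) {
  q <- if (inherits(pattern, "smarts_query")) pattern else parse_smarts(pattern)
  env <- atom_env(mol)
  nb <- neighbors_of(mol)
  bl <- bond_order_lookup(mol)
  nq <- q$n
  # adjacency of the query
  qadj <- vector("list", nq)
  for (b in q$bonds) {
    qadj[[b$a1]] <- c(qadj[[b$a1]], list(list(to = b$a2, type = b$type)))
    qadj[[b$a2]] <- c(qadj[[b$a2]], list(list(to = b$a1, type = b$type)))
  }
  cand <- lapply(seq_len(nq), function(i) {
    which(vapply(seq_len(nrow(env)), function(a)
      .atom_ok(q$atoms[[i]], env[a, ]), logical(1)))
  })
  if (any(lengths(cand) == 0)) return(list())
  results <- list()
  assign_vec <- integer(nq)
  used <- logical(nrow(env))
  bt <- function(qi) {
    if (qi > nq) {
      results[[length(results) + 1]] <<- assign_vec
      return(invisible(NULL))
    }
    for (a in cand[[qi]]) {
      if (used[a]) next
      ok <- TRUE
      for (e in qadj[[qi]]) {
        if (e$to < qi) {
          if (!.bond_ok(e$type, bl$get(a, assign_vec[e$to]))) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      assign_vec[qi] <<- a
      used[a] <<- TRUE
      bt(qi + 1L)
      used[a] <<- FALSE
    }
    invisible(NULL)
  }
  bt(1L)
  if (unique_sets && length(results) > 1) {
    keys <- vapply(results, function(r) paste(sort(r), collapse = ","),
                   character(1))
    results <- results[!duplicated(keys)]
  }
  results
}

#' @rdname parse_smarts
#' @export
smarts_count <- function(mol, pattern) {
  length(smarts_match(mol, pattern, unique_sets = TRUE))
}
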