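# Substructure patterns and matching.
#
# Patterns use a declared SMARTS subset: element symbols (uppercase =
# aliphatic, lowercase = aromatic), bracket atoms with charge and an optional
# ring-membership primitive R / R0, and bond primitives - = # : plus the
# default "single or aromatic" bond.  Anything outside this subset is a hard
# parse error -- predictable matching beats full SMARTS.

#' Compile a substructure pattern
#'
#' @param pattern pattern string in the supported SMARTS subset, e.g. `"N=O"`,
#'   `"C=C"`, `"[cR]"`.
#' @param label optional human-readable label.
#' @return an object of class `orbgap_fragment`.
#' @examples
#' fp <- fragment_pattern("N=O", "nitroso")
#' @export
fragment_pattern <- function(pattern, label = pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern))
    stopf("pattern must be a single non-empty string")
  q <- parse_pattern(pattern)
  structure(list(pattern = pattern, label = label,
                 atoms = q$atoms, bonds = q$bonds),
            class = "orbgap_fragment")
}

parse_pattern <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars); i <- 1L
  atoms <- list(); bonds <- list()
  stack <- integer(0); prev <- NA_integer_; pending <- NA_integer_
  ring_open <- list()
  add_atom <- function(el, arom, charge, ring) {
    atoms[[length(atoms) + 1L]] <<- list(element = el, aromatic = arom,
                                         charge = charge, ring = ring)
    idx <- length(atoms)
    if (!is.na(prev))
      bonds[[length(bonds) + 1L]] <<- list(i = prev, j = idx, order = pending)
    pending <<- NA_integer_
    prev <<- idx
  }
  while (i <= n) {
    ch <- chars[i]
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stopf("pattern parse error at position %d: unclosed '['", i)
      body <- substr(s, i + 1L, j - 1L)
      m <- regmatches(body, regexec(
        "^([A-Za-z][a-z]?)([+-][0-9]*)?(R0?)?$", body))[[1]]
      if (length(m) == 0L)
        stopf("pattern parse error at position %d: unsupported primitive in '[%s]'", i, body)
      sym <- m[2]
      arom <- sym %in% AROMATIC_ELEMS
      el <- if (arom) toupper(sym) else sym
      if (!el %in% ORGANIC_SUBSET)
        stopf("pattern parse error at position %d: unsupported element '%s'", i, sym)
      charge <- NA_integer_
      if (!is.na(m[3]) && m[3] != "") {
        sign <- if (substr(m[3], 1L, 1L) == "+") 1L else -1L
        digits <- gsub("[+-]", "", m[3])
        charge <- if (digits != "") sign * as.integer(digits) else sign
      }
      ring <- if (is.na(m[4]) || m[4] == "") NA else m[4] == "R"
      add_atom(el, arom, charge, ring)
      i <- j + 1L
    } else if (two %in% c("Cl", "Br")) {
      add_atom(two, FALSE, NA_integer_, NA); i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      add_atom(ch, FALSE, NA_integer_, NA); i <- i + 1L
    } else if (ch %in% AROMATIC_ELEMS) {
      add_atom(toupper(ch), TRUE, NA_integer_, NA); i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":")) {
      if (is.na(prev))
        stopf("pattern parse error at position %d: bond before any atom", i)
      pending <- switch(ch, "-" = 1L, "=" = 2L, "#" = 3L, ":" = 4L)
      i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L)
        stopf("pattern parse error at position %d: unmatched ')'", i)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      lab <- ch
      if (is.null(ring_open[[lab]])) {
        ring_open[[lab]] <- list(atom = prev, order = pending)
      } else {
        op <- ring_open[[lab]]; ring_open[[lab]] <- NULL
        ord <- if (!is.na(op$order)) op$order else pending
        bonds[[length(bonds) + 1L]] <- list(i = op$atom, j = prev, order = ord)
      }
      pending <- NA_integer_
      i <- i + 1L
    } else {
      stopf("pattern parse error at position %d: unsupported token '%s'", i, ch)
    }
  }
  if (length(ring_open) > 0L) stopf("pattern parse error: unclosed ring bond")
  if (length(atoms) == 0L) stopf("pattern parse error: no atoms")
  list(
    atoms = data.frame(
      element = vapply(atoms, `[[`, "", "element"),
      aromatic = vapply(atoms, `[[`, FALSE, "aromatic"),
      charge = vapply(atoms, function(a) as.integer(a$charge), 0L),
      ring = vapply(atoms, function(a) as.logical(a$ring), NA)),
    bonds = if (length(bonds) > 0L) data.frame(
      i = vapply(bonds, `[[`, 0L, "i"),
      j = vapply(bonds, `[[`, 0L, "j"),
      order = vapply(bonds, function(b) as.integer(b$order), NA_integer_))
    else data.frame(i = integer(0), j = integer(0), order = integer(0)))
}

atom_matches <- function(q, mol, a) {
  if (q$element[1] != mol$atoms$element[a]) return(FALSE)
  if (q$aromatic[1] != mol$atoms$aromatic[a]) return(FALSE)
  if (!is.na(q$charge[1]) && q$charge[1] != mol$atoms$charge[a]) return(FALSE)
  if (!is.na(q$ring[1]) && q$ring[1] != mol$atoms$in_ring[a]) return(FALSE)
  TRUE
}

bond_matches <- function(qorder, morder) {
  if (is.na(qorder)) return(morder %in% c(1L, 4L))  # default: single or aromatic
  qorder == morder
}

#' Match a fragment pattern against a molecule
#'
#' Subgraph matching on element, aromaticity, charge, ring membership and bond
#' order.  Matches that cover the same atom set (automorphic images) are
#' collapsed to one.
#'
#' @param mol an `orbgap_mol`.
#' @param fragment an `orbgap_fragment` or pattern string.
#' @return a list of integer vectors (sorted atom indices), ordered
#'   lexicographically; empty list when there is no match.
#' @examples
#' m <- parse_smiles("C=CC=C")
#' match_fragment(m, "C=C")   # two matches
#' @export
match_fragment <- function(mol, fragment) {
  stopifnot(inherits(mol, "orbgap_mol"))
  if (is.character(fragment)) fragment <- fragment_pattern(fragment)
  stopifnot(inherits(fragment, "orbgap_fragment"))
  qa <- fragment$atoms; qb <- fragment$bonds
  np <- nrow(qa); nm <- nrow(mol$atoms)
  if (np > nm) return(list())
  ord_of <- bond_lookup(mol)
  adj <- adjacency_list(mol)

  # pattern adjacency
  padj <- vector("list", np)
  for (r in seq_len(nrow(qb))) {
    padj[[qb$i[r]]] <- rbind(padj[[qb$i[r]]], c(qb$j[r], qb$order[r]))
    padj[[qb$j[r]]] <- rbind(padj[[qb$j[r]]], c(qb$i[r], qb$order[r]))
  }

  matches <- list(); seen <- character(0)
  map <- rep(NA_integer_, np)
  used <- rep(FALSE, nm)

  try_atom <- function(p) {
    if (p > np) {
      key <- paste(sort(map), collapse = ",")
      if (!key %in% seen) {
        seen <<- c(seen, key)
        matches[[length(matches) + 1L]] <<- sort(map)
      }
      return(invisible(NULL))
    }
    # candidate molecule atoms: constrained by already-mapped pattern neighbors
    anchored <- if (!is.null(padj[[p]]))
      padj[[p]][!is.na(map[padj[[p]][, 1L]]), , drop = FALSE]
    else matrix(numeric(0), 0L, 2L)
    cands <- if (nrow(anchored) > 0L) adj[[map[anchored[1L, 1L]]]] else seq_len(nm)
    for (a in cands) {
      if (used[a] || !atom_matches(qa[p, , drop = FALSE], mol, a)) next
      ok <- TRUE
      if (nrow(anchored) > 0L) {
        for (r in seq_len(nrow(anchored))) {
          ma <- map[anchored[r, 1L]]
          k <- paste(min(a, ma), max(a, ma))
          mo <- ord_of[[k]]
          if (is.null(mo) || !bond_matches(anchored[r, 2L], mo)) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      map[p] <<- a; used[a] <<- TRUE
      try_atom(p + 1L)
      map[p] <<- NA_integer_; used[a] <<- FALSE
    }
    invisible(NULL)
  }
  try_atom(1L)
  keys <- vapply(matches, function(m) paste(sprintf("%06d", m), collapse = ","), "")
  matches[order(keys)]
}
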