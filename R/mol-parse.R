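# SMILES parsing and molecular graph construction.
#
# The supported SMILES dialect is a declared subset: organic-subset and
# bracket atoms (element, charge, explicit H, @/@@ stereo annotations),
# bonds - = # : / \, branches, ring closures (incl. %nn).  Dot-separated
# multi-fragment input is rejected.  Anything outside the subset is a hard
# parse error naming the offending position.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_ELEMS <- c("b", "c", "n", "o", "p", "s")

# Normal valences used for implicit-hydrogen inference.
default_valence <- function(element, charge) {
  v <- switch(element,
    B = 3 - charge, C = 4 - abs(charge), N = 3 + charge, P = 3 + charge,
    O = 2 + charge, S = 2 + charge,
    F = 1, Cl = 1, Br = 1, I = 1, H = 1,
    stopf("no default valence for element '%s'", element))
  max(v, 0L)
}

new_molecule <- function(atoms, bonds, name = "", source_smiles = "") {
  structure(list(atoms = atoms, bonds = bonds, name = name,
                 source_smiles = source_smiles),
            class = "orbgap_mol")
}

#' Parse a SMILES string into a molecule
#'
#' Builds an attributed molecular graph (heavy atoms only: explicit hydrogens
#' are folded into per-atom hydrogen counts), perceives aromaticity by the
#' Hueckel 4n+2 rule on rings of up to seven atoms, and stores atoms in
#' canonical order so that every downstream computation is independent of the
#' input atom ordering.
#'
#' @param smiles a single SMILES string (one connected molecule; dot-separated
#'   fragment lists are rejected).
#' @param name optional molecule name.
#' @return an object of class `orbgap_mol` with components `atoms`
#'   (data.frame: element, charge, aromatic, h_count, in_ring, stereo),
#'   `bonds` (data.frame: i, j, order with 4 = aromatic), `name`,
#'   `source_smiles`.  Atoms are in canonical order.
#' @examples
#' m <- parse_smiles("O=NC1=CC=CC=C1", name = "nitrosobenzene")
#' nrow(m$atoms)
#' canonical_smiles(m)
#' @export
parse_smiles <- function(smiles, name = "") {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      nchar(smiles) == 0L)
    stopf("SMILES must be a single non-empty string")
  raw <- tokenize_smiles(smiles)
  mol <- build_graph(raw, smiles, name)
  mol <- strip_explicit_h(mol)
  mol <- assign_rings(mol)
  mol <- perceive_aromaticity(mol, smiles)
  mol <- assign_hydrogens(mol)
  check_connected(mol)
  canonicalize(mol)
}

# --- tokenizer -------------------------------------------------------------

# Returns a list of events: atom / bond / open / close / ring.
tokenize_smiles <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  ev <- list()
  add <- function(e) ev[[length(ev) + 1L]] <<- e
  while (i <= n) {
    ch <- chars[i]
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stopf("SMILES parse error at position %d: unclosed '['", i)
      body <- substr(s, i + 1L, j - 1L)
      add(c(list(type = "atom", pos = i), parse_bracket_atom(body, i)))
      i <- j + 1L
    } else if (two %in% c("Cl", "Br")) {
      add(list(type = "atom", pos = i, element = two, aromatic = FALSE,
               charge = 0L, h_explicit = NA_integer_, stereo = ""))
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      add(list(type = "atom", pos = i, element = ch, aromatic = FALSE,
               charge = 0L, h_explicit = NA_integer_, stereo = ""))
      i <- i + 1L
    } else if (ch %in% AROMATIC_ELEMS) {
      add(list(type = "atom", pos = i, element = toupper(ch), aromatic = TRUE,
               charge = 0L, h_explicit = NA_integer_, stereo = ""))
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      ord <- switch(ch, "-" = 1L, "=" = 2L, "#" = 3L, ":" = 4L, 1L)
      add(list(type = "bond", pos = i, order = ord,
               stereo = ch %in% c("/", "\\")))
      i <- i + 1L
    } else if (ch == "(") {
      add(list(type = "open", pos = i)); i <- i + 1L
    } else if (ch == ")") {
      add(list(type = "close", pos = i)); i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      add(list(type = "ring", pos = i, label = ch)); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", substr(s, i + 1L, i + 2L)))
        stopf("SMILES parse error at position %d: '%%' needs two digits", i)
      add(list(type = "ring", pos = i, label = substr(s, i + 1L, i + 2L)))
      i <- i + 3L
    } else if (ch == ".") {
      stopf("multi-fragment SMILES (position %d): only single connected molecules are supported", i)
    } else {
      stopf("SMILES parse error at position %d: unsupported token '%s'", i, ch)
    }
  }
  ev
}

parse_bracket_atom <- function(body, pos) {
  m <- regmatches(body, regexec(
    "^([0-9]*)([A-IK-PR-Za-ik-pr-z][a-z]?)(@{0,2})(H[0-9]*)?([+-]+[0-9]*)?$",
    body))[[1]]
  if (length(m) == 0L)
    stopf("SMILES parse error at position %d: cannot parse bracket atom '[%s]'", pos, body)
  sym <- m[3]
  aromatic <- sym %in% AROMATIC_ELEMS
  element <- if (aromatic) toupper(sym) else sym
  if (!element %in% c(ORGANIC_SUBSET, "H", "Si", "Se", "As"))
    stopf("SMILES parse error at position %d: unsupported element '%s'", pos, sym)
  hmatch <- m[5]
  h_explicit <- if (is.na(hmatch) || hmatch == "") 0L
                else if (hmatch == "H") 1L
                else as.integer(substring(hmatch, 2L))
  cmatch <- m[6]
  charge <- 0L
  if (!is.na(cmatch) && cmatch != "") {
    sign <- if (substr(cmatch, 1L, 1L) == "+") 1L else -1L
    digits <- gsub("[+-]", "", cmatch)
    nsym <- nchar(gsub("[0-9]", "", cmatch))
    charge <- if (digits != "") sign * as.integer(digits) else sign * nsym
  }
  list(element = element, aromatic = aromatic, charge = charge,
       h_explicit = h_explicit, stereo = m[4])
}

# --- graph assembly --------------------------------------------------------

build_graph <- function(ev, smiles, name) {
  atoms <- list(); bonds <- list()
  stack <- integer(0)   # branch stack, last = current attachment atom
  prev <- NA_integer_
  pending <- NULL       # bond event awaiting next atom / ring closure
  ring_open <- list()   # label -> list(atom, order)
  for (e in ev) {
    if (e$type == "atom") {
      idx <- length(atoms) + 1L
      atoms[[idx]] <- e
      if (!is.na(prev)) {
        ord <- if (is.null(pending)) NA_integer_ else pending$order
        bonds[[length(bonds) + 1L]] <- list(i = prev, j = idx, order = ord)
      }
      pending <- NULL
      prev <- idx
    } else if (e$type == "bond") {
      if (!is.null(pending))
        stopf("SMILES parse error at position %d: consecutive bond symbols", e$pos)
      if (is.na(prev))
        stopf("SMILES parse error at position %d: bond before any atom", e$pos)
      pending <- e
    } else if (e$type == "open") {
      if (is.na(prev))
        stopf("SMILES parse error at position %d: branch before any atom", e$pos)
      stack <- c(stack, prev)
    } else if (e$type == "close") {
      if (length(stack) == 0L)
        stopf("SMILES parse error at position %d: unmatched ')'", e$pos)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (e$type == "ring") {
      if (is.na(prev))
        stopf("SMILES parse error at position %d: ring bond before any atom", e$pos)
      lab <- e$label
      ord <- if (is.null(pending)) NA_integer_ else pending$order
      pending <- NULL
      if (is.null(ring_open[[lab]])) {
        ring_open[[lab]] <- list(atom = prev, order = ord)
      } else {
        op <- ring_open[[lab]]
        ring_open[[lab]] <- NULL
        if (op$atom == prev)
          stopf("SMILES parse error at position %d: ring bond to self", e$pos)
        ord2 <- if (!is.na(op$order) && !is.na(ord)) {
          if (op$order != ord)
            stopf("SMILES parse error at position %d: conflicting ring-bond orders", e$pos)
          ord
        } else if (!is.na(op$order)) op$order else ord
        bonds[[length(bonds) + 1L]] <- list(i = op$atom, j = prev, order = ord2)
      }
    }
  }
  if (length(ring_open) > 0L)
    stopf("SMILES parse error: unclosed ring bond label(s) %s",
          paste(names(ring_open), collapse = ", "))
  if (length(stack) > 0L) stopf("SMILES parse error: unmatched '('")
  if (length(atoms) == 0L) stopf("SMILES parse error: no atoms")

  adf <- data.frame(
    element  = vapply(atoms, `[[`, "", "element"),
    charge   = vapply(atoms, `[[`, 0L, "charge"),
    aromatic = vapply(atoms, `[[`, FALSE, "aromatic"),
    h_count  = vapply(atoms, `[[`, NA_integer_, "h_explicit"),
    stereo   = vapply(atoms, `[[`, "", "stereo"),
    stringsAsFactors = FALSE)
  if (length(bonds) > 0L) {
    bdf <- data.frame(
      i = vapply(bonds, `[[`, 0L, "i"),
      j = vapply(bonds, `[[`, 0L, "j"),
      order = vapply(bonds, `[[`, NA_integer_, "order"))
  } else {
    bdf <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  }
  # default bond order: aromatic between two aromatic-typed atoms, else single
  if (nrow(bdf) > 0L) {
    dflt <- ifelse(adf$aromatic[bdf$i] & adf$aromatic[bdf$j], 4L, 1L)
    bdf$order <- ifelse(is.na(bdf$order), dflt, bdf$order)
    key <- paste(pmin(bdf$i, bdf$j), pmax(bdf$i, bdf$j))
    if (anyDuplicated(key)) stopf("SMILES parse error: duplicate bond")
  }
  new_molecule(adf, bdf, name = name, source_smiles = smiles)
}

strip_explicit_h <- function(mol) {
  hs <- which(mol$atoms$element == "H")
  if (length(hs) == 0L) return(mol)
  if (length(hs) == nrow(mol$atoms))
    stopf("molecule consists only of hydrogen atoms")
  b <- mol$bonds
  for (h in hs) {
    nb <- c(b$j[b$i == h], b$i[b$j == h])
    if (length(nb) != 1L) stopf("explicit hydrogen with %d bonds", length(nb))
    cur <- mol$atoms$h_count[nb]
    mol$atoms$h_count[nb] <- ifelse(is.na(cur), 1L, cur + 1L)
  }
  keep <- setdiff(seq_len(nrow(mol$atoms)), hs)
  remap <- integer(nrow(mol$atoms)); remap[keep] <- seq_along(keep)
  b <- b[!(b$i %in% hs | b$j %in% hs), , drop = FALSE]
  b$i <- remap[b$i]; b$j <- remap[b$j]
  mol$atoms <- mol$atoms[keep, , drop = FALSE]
  rownames(mol$atoms) <- NULL
  mol$bonds <- b
  mol
}

# --- ring perception -------------------------------------------------------

adjacency_list <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  b <- mol$bonds
  for (r in seq_len(nrow(b))) {
    adj[[b$i[r]]] <- c(adj[[b$i[r]]], b$j[r])
    adj[[b$j[r]]] <- c(adj[[b$j[r]]], b$i[r])
  }
  adj
}

# shortest path between from and to, avoiding the direct edge (from,to);
# returns atom index vector or NULL
shortest_path_avoiding <- function(adj, from, to, max_len) {
  n <- length(adj)
  parent <- rep(NA_integer_, n); dist <- rep(NA_integer_, n)
  dist[from] <- 0L; queue <- from
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    if (dist[v] >= max_len) next
    for (w in adj[[v]]) {
      if (v == from && w == to) next
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L; parent[w] <- v
        if (w == to) {
          path <- w
          while (!is.na(parent[path[1L]])) path <- c(parent[path[1L]], path)
          return(path)
        }
        queue <- c(queue, w)
      }
    }
  }
  NULL
}

# Smallest ring through each bond (size cap), deduplicated.
find_rings <- function(mol, max_size = 7L) {
  adj <- adjacency_list(mol)
  rings <- list(); seen <- character(0)
  b <- mol$bonds
  for (r in seq_len(nrow(b))) {
    p <- shortest_path_avoiding(adj, b$i[r], b$j[r], max_size - 1L)
    if (is.null(p)) next
    key <- paste(sort(p), collapse = ",")
    if (!key %in% seen) { seen <- c(seen, key); rings[[length(rings) + 1L]] <- p }
  }
  rings
}

assign_rings <- function(mol) {
  rings <- find_rings(mol, max_size = 12L)
  in_ring <- rep(FALSE, nrow(mol$atoms))
  for (p in rings) in_ring[p] <- TRUE
  mol$atoms$in_ring <- in_ring
  attr(mol, "rings") <- find_rings(mol, max_size = 7L)
  mol
}

# --- aromaticity -----------------------------------------------------------

bond_lookup <- function(mol) {
  b <- mol$bonds
  stats::setNames(b$order, paste(pmin(b$i, b$j), pmax(b$i, b$j)))
}

# lone-pair donor in an aromatic ring context (pyrrole N, furan O, ...)
is_donor_atom <- function(mol, a, ord_of) {
  el <- mol$atoms$element[a]; ch <- mol$atoms$charge[a]
  b <- mol$bonds
  mine <- b$order[b$i == a | b$j == a]
  has_multiple <- any(mine %in% c(2L, 3L))
  deg <- length(mine)
  h <- mol$atoms$h_count[a]
  if (is.na(h)) {
    # organic-subset atom: infer hydrogens from the kekule bond orders;
    # lowercase aromatic atoms carry no implicit H unless bracketed
    h <- if (mol$atoms$aromatic[a]) 0L
         else max(0L, default_valence(el, ch) - sum(ifelse(mine == 4L, 1L, mine)))
  }
  if (has_multiple) return(FALSE)
  if (el %in% c("O", "S") && ch == 0L) return(TRUE)
  if (el %in% c("N", "P") && ch == 0L && (h >= 1L || deg >= 3L)) return(TRUE)
  if (el == "C" && ch == -1L) return(TRUE)
  FALSE
}

perceive_aromaticity <- function(mol, smiles) {
  rings <- attr(mol, "rings") %||% list()
  n <- nrow(mol$atoms)
  b <- mol$bonds
  ord_of <- bond_lookup(mol)
  ring_atoms <- unique(unlist(rings))
  pi_contrib <- rep(NA_integer_, n)

  for (p in rings) {
    contrib <- integer(length(p))
    ok <- TRUE
    for (t in seq_along(p)) {
      a <- p[t]
      el <- mol$atoms$element[a]; ch <- mol$atoms$charge[a]
      mine_i <- which(b$i == a | b$j == a)
      orders <- b$order[mine_i]
      partners <- ifelse(b$i[mine_i] == a, b$j[mine_i], b$i[mine_i])
      if (any(orders == 3L)) { ok <- FALSE; break }
      dbl <- partners[orders == 2L]
      arom <- any(orders == 4L)
      if (length(dbl) > 1L) { ok <- FALSE; break }
      if (arom || length(dbl) == 1L && dbl[1L] %in% ring_atoms) {
        # sp2 with a pi bond inside the ring system
        if (arom && is_donor_atom(mol, a, ord_of)) contrib[t] <- 2L
        else if (el == "C" && ch == 1L) contrib[t] <- 0L
        else contrib[t] <- 1L
      } else if (length(dbl) == 1L) {
        contrib[t] <- 0L   # exocyclic double bond: empty contribution
      } else if (is_donor_atom(mol, a, ord_of)) {
        contrib[t] <- 2L
      } else if (el == "C" && ch == 1L) {
        contrib[t] <- 0L
      } else {
        ok <- FALSE; break # sp3 atom: ring cannot be aromatic
      }
    }
    if (!ok) next
    if (sum(contrib) %% 4L != 2L) next
    # aromatic ring: flag atoms and in-ring bonds
    mol$atoms$aromatic[p] <- TRUE
    pi_contrib[p] <- ifelse(is.na(pi_contrib[p]), contrib, pmax(pi_contrib[p], contrib))
    m <- length(p)
    for (t in seq_len(m)) {
      a1 <- p[t]; a2 <- p[if (t == m) 1L else t + 1L]
      sel <- (b$i == a1 & b$j == a2) | (b$i == a2 & b$j == a1)
      b$order[sel] <- 4L
    }
  }
  mol$bonds <- b

  # input-declared aromatic atoms must end up in a perceived aromatic ring
  bad <- which(vapply(seq_len(n), function(a) {
    declared <- isTRUE(mol$atoms$aromatic[a])
    declared && is.na(pi_contrib[a])
  }, FALSE))
  if (length(bad) > 0L) {
    # atoms written lowercase but not confirmed by perception
    anyb <- mol$bonds$order == 4L
    arom_deg <- vapply(bad, function(a)
      sum((mol$bonds$i == a | mol$bonds$j == a) & anyb), 0L)
    if (any(arom_deg > 0L))
      stopf("aromatic atoms outside any perceivable aromatic ring in '%s'", smiles)
    mol$atoms$aromatic[bad] <- FALSE
  }
  stray <- mol$bonds$order == 4L &
    !(mol$atoms$aromatic[mol$bonds$i] & mol$atoms$aromatic[mol$bonds$j])
  if (any(stray))
    stopf("aromatic bond outside any perceivable aromatic ring in '%s'", smiles)
  attr(mol, "pi_contrib_aromatic") <- pi_contrib
  attr(mol, "rings") <- NULL
  mol
}

assign_hydrogens <- function(mol) {
  n <- nrow(mol$atoms); b <- mol$bonds
  for (a in seq_len(n)) {
    if (!is.na(mol$atoms$h_count[a])) next   # bracket atom: explicit count
    el <- mol$atoms$element[a]; ch <- mol$atoms$charge[a]
    mine <- b$order[b$i == a | b$j == a]
    val <- default_valence(el, ch)
    if (mol$atoms$aromatic[a]) {
      deg <- length(mine)
      contrib <- attr(mol, "pi_contrib_aromatic")[a]
      used <- deg + if (!is.na(contrib) && contrib == 1L) 1L else 0L
      mol$atoms$h_count[a] <- max(0L, val - used)
    } else {
      used <- sum(ifelse(mine == 4L, 1L, mine))
      mol$atoms$h_count[a] <- max(0L, val - used)
    }
  }
  mol
}

check_connected <- function(mol) {
  n <- nrow(mol$atoms)
  if (n == 1L) return(invisible(TRUE))
  adj <- adjacency_list(mol)
  seen <- rep(FALSE, n); queue <- 1L; seen[1L] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  if (!all(seen)) stopf("molecule graph is disconnected")
  invisible(TRUE)
}

#' @export
print.orbgap_mol <- function(x, ...) {
  cat(sprintf("<orbgap_mol> %s: %d heavy atoms, %d bonds\n",
              if (nzchar(x$name)) x$name else canonical_smiles(x),
              nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}
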