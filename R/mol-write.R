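# Canonical atom ranking (iterative neighborhood refinement with deterministic
# tie resolution) and SMILES emission.

bond_class_chr <- function(order) as.character(order)

refine_ranks <- function(mol, ranks) {
  adj <- adjacency_list(mol)
  b <- mol$bonds
  ord_of <- bond_lookup(mol)
  n <- nrow(mol$atoms)
  repeat {
    inv <- vapply(seq_len(n), function(a) {
      nb <- adj[[a]]
      if (length(nb) == 0L) return(sprintf("%06d|", ranks[a]))
      toks <- vapply(nb, function(w) {
        o <- ord_of[[paste(min(a, w), max(a, w))]]
        sprintf("%s%06d", bond_class_chr(o), ranks[w])
      }, "")
      sprintf("%06d|%s", ranks[a], paste(sort(toks), collapse = ","))
    }, "")
    new_ranks <- match(inv, sort(unique(inv)))
    if (length(unique(new_ranks)) == length(unique(ranks))) return(new_ranks)
    ranks <- new_ranks
  }
}

initial_ranks <- function(mol) {
  n <- nrow(mol$atoms)
  deg <- tabulate(c(mol$bonds$i, mol$bonds$j), nbins = n)
  inv <- sprintf("%s|%+d|%d|%d|%d|%d",
                 mol$atoms$element, mol$atoms$charge,
                 as.integer(mol$atoms$aromatic), mol$atoms$h_count,
                 deg, as.integer(mol$atoms$in_ring))
  match(inv, sort(unique(inv)))
}

bump_rank <- function(ranks, a) {
  # promote atom a ahead of its tied cell
  ranks[ranks >= ranks[a]] <- ranks[ranks >= ranks[a]] + 1L
  ranks[a] <- ranks[a] - 1L
  match(ranks, sort(unique(ranks)))
}

greedy_resolve <- function(mol, ranks) {
  n <- length(ranks)
  while (length(unique(ranks)) < n) {
    tab <- table(ranks)
    tied <- as.integer(names(tab)[tab > 1L])
    cell <- which(ranks == min(tied))
    ranks <- refine_ranks(mol, bump_rank(ranks, cell[1L]))
  }
  ranks
}

canonical_rank_vector <- function(mol) {
  ranks <- refine_ranks(mol, initial_ranks(mol))
  n <- length(ranks)
  if (length(unique(ranks)) == n) return(ranks)
  # branch over the first ambiguous cell; deeper ties resolved greedily
  tab <- table(ranks)
  tied <- as.integer(names(tab)[tab > 1L])
  cell <- which(ranks == min(tied))
  best_s <- NULL; best_r <- NULL
  for (a in cell) {
    r <- greedy_resolve(mol, refine_ranks(mol, bump_rank(ranks, a)))
    s <- emit_smiles(mol, r)
    if (is.null(best_s) || s < best_s) { best_s <- s; best_r <- r }
  }
  best_r
}

# --- emission --------------------------------------------------------------

atom_token <- function(mol, a) {
  el <- mol$atoms$element[a]
  arom <- mol$atoms$aromatic[a]
  ch <- mol$atoms$charge[a]
  h <- mol$atoms$h_count[a]
  sym <- if (arom && el %in% c("B", "C", "N", "O", "P", "S")) tolower(el) else el
  organic <- el %in% ORGANIC_SUBSET
  needs_bracket <- ch != 0L || !organic ||
    (arom && el %in% c("N", "P") && h > 0L)
  if (!needs_bracket) {
    # would the parser infer this H count without a bracket?
    b <- mol$bonds
    mine <- b$order[b$i == a | b$j == a]
    val <- default_valence(el, ch)
    inferred <- if (arom) {
      deg <- length(mine)
      donor <- el %in% c("O", "S") || (el %in% c("N", "P") && deg >= 3L)
      max(0L, val - (deg + if (donor) 0L else 1L))
    } else {
      max(0L, val - sum(ifelse(mine == 4L, 1L, mine)))
    }
    if (inferred != h) needs_bracket <- TRUE
  }
  if (!needs_bracket) return(sym)
  htok <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
  ctok <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
          else sprintf("%+d", ch)
  paste0("[", sym, htok, ctok, "]")
}

# pi electrons an aromatic atom contributes (2 for pyrrole-type donors)
pi_contrib_of <- function(mol, a) {
  pc <- attr(mol, "pi_contrib_aromatic")
  if (!is.null(pc) && !is.na(pc[a])) return(pc[a])
  el <- mol$atoms$element[a]; ch <- mol$atoms$charge[a]
  h <- mol$atoms$h_count[a]; h <- ifelse(is.na(h), 0L, h)
  deg <- sum(mol$bonds$i == a | mol$bonds$j == a)
  if (el %in% c("O", "S") && ch == 0L) return(2L)
  if (el %in% c("N", "P") && ch == 0L && (h >= 1L || deg >= 3L)) return(2L)
  if (el == "C" && ch == -1L) return(2L)
  if (el == "C" && ch == 1L) return(0L)
  1L
}

bond_token <- function(mol, a1, a2, order) {
  both_arom <- mol$atoms$aromatic[a1] && mol$atoms$aromatic[a2]
  switch(as.character(order),
         "1" = if (both_arom) "-" else "",
         "2" = "=", "3" = "#",
         "4" = if (both_arom) "" else ":",
         stopf("bad bond order %s", order))
}

emit_smiles <- function(mol, ranks) {
  n <- nrow(mol$atoms)
  adj <- adjacency_list(mol)
  ord_of <- bond_lookup(mol)
  start <- which.min(ranks)
  visited <- rep(FALSE, n)
  ring_num <- 0L
  ring_at <- vector("list", n)   # per atom: list of (digit, bondtok)
  edge_used <- new.env(hash = TRUE)
  ekey <- function(a, b) paste(min(a, b), max(a, b))

  # first pass: DFS to find back edges and assign ring-closure digits
  order_visit <- integer(0)
  dfs1 <- function(a, parent) {
    visited[a] <<- TRUE
    order_visit <<- c(order_visit, a)
    nb <- adj[[a]][order(ranks[adj[[a]]])]
    for (w in nb) {
      if (w == parent && !isTRUE(edge_used[[ekey(a, w)]])) {
        edge_used[[ekey(a, w)]] <- TRUE
        next
      }
      k <- ekey(a, w)
      if (isTRUE(edge_used[[k]])) next
      if (visited[w]) {
        edge_used[[k]] <- TRUE
        ring_num <<- ring_num + 1L
        dig <- if (ring_num <= 9L) as.character(ring_num)
               else sprintf("%%%02d", ring_num)
        btok <- bond_token(mol, a, w, ord_of[[k]])
        ring_at[[w]] <<- c(ring_at[[w]], list(list(dig = dig, tok = btok)))
        ring_at[[a]] <<- c(ring_at[[a]], list(list(dig = dig, tok = "")))
      } else {
        edge_used[[k]] <- TRUE
        dfs1(w, a)
      }
    }
  }
  dfs1(start, 0L)

  # second pass: rebuild string along the same traversal
  visited2 <- rep(FALSE, n)
  for (k in ls(edge_used)) rm(list = k, envir = edge_used)
  build <- function(a, bond_str) {
    visited2[a] <<- TRUE
    out <- paste0(bond_str, atom_token(mol, a))
    for (rc in ring_at[[a]]) out <- paste0(out, rc$tok, rc$dig)
    nb <- adj[[a]][order(ranks[adj[[a]]])]
    children <- character(0)
    for (w in nb) {
      k <- ekey(a, w)
      if (isTRUE(edge_used[[k]]) || visited2[w]) { edge_used[[k]] <- TRUE; next }
      edge_used[[k]] <- TRUE
      btok <- bond_token(mol, a, w, ord_of[[k]])
      children <- c(children, build(w, btok))
    }
    if (length(children) > 0L) {
      nc <- length(children)
      if (nc > 1L)
        out <- paste0(out, paste0("(", children[-nc], ")", collapse = ""))
      out <- paste0(out, children[nc])
    }
    out
  }
  build(start, "")
}

canonicalize <- function(mol) {
  ranks <- canonical_rank_vector(mol)
  ord <- order(ranks)
  remap <- integer(length(ranks)); remap[ord] <- seq_along(ord)
  pc <- attr(mol, "pi_contrib_aromatic")
  mol$atoms <- mol$atoms[ord, , drop = FALSE]
  rownames(mol$atoms) <- NULL
  b <- mol$bonds
  b$i <- remap[b$i]; b$j <- remap[b$j]
  swap <- b$i > b$j
  tmp <- b$i[swap]; b$i[swap] <- b$j[swap]; b$j[swap] <- tmp
  b <- b[order(b$i, b$j), , drop = FALSE]
  rownames(b) <- NULL
  mol$bonds <- b
  if (!is.null(pc)) attr(mol, "pi_contrib_aromatic") <- pc[ord]
  mol$canonical_smiles <- emit_smiles(mol, seq_len(nrow(mol$atoms)))
  mol
}

#' Canonical SMILES of a molecule
#'
#' @param mol an `orbgap_mol`.
#' @return the canonical SMILES string; identical for any SMILES rewriting of
#'   the same molecule.
#' @export
canonical_smiles <- function(mol) {
  stopifnot(inherits(mol, "orbgap_mol"))
  mol$canonical_smiles %||% emit_smiles(mol, seq_len(nrow(mol$atoms)))
}

#' Write a (possibly randomized) SMILES string
#'
#' Emits a valid SMILES for the molecule using an arbitrary atom priority;
#' with `seed` set, priorities are randomly permuted, which yields alternative
#' spellings of the same structure (useful for canonicalization testing).
#'
#' @param mol an `orbgap_mol`.
#' @param seed optional integer; if given, atom priorities are shuffled.
#' @return a SMILES string that reparses to the same canonical form.
#' @export
write_smiles <- function(mol, seed = NULL) {
  stopifnot(inherits(mol, "orbgap_mol"))
  n <- nrow(mol$atoms)
  ranks <- if (is.null(seed)) seq_len(n) else with_seed(seed, sample.int(n))
  emit_smiles(mol, ranks)
}
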