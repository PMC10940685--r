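# Conjugated pi-system extraction.
#
# Membership: atoms carrying a pi bond (double, triple or aromatic) plus
# lone-pair donor heteroatoms (and carbanions) directly bonded to such an
# atom.  Electron contributions follow the standard counting rules: one
# electron per atom of a multiple bond (C=C, C=O, N=O, ...), two for a
# pyrrole-type donor, zero for an empty-p cation.

#' Extract the largest conjugated pi system of a molecule
#'
#' @param mol an `orbgap_mol`.
#' @return an object of class `orbgap_pisystem` with components `members`
#'   (atom indices into `mol$atoms`), `bonds` (pi-conjugated bonds among
#'   members), `contrib` (per-member pi-electron contribution), `electrons`
#'   (total pi-electron count) and `mol` (the parent molecule).
#' @examples
#' extract_pi_system(parse_smiles("C=CC=C"))$electrons   # 4
#' @export
extract_pi_system <- function(mol) {
  stopifnot(inherits(mol, "orbgap_mol"))
  n <- nrow(mol$atoms)
  b <- mol$bonds
  has_pi_bond <- rep(FALSE, n)
  for (r in seq_len(nrow(b))) {
    if (b$order[r] %in% c(2L, 3L, 4L)) {
      has_pi_bond[b$i[r]] <- TRUE; has_pi_bond[b$j[r]] <- TRUE
    }
  }
  if (!any(has_pi_bond)) stopf("no conjugation: molecule has no pi bonds")

  contrib <- rep(NA_integer_, n)
  for (a in which(has_pi_bond)) {
    contrib[a] <- if (mol$atoms$aromatic[a]) pi_contrib_of(mol, a)
                  else if (mol$atoms$element[a] == "C" && mol$atoms$charge[a] == 1L) 0L
                  else 1L
  }
  # lone-pair donors adjacent to a pi-bonded atom
  donor_elems <- c("N", "O", "S", "P", "F", "Cl", "Br", "I")
  repeat {
    grew <- FALSE
    for (r in seq_len(nrow(b))) {
      for (pair in list(c(b$i[r], b$j[r]), c(b$j[r], b$i[r]))) {
        a <- pair[1L]; w <- pair[2L]
        if (!is.na(contrib[a]) || is.na(contrib[w])) next
        el <- mol$atoms$element[a]; ch <- mol$atoms$charge[a]
        if (el %in% donor_elems && ch <= 0L) { contrib[a] <- 2L; grew <- TRUE }
        else if (el == "C" && ch == -1L) { contrib[a] <- 2L; grew <- TRUE }
        else if (el == "C" && ch == 1L) { contrib[a] <- 0L; grew <- TRUE }
      }
    }
    if (!grew) break
  }

  members_all <- which(!is.na(contrib))
  pib <- b[b$i %in% members_all & b$j %in% members_all, , drop = FALSE]

  # connected components over the candidate pi graph; keep the largest
  comp <- rep(NA_integer_, n); cid <- 0L
  for (s in members_all) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L; queue <- s; comp[s] <- cid
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- c(pib$j[pib$i == v], pib$i[pib$j == v])
      for (w in nb) if (is.na(comp[w])) { comp[w] <- cid; queue <- c(queue, w) }
    }
  }
  sizes <- tabulate(comp[members_all], nbins = cid)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie: component containing the smallest atom index
    first_atom <- vapply(best, function(k) min(which(comp == k)), 0L)
    best <- best[which.min(first_atom)]
  }
  members <- members_all[comp[members_all] == best]
  if (length(members) < 2L) stopf("no conjugation: pi system has fewer than two atoms")
  pib <- pib[pib$i %in% members & pib$j %in% members, , drop = FALSE]
  rownames(pib) <- NULL
  electrons <- sum(contrib[members])
  if (electrons %% 2L != 0L)
    stopf("open shell unsupported: odd pi-electron count (%d)", electrons)
  structure(list(members = members, bonds = pib,
                 contrib = contrib[members], electrons = electrons,
                 mol = mol),
            class = "orbgap_pisystem")
}

#' @export
print.orbgap_pisystem <- function(x, ...) {
  cat(sprintf("<orbgap_pisystem> %d atoms, %d pi electrons\n",
              length(x$members), x$electrons))
  invisible(x)
}
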