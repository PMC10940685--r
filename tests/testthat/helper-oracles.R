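# Independent test oracles, written against the raw data structures so they
# share no code path with the implementation under test.

# Brute-force subgraph-monomorphism enumeration over all injective mappings.
brute_force_matches <- function(mol, fragment) {
  if (is.character(fragment)) fragment <- fragment_pattern(fragment)
  qa <- fragment$atoms; qb <- fragment$bonds
  np <- nrow(qa); nm <- nrow(mol$atoms)
  if (np > nm) return(list())
  bond_tab <- new.env(hash = TRUE)
  for (r in seq_len(nrow(mol$bonds)))
    bond_tab[[paste(min(mol$bonds$i[r], mol$bonds$j[r]),
                    max(mol$bonds$i[r], mol$bonds$j[r]))]] <- mol$bonds$order[r]
  atom_ok <- function(p, a) {
    qa$element[p] == mol$atoms$element[a] &&
      qa$aromatic[p] == mol$atoms$aromatic[a] &&
      (is.na(qa$charge[p]) || qa$charge[p] == mol$atoms$charge[a]) &&
      (is.na(qa$ring[p]) || qa$ring[p] == mol$atoms$in_ring[a])
  }
  bond_ok <- function(qo, mo) if (is.na(qo)) mo %in% c(1L, 4L) else qo == mo
  found <- character(0)
  perms <- utils::combn(nm, np, simplify = FALSE)
  for (subset in perms) {
    for (perm in all_perms(subset)) {
      ok <- all(vapply(seq_len(np), function(p) atom_ok(p, perm[p]), TRUE))
      if (!ok) next
      for (r in seq_len(nrow(qb))) {
        a <- perm[qb$i[r]]; b <- perm[qb$j[r]]
        mo <- bond_tab[[paste(min(a, b), max(a, b))]]
        if (is.null(mo) || !bond_ok(qb$order[r], mo)) { ok <- FALSE; break }
      }
      if (ok) found <- c(found, paste(sort(perm), collapse = ","))
    }
  }
  lapply(unique(sort(found)), function(s) as.integer(strsplit(s, ",")[[1]]))
}

all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# Independent Hueckel matrix assembled directly from the pi-system bond list
# and the parameter table (no shared code with huckel_spectrum()).
brute_force_energies <- function(pisys, params = default_huckel_params()) {
  mem <- pisys$members
  n <- length(mem)
  el <- pisys$mol$atoms$element[mem]
  env <- c("0" = "vac", "1" = "pi", "2" = "lp")[as.character(pisys$contrib)]
  H <- matrix(0, n, n)
  diag(H) <- -unname(params$h[paste0(el, ".", env)])
  for (r in seq_len(nrow(pisys$bonds))) {
    bi <- match(pisys$bonds$i[r], mem); bj <- match(pisys$bonds$j[r], mem)
    cls <- if (pisys$bonds$order[r] %in% c(2L, 3L) ||
               (pisys$bonds$order[r] == 4L &&
                pisys$contrib[bi] == 1L && pisys$contrib[bj] == 1L))
      "multiple" else "single"
    pair <- paste(sort(c(el[bi], el[bj])), collapse = "~")
    k <- unname(params$k[paste0(pair, ".", cls)])
    H[bi, bj] <- H[bj, bi] <- -k
  }
  sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
}

# Random conjugated polyene SMILES (trees of vinyl units, <= 12 pi atoms).
random_polyene <- function(seed) {
  with_seed(seed, {
    n_units <- sample(2:5, 1L)
    s <- "C=C"
    for (k in seq_len(n_units - 1L)) {
      # graft a new vinyl unit onto a random growth point
      s <- sub("C=C", sample(c("C(=CC=C)C", "C=CC=C", "C(C=C)=C"), 1L), s)
    }
    s
  })
}

fixture_molecules <- function() {
  read_smi(test_path("fixtures", "molecules.smi"))
}

with_seed <- orbgap:::with_seed
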