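# Hashed molecular fingerprints: circular (Morgan-style atom environments)
# and path-based (linear atom/bond token paths).  Hashing is 32-bit FNV-1a
# with a fixed offset basis -- never process-salted -- so fingerprints are
# bit-identical across runs and platforms.

#' Featurizer configuration
#'
#' @param family `"circular"` (radius-limited atom environments) or `"path"`
#'   (simple linear paths).
#' @param n_bits fingerprint length; one of 512, 1024, 2048, 4096.
#' @param radius circular family only: environment radius 0--4.
#' @param max_path_length path family only: maximum path length in bonds.
#' @return an `orbgap_featconfig` object (with `hash_version` tag).
#' @export
featurizer_config <- function(family = c("circular", "path"),
                              n_bits = 2048L, radius = 4L,
                              max_path_length = 7L) {
  family <- match.arg(family)
  n_bits <- as.integer(n_bits)
  if (!n_bits %in% c(512L, 1024L, 2048L, 4096L))
    stopf("n_bits must be one of 512, 1024, 2048, 4096")
  if (family == "circular") {
    radius <- as.integer(radius)
    if (radius < 0L || radius > 4L) stopf("radius must be in 0..4")
  } else {
    max_path_length <- as.integer(max_path_length)
    if (max_path_length < 1L) stopf("max_path_length must be >= 1")
  }
  cfg <- structure(list(family = family, n_bits = n_bits,
                        radius = if (family == "circular") radius else NA_integer_,
                        max_path_length = if (family == "path") max_path_length else NA_integer_,
                        hash_version = HASH_VERSION),
                   class = "orbgap_featconfig")
  cfg$checksum <- content_checksum(unclass(cfg))
  cfg
}

featconfig_id <- function(cfg) {
  if (cfg$family == "circular")
    sprintf("circular_r%d_%db", cfg$radius, cfg$n_bits)
  else
    sprintf("path_l%d_%db", cfg$max_path_length, cfg$n_bits)
}

atom_init_token <- function(mol) {
  n <- nrow(mol$atoms)
  deg <- tabulate(c(mol$bonds$i, mol$bonds$j), nbins = n)
  sprintf("%s|%+d|%d|%d|%d", mol$atoms$element, mol$atoms$charge,
          deg, mol$atoms$h_count, as.integer(mol$atoms$aromatic))
}

#' Compute a molecular fingerprint
#'
#' Circular family: for every atom and every radius `0..r`, the canonical
#' encoding of the atom's r-neighborhood (atom attributes: element, charge,
#' degree, hydrogen count, aromaticity; bond orders; neighbor identifiers
#' sorted) is hashed into `[0, n_bits)`.  Path family: every simple path of
#' up to `max_path_length` bonds (plus the bare atom tokens, so no molecule
#' maps to the zero vector), read in its lexicographically smaller direction,
#' is hashed.  Both are invariant under atom reordering.
#'
#' @param mol an `orbgap_mol`.
#' @param config an `orbgap_featconfig`.
#' @return an `orbgap_fingerprint`: logical `bits` of length `n_bits`,
#'   `popcount`, and the `config`.
#' @examples
#' fp <- fingerprint(parse_smiles("c1ccccc1"), featurizer_config("circular", 512, radius = 2))
#' fp$popcount
#' @export
fingerprint <- function(mol, config) {
  stopifnot(inherits(mol, "orbgap_mol"), inherits(config, "orbgap_featconfig"))
  ids <- if (config$family == "circular") circular_ids(mol, config$radius)
         else path_ids(mol, config$max_path_length)
  bits <- rep(FALSE, config$n_bits)
  bits[(ids %% config$n_bits) + 1L] <- TRUE
  structure(list(bits = bits, popcount = sum(bits), config = config),
            class = "orbgap_fingerprint")
}

circular_ids <- function(mol, radius) {
  adj <- adjacency_list(mol)
  ord_of <- bond_lookup(mol)
  n <- nrow(mol$atoms)
  cur <- fnv_hash(atom_init_token(mol))
  ids <- cur
  if (radius > 0L) {
    for (r in seq_len(radius)) {
      nxt <- numeric(n)
      for (a in seq_len(n)) {
        nb <- adj[[a]]
        toks <- if (length(nb) == 0L) character(0) else
          sort(vapply(nb, function(w)
            sprintf("%d:%.0f", ord_of[[paste(min(a, w), max(a, w))]], cur[w]), ""))
        nxt[a] <- fnv_hash(sprintf("%.0f|%s", cur[a], paste(toks, collapse = ",")))
      }
      cur <- nxt
      ids <- c(ids, cur)
    }
  }
  unique(ids)
}

path_ids <- function(mol, max_len) {
  adj <- adjacency_list(mol)
  ord_of <- bond_lookup(mol)
  atok <- atom_path_token(mol)
  n <- nrow(mol$atoms)
  strings <- character(0)
  seen <- new.env(hash = TRUE)
  add_path <- function(atoms_idx) {
    fwd <- path_string(atoms_idx, atok, ord_of)
    rev_ <- path_string(rev(atoms_idx), atok, ord_of)
    s <- if (fwd <= rev_) fwd else rev_
    if (is.null(seen[[s]])) { seen[[s]] <- TRUE; strings[[length(strings) + 1L]] <<- s }
  }
  walk <- function(path) {
    a <- path[length(path)]
    if (length(path) > 1L) add_path(path)
    if (length(path) > max_len) return(invisible(NULL))
    for (w in adj[[a]]) if (!w %in% path) walk(c(path, w))
    invisible(NULL)
  }
  for (a in seq_len(n)) {
    # single-atom token: guarantees a non-empty fingerprint
    s <- atok[a]
    if (is.null(seen[[s]])) { seen[[s]] <- TRUE; strings[[length(strings) + 1L]] <- s }
    walk(a)
  }
  unique(fnv_hash(strings))
}

atom_path_token <- function(mol) {
  tok <- ifelse(mol$atoms$aromatic, tolower(mol$atoms$element), mol$atoms$element)
  ifelse(mol$atoms$charge != 0L,
         sprintf("[%s%+d]", tok, mol$atoms$charge), tok)
}

path_string <- function(idx, atok, ord_of) {
  out <- atok[idx[1L]]
  for (t in seq_along(idx)[-1L]) {
    a <- idx[t - 1L]; w <- idx[t]
    o <- ord_of[[paste(min(a, w), max(a, w))]]
    out <- paste0(out, switch(as.character(o), "1" = "-", "2" = "=",
                              "3" = "#", "4" = ":"), atok[w])
  }
  out
}

#' Build a feature matrix from molecules
#'
#' @param mols list of `orbgap_mol` objects, or a character vector of SMILES.
#' @param config an `orbgap_featconfig`.
#' @return a 0/1 numeric matrix (rows = molecules in input order, columns =
#'   bits) with attributes `config` and `hash_version`.
#' @export
feature_matrix <- function(mols, config) {
  if (is.character(mols)) {
    errs <- character(0)
    parsed <- vector("list", length(mols))
    for (idx in seq_along(mols)) {
      parsed[[idx]] <- tryCatch(parse_smiles(mols[idx]), error = function(e) {
        errs <<- c(errs, sprintf("row %d ('%s'): %s", idx, mols[idx],
                                 conditionMessage(e)))
        NULL
      })
    }
    if (length(errs) > 0L)
      stopf("unparseable molecules:\n%s", paste(errs, collapse = "\n"))
    mols <- parsed
  }
  if (length(mols) == 0L) stopf("empty molecule list")
  X <- matrix(0, nrow = length(mols), ncol = config$n_bits)
  for (idx in seq_along(mols))
    X[idx, ] <- as.numeric(fingerprint(mols[[idx]], config)$bits)
  colnames(X) <- sprintf("bit%04d", seq_len(config$n_bits) - 1L)
  attr(X, "config") <- config
  attr(X, "hash_version") <- config$hash_version
  X
}

#' Serialize a feature matrix as sparse triplets
#'
#' Writes `(row, bit, 1)` triplet CSV plus a JSON sidecar holding the
#' featurizer config, hash version and dimensions.
#'
#' @param X matrix from [feature_matrix()].
#' @param path CSV output path; the sidecar is `<path>.json`.
#' @export
write_feature_matrix <- function(X, path) {
  idx <- which(X != 0, arr.ind = TRUE)
  df <- data.frame(row = idx[, 1L], bit = idx[, 2L] - 1L, value = 1L)
  df <- df[order(df$row, df$bit), ]
  write.csv(df, path, row.names = FALSE)
  cfg <- attr(X, "config")
  jsonlite::write_json(
    list(config = unclass(cfg), n_rows = nrow(X), n_bits = ncol(X)),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
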