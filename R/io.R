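# Molecule file I/O: .smi lists and MDL SDF (V2000).

#' Read a .smi file
#'
#' One SMILES per line with an optional whitespace-separated name; `#` starts
#' a comment.
#'
#' @param path file path.
#' @return a list of `orbgap_mol` objects.
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stopf("no molecules in '%s'", path)
  lapply(seq_along(lines), function(idx) {
    f <- strsplit(lines[idx], "[[:space:]]+")[[1]]
    name <- if (length(f) > 1L) paste(f[-1L], collapse = " ") else ""
    tryCatch(parse_smiles(f[1L], name = name),
             error = function(e) stopf("line %d of '%s': %s",
                                       idx, path, conditionMessage(e)))
  })
}

#' Write molecules to a .smi file as canonical SMILES
#'
#' @param mols a list of `orbgap_mol` objects (or a single one).
#' @param path output path.
#' @export
write_smi <- function(mols, path) {
  if (inherits(mols, "orbgap_mol")) mols <- list(mols)
  lines <- vapply(mols, function(m) {
    trimws(paste(canonical_smiles(m), m$name))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read molecules from an MDL SDF (V2000) file
#'
#' The molfile connection tables are parsed with ChemmineR; formal charges
#' are taken from `M  CHG` property lines, coordinates are ignored, explicit
#' hydrogens are folded into hydrogen counts, and aromaticity is perceived
#' from the kekulized (or order-4) bond block.  Only the first conformer of
#' each record is used.
#'
#' @param path file path.
#' @return a list of `orbgap_mol` objects in canonical atom order.
#' @export
read_sdf <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stopf("reading SDF requires the ChemmineR package")
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
  charges <- sdf_charge_blocks(path)
  out <- vector("list", length(sdfs))
  for (ri in seq_along(sdfs)) {
    sdf <- sdfs[[ri]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elements <- sub("_.*$", "", rownames(ab))
    n <- length(elements)
    chg <- rep(0L, n)
    if (ri <= length(charges) && nrow(charges[[ri]]) > 0L) {
      cb <- charges[[ri]]
      chg[cb$atom] <- cb$charge
    }
    atoms <- data.frame(element = elements, charge = chg,
                        aromatic = FALSE, h_count = NA_integer_,
                        stereo = "", stringsAsFactors = FALSE)
    if (is.null(dim(bb))) bb <- matrix(bb, nrow = 1L)
    bonds <- data.frame(i = as.integer(bb[, 1L]), j = as.integer(bb[, 2L]),
                        order = as.integer(bb[, 3L]))
    if (any(!bonds$order %in% 1:4))
      stopf("record %d of '%s': unsupported bond type %s", ri, path,
            paste(setdiff(bonds$order, 1:4), collapse = ","))
    name <- ChemmineR::sdfid(sdf)
    mol <- new_molecule(atoms, bonds, name = if (is.na(name)) "" else name)
    mol <- strip_explicit_h(mol)
    mol <- assign_rings(mol)
    mol <- perceive_aromaticity(mol, sprintf("record %d of %s", ri, path))
    mol <- assign_hydrogens(mol)
    check_connected(mol)
    out[[ri]] <- canonicalize(mol)
  }
  out
}

# formal charges from M  CHG lines, per record
sdf_charge_blocks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec_end <- c(grep("^\\$\\$\\$\\$", lines), length(lines) + 1L)
  start <- 1L
  out <- list()
  for (e in rec_end) {
    block <- lines[start:(e - 1L)]
    chg_lines <- grep("^M  CHG", block, value = TRUE)
    pairs <- list()
    for (cl in chg_lines) {
      f <- strsplit(trimws(substring(cl, 7L)), "[[:space:]]+")[[1]]
      cnt <- as.integer(f[1L])
      for (t in seq_len(cnt)) {
        pairs[[length(pairs) + 1L]] <-
          c(as.integer(f[2L * t]), as.integer(f[2L * t + 1L]))
      }
    }
    out[[length(out) + 1L]] <- if (length(pairs) > 0L)
      data.frame(atom = vapply(pairs, `[`, 0L, 1L),
                 charge = vapply(pairs, `[`, 0L, 2L))
    else data.frame(atom = integer(0), charge = integer(0))
    start <- e + 1L
    if (start > length(lines)) break
  }
  out
}
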