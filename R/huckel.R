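# Parameterized Hueckel pi molecular-orbital engine.
#
# Orbital energies are reported in beta-scaled units with alpha = 0 and
# beta = -1: an orbital with secular eigenvalue x has energy E = -x, so the
# numeric energy axis is the physical one (more negative = more stable).
# Heteroatoms enter through Coulomb offsets h (alpha_X = alpha + h.beta) and
# resonance scale factors k (beta_XY = k.beta), the classical Streitwieser
# parameterization.  Carbon defines the scale: h(C) = 0, k(C~C) = 1.

#' Load Hueckel parameters from a key-value file
#'
#' The file holds lines `h <element>.<env> <value>` and
#' `k <el1>~<el2>.<class> <value>` (`env` is `pi` for multiple-bonded atoms,
#' `lp` for lone-pair donors, `vac` for empty-p cations; `class` is `single`
#' or `multiple`).  `#` starts a comment.
#'
#' @param path file path; default is the parameter table shipped with the
#'   package.
#' @return an object of class `orbgap_huckel_params` with elements `h`, `k`,
#'   `checksum` and the optional affine eV map `alpha_ev`, `beta_ev`.
#' @export
read_huckel_params <- function(path = system.file("extdata",
                                                  "huckel_default_params.txt",
                                                  package = "orbgap")) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  h <- c(); k <- c(); alpha_ev <- NA_real_; beta_ev <- NA_real_
  for (ln in lines) {
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(f) != 3L) stopf("malformed parameter line: '%s'", ln)
    val <- suppressWarnings(as.numeric(f[3]))
    if (is.na(val)) stopf("non-numeric parameter value in line: '%s'", ln)
    if (f[1] == "h") h[f[2]] <- val
    else if (f[1] == "k") k[f[2]] <- val
    else if (f[1] == "ev" && f[2] == "alpha") alpha_ev <- val
    else if (f[1] == "ev" && f[2] == "beta") beta_ev <- val
    else stopf("unknown parameter kind '%s' in line: '%s'", f[1], ln)
  }
  huckel_params(h = h, k = k, alpha_ev = alpha_ev, beta_ev = beta_ev)
}

#' Construct a Hueckel parameter set
#'
#' @param h named numeric vector of Coulomb offsets (units of beta).
#' @param k named numeric vector of resonance scale factors (dimensionless,
#'   all positive).
#' @param alpha_ev,beta_ev optional affine map to eV: `E_eV = alpha_ev +
#'   x * beta_ev` for secular eigenvalue x (`beta_ev < 0`).
#' @return an `orbgap_huckel_params` object.
#' @export
huckel_params <- function(h, k, alpha_ev = NA_real_, beta_ev = NA_real_) {
  if (is.null(names(h)) || is.null(names(k)))
    stopf("h and k must be named vectors")
  if (!identical(unname(h[["C.pi"]]), 0)) stopf("h(C.pi) must be 0 (scale definition)")
  if (!identical(unname(k[["C~C.single"]]), 1) ||
      !identical(unname(k[["C~C.multiple"]]), 1))
    stopf("k(C~C) must be 1 (scale definition)")
  if (any(k <= 0)) stopf("all resonance factors k must be positive")
  p <- structure(list(h = h, k = k, alpha_ev = alpha_ev, beta_ev = beta_ev),
                 class = "orbgap_huckel_params")
  p$checksum <- content_checksum(list(h = h, k = k))
  p
}

#' Default Hueckel parameter table
#'
#' The shipped Streitwieser-style table, read once and cached.
#'
#' @return an `orbgap_huckel_params` object.
#' @export
default_huckel_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_huckel_params()
    cache
  }
})

atom_env <- function(pi, pos) {
  # pos indexes into pi$members
  switch(as.character(pi$contrib[pos]),
         "1" = "pi", "2" = "lp", "0" = "vac",
         stopf("unknown pi contribution %s", pi$contrib[pos]))
}

bond_class <- function(pi, i, j, order) {
  pos_i <- match(i, pi$members); pos_j <- match(j, pi$members)
  if (order %in% c(2L, 3L)) return("multiple")
  if (order == 4L && pi$contrib[pos_i] == 1L && pi$contrib[pos_j] == 1L)
    return("multiple")
  "single"
}

#' Hueckel orbital spectrum of a pi system
#'
#' Diagonalizes the parameterized connectivity matrix `H` with
#' `H[i,i] = h_i * beta` and `H[i,j] = k_ij * beta` for pi-bonded pairs
#' (alpha = 0, beta = -1), fills the lowest `electrons/2` orbitals with two
#' electrons each, and returns the ordered spectrum.
#'
#' @param pi an `orbgap_pisystem`.
#' @param params an `orbgap_huckel_params` (default: shipped table).
#' @return an object of class `orbgap_spectrum`: `energies` (ascending,
#'   beta-scaled), `coefficients` (atoms x orbitals, each column normalized),
#'   `occupations` (0/2), `n_electrons`, `members` (molecule atom indices),
#'   `unit` (`"beta"`), `param_checksum`.
#' @examples
#' sp <- huckel_spectrum(extract_pi_system(parse_smiles("C=C")))
#' sp$energies   # -1, 1
#' @export
huckel_spectrum <- function(pi, params = default_huckel_params()) {
  stopifnot(inherits(pi, "orbgap_pisystem"),
            inherits(params, "orbgap_huckel_params"))
  n <- length(pi$members)
  els <- pi$mol$atoms$element[pi$members]
  H <- matrix(0, n, n)
  for (pos in seq_len(n)) {
    key <- paste0(els[pos], ".", atom_env(pi, pos))
    if (!key %in% names(params$h))
      stopf("missing Hueckel Coulomb parameter for '%s'", key)
    H[pos, pos] <- -params$h[[key]]          # alpha + h*beta with beta = -1
  }
  b <- pi$bonds
  for (r in seq_len(nrow(b))) {
    pos_i <- match(b$i[r], pi$members); pos_j <- match(b$j[r], pi$members)
    pair <- paste(sort(c(els[pos_i], els[pos_j])), collapse = "~")
    key <- paste0(pair, ".", bond_class(pi, b$i[r], b$j[r], b$order[r]))
    if (!key %in% names(params$k))
      stopf("missing Hueckel resonance parameter for '%s'", key)
    H[pos_i, pos_j] <- H[pos_j, pos_i] <- -params$k[[key]]   # k*beta
  }
  eg <- eigen(H, symmetric = TRUE)
  ord <- order(eg$values)                    # ascending energy
  energies <- eg$values[ord]
  coefs <- eg$vectors[, ord, drop = FALSE]
  n_occ <- pi$electrons %/% 2L
  if (n_occ > n) stopf("more electron pairs (%d) than orbitals (%d)", n_occ, n)
  occ <- c(rep(2L, n_occ), rep(0L, n - n_occ))
  structure(list(energies = energies, coefficients = coefs,
                 occupations = occ, n_electrons = pi$electrons,
                 members = pi$members, unit = "beta",
                 param_checksum = params$checksum, H = H),
            class = "orbgap_spectrum")
}

#' Fraction of an orbital localized on an atom set
#'
#' Sum of squared coefficients of one orbital over the given atoms; by
#' normalization the full member set gives exactly 1.
#'
#' @param spectrum an `orbgap_spectrum`.
#' @param orbital orbital index (1 = lowest energy).
#' @param atoms molecule atom indices (must lie inside the pi system).
#' @return a fraction in `[0, 1]`.
#' @export
fragment_weight <- function(spectrum, orbital, atoms) {
  stopifnot(inherits(spectrum, "orbgap_spectrum"))
  if (orbital < 1L || orbital > length(spectrum$energies))
    stopf("orbital index %d out of range", orbital)
  pos <- match(atoms, spectrum$members)
  if (anyNA(pos))
    stopf("atom(s) %s outside the pi system",
          paste(atoms[is.na(pos)], collapse = ", "))
  sum(spectrum$coefficients[pos, orbital]^2)
}

#' Fragment-localized frontier bond orbitals (HOBO / LUBO)
#'
#' Finds the highest occupied and lowest unoccupied orbitals whose weight on
#' the matched fragment reaches `threshold` -- the bond orbitals of the
#' unsaturated unit of interest, as opposed to the global HOMO/LUMO which may
#' live on a different functional group.  Among energy-degenerate candidates
#' the larger fragment weight wins, then the lower orbital index.
#'
#' @param mol an `orbgap_mol`.
#' @param fragment an `orbgap_fragment` or pattern string; the first match
#'   (deterministic order) lying inside the pi system is used.
#' @param params Hueckel parameters.
#' @param threshold minimum fragment weight in `(0, 1]`; default 0.3.
#' @return an object of class `orbgap_bolabel`: `hobo_energy`, `lubo_energy`,
#'   `hobo_index`, `lubo_index`, `hobo_weight`, `lubo_weight`,
#'   `fragment_atoms`, `unit`, `threshold`, `param_checksum`, `smiles`.
#' @examples
#' lab <- bond_orbital_label(parse_smiles("O=NC1=CC=CC=C1"), "N=O")
#' lab$lubo_energy
#' @export
bond_orbital_label <- function(mol, fragment,
                               params = default_huckel_params(),
                               threshold = 0.3) {
  if (threshold <= 0 || threshold > 1) stopf("threshold must be in (0, 1]")
  if (is.character(fragment)) fragment <- fragment_pattern(fragment)
  pi <- extract_pi_system(mol)
  spec <- huckel_spectrum(pi, params)
  matches <- match_fragment(mol, fragment)
  if (length(matches) == 0L)
    stopf("fragment '%s' does not match molecule '%s'",
          fragment$pattern, canonical_smiles(mol))
  inside <- Filter(function(m) all(m %in% pi$members), matches)
  if (length(inside) == 0L)
    stopf("no match of fragment '%s' lies inside the conjugated pi system",
          fragment$pattern)
  atoms <- inside[[1L]]
  w <- vapply(seq_along(spec$energies), function(o)
    fragment_weight(spec, o, atoms), 0)

  pick <- function(idx, highest) {
    ok <- idx[w[idx] >= threshold]
    if (length(ok) == 0L) return(NA_integer_)
    e <- spec$energies[ok]
    target <- if (highest) max(e) else min(e)
    cand <- ok[abs(spec$energies[ok] - target) < 1e-9]
    cand <- cand[order(-w[cand], cand)]
    cand[1L]
  }
  occ <- which(spec$occupations == 2L)
  vac <- which(spec$occupations == 0L)
  hobo <- pick(occ, highest = TRUE)
  lubo <- pick(vac, highest = FALSE)
  if (is.na(hobo))
    stopf("orbital not localized on fragment: no occupied orbital reaches weight %.2f", threshold)
  if (is.na(lubo))
    stopf("orbital not localized on fragment: no unoccupied orbital reaches weight %.2f", threshold)
  structure(list(
    hobo_energy = spec$energies[hobo], lubo_energy = spec$energies[lubo],
    hobo_index = hobo, lubo_index = lubo,
    hobo_weight = w[hobo], lubo_weight = w[lubo],
    fragment_atoms = atoms, fragment = fragment$pattern,
    unit = spec$unit, threshold = threshold,
    param_checksum = spec$param_checksum,
    smiles = canonical_smiles(mol)),
    class = "orbgap_bolabel")
}

#' HOBO/LUBO gap between a substrate and an enophile
#'
#' `gap = LUBO(enophile) - HOBO(substrate)`; always positive on the physical
#' scale, and smaller means a more reactive orbital-controlled pairing.
#'
#' @param substrate,enophile `orbgap_bolabel` objects in the same unit system.
#' @return the energy difference (same unit).
#' @export
orbital_gap <- function(substrate, enophile) {
  stopifnot(inherits(substrate, "orbgap_bolabel"),
            inherits(enophile, "orbgap_bolabel"))
  if (!identical(substrate$unit, enophile$unit))
    stopf("unit mismatch: substrate '%s' vs enophile '%s'",
          substrate$unit, enophile$unit)
  enophile$lubo_energy - substrate$hobo_energy
}

#' Convert a bond-orbital label from beta-scaled units to eV
#'
#' Applies the affine map `E_eV = alpha_ev + x * beta_ev` (x the secular
#' eigenvalue) configured in the parameter set.
#'
#' @param label an `orbgap_bolabel` in `"beta"` units.
#' @param params parameter set carrying `alpha_ev` / `beta_ev`.
#' @return the label with energies in `"eV"`.
#' @export
label_to_ev <- function(label, params = default_huckel_params()) {
  stopifnot(inherits(label, "orbgap_bolabel"))
  if (!identical(label$unit, "beta")) stopf("label is not in beta units")
  if (is.na(params$alpha_ev) || is.na(params$beta_ev))
    stopf("no eV affine map configured (alpha_ev/beta_ev missing)")
  conv <- function(e_beta) params$alpha_ev + (-e_beta) * params$beta_ev
  label$hobo_energy <- conv(label$hobo_energy)
  label$lubo_energy <- conv(label$lubo_energy)
  label$unit <- "eV"
  label
}
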