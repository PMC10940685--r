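#' Run code with a local RNG seed
#'
#' Evaluates `expr` with the global RNG temporarily seeded, restoring the
#' previous RNG state afterwards so library code never perturbs user-level
#' random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic derived seeds: one user-facing seed fans out to per-stage
# streams via hashing, so stages can be re-run independently.
derive_seed <- function(seed, stage) {
  h <- fnv_hash(paste0("seed:", as.integer(seed), ":", stage))
  as.integer(h %% 2147483647)
}

#' Hash strings with 32-bit FNV-1a
#'
#' Fixed-constant hash used for fingerprint bits and content checksums; the
#' hash is platform-independent and never salted, so outputs are bit-identical
#' across processes.
#'
#' @param x character vector.
#' @return numeric vector of unsigned 32-bit hash values.
#' @export
fnv_hash <- function(x) {
  .fnv1a32(as.character(x))
}

# Short hex content checksum for parameter sets / configs.
content_checksum <- function(x) {
  s <- paste(deparse(x, control = c("keepNA", "niceNames")), collapse = "\n")
  v <- fnv_hash(s)
  sprintf("%04x%04x", as.integer(v %/% 65536), as.integer(v %% 65536))
}

HASH_VERSION <- "fnv1a-32/v1"

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
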