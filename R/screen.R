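# Virtual reactivity screening: predict orbital energies for candidate
# enophiles, compose HOBO/LUBO gaps against a reference substrate, rank,
# and classify reactive clusters.

#' Train per-energy prediction models on a labeled dataset
#'
#' Fits one model for the HOBO energy and one for the LUBO energy on the full
#' dataset with a single featurizer config; the config checksum is stored so
#' prediction can refuse silently re-featurized input.
#'
#' @param records labeled dataset.
#' @param feat_config an `orbgap_featconfig`.
#' @param spec model spec used for both energies (or a list with elements
#'   `hobo` and `lubo` for per-target specs).
#' @return an `orbgap_energy_models` object.
#' @export
train_energy_models <- function(records, feat_config, spec) {
  specs <- if (inherits(spec, "orbgap_modelspec")) list(hobo = spec, lubo = spec)
           else spec
  X <- feature_matrix(records$smiles, feat_config)
  unit <- unique(records$unit)
  if (length(unit) != 1L) stopf("dataset mixes energy units: %s",
                                paste(unit, collapse = ", "))
  structure(list(
    hobo = fit_model(specs$hobo, X, records$hobo),
    lubo = fit_model(specs$lubo, X, records$lubo),
    feat_config = feat_config,
    feat_checksum = feat_config$checksum,
    unit = unit, n_train = nrow(records)),
    class = "orbgap_energy_models")
}

#' Predict HOBO/LUBO energies from SMILES
#'
#' Featurizes with the exact config the models were trained with
#' (checksum-verified) and predicts both energies.
#'
#' @param models an `orbgap_energy_models`.
#' @param smiles character vector of SMILES.
#' @param feat_config optional config for verification; if supplied it must
#'   have the same checksum as the training config (no silent
#'   re-featurization).
#' @return data.frame with columns smiles, hobo, lubo, unit.
#' @export
predict_energies <- function(models, smiles, feat_config = NULL) {
  stopifnot(inherits(models, "orbgap_energy_models"))
  if (!is.null(feat_config) &&
      !identical(feat_config$checksum, models$feat_checksum))
    stopf("featurizer config mismatch: model trained with %s, request has %s",
          models$feat_checksum, feat_config$checksum)
  X <- feature_matrix(smiles, models$feat_config)
  data.frame(smiles = smiles,
             hobo = predict(models$hobo, X),
             lubo = predict(models$lubo, X),
             unit = models$unit, stringsAsFactors = FALSE)
}

#' Reference substrate label
#'
#' The default reference is a cycloheptatriene model compound whose
#' conjugated triene carries the HOBO; the label comes from the oracle unless
#' an external HOBO energy is supplied.
#'
#' @param smiles substrate SMILES (default: cycloheptatriene).
#' @param fragment fragment pattern holding the reacting unit.
#' @param params Hueckel parameters.
#' @param hobo_energy optional externally supplied HOBO energy (e.g. DFT);
#'   overrides the oracle value.
#' @param unit unit of `hobo_energy` when supplied.
#' @return a list with `smiles`, `hobo_energy`, `unit`, `provenance`.
#' @export
reference_substrate <- function(smiles = "C1=CC=CC=CC1",
                                fragment = "C=CC=CC=C",
                                params = default_huckel_params(),
                                hobo_energy = NULL, unit = "beta") {
  if (!is.null(hobo_energy)) {
    return(list(smiles = smiles, hobo_energy = hobo_energy, unit = unit,
                provenance = "external"))
  }
  lab <- bond_orbital_label(parse_smiles(smiles), fragment, params)
  list(smiles = lab$smiles, hobo_energy = lab$hobo_energy, unit = lab$unit,
       provenance = "oracle")
}

#' Load the shipped candidate enophile panel
#'
#' A fixture list of named common enophiles/dienophiles spanning the alkene,
#' alkyne, carbonyl, nitroso, azo/triazolinedione and aryne classes.  Aryne
#' entries carry externally supplied (synthetic stand-in) LUBO labels because
#' the in-plane aryne orbital is outside a pi-only treatment; they are
#' flagged `surrogate_incomputable`.
#'
#' @param path CSV path (default: packaged panel).
#' @return data.frame with columns name, smiles, class, fragment,
#'   external_lubo, unit.
#' @export
load_enophile_panel <- function(path = system.file("extdata",
                                                   "enophile_panel.csv",
                                                   package = "orbgap")) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Screen candidate enophiles against a reference substrate
#'
#' Computes `gap = LUBO(candidate) - HOBO(reference)` per candidate, ranks
#' ascending (small gap = predicted reactive), and flags candidates at or
#' below the threshold.  LUBO energies come from, in order of precedence:
#' the candidate's `external_lubo` column, the trained `models`, or the
#' Hueckel oracle on the candidate's fragment.
#'
#' @param candidates data.frame with columns smiles, class, fragment, and
#'   optionally name and external_lubo (NA where not applicable).
#' @param reference result of [reference_substrate()].
#' @param models optional `orbgap_energy_models`; when NULL the oracle labels
#'   are used.
#' @param params Hueckel parameters for oracle labeling.
#' @param threshold gap threshold for the reactive flag; when NULL and
#'   `anchor` is given, derived as anchor gap x (1 + tolerance).
#' @param anchor SMILES of a known-reactive candidate present in the panel.
#' @param tolerance anchor tolerance (default 0.1).
#' @return an `orbgap_screen_report`.
#' @export
screen_candidates <- function(candidates, reference, models = NULL,
                              params = default_huckel_params(),
                              threshold = NULL, anchor = NULL,
                              tolerance = 0.1) {
  if (nrow(candidates) == 0L) stopf("empty candidate list")
  if (!"external_lubo" %in% names(candidates))
    candidates$external_lubo <- NA_real_
  if (!"name" %in% names(candidates)) candidates$name <- candidates$smiles

  lubo <- rep(NA_real_, nrow(candidates))
  source <- rep(NA_character_, nrow(candidates))
  need <- which(is.na(candidates$external_lubo))
  ext <- which(!is.na(candidates$external_lubo))
  lubo[ext] <- candidates$external_lubo[ext]
  source[ext] <- "external"
  if (length(need) > 0L) {
    if (is.null(models)) {
      for (idx in need) {
        lab <- bond_orbital_label(parse_smiles(candidates$smiles[idx]),
                                  candidates$fragment[idx], params)
        lubo[idx] <- lab$lubo_energy
      }
      source[need] <- "oracle"
    } else {
      if (!identical(models$unit, reference$unit))
        stopf("unit mismatch between models ('%s') and reference ('%s')",
              models$unit, reference$unit)
      pred <- predict_energies(models, candidates$smiles[need])
      lubo[need] <- pred$lubo
      source[need] <- "model"
    }
  }
  gap <- lubo - reference$hobo_energy
  ord <- order(gap, candidates$smiles)
  res <- data.frame(
    name = candidates$name, smiles = candidates$smiles,
    class = candidates$class, lubo = lubo, gap = gap,
    lubo_source = source, stringsAsFactors = FALSE)[ord, ]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL

  if (is.null(threshold) && !is.null(anchor)) {
    hit <- match(anchor, res$smiles)
    if (is.na(hit)) stopf("anchor '%s' not among candidates", anchor)
    threshold <- res$gap[hit] * (1 + tolerance)
  }
  res$reactive <- if (is.null(threshold)) NA else res$gap <= threshold
  structure(list(reference = reference, results = res,
                 threshold = threshold, tolerance = tolerance,
                 unit = reference$unit,
                 model_metadata = if (!is.null(models))
                   list(feat_checksum = models$feat_checksum,
                        n_train = models$n_train) else NULL),
            class = "orbgap_screen_report")
}

#' Re-derive the reactive threshold from an anchor candidate
#'
#' `threshold = gap(anchor) * (1 + tolerance)`; raising the tolerance never
#' unflags a previously reactive candidate.
#'
#' @param report an `orbgap_screen_report`.
#' @param anchor_smiles SMILES of the anchor (must be among the candidates).
#' @param tolerance non-negative tolerance.
#' @return the updated report (threshold recorded, flags recomputed).
#' @export
set_threshold <- function(report, anchor_smiles, tolerance = 0.1) {
  stopifnot(inherits(report, "orbgap_screen_report"))
  hit <- match(anchor_smiles, report$results$smiles)
  if (is.na(hit)) stopf("anchor '%s' not among candidates", anchor_smiles)
  report$threshold <- report$results$gap[hit] * (1 + tolerance)
  report$tolerance <- tolerance
  report$results$reactive <- report$results$gap <= report$threshold
  report
}

#' @export
print.orbgap_screen_report <- function(x, ...) {
  cat(sprintf("<orbgap_screen_report> %d candidates vs %s (HOBO %.3f %s)\n",
              nrow(x$results), x$reference$smiles, x$reference$hobo_energy,
              x$unit))
  if (!is.null(x$threshold))
    cat(sprintf("threshold %.3f: %d flagged reactive\n", x$threshold,
                sum(x$results$reactive)))
  print(head(x$results, 10L))
  invisible(x)
}

#' Serialize a screening report to JSON (and optionally CSV)
#'
#' @param report an `orbgap_screen_report`.
#' @param path JSON output path.
#' @param csv optional CSV path for the per-candidate table.
#' @export
write_screen_report <- function(report, path, csv = NULL) {
  payload <- list(reference = report$reference,
                  threshold = report$threshold,
                  tolerance = report$tolerance,
                  unit = report$unit,
                  model_metadata = report$model_metadata,
                  results = report$results)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  if (!is.null(csv)) write.csv(report$results, csv, row.names = FALSE)
  invisible(path)
}

#' Read back a screening report written by [write_screen_report()]
#'
#' @param path JSON path.
#' @return an `orbgap_screen_report`.
#' @export
read_screen_report <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  res <- as.data.frame(p$results, stringsAsFactors = FALSE)
  structure(list(reference = p$reference, results = res,
                 threshold = p$threshold, tolerance = p$tolerance,
                 unit = p$unit, model_metadata = p$model_metadata),
            class = "orbgap_screen_report")
}

#' Scatter plot of screening gaps by class
#'
#' Class-colored strip plot of predicted gaps, mirroring a predicted
#' energy-gap cluster plot.
#'
#' @param report an `orbgap_screen_report`.
#' @param ... passed to [graphics::plot()].
#' @export
plot_screen_report <- function(report, ...) {
  res <- report$results
  cls <- factor(res$class)
  graphics::plot(as.integer(cls), res$gap, xaxt = "n",
                 xlab = "enophile class", ylab = sprintf("gap (%s)", report$unit),
                 pch = 19, col = as.integer(cls), ...)
  graphics::axis(1, at = seq_along(levels(cls)), labels = levels(cls), las = 2)
  if (!is.null(report$threshold))
    graphics::abline(h = report$threshold, lty = 2)
  invisible(report)
}
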