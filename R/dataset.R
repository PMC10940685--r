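# Labeled-record schema, CSV I/O, stratified splits, and the synthetic
# corpus generator.
#
# The generator enumerates substituted scaffolds for five enophile classes
# (alkenes, alkynes, carbonyls, nitroso compounds, azo/triazolinedione
# compounds), labels each molecule with the Hueckel oracle and adds Gaussian
# noise to both energies.  Arynes cannot be labeled by a pi-only oracle
# (their reactive orbital is in-plane) and are accepted only with externally
# supplied labels.

DATASET_COLUMNS <- c("smiles", "fragment", "hobo", "lubo", "unit", "role",
                     "class", "label_source", "hobo_weight", "lubo_weight",
                     "param_checksum")

CLASS_FRAGMENTS <- c(alkene = "C=C", alkyne = "C#C", carbonyl = "C=O",
                     nitroso = "N=O", azo = "N=N")

# Scaffold templates per class.  Substituents are SMILES prefixes attaching
# through their final atom; "" stands for hydrogen.
class_templates <- function(class) {
  A <- c("", "C", "CC", "CCC", "C(C)C", "c1ccccc1", "CO", "Cl", "F",
         "N#C", "COC(=O)", "O=C", "C=C", "Cc1ccc(cc1)", "COc1ccc(cc1)")
  switch(class,
    alkene = {
      pairs <- expand.grid(a = A, b = A, stringsAsFactors = FALSE)
      c(paste0(pairs$a, "C=C", pairs$b),
        paste0("C(=C)(C)", c("C", "CC", "c1ccccc1", "Cl", "CO")),
        "C1=CCCCC1", "C1=CCCC1", "CC=C(C)C")
    },
    alkyne = {
      pairs <- expand.grid(a = A, b = A, stringsAsFactors = FALSE)
      c(paste0(pairs$a, "C#C", pairs$b))
    },
    carbonyl = {
      Ak <- c("C", "CC", "CCC", "C(C)C", "c1ccccc1", "Cc1ccc(cc1)",
              "COc1ccc(cc1)", "C=C", "CO", "CN", "CCO", "CCN", "N", "O",
              "Clc1ccc(cc1)")
      pairs <- expand.grid(a = Ak, b = Ak, stringsAsFactors = FALSE)
      c(paste0("O=C", c("C", "CC", "c1ccccc1", "C=C")),   # aldehydes
        paste0(pairs$a, "C(=O)", pairs$b))
    },
    nitroso = {
      ring_sub <- c("C", "CC", "Cl", "F", "Br", "OC", "C(=O)OC", "C#N",
                    "CCC", "C(C)C", "N(C)C", "OCC", "CCCC")
      disub <- expand.grid(x = ring_sub, y = ring_sub, stringsAsFactors = FALSE)
      c("O=NC", "O=NCC", "O=NCCC", "O=NC(C)C", "O=NC(C)(C)C", "O=NCCCC",
        "O=NCC(C)C", "O=Nc1ccccc1",
        paste0("O=Nc1ccc(", ring_sub, ")cc1"),
        paste0("O=Nc1cccc(", ring_sub, ")c1"),
        paste0("O=Nc1ccccc1", ring_sub),
        paste0("O=Nc1ccc(", disub$x, ")c(", disub$y, ")c1"))
    },
    azo = {
      Az <- c("C", "CC", "CCC", "CCCC", "C(C)C", "C(C)(C)C", "c1ccccc1",
              "COC(=O)", "CCOC(=O)", "CC(=O)", "Cc1ccc(cc1)",
              "Clc1ccc(cc1)", "COc1ccc(cc1)")
      pairs <- expand.grid(a = Az, b = Az, stringsAsFactors = FALSE)
      tad_n <- c("C", "CC", "CCC", "CCCC", "C(C)C", "C(C)(C)C",
                 "c1ccccc1", "Cc1ccc(cc1)", "COc1ccc(cc1)", "Clc1ccc(cc1)",
                 "Fc1ccc(cc1)", "Brc1ccc(cc1)", "CCc1ccc(cc1)",
                 "Cc1cccc(c1)", "CCCCC")
      c(paste0(pairs$a, "N=N", pairs$b),
        paste0("O=C1N(", tad_n, ")C(=O)N=N1"))
    },
    stopf("no generator templates for class '%s'", class))
}

#' Generate a synthetic oracle-labeled corpus
#'
#' Enumerates substituted scaffolds per enophile class, labels each with the
#' Hueckel oracle (HOBO/LUBO on the class fragment) and adds Gaussian label
#' noise.  Deterministic under `seed`.
#'
#' @param n_per_class molecules per class.
#' @param classes class tags; any of `"alkene"`, `"alkyne"`, `"carbonyl"`,
#'   `"nitroso"`, `"azo"`.  Class `"aryne"` has no oracle templates and must
#'   come with external labels via [read_dataset()].
#' @param noise_sd standard deviation of the Gaussian label noise, in beta
#'   units (default 0.05).
#' @param seed integer seed.
#' @param params Hueckel parameters.
#' @param threshold localization threshold passed to [bond_orbital_label()].
#' @return a `data.frame` of labeled records (see [read_dataset()] for the
#'   schema).
#' @examples
#' head(generate_corpus(5, classes = c("alkene", "nitroso"), seed = 1))
#' @export
generate_corpus <- function(n_per_class = 30L,
                            classes = c("alkene", "alkyne", "carbonyl",
                                        "nitroso", "azo"),
                            noise_sd = 0.05, seed = 1L,
                            params = default_huckel_params(),
                            threshold = 0.3) {
  if ("aryne" %in% classes)
    stopf("class 'aryne' is not oracle-computable; supply external labels instead")
  unknown <- setdiff(classes, names(CLASS_FRAGMENTS))
  if (length(unknown) > 0L)
    stopf("no generator templates for class(es) %s",
          paste(unknown, collapse = ", "))
  if (n_per_class == 0L) return(empty_dataset())
  rows <- list()
  for (cls in classes) {
    frag <- fragment_pattern(CLASS_FRAGMENTS[[cls]])
    smis <- class_templates(cls)
    taken <- 0L; seen <- character(0)
    for (s in smis) {
      if (taken >= n_per_class) break
      lab <- tryCatch({
        mol <- parse_smiles(s)
        can <- canonical_smiles(mol)
        if (can %in% seen) NULL
        else bond_orbital_label(mol, frag, params, threshold)
      }, error = function(e) NULL)
      if (is.null(lab)) next
      seen <- c(seen, lab$smiles)
      taken <- taken + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        smiles = lab$smiles, fragment = frag$pattern,
        hobo = lab$hobo_energy, lubo = lab$lubo_energy, unit = lab$unit,
        role = "enophile", class = cls, label_source = "oracle",
        hobo_weight = lab$hobo_weight, lubo_weight = lab$lubo_weight,
        param_checksum = lab$param_checksum, stringsAsFactors = FALSE)
    }
    if (taken < n_per_class)
      stopf("class '%s': only %d of %d requested molecules available from templates",
            cls, taken, n_per_class)
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  if (noise_sd > 0) {
    records <- with_seed(derive_seed(seed, "corpus_noise"), {
      for (r in seq_len(nrow(records))) {
        repeat {
          e <- rnorm(2L, sd = noise_sd)
          if (records$hobo[r] + e[1L] < records$lubo[r] + e[2L]) {
            records$hobo[r] <- records$hobo[r] + e[1L]
            records$lubo[r] <- records$lubo[r] + e[2L]
            break
          }
        }
      }
      records
    })
  }
  records
}

empty_dataset <- function() {
  df <- data.frame(smiles = character(0), fragment = character(0),
                   hobo = numeric(0), lubo = numeric(0), unit = character(0),
                   role = character(0), class = character(0),
                   label_source = character(0), hobo_weight = numeric(0),
                   lubo_weight = numeric(0), param_checksum = character(0),
                   stringsAsFactors = FALSE)
  df
}

validate_dataset <- function(records) {
  missing <- setdiff(DATASET_COLUMNS, names(records))
  if (length(missing) > 0L)
    stopf("dataset missing column(s): %s", paste(missing, collapse = ", "))
  bad <- which(records$hobo >= records$lubo)
  if (length(bad) > 0L)
    stopf("record(s) %s violate hobo < lubo", paste(head(bad), collapse = ", "))
  aryne_oracle <- records$class == "aryne" & records$label_source != "external"
  if (any(aryne_oracle))
    stopf("aryne records must have label_source = 'external'")
  invisible(records)
}

#' Write a labeled dataset to CSV
#'
#' Fixed-header UTF-8 CSV with '.' decimal separator; round-trips
#' field-for-field through [read_dataset()].
#'
#' @param records dataset data.frame.
#' @param path output path.
#' @export
write_dataset <- function(records, path) {
  validate_dataset(records)
  write.csv(records[, DATASET_COLUMNS], path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a labeled dataset from CSV
#'
#' @param path CSV path with the schema written by [write_dataset()]:
#'   columns smiles, fragment, hobo, lubo, unit, role, class, label_source,
#'   hobo_weight, lubo_weight, param_checksum.
#' @return validated data.frame.
#' @export
read_dataset <- function(path) {
  records <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_dataset(records)
  records
}

#' Stratified train/validation/test split
#'
#' Disjoint, exhaustive, stratified by class tag, deterministic under `seed`.
#' Classes with fewer records than splits are assigned best-effort with a
#' warning.
#'
#' @param records dataset data.frame (>= 3 rows).
#' @param fractions numeric length-3 vector summing to 1.
#' @param seed integer seed.
#' @return list with elements `train`, `validation`, `test`.
#' @export
split_records <- function(records, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (nrow(records) < 3L) stopf("need at least 3 records to split")
  if (abs(sum(fractions) - 1) > 1e-9) stopf("fractions must sum to 1")
  assign_split <- with_seed(derive_seed(seed, "split"), {
    out <- rep(NA_integer_, nrow(records))
    for (cls in unique(records$class)) {
      idx <- which(records$class == cls)
      idx <- idx[sample.int(length(idx))]
      n <- length(idx)
      n_test <- round(fractions[3L] * n)
      n_val <- round(fractions[2L] * n)
      if (n < 3L)
        warnf("class '%s' has only %d record(s); best-effort assignment", cls, n)
      n_train <- n - n_val - n_test
      out[idx] <- rep(1:3, times = c(n_train, n_val, n_test))
    }
    out
  })
  list(train = records[assign_split == 1L, , drop = FALSE],
       validation = records[assign_split == 2L, , drop = FALSE],
       test = records[assign_split == 3L, , drop = FALSE])
}
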