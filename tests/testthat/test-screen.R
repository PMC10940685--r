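oracle_screen <- function(anchor = NULL, tolerance = 0.1) {
  screen_candidates(load_enophile_panel(), reference_substrate(),
                    anchor = anchor, tolerance = tolerance)
}

test_that("energy models predict their own training data and refuse config drift", {
  rec <- generate_corpus(15, classes = c("alkene", "nitroso", "azo"), seed = 21)
  cfg <- featurizer_config("path", 1024)
  models <- train_energy_models(rec, cfg,
                                model_spec("elastic_net", lambda = 1e-3,
                                           mixing = 0.5))
  pred <- predict_energies(models, rec$smiles)
  # training-set residual band
  expect_lt(sqrt(mean((pred$lubo - rec$lubo)^2)), 0.1)
  expect_identical(pred$unit, rep("beta", nrow(rec)))
  # duplicate SMILES give identical predictions
  p2 <- predict_energies(models, c(rec$smiles[1], rec$smiles[1]))
  expect_identical(p2$lubo[1], p2$lubo[2])
  # featurizer config mismatch is a hard error, never silent re-featurization
  other <- featurizer_config("circular", 1024, radius = 2)
  expect_error(predict_energies(models, rec$smiles[1], feat_config = other),
               "mismatch")
  expect_silent(predict_energies(models, rec$smiles[1], feat_config = cfg))
})

test_that("unit systems may not be mixed when composing gaps", {
  rec <- generate_corpus(10, classes = c("alkene", "azo"), seed = 22)
  models <- train_energy_models(rec, featurizer_config("path", 512),
                                model_spec("elastic_net"))
  ref_ev <- reference_substrate(hobo_energy = -7.8, unit = "eV")
  expect_error(
    screen_candidates(data.frame(smiles = "C=C", class = "alkene",
                                 fragment = "C=C"),
                      ref_ev, models = models),
    "unit mismatch")
})

test_that("screening ranks by ascending gap with a permutation of ranks", {
  rep <- oracle_screen()
  res <- rep$results
  expect_setequal(res$rank, seq_len(nrow(res)))
  expect_false(is.unsorted(res$gap))
  expect_true(all(diff(res$rank) == 1))
  # single candidate gets rank 1
  one <- screen_candidates(data.frame(smiles = "C=C", class = "alkene",
                                      fragment = "C=C"),
                           reference_substrate())
  expect_equal(one$results$rank, 1L)
  expect_error(screen_candidates(data.frame(), reference_substrate()), "empty")
})

test_that("oracle screening clusters reactive classes below inert ones", {
  res <- oracle_screen()$results
  med <- tapply(res$gap, res$class, median)
  reactive <- c("nitroso", "azo", "aryne")
  inert <- c("alkene", "alkyne", "carbonyl")
  expect_lt(max(med[reactive]), min(med[inert]))
  # triazolinediones sit at the very bottom of the gap ranking
  expect_true(any(grepl("triazoline", res$name[1:2])))
  # aryne labels are externally supplied, everything else oracle-computed
  expect_true(all(res$lubo_source[res$class == "aryne"] == "external"))
  expect_true(all(res$lubo_source[res$class != "aryne"] == "oracle"))
})

test_that("anchor-derived thresholds behave monotonically", {
  ptad <- "O=C1N(c2ccccc2)C(=O)N=N1"
  rep0 <- oracle_screen(anchor = ptad, tolerance = 0)
  # tolerance 0: anchor and strictly-lower gaps flagged
  anchor_gap <- rep0$results$gap[match(ptad, rep0$results$smiles)]
  expect_true(all(rep0$results$reactive == (rep0$results$gap <= anchor_gap)))
  # raising the tolerance never unflags a reactive candidate
  prev <- rep0$results$reactive
  for (tol in c(0.1, 0.3, 0.6)) {
    cur <- set_threshold(rep0, ptad, tolerance = tol)$results$reactive
    expect_true(all(cur[prev]))
    prev <- cur
  }
  expect_error(set_threshold(rep0, "C#N"), "not among")
  # reactive flag always equals the threshold comparison
  rep1 <- oracle_screen(anchor = ptad, tolerance = 0.1)
  expect_identical(rep1$results$reactive, rep1$results$gap <= rep1$threshold)
})

test_that("rank order is invariant under a consistent affine unit change", {
  res <- oracle_screen()$results
  # affine map x -> alpha + beta*x with beta < 0 on the secular eigenvalue
  # scale equals an increasing affine map on the energy scale
  ref_ev <- reference_substrate(hobo_energy = -6.6 + (-0.445) * -2.7,
                                unit = "eV")
  cand_ev <- data.frame(smiles = res$smiles, class = res$class,
                        fragment = NA,
                        external_lubo = -6.6 + (-res$lubo) * -2.7,
                        name = res$name)
  rep_ev <- screen_candidates(cand_ev, ref_ev)
  expect_identical(rep_ev$results$smiles, res$smiles)
})

test_that("screening reports round-trip through JSON bit-exactly", {
  rep <- oracle_screen(anchor = "O=C1N(C)C(=O)N=N1")
  tf <- tempfile(fileext = ".json")
  write_screen_report(rep, tf, csv = sub("json$", "csv", tf))
  back <- read_screen_report(tf)
  expect_equal(back$results, rep$results, tolerance = 1e-12)
  expect_equal(back$threshold, rep$threshold, tolerance = 1e-12)
  expect_equal(nrow(read.csv(sub("json$", "csv", tf))), nrow(rep$results))
})

test_that("model-based screening tracks the oracle ranking", {
  rec <- generate_corpus(30, seed = 23)
  sp <- split_records(rec, c(0.8, 0, 0.2), seed = 23)
  models <- train_energy_models(
    sp$train, featurizer_config("path", 2048),
    model_spec("neural_net", hidden = c(64L, 32L), seed = 1))
  ref <- reference_substrate()
  held <- data.frame(smiles = sp$test$smiles, class = sp$test$class,
                     fragment = sp$test$fragment)
  rep_ml <- screen_candidates(held, ref, models = models)
  rep_or <- screen_candidates(held, ref)
  merged <- merge(rep_ml$results[, c("smiles", "gap")],
                  rep_or$results[, c("smiles", "gap")], by = "smiles")
  rho <- cor(merged$gap.x, merged$gap.y, method = "spearman")
  expect_gte(rho, 0.7)
})
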