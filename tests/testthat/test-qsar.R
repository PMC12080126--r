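# Oversampling, classifier training and library screening.

test_that("oversampling reaches its target and is seeded", {
  set.seed(71)
  n <- 100; k <- 4
  labels <- matrix(0L, n, k)
  labels[1:5, ] <- 1L                 # reachable: actives are multisite
  feats <- matrix(stats::rbinom(n * 8, 1, 0.3), n)
  aug <- oversample_actives(feats, labels, target = 0.25, seed = 3)
  f <- mean(colMeans(aug$labels))
  expect_gte(f, 0.25 - k / nrow(aug$labels))   # within one duplication
  expect_true(all(seq_len(n) %in% aug$origin)) # originals retained
  expect_true(all(aug$origin[-seq_len(n)] %in% 1:5))
  aug2 <- oversample_actives(feats, labels, target = 0.25, seed = 3)
  expect_identical(aug$origin, aug2$origin)
  # already balanced input is untouched
  bal <- matrix(1L, 10, 2)
  expect_equal(nrow(oversample_actives(feats[1:10, ], bal)$labels), 10)
  # no actives: warn and pass through
  expect_warning(none <- oversample_actives(feats, matrix(0L, n, k)),
                 "no active")
  expect_equal(nrow(none$labels), n)
})

test_that("selection boundary is strict at the fraction-of-sites rule", {
  pred <- rbind(sel = c(rep(1, 29), rep(0, 12)),
                not = c(rep(1, 28), rep(0, 13)))
  out <- select_multibinders(pred, site_fraction_threshold = 0.70)
  expect_equal(out$selected, "sel")
  expect_equal(unname(out$fraction), c(29, 28) / 41)
  none <- select_multibinders(matrix(0, 3, 41), 0.70)
  expect_length(none$selected, 0)
})

test_that("screening selection is invariant under library permutation", {
  set.seed(73)
  spec <- small_spec()
  fx <- gen_screening_fixture(spec)
  fp <- featurize(fx$train$smiles)
  labels <- build_labels(fx$train$energy, 5)
  cfg <- model_config(hidden = 32L, epochs = 4L, batch_size = 64L,
                      lr = 2e-3, seed = 11L)
  model <- train_classifier(fp, labels, cfg)
  lib <- fx$screen$smiles
  s1 <- screen(model, lib)
  perm <- sample(length(lib))
  s2 <- screen(model, lib[perm])
  expect_setequal(s1$selected, s2$selected)
  expect_equal(s1$fraction[names(s2$fraction)], s2$fraction)
})

test_that("training learns a separable planted signal (MCC > 0.8)", {
  spec <- fixture_spec(n_compounds = 2000L, n_sites = 10L,
                       n_planted = 90L, delta = 5,
                       planted_site_fraction = 1.0,
                       screen_size = 40L, screen_planted = 10L,
                       seed = 19L)
  fx <- gen_screening_fixture(spec)
  fp <- featurize(fx$train$smiles)
  labels <- build_labels(fx$train$energy, 5)
  cfg <- model_config(hidden = c(128L), epochs = 12L,
                      batch_size = 256L, lr = 2e-3, seed = 19L)
  model <- train_classifier(fp, labels, cfg)
  expect_gt(model$report$mean_mcc, 0.8)

  # permuted labels carry no signal: test MCC within 0.1 of zero
  perm_labels <- labels$labels[sample(nrow(labels$labels)), ]
  rownames(perm_labels) <- rownames(labels$labels)
  null_model <- train_classifier(fp, perm_labels, cfg)
  expect_lt(abs(null_model$report$mean_mcc), 0.1)

  # seeded determinism: identical metrics on a re-run
  model2 <- train_classifier(fp, labels, cfg)
  expect_identical(model$report$mean_mcc, model2$report$mean_mcc)
  expect_identical(model$val_mcc_trace, model2$val_mcc_trace)
  expect_identical(model$weights, model2$weights)
})

test_that("models survive a save/load round trip", {
  spec <- small_spec(seed = 23L)
  fx <- gen_screening_fixture(spec)
  fp <- featurize(fx$train$smiles)
  model <- train_classifier(fp, build_labels(fx$train$energy, 5),
                            model_config(hidden = 16L, epochs = 2L,
                                         batch_size = 64L, seed = 23L))
  dir <- tempfile("model_")
  save_model(model, dir)
  back <- load_model(dir)
  p1 <- predict(model, fp[1:10, ])
  p2 <- predict(back, fp[1:10, ])
  expect_equal(p1, p2, tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(back$sites, model$sites)
})

test_that("config validation catches bad splits and label NAs", {
  expect_error(model_config(split = c(0.9, 0.1, 0.1)), "summing to 1")
  fp <- matrix(0L, 30, 16)
  y <- matrix(NA_integer_, 30, 2)
  expect_error(train_classifier(fp, y, model_config(hidden = 4L)),
               "NA")
})
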