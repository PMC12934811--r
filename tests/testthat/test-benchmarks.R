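test_that("cross-validation folds exactly partition curves", {
  ds <- simulate_screens(synth_config(n_studies = 3, samples_per_study = 5,
                                      n_drugs = 15, seed = 13))
  folds <- cv_folds(ds, n_folds = 5, seed = 1)
  key <- paste(ds$records$study_id, ds$records$sample_id,
               ds$records$drug_id)
  per_curve <- tapply(folds, key, function(f) length(unique(f)))
  expect_true(all(per_curve == 1))            # whole curves move together
  expect_setequal(unique(folds), 1:5)
})

test_that("an oracle predictor scores r = 1 in every stratum", {
  ds <- simulate_screens(synth_config(n_studies = 2, samples_per_study = 5,
                                      n_drugs = 12, noise_sd = 0.02,
                                      seed = 14))
  oracle_factory <- function(train) {
    function(records) records$viability
  }
  rep_ <- cv_curve_holdout(ds, oracle_factory, n_folds = 3, seed = 2)
  expect_equal(rep_$overall$r, 1, tolerance = 1e-12)
  ok <- is.finite(rep_$by_stratum$disease$r)
  expect_true(all(abs(rep_$by_stratum$disease$r[ok] - 1) < 1e-12))
})

test_that("bucket-mean baseline averages buckets with documented fallbacks", {
  train <- data.frame(study_id = "s", sample_id = c("a", "a", "b"),
                      drug_id = c("d1", "d1", "d2"),
                      concentration_uM = c(1, 1, 1),
                      viability = c(0.4, 0.6, 0.9))
  test <- data.frame(study_id = "s", sample_id = "c",
                     drug_id = c("d1", "d2", "d3"),
                     concentration_uM = c(1, 100, 1))
  p <- baseline_predict("bucket_mean", train, test)
  expect_equal(p[1], 0.5)                     # bucket mean
  expect_equal(p[2], 0.9)                     # drug-mean fallback
  expect_equal(p[3], mean(train$viability))   # global fallback
})

test_that("closed-form ridge at zero penalty reproduces ordinary least squares", {
  set.seed(19)
  train <- data.frame(study_id = rep(c("s1", "s2"), each = 10),
                      sample_id = "p",
                      drug_id = rep(c("d1", "d2"), 10),
                      concentration_uM = 10^runif(20, -2, 1))
  train$viability <- runif(20)
  test <- train[1:6, ]
  p_ridge <- baseline_predict("ridge", train, test, lambda = 0)
  cols <- c("study_id", "sample_id", "drug_id", "concentration_uM")
  enc <- panscreen:::encode_features(rbind(train[, cols], test[, cols]))
  Xtr <- cbind(1, enc[seq_len(nrow(train)), , drop = FALSE])
  Xte <- cbind(1, enc[nrow(train) + seq_len(nrow(test)), , drop = FALSE])
  # independent least-squares fit of the same design
  fit <- lm.fit(Xtr, train$viability)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  expect_equal(p_ridge, as.vector(Xte %*% beta), tolerance = 1e-8)
})

test_that("tree, boosting and network baselines produce finite predictions", {
  ds <- simulate_screens(synth_config(n_studies = 2, samples_per_study = 6,
                                      n_drugs = 16,
                                      single_dose_studies = integer(0),
                                      seed = 15))
  set.seed(1)
  idx <- sample(nrow(ds$records), 200)
  train <- ds$records[idx, ]; test <- ds$records[-idx, ][1:50, ]
  for (kind in c("tree_ensemble", "boosted_trees", "feedforward_net",
                 "context_mean")) {
    p <- baseline_predict(kind, train, test, seed = 1)
    expect_length(p, 50)
    expect_true(all(is.finite(p)))
  }
  expect_error(baseline_predict("nonsense", train, test))
})

test_that("power analysis matches its analytic reference modes", {
  set.seed(20)
  panel <- paste0("d", 1:100)
  true_ic50 <- matrix(rnorm(20 * 100), 20, 100,
                      dimnames = list(paste0("p", 1:20), panel))
  oracle <- power_analysis(panel, true_ic50, rank_fn = "oracle",
                           pilot_size = 10, budgets = c(1, 5, 20),
                           n_seeds = 2, seed = 1)
  expect_true(all(oracle$power == 1))

  rnd <- power_analysis(panel, true_ic50, rank_fn = "random",
                        pilot_size = 10, budgets = 10, n_seeds = 60,
                        seed = 1)
  expect_lt(abs(rnd$power - 0.20), 0.04)

  # monotone non-decreasing in budget
  curve <- power_analysis(panel, true_ic50, rank_fn = "random",
                          pilot_size = 10, budgets = c(1, 5, 10, 25, 50),
                          n_seeds = 5, seed = 2)
  expect_true(all(diff(curve$power) >= 0))
  # strict mode: budget-0 equivalent handled through pilot_in_success
  strict <- power_analysis(panel, true_ic50, rank_fn = "random",
                           pilot_size = 10, budgets = 10,
                           pilot_in_success = FALSE, n_seeds = 30, seed = 3)
  expect_lt(abs(strict$power - 0.10), 0.04)
  expect_error(power_analysis(panel, true_ic50, budgets = 0), "budgets")
})

test_that("ablation flags a duplicated study and not an independent one", {
  set.seed(21)
  # target study with drug-dose structure a duplicate donor shares exactly
  base <- expand.grid(sample_id = paste0("p", 1:6),
                      drug_id = paste0("d", 1:10),
                      concentration_uM = c(0.1, 1, 10),
                      stringsAsFactors = FALSE)
  drug_eff <- setNames(runif(10, 0.2, 0.9), paste0("d", 1:10))
  base$viability <- drug_eff[base$drug_id] +
    0.05 * rnorm(nrow(base))
  tgt <- cbind(study_id = "target", base)
  dup <- cbind(study_id = "twin", base)
  dup$sample_id <- paste0("twin_", dup$sample_id)
  ind <- cbind(study_id = "independent", base)
  ind$sample_id <- paste0("ind_", ind$sample_id)
  ind$drug_id <- paste0("x", ind$drug_id)       # disjoint drugs
  ind$viability <- runif(nrow(ind))             # independent truth
  ds <- screen_dataset(rbind(tgt, dup, ind))

  # cheap factory: per (drug, dose) training mean with fallbacks
  factory <- function(train_ds) {
    train <- train_ds$records
    function(records) baseline_predict("bucket_mean", train, records)
  }
  am <- ablation_matrix(ds, factory, n_folds = 2, seed = 1)
  expect_false(any(am$donor == am$target))      # diagonal excluded
  twin_cell <- am[am$donor == "twin" & am$target == "target", ]
  ind_cell <- am[am$donor == "independent" & am$target == "target", ]
  expect_lt(twin_cell$p, 0.05)
  expect_gt(ind_cell$p, 0.05)
})

test_that("the CLI simulates, summarizes, and writes manifests", {
  tmp <- withr::local_tempdir()
  status <- run_cli(c("simulate", "--seed", "3", "--out", tmp))
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(tmp, "viability.tsv")))
  expect_true(file.exists(file.path(tmp, "manifest.json")))
  man <- jsonlite::read_json(file.path(tmp, "manifest.json"))
  expect_equal(man$seed, 3)

  out2 <- withr::local_tempdir()
  status2 <- run_cli(c("summary", "--data", file.path(tmp, "viability.tsv"),
                       "--out", out2))
  expect_equal(status2, 0L)
  expect_true(file.exists(file.path(out2, "summary.tsv")))
  expect_equal(run_cli(character(0)), 2L)
  expect_equal(run_cli(c("unknown-cmd", "--seed", "1")), 2L)
})
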