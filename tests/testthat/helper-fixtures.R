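# Shared fixtures, built once per test run and memoized. The heavy fits
# (the default-config dose-response fit and the desk-scale foundation model)
# back several acceptance properties, so they are computed lazily and
# reused.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small 3-study dataset without noise or batch effects, multi-dose only
small_clean_ds <- function(seed = 2) {
  simulate_screens(synth_config(
    n_studies = 3, samples_per_study = 12, n_drugs = 30, n_tissues = 4,
    n_mechanisms = 5, single_dose_studies = integer(0), noise_sd = 0,
    batch_offset_sd = 0, batch_scale_sd = 0, seed = seed))
}

fixture_default_ds <- function() {
  memo("default_ds", function() simulate_screens(synth_config(seed = 1)))
}

# default-config fit with 10% of curves held out, plus imputations
fixture_drm <- function() {
  memo("drm", function() {
    ds <- fixture_default_ds()
    folds <- cv_folds(ds, n_folds = 10, seed = 7)
    train <- ds
    train$records <- ds$records[folds != 1, , drop = FALSE]
    fit <- fit_drm(train, drm_config(n_iter = 300, seed = 1),
                   grids = build_dose_grids(ds, K = 10))
    cs <- impute_curves(fit, n_draws = 30, seed = 2)
    list(ds = ds, folds = folds, fit = fit,
         test = ds$records[folds == 1, , drop = FALSE], cs = cs)
  })
}

fixture_fm <- function() {
  memo("fm", function() {
    ds <- fixture_default_ds()
    fm <- train_fm(ds, fm_config(scale = "desk", n_steps = 400, seed = 3),
                   hold_out_study = "study5")
    list(ds = ds, fm = fm, hold_out = "study5")
  })
}

# brute-force BH step-up, independent of p.adjust
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (r in n:1) {
    prev <- min(prev, p[o[r]] * n / r)
    q[o[r]] <- prev
  }
  pmin(q, 1)
}
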