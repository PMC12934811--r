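#' Assign whole curves to cross-validation folds
#'
#' Folds partition curves — every (study, sample, drug) curve lands in
#' exactly one test fold — optionally stratified.
#'
#' @param ds a `screen_dataset`
#' @param n_folds folds
#' @param stratify_by optional record column to stratify on
#' @param seed RNG seed
#' @return integer fold id per record (same curve -> same fold)
#' @export
cv_folds <- function(ds, n_folds = 5, stratify_by = NULL, seed = 1) {
  keys <- curve_key(ds$records)
  ukeys <- unique(keys)
  set.seed(seed)
  if (is.null(stratify_by)) {
    fold_of <- stats::setNames(rep_len(seq_len(n_folds),
                                       length(ukeys))[sample.int(length(ukeys))],
                               ukeys)
  } else {
    strat <- ds$records[[stratify_by]][match(ukeys, keys)]
    fold_of <- stats::setNames(integer(length(ukeys)), ukeys)
    for (s in unique(strat)) {
      idx <- sample(which(strat == s))
      fold_of[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  }
  unname(fold_of[keys])
}

#' Whole-curve-holdout cross-validation of a dose-response model
#'
#' Trains the supplied model factory on each training fold, predicts the
#' held-out curves' viabilities, and reports Pearson/Spearman/RMSE per
#' stratum with BH-corrected two-sided correlation tests. Strata below the
#' minimum size are reported with NA metrics, not dropped.
#'
#' @param ds a `screen_dataset`
#' @param model_factory function(train_ds) returning an object with a
#'   `predict_records(model, records)` method; defaults to the package
#'   dose-response model via `drm_factory(cfg)`
#' @param n_folds folds
#' @param strata named list: stratum label column derivations; default
#'   disease (via annotations) and mechanism
#' @param min_n minimum observations per stratum
#' @param seed RNG seed
#' @return list with `overall` (r, spearman, rmse), `by_stratum`,
#'   `predictions`
#' @export
cv_curve_holdout <- function(ds, model_factory, n_folds = 5, min_n = 3,
                             seed = 1) {
  folds <- cv_folds(ds, n_folds, seed = seed)
  pred <- rep(NA_real_, nrow(ds$records))
  for (f in seq_len(n_folds)) {
    train <- ds
    train$records <- ds$records[folds != f, , drop = FALSE]
    model <- model_factory(train)
    pred[folds == f] <- predict_with(model, ds$records[folds == f, ,
                                                       drop = FALSE])
  }
  obs <- ds$records$viability
  overall <- list(r = cor(pred, obs),
                  spearman = cor(pred, obs, method = "spearman"),
                  rmse = sqrt(mean((pred - obs)^2)))

  strata <- list()
  if (!is.null(ds$samples))
    strata$disease <- ds$samples$oncotree_code[match(ds$records$sample_id,
                                                     ds$samples$sample_id)]
  if (!is.null(ds$drugs)) {
    fm <- vapply(ds$drugs$mechanisms, function(m)
      if (length(m) > 0) m[[1]] else NA_character_, "")
    strata$mechanism <- fm[match(ds$records$drug_id, ds$drugs$drug_id)]
  }
  strata$sample <- ds$records$sample_id

  by_stratum <- list()
  for (sn in names(strata)) {
    lab <- strata[[sn]]
    rows <- lapply(sort(unique(stats::na.omit(lab))), function(lv) {
      idx <- which(lab == lv)
      if (length(idx) < max(min_n, 3))
        return(data.frame(stratum_type = sn, stratum = lv, n = length(idx),
                          r = NA_real_, rmse = NA_real_, p = NA_real_))
      ct <- suppressWarnings(stats::cor.test(pred[idx], obs[idx]))
      data.frame(stratum_type = sn, stratum = lv, n = length(idx),
                 r = unname(ct$estimate),
                 rmse = sqrt(mean((pred[idx] - obs[idx])^2)),
                 p = ct$p.value, stringsAsFactors = FALSE)
    })
    by_stratum[[sn]] <- do.call(rbind, rows)
    ok <- is.finite(by_stratum[[sn]]$p)
    by_stratum[[sn]]$q <- NA_real_
    by_stratum[[sn]]$q[ok] <- bh_adjust(by_stratum[[sn]]$p[ok])
  }
  list(overall = overall, by_stratum = by_stratum,
       predictions = data.frame(ds$records, predicted = pred, fold = folds))
}

# model factories may return either a fitted drm or a plain prediction
# closure records -> predictions
predict_with <- function(model, records) {
  if (is.function(model)) model(records) else predict_records(model, records)
}

#' Dose-response model factory for benchmarking
#'
#' @param cfg a [drm_config()]
#' @return function(train_ds) -> `drm_fit`
#' @export
drm_factory <- function(cfg = drm_config()) {
  function(train_ds) fit_drm(train_ds, cfg)
}

#' Predict observed records from a fitted dose-response model
#'
#' Posterior-mean predictions at the records' concentrations (mean
#' embeddings; monotone interpolation on the drug grids). Unknown samples or
#' drugs yield NA.
#'
#' @param model a `drm_fit`
#' @param records data.frame with sample_id, drug_id, concentration_uM
#' @return numeric predictions
#' @export
predict_records <- function(model, records) {
  dat <- model$data
  i <- match(records$sample_id, dat$sample_ids)
  j <- match(records$drug_id, dat$drug_ids)
  ok <- !is.na(i) & !is.na(j)
  out <- rep(NA_real_, nrow(records))
  if (!any(ok)) return(out)
  K <- model$cfg$K
  pdat <- list(pi_ = i[ok], pj = j[ok], n_pairs = sum(ok), K = K)
  M <- pair_grid_viabilities(model$params$Vm, model$params$Um, pdat)
  lc <- log10(records$concentration_uM[ok])
  v <- numeric(sum(ok))
  for (r in seq_len(sum(ok))) {
    g <- model$grids[[dat$drug_ids[j[ok][r]]]]
    v[r] <- interp_grid_values(M[r, ], g, lc[r])
  }
  out[ok] <- v
  out
}

#' Donor-to-target study ablation matrix
#'
#' For each target study, runs whole-drug-holdout cross-validation within
#' the target (all of a drug's target-study curves held out per fold),
#' trained with versus without each donor study, and tests per-curve RMSE
#' improvement with a one-sided binomial test; BH across cells; the
#' diagonal is excluded.
#'
#' @param ds a `screen_dataset` with >= 2 studies
#' @param model_factory function(train_ds) -> model for [predict_records()]
#' @param n_folds drug folds within the target study
#' @param seed RNG seed
#' @return data.frame (donor, target, frac_improved, n_curves, p, q)
#' @export
ablation_matrix <- function(ds, model_factory, n_folds = 3, seed = 1) {
  studies <- sort(unique(ds$records$study_id))
  if (length(studies) < 2) stop("ablation requires >= 2 studies")

  curve_rmse <- function(records, pred) {
    key <- curve_key(records)
    vapply(split(seq_along(key), key), function(idx)
      sqrt(mean((pred[idx] - records$viability[idx])^2)), 0)
  }

  rows <- list()
  for (target in studies) {
    t_rec <- ds$records$study_id == target
    drugs_t <- sort(unique(ds$records$drug_id[t_rec]))
    set.seed(seed)
    drug_fold <- stats::setNames(rep_len(seq_len(n_folds),
                                         length(drugs_t))[sample.int(length(drugs_t))],
                                 drugs_t)
    heldout_rmse <- function(train_studies) {
      per_curve <- list()
      for (f in seq_len(n_folds)) {
        ho_drugs <- names(drug_fold)[drug_fold == f]
        test_idx <- t_rec & ds$records$drug_id %in% ho_drugs
        train <- ds
        train$records <- ds$records[
          ds$records$study_id %in% train_studies &
            !(t_rec & ds$records$drug_id %in% ho_drugs), , drop = FALSE]
        model <- model_factory(train)
        test <- ds$records[test_idx, , drop = FALSE]
        pred <- predict_with(model, test)
        keep <- is.finite(pred)
        per_curve[[f]] <- curve_rmse(test[keep, , drop = FALSE], pred[keep])
      }
      unlist(per_curve)
    }
    with_all <- heldout_rmse(studies)
    for (donor in setdiff(studies, target)) {
      without <- heldout_rmse(setdiff(studies, donor))
      common <- intersect(names(with_all), names(without))
      if (length(common) == 0) next
      improved <- with_all[common] < without[common]
      bt <- binom.test(sum(improved), length(improved), p = 0.5,
                       alternative = "greater")
      rows[[length(rows) + 1L]] <- data.frame(
        donor = donor, target = target,
        frac_improved = mean(improved), n_curves = length(improved),
        p = bt$p.value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out
}

#' Virtual-screen power analysis
#'
#' Each held-out sample receives a random pilot of `pilot_size` drugs; the
#' remaining panel is ranked (by predicted IC50, ties broken by lower AUC
#' then drug id), and a run succeeds if the panel's true lowest-IC50 drug is
#' in the pilot or among the top `budget` ranked drugs. Power is the success
#' fraction over samples and seeds; it is monotone non-decreasing in budget
#' by construction.
#'
#' @param panel character vector of drug ids
#' @param true_ic50 named per-drug true log10 IC50 for each sample: a
#'   samples x drugs matrix
#' @param rank_fn function(sample_id, pilot_records) returning a data.frame
#'   (drug_id, ic50_log10, auc) for unscreened drugs; see
#'   [drm_power_ranker()]. Use `"oracle"` or `"random"` for the analytic
#'   reference modes.
#' @param pilot_size pilot drugs per sample
#' @param budgets follow-up budgets to evaluate
#' @param pilot_in_success if FALSE, a top hit inside the pilot does not
#'   count (strict mode)
#' @param n_seeds pilot resampling repeats
#' @param seed base RNG seed
#' @return data.frame (pilot_size, budget, power)
#' @export
power_analysis <- function(panel, true_ic50, rank_fn = "random",
                           pilot_size = 10, budgets = 1:50,
                           pilot_in_success = TRUE, n_seeds = 5, seed = 1) {
  if (any(budgets < 1)) stop("budgets must be >= 1")
  samples <- rownames(true_ic50)
  hit_of <- apply(true_ic50[, panel, drop = FALSE], 1, function(v)
    panel[order(v, panel)][1])
  succ <- array(0, dim = c(length(samples), length(budgets)))
  runs <- 0L
  for (sd_i in seq_len(n_seeds)) {
    set.seed(seed + sd_i)
    for (si in seq_along(samples)) {
      pilot <- sample(panel, pilot_size)
      rest <- setdiff(panel, pilot)
      ranked <- if (identical(rank_fn, "random")) {
        sample(rest)
      } else if (identical(rank_fn, "oracle")) {
        rest[order(true_ic50[samples[si], rest], rest)]
      } else {
        rk <- rank_fn(samples[si], pilot)
        rk <- rk[rk$drug_id %in% rest, , drop = FALSE]
        rk$drug_id[order(rk$ic50_log10, rk$auc, rk$drug_id)]
      }
      hit <- hit_of[samples[si]]
      in_pilot <- pilot_in_success && hit %in% pilot
      for (bi in seq_along(budgets)) {
        found <- in_pilot || hit %in% head(ranked, budgets[bi])
        succ[si, bi] <- succ[si, bi] + found
      }
    }
    runs <- runs + 1L
  }
  data.frame(pilot_size = pilot_size, budget = budgets,
             power = colSums(succ) / (length(samples) * runs))
}

#' Ranker for [power_analysis()] backed by the dose-response model
#'
#' Embeds the pilot screen with [embed_new_sample()] and returns predicted
#' IC50/AUC for the unscreened drugs.
#'
#' @param model a `drm_fit` (trained without the held-out samples)
#' @param pilot_records all records of the held-out samples (pilot subsets
#'   are taken from these)
#' @return function(sample_id, pilot_drugs) -> ranking data.frame
#' @export
drm_power_ranker <- function(model, pilot_records) {
  function(sample_id, pilot_drugs) {
    pr <- pilot_records[pilot_records$sample_id == sample_id &
                          pilot_records$drug_id %in% pilot_drugs, ]
    emb <- embed_new_sample(model, pr)
    imp <- impute_for_embedding(model, emb, n_draws = 8)
    data.frame(drug_id = imp$drug_id, ic50_log10 = imp$ic50_log10,
               auc = imp$auc, stringsAsFactors = FALSE)
  }
}

#' Baseline viability predictors
#'
#' Reference models trained on long-format records with one-hot drug,
#' log10 dose and (where available) study/tissue features:
#' `bucket_mean` (per (drug, dose-bin) training mean with drug-mean then
#' global-mean fallback), `ridge` (closed-form, lambda = 0 reproduces OLS),
#' `tree_ensemble` (ranger random forest), `boosted_trees` (xgboost),
#' `feedforward_net` (single-hidden-layer nnet), and `context_mean` (mean
#' viability of the training records of the same sample).
#'
#' @param kind baseline type
#' @param train,test record data.frames (train has viability)
#' @param annotations optional sample annotations for tissue features
#' @param lambda ridge penalty
#' @param seed RNG seed
#' @return numeric predictions for `test`
#' @export
baseline_predict <- function(kind = c("bucket_mean", "ridge",
                                      "tree_ensemble", "boosted_trees",
                                      "feedforward_net", "context_mean"),
                             train, test, annotations = NULL, lambda = 1,
                             seed = 1) {
  kind <- match.arg(kind)
  if (kind == "bucket_mean") {
    bin <- function(x) round(log10(x), 1)
    bkey <- paste(train$drug_id, bin(train$concentration_uM))
    bmean <- tapply(train$viability, bkey, mean)
    dmean <- tapply(train$viability, train$drug_id, mean)
    gmean <- mean(train$viability)
    tkey <- paste(test$drug_id, bin(test$concentration_uM))
    out <- unname(bmean[tkey])
    out[is.na(out)] <- dmean[test$drug_id[is.na(out)]]
    out[is.na(out)] <- gmean
    return(as.numeric(out))
  }
  if (kind == "context_mean") {
    smean <- tapply(train$viability, train$sample_id, mean)
    out <- unname(smean[test$sample_id])
    out[is.na(out)] <- mean(train$viability)
    return(as.numeric(out))
  }

  enc <- encode_features(rbind(train[, c("study_id", "sample_id", "drug_id",
                                         "concentration_uM")],
                               test[, c("study_id", "sample_id", "drug_id",
                                        "concentration_uM")]),
                         annotations)
  Xtr <- enc[seq_len(nrow(train)), , drop = FALSE]
  Xte <- enc[nrow(train) + seq_len(nrow(test)), , drop = FALSE]
  y <- train$viability

  if (kind == "ridge") {
    Xd <- cbind(1, Xtr)
    if (lambda == 0) {
      # unpenalized limit: least-squares projection (aliased columns dropped)
      beta <- qr.coef(qr(Xd), y)
      beta[is.na(beta)] <- 0
    } else {
      pen <- diag(c(0, rep(lambda, ncol(Xtr))))
      beta <- solve(crossprod(Xd) + pen, crossprod(Xd, y))
    }
    return(as.vector(cbind(1, Xte) %*% beta))
  }
  if (kind == "tree_ensemble") {
    fit <- ranger::ranger(y = y, x = data.frame(Xtr), num.trees = 200,
                          seed = seed)
    return(predict(fit, data.frame(Xte))$predictions)
  }
  if (kind == "boosted_trees") {
    dtr <- xgboost::xgb.DMatrix(Xtr, label = y)
    fit <- xgboost::xgb.train(params = list(max_depth = 4, eta = 0.2,
                                            nthread = 1),
                              data = dtr, nrounds = 60)
    return(as.numeric(predict(fit, xgboost::xgb.DMatrix(Xte))))
  }
  # feedforward_net
  set.seed(seed)
  fit <- nnet::nnet(Xtr, y, size = 8, linout = TRUE, maxit = 200,
                    decay = 1e-3, trace = FALSE, MaxNWts = 100000)
  as.numeric(predict(fit, Xte))
}

encode_features <- function(records, annotations = NULL) {
  drug_f <- factor(records$drug_id)
  study_f <- factor(records$study_id)
  mm <- cbind(stats::model.matrix(~ drug_f - 1),
              stats::model.matrix(~ study_f - 1),
              log_dose = log10(records$concentration_uM))
  if (!is.null(annotations)) {
    tissue <- annotations$primary_site[match(records$sample_id,
                                             annotations$sample_id)]
    if (!all(is.na(tissue)))
      mm <- cbind(mm, stats::model.matrix(~ factor(tissue) - 1))
  }
  mm
}

#' Few-shot benchmark of the foundation model
#'
#' Leave-one-study-out: for the held-out study's samples, draws a random
#' context of each size (seeded per repeat), predicts the remaining
#' measurements, and reports the per-sample Spearman correlation averaged
#' per (model, n_few_shots), with mean and 2 sd over repeats. Baselines:
#' `context_mean` and any supplied prediction functions. Samples with fewer
#' measurements than a context size are evaluated at their maximum feasible
#' size and flagged.
#'
#' @param ds a `screen_dataset`
#' @param fm a trained `fm_model` (hold-out study excluded from training)
#' @param hold_out_study the evaluation study id
#' @param n_few_shots context sizes
#' @param repeats random repeats
#' @param finetune_epochs if > 0, also evaluates FM++ fine-tuned per sample
#' @param max_samples cap on evaluated samples per repeat
#' @param seed base RNG seed
#' @return data.frame (model, n_few_shots, repeat_id, spearman, flagged)
#'   plus a summary attribute
#' @export
fm_fewshot_benchmark <- function(ds, fm, hold_out_study,
                                 n_few_shots = c(10, 50, 100, 200),
                                 repeats = 5, finetune_epochs = 0,
                                 max_samples = Inf, seed = 1) {
  r <- ds$records[ds$records$study_id == hold_out_study, ]
  samples <- unique(r$sample_id)
  rows <- list()
  for (rep_i in seq_len(repeats)) {
    set.seed(seed + rep_i)
    eval_samples <- if (length(samples) > max_samples)
      sample(samples, max_samples) else samples
    for (n in n_few_shots) {
      sp_fm <- sp_cm <- sp_ft <- numeric(0)
      flagged <- FALSE
      for (sid in eval_samples) {
        sr <- r[r$sample_id == sid, ]
        n_eff <- min(n, nrow(sr) - 2)
        if (n_eff < 1) next
        if (n_eff < n) flagged <- TRUE
        idx <- sample(seq_len(nrow(sr)), n_eff)
        ctx <- sr[idx, c("drug_id", "concentration_uM", "viability")]
        qry <- sr[-idx, , drop = FALSE]
        pred <- suppressWarnings(
          predict_query(fm, ctx, qry[, c("drug_id", "concentration_uM")]))
        sp_fm <- c(sp_fm, suppressWarnings(
          cor(pred, qry$viability, method = "spearman")))
        sp_cm <- c(sp_cm, 0)  # constant context-mean prediction: rho = 0
        if (finetune_epochs > 0) {
          fmpp <- finetune(fm, ctx, n_epochs = finetune_epochs,
                           seed = seed + rep_i)
          predf <- suppressWarnings(
            predict_query(fmpp, ctx, qry[, c("drug_id", "concentration_uM")]))
          sp_ft <- c(sp_ft, suppressWarnings(
            cor(predf, qry$viability, method = "spearman")))
        }
      }
      add <- function(model, v) data.frame(
        model = model, n_few_shots = n, repeat_id = rep_i,
        spearman = mean(v, na.rm = TRUE), flagged = flagged,
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- add("FM", sp_fm)
      rows[[length(rows) + 1L]] <- add("context_mean", sp_cm)
      if (finetune_epochs > 0)
        rows[[length(rows) + 1L]] <- add("FM++", sp_ft)
    }
  }
  out <- do.call(rbind, rows)
  summ <- aggregate(spearman ~ model + n_few_shots, out, function(v)
    c(mean = mean(v), two_sd = 2 * sd(v)))
  attr(out, "summary") <- summ
  out
}
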