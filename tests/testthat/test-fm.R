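tiny_fm <- function(n_steps = 30, seed = 2, ds = NULL) {
  if (is.null(ds))
    ds <- simulate_screens(synth_config(n_studies = 2, samples_per_study = 4,
                                        n_drugs = 12,
                                        single_dose_studies = integer(0),
                                        seed = 11))
  train_fm(ds, fm_config(scale = "desk", n_steps = n_steps,
                         context_range = c(4, 10), seed = seed))
}

test_that("Fourier scalar embeddings are deterministic and discriminate doses", {
  set.seed(1)
  Fq <- 16; S <- 32
  freq <- matrix(exp(seq(log(0.2), log(8), length.out = Fq)))
  phase <- matrix(0, Fq, 1)
  proj <- matrix(rnorm(2 * Fq * S, 0, 0.1), 2 * Fq, S)
  bias <- matrix(0, 1, S)
  e1 <- fourier_embed(c(0.5, 0.5), freq, phase, proj, bias)
  expect_equal(ncol(e1), S)
  expect_equal(e1[1, ], e1[2, ])
  e2 <- fourier_embed(c(-1, 1), freq, phase, proj, bias)
  expect_gt(sqrt(sum((e2[1, ] - e2[2, ])^2)), 0)
  expect_error(fourier_embed(NA_real_, freq, phase, proj, bias),
               "non-finite")
})

test_that("tokens concatenate three sub-embeddings; queries share one placeholder", {
  fm <- tiny_fm()
  ctx <- data.frame(drug_id = fm$drug_vocab[1:3],
                    concentration_uM = c(0.1, 1, 10),
                    viability = c(0.9, 0.5, 0.2))
  qry <- data.frame(drug_id = fm$drug_vocab[c(1, 1)],
                    concentration_uM = c(1, 1))
  tok <- tokenize(fm, ctx, qry)
  expect_equal(ncol(tok$context), fm$cfg$hidden)
  expect_equal(ncol(tok$queries), fm$cfg$hidden)
  expect_equal(tok$queries[1, ], tok$queries[2, ])  # identical (drug, dose)
  S <- fm$cfg$sub_embedding
  expect_equal(unname(tok$queries[1, (2 * S + 1):(3 * S)]),
               as.vector(fm$params$via_placeholder))
  expect_warning(tokenize(fm, ctx,
                          data.frame(drug_id = "never_seen",
                                     concentration_uM = 1)),
                 "out-of-vocabulary")
})

test_that("query predictions are permutation-invariant, bounded and counted", {
  fm <- tiny_fm()
  ctx <- data.frame(drug_id = rep(fm$drug_vocab[1:4], 2),
                    concentration_uM = rep(c(0.1, 1), each = 4),
                    viability = runif(8))
  qry <- data.frame(drug_id = fm$drug_vocab[5:7],
                    concentration_uM = c(0.5, 1, 2))
  p <- predict_query(fm, ctx, qry)
  expect_length(p, 3)
  expect_true(all(p >= 0 & p <= 2))
  set.seed(3)
  p2 <- predict_query(fm, ctx[sample(nrow(ctx)), ], qry)
  expect_equal(p, p2, tolerance = 1e-6)
  p3 <- predict_query(fm, ctx, qry[c(3, 1, 2), ])
  expect_equal(p3, p[c(3, 1, 2)], tolerance = 1e-6)

  expect_length(predict_query(fm, ctx, qry[0, ]), 0)
  p_empty <- predict_query(fm, ctx[0, ], qry)
  expect_true(isTRUE(attr(p_empty, "empty_context")))
  expect_length(p_empty, 3)
})

test_that("training is seed-deterministic, decreases loss, and respects holdout", {
  ds <- simulate_screens(synth_config(n_studies = 3, samples_per_study = 4,
                                      n_drugs = 15,
                                      single_dose_studies = integer(0),
                                      seed = 12))
  fm1 <- train_fm(ds, fm_config(scale = "desk", n_steps = 25,
                                context_range = c(4, 10), seed = 5))
  fm2 <- train_fm(ds, fm_config(scale = "desk", n_steps = 25,
                                context_range = c(4, 10), seed = 5))
  expect_identical(fm1$params, fm2$params)

  fm3 <- train_fm(ds, fm_config(scale = "desk", n_steps = 150,
                                context_range = c(4, 10), seed = 5),
                  hold_out_study = "study3")
  tr <- fm3$loss_trace
  expect_lt(mean(tail(tr, 30)), mean(head(tr, 30)))
  expect_equal(fm3$excluded_study, "study3")
  # vocabulary only contains drugs from training studies
  train_drugs <- unique(ds$records$drug_id[ds$records$study_id != "study3"])
  expect_true(all(fm3$drug_vocab %in% train_drugs))
})

test_that("fine-tuning adapts a copy and zero epochs is the identity", {
  fm <- tiny_fm(n_steps = 80)
  # a context violating the training distribution: shifted viabilities
  ctx <- data.frame(drug_id = rep(fm$drug_vocab[1:5], each = 4),
                    concentration_uM = rep(c(0.05, 0.5, 5, 50), 5),
                    viability = rep(1.8, 20))
  qry <- ctx[, c("drug_id", "concentration_uM")]
  p_static <- predict_query(fm, ctx, qry)
  before <- fm$params
  fm0 <- finetune(fm, ctx, n_epochs = 0)
  expect_identical(predict_query(fm0, ctx, qry), p_static)
  fmpp <- finetune(fm, ctx, n_epochs = 15, lr = 1e-3, seed = 4)
  expect_identical(fm$params, before)  # original untouched
  p_ft <- predict_query(fmpp, ctx, qry)
  mse <- function(p) mean((p - ctx$viability)^2)
  expect_lt(mse(p_ft), mse(p_static))
  expect_error(finetune(fm, ctx[0, ]), "empty few-shot")
})

test_that("sample embeddings are pooled, invariant, and sized to the hidden width", {
  fm <- tiny_fm()
  ctx <- data.frame(drug_id = fm$drug_vocab[1:6],
                    concentration_uM = 10^seq(-2, 1, length.out = 6),
                    viability = seq(1, 0.3, length.out = 6))
  e <- extract_sample_embedding(fm, ctx)
  expect_length(e, fm$cfg$hidden)
  set.seed(2)
  e2 <- extract_sample_embedding(fm, ctx[sample(6), ])
  expect_equal(e, e2, tolerance = 1e-10)
  expect_identical(e, extract_sample_embedding(fm, ctx))
  expect_error(extract_sample_embedding(fm, ctx[0, ]), "empty context")
})

test_that("the paper-scale configuration yields 384-dimensional tokens", {
  cfg <- fm_config(scale = "paper")
  expect_equal(cfg$hidden, 384)
  expect_equal(cfg$sub_embedding, 128)
  expect_equal(cfg$n_blocks, 8)
  expect_equal(cfg$intermediate, 512)
  expect_equal(cfg$n_heads, 8)
  expect_error(fm_config(hidden = 100), "3 \\* sub_embedding")
})
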