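test_that("curve_from_embeddings matches a hand-computed cumulative sigmoid", {
  d <- 4; K <- 3
  v <- rep(0, d); u <- matrix(0, K, d)
  expect_equal(curve_from_embeddings(v, u, c(-1, 0, 1), c(-1, 0, 1)),
               c(0.5, 0.25, 0.125), tolerance = 1e-10)

  # independent oracle: explicit products of logistic retention fractions
  set.seed(21)
  v <- rnorm(d); u <- matrix(rnorm(K * d), K, d)
  a <- u %*% v
  expected <- cumprod(1 / (1 + exp(-a)))
  got <- curve_from_embeddings(v, u, c(-2, 0, 2), c(-2, 0, 2))
  expect_equal(got, as.vector(expected), tolerance = 1e-10)

  # saturation
  u_hi <- matrix(20 / d, K, d)
  expect_equal(curve_from_embeddings(rep(1, d), u_hi, c(-1, 0, 1),
                                     c(-1, 0, 1)),
               rep(1, 3), tolerance = 1e-8)
  expect_error(curve_from_embeddings(rep(0, 3), u, c(0), c(-2, 0, 2)),
               "dimension mismatch")
})

test_that("interpolation is linear in log-concentration and clamps beyond the grid", {
  # build embeddings whose grid viabilities are 0.8 and 0.4
  d <- 1; K <- 2
  a1 <- qlogis(0.8); a2 <- qlogis(0.4 / 0.8)
  u <- matrix(c(a1, a2), 2, 1); v <- 1
  mid <- curve_from_embeddings(v, u, 0.5, c(0, 1))
  expect_equal(mid, 0.6, tolerance = 1e-10)
  ends <- curve_from_embeddings(v, u, c(-5, 5), c(0, 1))
  expect_equal(ends, c(0.8, 0.4), tolerance = 1e-10)
})

test_that("contrastive penalty matches its closed form and rewards tight groups", {
  # all embeddings identical: per-anchor penalty log(n-1) - log(n_pos)
  n <- 6
  X <- matrix(rep(c(1, 2), each = n / 2), n, 2)
  X[] <- 1
  lab <- rep(c("a", "b"), each = 3)
  p <- contrastive_penalty(X, lab, temperature = 1)
  expect_equal(as.numeric(p), log(n - 1) - log(2), tolerance = 1e-10)

  # orthogonal tight groups beat a perturbed layout
  A <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  labs <- c("g1", "g1", "g2", "g2")
  tight <- as.numeric(contrastive_penalty(A, labs, temperature = 1))
  B <- A; B[2, ] <- c(0.6, 0.8)  # rotate one member toward the other group
  expect_lt(tight, as.numeric(contrastive_penalty(B, labs, temperature = 1)))

  expect_warning(p0 <- contrastive_penalty(A, rep("g", 4)), "single group")
  expect_equal(as.numeric(p0), 0)
})

test_that("contrastive penalty gradient agrees with finite differences", {
  set.seed(5)
  X <- matrix(rnorm(12), 6, 2)
  lab <- rep(c("a", "b", "c"), each = 2)
  p <- contrastive_penalty(X, lab, temperature = 0.7, with_grad = TRUE)
  G <- attr(p, "grad")
  eps <- 1e-6
  for (idx in c(1, 5, 9)) {
    Xp <- X; Xp[idx] <- Xp[idx] + eps
    Xm <- X; Xm[idx] <- Xm[idx] - eps
    num <- (as.numeric(contrastive_penalty(Xp, lab, 0.7)) -
              as.numeric(contrastive_penalty(Xm, lab, 0.7))) / (2 * eps)
    expect_equal(G[idx], num, tolerance = 1e-5)
  }
})

test_that("fitting a clean fixture reaches low error, deterministically", {
  ds <- small_clean_ds()
  cfg <- drm_config(d = 8, K = 6, lambda_sample = 0, lambda_drug = 0,
                    seed = 1)
  fit <- fit_drm(ds, cfg)
  pred <- predict_records(fit, ds$records)
  expect_lt(sqrt(mean((pred - ds$records$viability)^2)), 0.05)

  fit2 <- fit_drm(ds, cfg)
  expect_identical(fit$params, fit2$params)

  # moving-average training loss decreases
  tr <- -fit$elbo_trace   # loss scale
  expect_lt(mean(tail(tr, 50)), mean(head(tr, 50)))
})

test_that("the sample contrastive penalty tightens within-tissue embeddings", {
  ds <- small_clean_ds(seed = 3)
  base <- fit_drm(ds, drm_config(d = 8, K = 6, n_iter = 250,
                                 lambda_sample = 0, lambda_drug = 0,
                                 seed = 1))
  reg <- fit_drm(ds, drm_config(d = 8, K = 6, n_iter = 250,
                                lambda_sample = 0.5, lambda_drug = 0,
                                seed = 1))
  within_cos <- function(fit) {
    V <- drm_embeddings(fit)$samples
    lab <- ds$samples$primary_site[match(rownames(V), ds$samples$sample_id)]
    Z <- V / sqrt(rowSums(V^2))
    S <- Z %*% t(Z)
    same <- outer(lab, lab, "==") & upper.tri(S)
    mean(S[same])
  }
  expect_gt(within_cos(reg), within_cos(base))
})

test_that("the ELBO is finite and improves over training", {
  ds <- small_clean_ds(seed = 4)
  early <- fit_drm(ds, drm_config(d = 8, K = 6, n_iter = 5, seed = 1))
  late <- fit_drm(ds, drm_config(d = 8, K = 6, n_iter = 300, seed = 1))
  e_early <- elbo(early, n_mc = 5, seed = 2)
  e_late <- elbo(late, n_mc = 5, seed = 2)
  expect_true(is.finite(e_early) && is.finite(e_late))
  expect_gt(e_late, e_early)
})

test_that("imputation returns monotone draws with bands and flags provenance", {
  ds <- small_clean_ds(seed = 5)
  fit <- fit_drm(ds, drm_config(d = 8, K = 6, n_iter = 200, seed = 1))
  # a mix of observed and never-observed pairs
  obs_pair <- ds$records[1, c("sample_id", "drug_id")]
  all_drugs <- unique(ds$records$drug_id)
  s1 <- obs_pair$sample_id
  unobs_drug <- setdiff(all_drugs,
                        ds$records$drug_id[ds$records$sample_id == s1])[1]
  pairs <- rbind(obs_pair,
                 data.frame(sample_id = s1, drug_id = unobs_drug))
  cs <- impute_curves(fit, pairs = pairs, n_draws = 20, seed = 3)
  expect_equal(cs$source, c("observed_fit", "imputed"))
  cm <- attr(cs, "curve_mean")
  expect_true(all(apply(cm, 1, function(m) all(diff(m) <= 1e-10))))
  expect_true(all(cm > 0 & cm <= 1))
  expect_true(all(attr(cs, "curve_lo") <= attr(cs, "curve_hi") + 1e-12))

  # single-draw band degenerates
  cs1 <- impute_curves(fit, pairs = pairs[1, ], n_draws = 1, seed = 3)
  expect_equal(cs1$auc_lo, cs1$auc_hi)
  expect_equal(cs1$band_width, 0)

  expect_error(impute_curves(fit, pairs = data.frame(sample_id = "ghost",
                                                     drug_id = all_drugs[1])),
               "unknown sample")
})

test_that("a pilot screen recovers a training sample's embedding", {
  ds <- small_clean_ds(seed = 6)
  fit <- fit_drm(ds, drm_config(d = 8, K = 6, n_iter = 300, seed = 1))
  sid <- ds$records$sample_id[1]
  pilot <- ds$records[ds$records$sample_id == sid,
                      c("drug_id", "concentration_uM", "viability")]
  emb <- embed_new_sample(fit, pilot, seed = 2)
  trained <- drm_embeddings(fit)$samples[sid, ]
  cosine <- sum(emb$mean * trained) /
    sqrt(sum(emb$mean^2) * sum(trained^2))
  expect_gte(cosine, 0.9)

  # a one-measurement pilot runs but is less certain than a 20-measurement one
  emb1 <- embed_new_sample(fit, pilot[1, ], seed = 2)
  emb20 <- embed_new_sample(fit, pilot[1:20, ], seed = 2)
  expect_gt(mean(exp(emb1$log_sd)), mean(exp(emb20$log_sd)))

  expect_error(embed_new_sample(fit, pilot[0, ]), "empty pilot")
  bad <- pilot[1, ]; bad$drug_id <- "not_a_drug"
  expect_error(embed_new_sample(fit, bad), "unknown")
})

test_that("models round-trip through save/load with identical predictions", {
  ds <- small_clean_ds(seed = 7)
  fit <- fit_drm(ds, drm_config(d = 6, K = 5, n_iter = 100, seed = 1))
  tmp <- withr::local_tempdir()
  save_model(fit, file.path(tmp, "m"))
  back <- load_model(file.path(tmp, "m"))
  p1 <- predict_records(fit, ds$records[1:50, ])
  p2 <- predict_records(back, ds$records[1:50, ])
  expect_identical(p1, p2)

  expect_error(load_model(tmp), "not a model directory")
  writeLines("{\"format\": \"something-else\"}", file.path(tmp, "m",
                                                           "meta.json"))
  expect_error(load_model(file.path(tmp, "m")), "foreign")
})
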