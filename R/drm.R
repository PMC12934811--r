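#' Dose-response model configuration
#'
#' Settings for the contrastive Bayesian tensor-factorization dose-response
#' model. Each sample carries an embedding v in R^d with a mean-field
#' Gaussian posterior; each drug carries K per-grid-point embeddings
#' u^(1)..u^(K). The latent curve is the cumulative product of retention
#' fractions sigma(u^(k) . v), which is monotone non-increasing by
#' construction.
#'
#' @param d embedding dimension
#' @param K dose-grid points per drug
#' @param tau prior standard deviation of embedding coordinates
#' @param lambda_sample,lambda_drug contrastive penalty weights for samples
#'   (grouped by primary site) and drugs (grouped by first mechanism)
#' @param temperature contrastive softmax temperature
#' @param n_iter optimizer iterations
#' @param lr Adam learning rate
#' @param n_posterior_samples default posterior draws for imputation bands
#' @param single_dose_span grid half-width for single-dose drugs (log10)
#' @param init_sd initial posterior sd
#' @param noise_sd_init initial per-study observation noise sd
#' @param seed RNG seed controlling initialization and reparameterization
#'   draws
#' @return a `drm_config` list
#' @export
drm_config <- function(d = 32, K = 10, tau = 1,
                       lambda_sample = 0.1, lambda_drug = 0.1,
                       temperature = 0.5,
                       n_iter = 600, lr = 0.05,
                       n_posterior_samples = 50,
                       single_dose_span = 1.0,
                       init_sd = 0.1, noise_sd_init = 0.15,
                       seed = 1) {
  stopifnot(d >= 1, K >= 2, lambda_sample >= 0, lambda_drug >= 0,
            n_posterior_samples >= 1)
  cfg <- as.list(environment())
  class(cfg) <- "drm_config"
  cfg
}

#' Evaluate an imputed curve from embeddings
#'
#' Latent grid viabilities follow `m_0 = 1`,
#' `m_k = m_{k-1} * sigma(u^(k) . v)` for k = 1..K (sigma the logistic
#' function); queried concentrations between grid points are linearly
#' interpolated in log10 concentration, and queries beyond the grid clamp to
#' the end values. Output is strictly in (0, 1] and non-increasing.
#'
#' @param v sample embedding, length d
#' @param u K x d matrix of per-grid-point drug embeddings
#' @param query_logconcs log10 concentrations to evaluate
#' @param grid_log10 the K grid log10 concentrations (defaults to the
#'   queries, i.e. queries at grid points)
#' @return viability vector, one value per query
#' @export
curve_from_embeddings <- function(v, u, query_logconcs,
                                  grid_log10 = query_logconcs) {
  if (length(v) != ncol(u)) stop("dimension mismatch between v and u")
  K <- nrow(u)
  if (length(grid_log10) != K) stop("grid length must equal nrow(u)")
  a <- as.vector(u %*% v)
  m <- exp(cumsum(stats::plogis(a, log.p = TRUE)))
  interp_grid_values(m, grid_log10, query_logconcs)
}

# linear interpolation of latent grid values in log10 concentration,
# clamped flat beyond the grid ends
interp_grid_values <- function(m, grid, query) {
  K <- length(grid)
  x <- pmin(pmax(query, grid[1]), grid[K])
  k <- findInterval(x, grid, rightmost.closed = TRUE)
  k <- pmin(pmax(k, 1L), K - 1L)
  w <- (x - grid[k]) / (grid[k + 1L] - grid[k])
  (1 - w) * m[k] + w * m[k + 1L]
}

# ---- internal: data preparation ----------------------------------------

# Flatten a dataset + dose grids into index vectors for vectorized
# likelihood/gradient computation.
prepare_drm_data <- function(ds, grids, K) {
  r <- ds$records
  sample_ids <- sort(unique(r$sample_id))
  drug_ids <- sort(unique(r$drug_id))
  study_ids <- sort(unique(r$study_id))
  i <- match(r$sample_id, sample_ids)
  j <- match(r$drug_id, drug_ids)
  s <- match(r$study_id, study_ids)

  pair_key <- paste(i, j)
  upk <- unique(pair_key)
  pr <- match(pair_key, upk)
  first <- match(upk, pair_key)
  pi_ <- i[first]
  pj <- j[first]

  lc <- log10(r$concentration_uM)
  klo <- integer(nrow(r)); w <- numeric(nrow(r))
  for (jj in seq_along(drug_ids)) {
    g <- grids[[drug_ids[jj]]]
    idx <- which(j == jj)
    x <- pmin(pmax(lc[idx], g[1]), g[K])
    kk <- findInterval(x, g, rightmost.closed = TRUE)
    kk <- pmin(pmax(kk, 1L), K - 1L)
    klo[idx] <- kk
    w[idx] <- (x - g[kk]) / (g[kk + 1L] - g[kk])
  }

  list(sample_ids = sample_ids, drug_ids = drug_ids, study_ids = study_ids,
       y = r$viability, i = i, j = j, s = s, pr = pr,
       pi_ = pi_, pj = pj, n_pairs = length(upk),
       klo = klo, w = w, K = K)
}

# latent grid viabilities for every pair: P x K matrix, given sampled
# embeddings V (n x d) and U ((J*K) x d)
pair_grid_viabilities <- function(V, U, dat) {
  P <- dat$n_pairs; K <- dat$K
  logM <- matrix(0, P, K)
  acc <- numeric(P)
  for (k in seq_len(K)) {
    a <- rowSums(V[dat$pi_, , drop = FALSE] *
                   U[(dat$pj - 1L) * K + k, , drop = FALSE])
    acc <- acc + stats::plogis(a, log.p = TRUE)
    logM[, k] <- acc
  }
  exp(logM)
}

drm_predict_records <- function(V, U, dat) {
  M <- pair_grid_viabilities(V, U, dat)
  lin_lo <- (dat$klo - 1L) * dat$n_pairs + dat$pr
  lin_hi <- dat$klo * dat$n_pairs + dat$pr
  (1 - dat$w) * M[lin_lo] + dat$w * M[lin_hi]
}

# add rowsum(mat by idx) into rows of target
accum_rows <- function(target, idx, mat) {
  rs <- rowsum(mat, idx)
  rows <- as.integer(rownames(rs))
  target[rows, ] <- target[rows, , drop = FALSE] + rs
  target
}

#' Supervised contrastive penalty over embeddings
#'
#' For each anchor with at least one same-group partner, the penalty is
#' `-log( sum_{positives} exp(sim/T) / sum_{all others} exp(sim/T) )` on
#' cosine similarities of the embeddings, averaged over anchors. Entities
#' with missing labels are excluded. Returns 0 with a warning when fewer
#' than two groups have two or more members.
#'
#' @param embeddings n x d matrix
#' @param group_labels length-n labels (NA = excluded)
#' @param temperature softmax temperature T
#' @param with_grad if TRUE, attach the gradient w.r.t. `embeddings` as
#'   attribute `grad`
#' @return scalar penalty
#' @export
contrastive_penalty <- function(embeddings, group_labels, temperature = 0.5,
                                with_grad = FALSE) {
  keep <- !is.na(group_labels)
  X <- embeddings[keep, , drop = FALSE]
  lab <- group_labels[keep]
  n <- nrow(X)
  grp_sizes <- table(lab)
  eligible <- names(grp_sizes)[grp_sizes >= 2]
  if (length(eligible) < 2 || n < 3) {
    if (length(eligible) <= 1) warning("contrastive penalty undefined for a single group; returning 0")
    out <- 0
    if (with_grad) attr(out, "grad") <- matrix(0, nrow(embeddings),
                                               ncol(embeddings))
    return(out)
  }
  norms <- sqrt(rowSums(X^2))
  norms[norms < 1e-12] <- 1e-12
  Z <- X / norms
  S <- Z %*% t(Z)
  E <- exp(S / temperature)
  diag(E) <- 0
  pos <- outer(lab, lab, "==")
  diag(pos) <- FALSE
  anchors <- which(rowSums(pos) > 0)
  Npos <- rowSums(E * pos)
  D <- rowSums(E)
  loss <- mean(-(log(Npos[anchors]) - log(D[anchors])))
  out <- loss
  if (with_grad) {
    W <- matrix(0, n, n)
    a <- anchors
    W[a, ] <- (E[a, , drop = FALSE] / D[a]) -
      (E[a, , drop = FALSE] * pos[a, , drop = FALSE]) / Npos[a]
    W <- W / (temperature * length(anchors))
    dZ <- (W + t(W)) %*% Z
    dX <- (dZ - Z * rowSums(dZ * Z)) / norms
    G <- matrix(0, nrow(embeddings), ncol(embeddings))
    G[keep, ] <- dX
    attr(out, "grad") <- G
  }
  out
}

# ---- Adam --------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- fitting -----------------------------------------------------------

#' Fit the contrastive Bayesian dose-response model
#'
#' Minimizes the negative evidence lower bound (Gaussian likelihood with
#' learned per-study noise, factorized Gaussian posteriors with N(0, tau^2)
#' priors, one reparameterized draw per step) plus the weighted contrastive
#' penalties on posterior means: samples grouped by primary tissue site and
#' drugs (concatenated grid embeddings) grouped by first-listed mechanism.
#' Deterministic given `cfg$seed`.
#'
#' @param ds a `screen_dataset` with sample and drug annotations
#' @param cfg a [drm_config()]
#' @param grids optional precomputed dose grids (see [build_dose_grids()])
#' @return a `drm_fit` object with posterior means/sds, noise sds, grids,
#'   labels, ELBO trace and the prepared training data
#' @export
fit_drm <- function(ds, cfg = drm_config(), grids = NULL) {
  if (is.null(grids))
    grids <- build_dose_grids(ds, K = cfg$K, single_dose_span = cfg$single_dose_span)
  dat <- prepare_drm_data(ds, grids, cfg$K)
  n <- length(dat$sample_ids); J <- length(dat$drug_ids)
  d <- cfg$d; K <- cfg$K
  N <- length(dat$y)

  site_lab <- drug_lab <- NULL
  if (!is.null(ds$samples))
    site_lab <- ds$samples$primary_site[match(dat$sample_ids,
                                              ds$samples$sample_id)]
  if (!is.null(ds$drugs)) {
    first_mech <- vapply(ds$drugs$mechanisms, function(m)
      if (length(m) > 0) m[[1]] else NA_character_, "")
    drug_lab <- first_mech[match(dat$drug_ids, ds$drugs$drug_id)]
  }

  set.seed(cfg$seed)
  params <- list(
    Vm = matrix(rnorm(n * d, 0, 0.05), n, d),
    Vls = matrix(log(cfg$init_sd), n, d),
    Um = matrix(rnorm(J * K * d, 0, 0.05), J * K, d),
    Uls = matrix(log(cfg$init_sd), J * K, d),
    log_noise = matrix(log(cfg$noise_sd_init), length(dat$study_ids), 1))

  state <- adam_init(params)
  trace <- numeric(cfg$n_iter)
  rec_s <- dat$s
  tau2 <- cfg$tau^2

  for (it in seq_len(cfg$n_iter)) {
    Vs <- exp(params$Vls); Us <- exp(params$Uls)
    epsV <- matrix(rnorm(n * d), n, d)
    epsU <- matrix(rnorm(J * K * d), J * K, d)
    V <- params$Vm + Vs * epsV
    U <- params$Um + Us * epsU

    M <- pair_grid_viabilities(V, U, dat)
    lin_lo <- (dat$klo - 1L) * dat$n_pairs + dat$pr
    lin_hi <- dat$klo * dat$n_pairs + dat$pr
    pred <- (1 - dat$w) * M[lin_lo] + dat$w * M[lin_hi]

    sig <- exp(params$log_noise[rec_s, 1])
    resid <- pred - dat$y
    nll <- sum(log(sig) + resid^2 / (2 * sig^2))
    kl <- sum(kl_gauss(params$Vm, Vs, tau2)) +
      sum(kl_gauss(params$Um, Us, tau2))
    loss <- nll + kl

    dpred <- resid / sig^2
    # scatter onto the pair grid
    li <- c(lin_lo, lin_hi)
    vals <- c((1 - dat$w) * dpred, dat$w * dpred)
    dM <- matrix(0, dat$n_pairs, K)
    acc <- rowsum(vals, li)
    dM[as.integer(rownames(acc))] <- acc
    # reverse-cumulate: dA[,l] = (1 - sigma_l) * sum_{g >= l} dM[,g] M[,g]
    C <- dM * M
    for (k in (K - 1):1) C[, k] <- C[, k] + C[, k + 1]

    gV <- matrix(0, n, d)
    gU <- matrix(0, J * K, d)
    for (k in seq_len(K)) {
      urows <- (dat$pj - 1L) * K + k
      a_k <- rowSums(V[dat$pi_, , drop = FALSE] * U[urows, , drop = FALSE])
      Gk <- C[, k] * (1 - stats::plogis(a_k))
      gV <- accum_rows(gV, dat$pi_, Gk * U[urows, , drop = FALSE])
      gU <- accum_rows(gU, urows, Gk * V[dat$pi_, , drop = FALSE])
    }

    grads <- list(
      Vm = gV + params$Vm / tau2,
      Vls = gV * epsV * Vs + (Vs^2 / tau2 - 1),
      Um = gU + params$Um / tau2,
      Uls = gU * epsU * Us + (Us^2 / tau2 - 1),
      log_noise = as.matrix(rowsum(1 - resid^2 / sig^2, rec_s)))

    # penalties are per-anchor averages while the likelihood is a sum over
    # N observations; scale by N so lambda has a data-independent meaning
    cp_s <- cp_d <- 0
    if (cfg$lambda_sample > 0 && !is.null(site_lab)) {
      cp <- suppressWarnings(contrastive_penalty(params$Vm, site_lab,
                                                 cfg$temperature,
                                                 with_grad = TRUE))
      cp_s <- as.numeric(cp)
      grads$Vm <- grads$Vm + cfg$lambda_sample * N * attr(cp, "grad")
    }
    if (cfg$lambda_drug > 0 && !is.null(drug_lab)) {
      Uconcat <- matrix(t(params$Um), nrow = J, byrow = TRUE)  # J x (K*d)
      cp <- suppressWarnings(contrastive_penalty(Uconcat, drug_lab,
                                                 cfg$temperature,
                                                 with_grad = TRUE))
      cp_d <- as.numeric(cp)
      gcat <- attr(cp, "grad")  # J x (K*d)
      grads$Um <- grads$Um +
        cfg$lambda_drug * N * matrix(t(gcat), nrow = J * K, byrow = FALSE,
                                     ncol = d)
    }
    loss <- loss + N * (cfg$lambda_sample * cp_s + cfg$lambda_drug * cp_d)

    if (!is.finite(loss)) {
      bad <- names(which(!vapply(params, function(p) all(is.finite(p)), TRUE)))
      stop("non-finite training loss at iteration ", it,
           if (length(bad)) paste0(" (parameter block: ",
                                   paste(bad, collapse = ", "), ")"))
    }
    trace[it] <- -loss  # ELBO minus penalties, up to additive constant

    lr <- cfg$lr * if (it > 0.75 * cfg$n_iter) 0.2 else 1
    st <- adam_step(params, grads, state, lr)
    params <- st$params; state <- st$state
  }

  structure(list(cfg = cfg, params = params, grids = grids,
                 data = dat, site_labels = site_lab, drug_labels = drug_lab,
                 elbo_trace = trace, version = "1.0"),
            class = "drm_fit")
}

kl_gauss <- function(m, s, tau2) {
  0.5 * ((s^2 + m^2) / tau2 - 1 - log(s^2 / tau2))
}

#' @export
print.drm_fit <- function(x, ...) {
  cat("drm_fit:", length(x$data$sample_ids), "samples x",
      length(x$data$drug_ids), "drugs, d =", x$cfg$d, ", K =", x$cfg$K, "\n")
  cat("final ELBO (up to const):", tail(x$elbo_trace, 1), "\n")
  invisible(x)
}

#' Monte-Carlo evidence lower bound of a fitted model
#'
#' Gaussian log-likelihood of the training observations around sampled
#' curves with per-study noise, minus the closed-form KL of the factorized
#' Gaussian posteriors from the N(0, tau^2) prior.
#'
#' @param model a `drm_fit`
#' @param n_mc Monte-Carlo samples
#' @param seed RNG seed
#' @return scalar ELBO estimate
#' @export
elbo <- function(model, n_mc = 10, seed = 1) {
  p <- model$params; dat <- model$data
  tau2 <- model$cfg$tau^2
  set.seed(seed)
  Vs <- exp(p$Vls); Us <- exp(p$Uls)
  sig <- exp(p$log_noise[dat$s, 1])
  ll <- 0
  for (m in seq_len(n_mc)) {
    V <- p$Vm + Vs * matrix(rnorm(length(Vs)), nrow(Vs))
    U <- p$Um + Us * matrix(rnorm(length(Us)), nrow(Us))
    pred <- drm_predict_records(V, U, dat)
    ll <- ll + sum(stats::dnorm(dat$y, pred, sig, log = TRUE))
  }
  ll <- ll / n_mc
  kl <- sum(kl_gauss(p$Vm, Vs, tau2)) + sum(kl_gauss(p$Um, Us, tau2))
  out <- ll - kl
  if (!is.finite(out)) stop("non-finite ELBO (check noise and embedding blocks)")
  out
}

# draw posterior embeddings; returns list(V, U)
draw_posterior <- function(params) {
  Vs <- exp(params$Vls); Us <- exp(params$Uls)
  list(V = params$Vm + Vs * matrix(rnorm(length(Vs)), nrow(Vs)),
       U = params$Um + Us * matrix(rnorm(length(Us)), nrow(Us)))
}

#' Impute monotone dose-response curves with uncertainty
#'
#' For each requested (sample, drug) pair — observed or not — draws
#' `n_draws` embedding samples from the posterior, evaluates the cumulative-
#' sigmoid curve on the drug's dose grid (every draw individually monotone
#' non-increasing), and summarizes the posterior mean curve, a pointwise
#' central 90% band, and the normalized AUC with its band.
#'
#' @param model a `drm_fit`
#' @param sample_ids,drug_ids ids known to the model; all pairs of the cross
#'   product are imputed unless `pairs` is given
#' @param pairs optional data.frame(sample_id, drug_id)
#' @param n_draws posterior draws
#' @param seed RNG seed
#' @return a data.frame (class `curve_summary`) with per-pair auc, auc_lo,
#'   auc_hi, ic50_log10, ic50_censored, band_width, source; grid curves in
#'   attributes `curve_mean`, `curve_lo`, `curve_hi`, `grids`
#' @export
impute_curves <- function(model, sample_ids = NULL, drug_ids = NULL,
                          pairs = NULL,
                          n_draws = model$cfg$n_posterior_samples,
                          seed = 1) {
  dat <- model$data
  if (is.null(pairs)) {
    if (is.null(sample_ids)) sample_ids <- dat$sample_ids
    if (is.null(drug_ids)) drug_ids <- dat$drug_ids
    pairs <- expand.grid(sample_id = sample_ids, drug_id = drug_ids,
                         stringsAsFactors = FALSE)
  }
  i <- match(pairs$sample_id, dat$sample_ids)
  j <- match(pairs$drug_id, dat$drug_ids)
  if (anyNA(i)) stop("unknown sample id(s): ",
                     paste(head(unique(pairs$sample_id[is.na(i)]), 3), collapse = ", "))
  if (anyNA(j)) stop("unknown drug id(s): ",
                     paste(head(unique(pairs$drug_id[is.na(j)]), 3), collapse = ", "))
  K <- model$cfg$K
  P <- nrow(pairs)
  pdat <- list(pi_ = i, pj = j, n_pairs = P, K = K)

  grids <- model$grids[dat$drug_ids[j]]
  # per-row trapezoid weights so AUC of every draw is a single row product
  Wt <- t(vapply(grids, trap_weights, numeric(K)))

  set.seed(seed)
  mean_curve <- matrix(0, P, K)
  auc_d <- matrix(0, P, n_draws)
  draws <- array(0, dim = c(P, K, n_draws))
  for (s in seq_len(n_draws)) {
    ps <- draw_posterior(model$params)
    M <- pair_grid_viabilities(ps$V, ps$U, pdat)
    draws[, , s] <- M
    mean_curve <- mean_curve + M / n_draws
    auc_d[, s] <- rowSums(M * Wt)
  }
  # pointwise 90% band
  q_lo <- apply(draws, c(1, 2), quantile, probs = 0.05, names = FALSE)
  q_hi <- apply(draws, c(1, 2), quantile, probs = 0.95, names = FALSE)

  auc_mean <- numeric(P); ic50v <- numeric(P); cens <- character(P)
  for (p in seq_len(P)) {
    g <- grids[[p]]
    auc_mean[p] <- auc(mean_curve[p, ], g)
    ic <- ic50(mean_curve[p, ], g)
    ic50v[p] <- ic$ic50_log10; cens[p] <- ic$censored
  }
  observed_keys <- unique(paste(dat$i, dat$j))
  src <- ifelse(paste(i, j) %in% observed_keys, "observed_fit", "imputed")

  out <- data.frame(sample_id = pairs$sample_id, drug_id = pairs$drug_id,
                    auc = auc_mean,
                    auc_lo = apply(auc_d, 1, quantile, probs = 0.05),
                    auc_hi = apply(auc_d, 1, quantile, probs = 0.95),
                    ic50_log10 = ic50v, ic50_censored = cens,
                    band_width = rowMeans(q_hi - q_lo),
                    source = src, stringsAsFactors = FALSE)
  attr(out, "curve_mean") <- mean_curve
  attr(out, "curve_lo") <- q_lo
  attr(out, "curve_hi") <- q_hi
  attr(out, "grids") <- grids
  class(out) <- c("curve_summary", "data.frame")
  out
}

#' Posterior-mean sample and drug embeddings
#'
#' Drug embeddings are the concatenation of the K per-grid-point embedding
#' means (J x (K*d)).
#' @param model a `drm_fit`
#' @return list with `samples` (n x d, rownames sample ids) and `drugs`
#' @export
drm_embeddings <- function(model) {
  d <- model$cfg$d; K <- model$cfg$K
  V <- model$params$Vm
  rownames(V) <- model$data$sample_ids
  J <- length(model$data$drug_ids)
  Ucat <- matrix(t(model$params$Um), nrow = J, byrow = TRUE)
  rownames(Ucat) <- model$data$drug_ids
  list(samples = V, drugs = Ucat)
}

#' Embed a new sample from a pilot screen
#'
#' Optimizes only the new sample's embedding posterior against the Gaussian
#' likelihood of the pilot measurements, with all drug parameters frozen at
#' their posterior means. The returned posterior can be passed to
#' [impute_for_embedding()].
#'
#' @param model a `drm_fit`
#' @param pilot data.frame with drug_id, concentration_uM, viability
#' @param n_iter,lr optimizer settings
#' @param seed RNG seed
#' @return list with `mean`, `log_sd` (length-d vectors)
#' @export
embed_new_sample <- function(model, pilot, n_iter = 300, lr = 0.05,
                             seed = 1) {
  if (nrow(pilot) == 0) stop("empty pilot screen")
  dat <- model$data
  j <- match(pilot$drug_id, dat$drug_ids)
  if (anyNA(j)) stop("pilot contains drug(s) unknown to the model: ",
                     paste(head(unique(pilot$drug_id[is.na(j)]), 3),
                           collapse = ", "))
  K <- model$cfg$K; d <- model$cfg$d
  U <- model$params$Um
  sig <- stats::median(exp(model$params$log_noise))
  tau2 <- model$cfg$tau^2

  lc <- log10(pilot$concentration_uM)
  grids <- model$grids[dat$drug_ids[j]]
  klo <- integer(nrow(pilot)); w <- numeric(nrow(pilot))
  for (r in seq_len(nrow(pilot))) {
    g <- grids[[r]]
    x <- min(max(lc[r], g[1]), g[K])
    k <- min(max(findInterval(x, g, rightmost.closed = TRUE), 1L), K - 1L)
    klo[r] <- k
    w[r] <- (x - g[k]) / (g[k + 1L] - g[k])
  }
  urows <- lapply(seq_len(nrow(pilot)), function(r) (j[r] - 1L) * K + seq_len(K))

  set.seed(seed)
  params <- list(vm = matrix(0, 1, d), vls = matrix(log(0.1), 1, d))
  state <- adam_init(params)
  for (it in seq_len(n_iter)) {
    vs <- exp(params$vls)
    eps <- matrix(rnorm(d), 1, d)
    v <- params$vm + vs * eps
    gv <- matrix(0, 1, d)
    for (r in seq_len(nrow(pilot))) {
      Ur <- U[urows[[r]], , drop = FALSE]
      a <- as.vector(Ur %*% t(v))
      sg <- stats::plogis(a)
      m <- exp(cumsum(log(sg)))
      pr <- (1 - w[r]) * m[klo[r]] + w[r] * m[klo[r] + 1L]
      dpr <- (pr - pilot$viability[r]) / sig^2
      dm <- numeric(K)
      dm[klo[r]] <- dm[klo[r]] + (1 - w[r]) * dpr
      dm[klo[r] + 1L] <- dm[klo[r] + 1L] + w[r] * dpr
      Cv <- rev(cumsum(rev(dm * m)))
      da <- Cv * (1 - sg)
      gv <- gv + matrix(colSums(da * Ur), 1, d)
    }
    grads <- list(vm = gv + params$vm / tau2,
                  vls = gv * eps * vs + (vs^2 / tau2 - 1))
    st <- adam_step(params, grads, state, lr)
    params <- st$params; state <- st$state
  }
  list(mean = as.vector(params$vm), log_sd = as.vector(params$vls))
}

#' Impute curves for an externally embedded sample
#'
#' @param model a `drm_fit`
#' @param embedding output of [embed_new_sample()]
#' @param drug_ids drugs to impute (default: all known drugs)
#' @param n_draws posterior draws
#' @param seed RNG seed
#' @return data.frame with drug_id, auc, ic50_log10, ic50_censored,
#'   band_width
#' @export
impute_for_embedding <- function(model, embedding, drug_ids = NULL,
                                 n_draws = model$cfg$n_posterior_samples,
                                 seed = 1) {
  dat <- model$data
  if (is.null(drug_ids)) drug_ids <- dat$drug_ids
  j <- match(drug_ids, dat$drug_ids)
  if (anyNA(j)) stop("unknown drug id(s)")
  K <- model$cfg$K; d <- model$cfg$d
  set.seed(seed)
  vs <- exp(embedding$log_sd)
  Us <- exp(model$params$Uls)
  P <- length(j)
  grids <- model$grids[dat$drug_ids[j]]
  Wt <- t(vapply(grids, trap_weights, numeric(K)))
  auc_d <- matrix(0, P, n_draws); mean_curve <- matrix(0, P, K)
  for (s in seq_len(n_draws)) {
    v <- embedding$mean + vs * rnorm(d)
    U <- model$params$Um + Us * matrix(rnorm(length(Us)), nrow(Us))
    pdat <- list(pi_ = rep(1L, P), pj = j, n_pairs = P, K = K)
    M <- pair_grid_viabilities(matrix(v, 1, d), U, pdat)
    mean_curve <- mean_curve + M / n_draws
    auc_d[, s] <- rowSums(M * Wt)
  }
  ic <- lapply(seq_len(P), function(p) ic50(mean_curve[p, ], grids[[p]]))
  data.frame(drug_id = drug_ids,
             auc = rowMeans(auc_d),
             ic50_log10 = vapply(ic, function(x) x$ic50_log10, 0),
             ic50_censored = vapply(ic, function(x) x$censored, ""),
             band_width = apply(auc_d, 1, function(x)
               diff(quantile(x, c(0.05, 0.95)))),
             stringsAsFactors = FALSE)
}

#' Save / load a fitted dose-response model
#'
#' The model is stored as a directory holding `meta.json` (config, version,
#' id maps) and `params.rds` (posterior arrays and index data). Reloading
#' reproduces predictions bit-identically at a fixed seed.
#'
#' @param model a `drm_fit`
#' @param path directory to create
#' @return `path` invisibly (`save_model`); the model (`load_model`)
#' @export
save_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format = "panscreen-drm", version = model$version,
               cfg = unclass(model$cfg),
               sample_ids = model$data$sample_ids,
               drug_ids = model$data$drug_ids,
               study_ids = model$data$study_ids)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  saveRDS(model, file.path(path, "params.rds"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop("not a model directory: ", path)
  meta <- tryCatch(jsonlite::read_json(meta_path),
                   error = function(e) stop("corrupted model metadata: ",
                                            conditionMessage(e)))
  if (is.null(meta$format) || meta$format != "panscreen-drm")
    stop("corrupted or foreign model directory")
  ver <- strsplit(as.character(meta$version), ".", fixed = TRUE)[[1]]
  cur <- strsplit("1.0", ".", fixed = TRUE)[[1]]
  if (ver[1] != cur[1]) stop("incompatible model major version: ", meta$version)
  if (ver[2] != cur[2]) warning("model minor version ", meta$version,
                                " loaded by 1.0; proceeding")
  model <- readRDS(file.path(path, "params.rds"))
  if (!inherits(model, "drm_fit")) stop("corrupted model payload")
  model
}
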