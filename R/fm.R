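#' Foundation-model configuration
#'
#' Architecture and training settings for the few-shot in-context
#' dose-response transformer. Each measured (drug, dose, viability) triplet
#' becomes one token: a dictionary embedding for the drug and learnable
#' Fourier-feature embeddings for the two scalars, concatenated
#' (`hidden = 3 * sub_embedding`). Query tokens replace the viability
#' component by a learned placeholder. Tokens carry no positional encoding:
#' context and query are sets, and predictions are permutation-invariant.
#'
#' @param scale `"paper"` (8 blocks, hidden 384, intermediate 512, 8 heads,
#'   sub-embeddings 128) or `"desk"` (2 blocks, hidden 96, intermediate 128,
#'   4 heads, sub-embeddings 32) for CPU-scale runs
#' @param n_blocks,hidden,intermediate,n_heads,sub_embedding architecture
#'   overrides
#' @param n_fourier Fourier frequencies per scalar embedding
#' @param context_range episode context sizes are drawn uniformly from this
#'   range
#' @param query_max maximum query tokens per training episode
#' @param lr Adam learning rate
#' @param n_steps optimizer steps
#' @param batch_episodes episodes averaged per gradient step
#' @param seed RNG seed
#' @return an `fm_config`
#' @export
fm_config <- function(scale = c("desk", "paper"),
                      n_blocks = NULL, hidden = NULL, intermediate = NULL,
                      n_heads = NULL, sub_embedding = NULL,
                      n_fourier = 16,
                      context_range = c(5, 50), query_max = 24,
                      lr = 2e-3, n_steps = 600, batch_episodes = 4,
                      seed = 1) {
  scale <- match.arg(scale)
  preset <- if (scale == "paper") {
    list(n_blocks = 8, hidden = 384, intermediate = 512, n_heads = 8,
         sub_embedding = 128)
  } else {
    list(n_blocks = 2, hidden = 96, intermediate = 128, n_heads = 4,
         sub_embedding = 32)
  }
  cfg <- list(scale = scale,
              n_blocks = n_blocks %||% preset$n_blocks,
              hidden = hidden %||% preset$hidden,
              intermediate = intermediate %||% preset$intermediate,
              n_heads = n_heads %||% preset$n_heads,
              sub_embedding = sub_embedding %||% preset$sub_embedding,
              n_fourier = n_fourier, context_range = context_range,
              query_max = query_max, lr = lr, n_steps = n_steps,
              batch_episodes = batch_episodes, seed = seed)
  if (cfg$hidden != 3 * cfg$sub_embedding)
    stop("hidden must equal 3 * sub_embedding")
  if (cfg$hidden %% cfg$n_heads != 0)
    stop("n_heads must divide hidden")
  class(cfg) <- "fm_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- parameter initialization ------------------------------------------

fm_init_params <- function(cfg, n_drugs) {
  H <- cfg$hidden; S <- cfg$sub_embedding; I <- cfg$intermediate
  Fq <- cfg$n_fourier
  rn <- function(nr, nc, sd = 0.02) matrix(rnorm(nr * nc, 0, sd), nr, nc)
  p <- list(
    drug_emb = rn(n_drugs + 1L, S),     # last row: reserved OOV embedding
    dose_freq = matrix(exp(seq(log(0.2), log(8), length.out = Fq)), Fq, 1),
    dose_phase = matrix(0, Fq, 1),
    dose_proj = rn(2 * Fq, S, 1 / sqrt(2 * Fq)),
    dose_bias = matrix(0, 1, S),
    via_freq = matrix(exp(seq(log(0.2), log(8), length.out = Fq)), Fq, 1),
    via_phase = matrix(0, Fq, 1),
    via_proj = rn(2 * Fq, S, 1 / sqrt(2 * Fq)),
    via_bias = matrix(0, 1, S),
    via_placeholder = rn(1, S),
    head_w = matrix(0, H, 1),
    head_b = matrix(0.7, 1, 1))
  out_sd <- 0.02 / sqrt(2 * cfg$n_blocks)
  for (b in seq_len(cfg$n_blocks)) {
    p[[paste0("b", b, "_ln1_g")]] <- matrix(1, 1, H)
    p[[paste0("b", b, "_ln1_b")]] <- matrix(0, 1, H)
    p[[paste0("b", b, "_Wq")]] <- rn(H, H)
    p[[paste0("b", b, "_Wk")]] <- rn(H, H)
    p[[paste0("b", b, "_Wv")]] <- rn(H, H)
    p[[paste0("b", b, "_Wo")]] <- rn(H, H, out_sd)
    p[[paste0("b", b, "_ln2_g")]] <- matrix(1, 1, H)
    p[[paste0("b", b, "_ln2_b")]] <- matrix(0, 1, H)
    p[[paste0("b", b, "_W1")]] <- rn(H, I)
    p[[paste0("b", b, "_b1")]] <- matrix(0, 1, I)
    p[[paste0("b", b, "_W2")]] <- rn(I, H, out_sd)
    p[[paste0("b", b, "_b2")]] <- matrix(0, 1, H)
  }
  p
}

# ---- primitive layers (forward + backward) -----------------------------

#' Fourier-feature embedding of a scalar
#'
#' sin/cos features at learnable frequencies and phases, linearly combined
#' to the sub-embedding width. Deterministic in its inputs.
#'
#' @param x finite numeric vector
#' @param freq,phase,proj,bias parameters (see [fm_config()] for shapes)
#' @return length(x) x sub_embedding matrix
#' @export
fourier_embed <- function(x, freq, phase, proj, bias) {
  if (any(!is.finite(x))) stop("non-finite scalar input to fourier_embed")
  ang <- outer(x, as.vector(freq)) +
    matrix(as.vector(phase), length(x), length(freq), byrow = TRUE)
  feats <- cbind(sin(ang), cos(ang))
  sweep(feats %*% proj, 2, as.vector(bias), "+")
}

fourier_backward <- function(x, freq, phase, proj, demb) {
  Fq <- length(freq)
  ang <- outer(x, as.vector(freq)) +
    matrix(as.vector(phase), length(x), Fq, byrow = TRUE)
  feats <- cbind(sin(ang), cos(ang))
  dproj <- t(feats) %*% demb
  dbias <- matrix(colSums(demb), 1)
  dfeats <- demb %*% t(proj)
  dang <- dfeats[, seq_len(Fq), drop = FALSE] * cos(ang) -
    dfeats[, Fq + seq_len(Fq), drop = FALSE] * sin(ang)
  list(dfreq = matrix(colSums(dang * x), ncol = 1),
       dphase = matrix(colSums(dang), ncol = 1),
       dproj = dproj, dbias = dbias)
}

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = sweep(xhat * rep(1, nrow(x)) %o% as.vector(g), 2,
                 as.vector(b), "+"),
       xhat = xhat, inv = inv)
}

layernorm_bwd <- function(cache, g, dy) {
  xhat <- cache$xhat; inv <- cache$inv
  H <- ncol(xhat)
  dg <- matrix(colSums(dy * xhat), 1)
  db <- matrix(colSums(dy), 1)
  dxhat <- dy * rep(1, nrow(dy)) %o% as.vector(g)
  dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

gelu_fwd <- function(x) x * pnorm(x)
gelu_bwd <- function(x, dy) dy * (pnorm(x) + x * stats::dnorm(x))

attention_fwd <- function(X, p, b, n_heads, allowed) {
  H <- ncol(X); dh <- H %/% n_heads
  Q <- X %*% p[[paste0("b", b, "_Wq")]]
  K <- X %*% p[[paste0("b", b, "_Wk")]]
  V <- X %*% p[[paste0("b", b, "_Wv")]]
  L <- nrow(X)
  O <- matrix(0, L, H)
  caches <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    sc <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) / sqrt(dh)
    sc[!allowed] <- -1e9
    sc <- sc - apply(sc, 1, max)
    E <- exp(sc)
    P <- E / rowSums(E)
    O[, cols] <- P %*% V[, cols, drop = FALSE]
    caches[[h]] <- P
  }
  Y <- O %*% p[[paste0("b", b, "_Wo")]]
  list(y = Y, Q = Q, K = K, V = V, O = O, P = caches)
}

attention_bwd <- function(cache, X, p, b, n_heads, dy, grads) {
  H <- ncol(X); dh <- H %/% n_heads
  Wo <- p[[paste0("b", b, "_Wo")]]
  grads[[paste0("b", b, "_Wo")]] <- grads[[paste0("b", b, "_Wo")]] +
    t(cache$O) %*% dy
  dO <- dy %*% t(Wo)
  dQ <- matrix(0, nrow(X), H); dK <- dQ; dV <- dQ
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    P <- cache$P[[h]]
    dOh <- dO[, cols, drop = FALSE]
    dP <- dOh %*% t(cache$V[, cols, drop = FALSE])
    dV[, cols] <- t(P) %*% dOh
    dS <- P * (dP - rowSums(dP * P))
    dS <- dS / sqrt(dh)
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE]
    dK[, cols] <- t(dS) %*% cache$Q[, cols, drop = FALSE]
  }
  for (nm in c("Wq", "Wk", "Wv")) {
    dW <- switch(nm, Wq = dQ, Wk = dK, Wv = dV)
    key <- paste0("b", b, "_", nm)
    grads[[key]] <- grads[[key]] + t(X) %*% dW
  }
  dX <- dQ %*% t(p[[paste0("b", b, "_Wq")]]) +
    dK %*% t(p[[paste0("b", b, "_Wk")]]) +
    dV %*% t(p[[paste0("b", b, "_Wv")]])
  list(dx = dX, grads = grads)
}

# ---- tokenization ------------------------------------------------------

#' Tokenize context triplets and query pairs
#'
#' Context tokens embed (drug, dose, viability); query tokens substitute the
#' learned placeholder for the viability component. Drugs absent from the
#' model vocabulary map to the reserved out-of-vocabulary embedding with a
#' warning.
#'
#' @param model an `fm_model`
#' @param context data.frame(drug_id, concentration_uM, viability)
#' @param queries data.frame(drug_id, concentration_uM)
#' @return list with `context` and `queries` token matrices (rows x hidden)
#' @export
tokenize <- function(model, context, queries) {
  p <- model$params
  embed_rows <- function(drug_id, log_dose, via = NULL) {
    idx <- match(drug_id, model$drug_vocab)
    if (anyNA(idx)) {
      warning("out-of-vocabulary drug(s) mapped to the reserved embedding: ",
              paste(head(unique(drug_id[is.na(idx)]), 3), collapse = ", "))
      idx[is.na(idx)] <- length(model$drug_vocab) + 1L
    }
    de <- p$drug_emb[idx, , drop = FALSE]
    ce <- fourier_embed(log_dose, p$dose_freq, p$dose_phase, p$dose_proj,
                        p$dose_bias)
    ve <- if (is.null(via)) {
      matrix(p$via_placeholder, nrow = length(drug_id),
             ncol = ncol(p$via_placeholder), byrow = TRUE)
    } else {
      fourier_embed(via, p$via_freq, p$via_phase, p$via_proj, p$via_bias)
    }
    cbind(de, ce, ve)
  }
  ctx <- if (nrow(context) > 0)
    embed_rows(context$drug_id, log10(context$concentration_uM),
               context$viability)
  else matrix(0, 0, model$cfg$hidden)
  qry <- if (nrow(queries) > 0)
    embed_rows(queries$drug_id, log10(queries$concentration_uM))
  else matrix(0, 0, model$cfg$hidden)
  list(context = ctx, queries = qry)
}

# attention permission mask for nc context + nq query tokens:
# context attends only to context; queries attend to context and themselves
fm_mask <- function(nc, nq) {
  L <- nc + nq
  allowed <- matrix(FALSE, L, L)
  if (nc > 0) allowed[, seq_len(nc)] <- TRUE
  if (nq > 0) {
    qi <- nc + seq_len(nq)
    allowed[cbind(qi, qi)] <- TRUE
    if (nc > 0) allowed[seq_len(nc), qi] <- FALSE
  }
  if (nc == 0 && nq > 0) {
    # prior-like behavior: queries see only themselves
    allowed[cbind(nc + seq_len(nq), nc + seq_len(nq))] <- TRUE
  }
  allowed
}

fm_forward <- function(model, X0, nc, nq, want_cache = FALSE) {
  cfg <- model$cfg; p <- model$params
  allowed <- fm_mask(nc, nq)
  X <- X0
  caches <- list()
  for (b in seq_len(cfg$n_blocks)) {
    ln1 <- layernorm_fwd(X, p[[paste0("b", b, "_ln1_g")]],
                         p[[paste0("b", b, "_ln1_b")]])
    att <- attention_fwd(ln1$y, p, b, cfg$n_heads, allowed)
    X1 <- X + att$y
    ln2 <- layernorm_fwd(X1, p[[paste0("b", b, "_ln2_g")]],
                         p[[paste0("b", b, "_ln2_b")]])
    Hpre <- sweep(ln2$y %*% p[[paste0("b", b, "_W1")]], 2,
                  as.vector(p[[paste0("b", b, "_b1")]]), "+")
    Hact <- gelu_fwd(Hpre)
    X2 <- X1 + sweep(Hact %*% p[[paste0("b", b, "_W2")]], 2,
                     as.vector(p[[paste0("b", b, "_b2")]]), "+")
    if (want_cache)
      caches[[b]] <- list(Xin = X, ln1 = ln1, att = att, X1 = X1, ln2 = ln2,
                          Hpre = Hpre, Hact = Hact)
    X <- X2
  }
  pred <- as.vector(X[nc + seq_len(nq), , drop = FALSE] %*% p$head_w) +
    p$head_b[1, 1]
  list(pred = pred, X = X, caches = caches, allowed = allowed)
}

fm_backward <- function(model, fwd, X0, nc, nq, dpred) {
  cfg <- model$cfg; p <- model$params
  grads <- lapply(p, function(x) x * 0)
  L <- nc + nq
  qrows <- nc + seq_len(nq)
  grads$head_w <- t(fwd$X[qrows, , drop = FALSE]) %*% matrix(dpred)
  grads$head_b <- matrix(sum(dpred), 1, 1)
  dX <- matrix(0, L, cfg$hidden)
  dX[qrows, ] <- matrix(dpred) %*% t(p$head_w)
  for (b in rev(seq_len(cfg$n_blocks))) {
    cc <- fwd$caches[[b]]
    # FFN branch
    dH2 <- dX
    grads[[paste0("b", b, "_W2")]] <- grads[[paste0("b", b, "_W2")]] +
      t(cc$Hact) %*% dH2
    grads[[paste0("b", b, "_b2")]] <- grads[[paste0("b", b, "_b2")]] +
      matrix(colSums(dH2), 1)
    dHact <- dH2 %*% t(p[[paste0("b", b, "_W2")]])
    dHpre <- gelu_bwd(cc$Hpre, dHact)
    grads[[paste0("b", b, "_W1")]] <- grads[[paste0("b", b, "_W1")]] +
      t(cc$ln2$y) %*% dHpre
    grads[[paste0("b", b, "_b1")]] <- grads[[paste0("b", b, "_b1")]] +
      matrix(colSums(dHpre), 1)
    dln2y <- dHpre %*% t(p[[paste0("b", b, "_W1")]])
    ln2b <- layernorm_bwd(cc$ln2, p[[paste0("b", b, "_ln2_g")]], dln2y)
    grads[[paste0("b", b, "_ln2_g")]] <- grads[[paste0("b", b, "_ln2_g")]] +
      ln2b$dg
    grads[[paste0("b", b, "_ln2_b")]] <- grads[[paste0("b", b, "_ln2_b")]] +
      ln2b$db
    dX1 <- dX + ln2b$dx
    # attention branch
    ab <- attention_bwd(cc$att, cc$ln1$y, p, b, cfg$n_heads, dX1, grads)
    grads <- ab$grads
    ln1b <- layernorm_bwd(cc$ln1, p[[paste0("b", b, "_ln1_g")]], ab$dx)
    grads[[paste0("b", b, "_ln1_g")]] <- grads[[paste0("b", b, "_ln1_g")]] +
      ln1b$dg
    grads[[paste0("b", b, "_ln1_b")]] <- grads[[paste0("b", b, "_ln1_b")]] +
      ln1b$db
    dX <- dX1 + ln1b$dx
  }
  list(grads = grads, dX0 = dX)
}

# backprop dX0 into the embedding parameters
fm_embed_backward <- function(model, context, queries, dX0, grads) {
  p <- model$params; S <- model$cfg$sub_embedding
  nc <- nrow(context); nq <- nrow(queries)
  all_drugs <- c(as.character(context$drug_id), as.character(queries$drug_id))
  idx <- match(all_drugs, model$drug_vocab)
  idx[is.na(idx)] <- length(model$drug_vocab) + 1L
  dDrug <- dX0[, seq_len(S), drop = FALSE]
  grads$drug_emb <- accum_rows(grads$drug_emb, idx, dDrug)
  dDose <- dX0[, S + seq_len(S), drop = FALSE]
  all_doses <- log10(c(context$concentration_uM, queries$concentration_uM))
  fb <- fourier_backward(all_doses, p$dose_freq, p$dose_phase, p$dose_proj,
                         dDose)
  grads$dose_freq <- grads$dose_freq + fb$dfreq
  grads$dose_phase <- grads$dose_phase + fb$dphase
  grads$dose_proj <- grads$dose_proj + fb$dproj
  grads$dose_bias <- grads$dose_bias + fb$dbias
  dVia <- dX0[, 2 * S + seq_len(S), drop = FALSE]
  if (nc > 0) {
    fbv <- fourier_backward(context$viability, p$via_freq, p$via_phase,
                            p$via_proj, dVia[seq_len(nc), , drop = FALSE])
    grads$via_freq <- grads$via_freq + fbv$dfreq
    grads$via_phase <- grads$via_phase + fbv$dphase
    grads$via_proj <- grads$via_proj + fbv$dproj
    grads$via_bias <- grads$via_bias + fbv$dbias
  }
  if (nq > 0)
    grads$via_placeholder <- grads$via_placeholder +
      matrix(colSums(dVia[nc + seq_len(nq), , drop = FALSE]), 1)
  grads
}

# ---- training ----------------------------------------------------------

#' Train the few-shot foundation model
#'
#' Episodic training: each episode samples one biological sample from the
#' training studies, splits its measurements into a context set (size drawn
#' from `cfg$context_range`) and a query set, and minimizes mean-squared
#' error on the query viabilities. Records touching `hold_out_study` are
#' never used (the sampling audit is kept on the model). Deterministic given
#' `cfg$seed`.
#'
#' @param ds a `screen_dataset`
#' @param cfg an [fm_config()]
#' @param hold_out_study optional study id excluded from training
#' @return an `fm_model` with `params`, `drug_vocab`, `loss_trace`
#' @export
train_fm <- function(ds, cfg = fm_config(), hold_out_study = NULL) {
  r <- ds$records
  if (!is.null(hold_out_study)) r <- r[r$study_id != hold_out_study, ]
  if (nrow(r) == 0) stop("no training records")
  drug_vocab <- sort(unique(r$drug_id))
  set.seed(cfg$seed)
  params <- fm_init_params(cfg, length(drug_vocab))
  model <- structure(list(cfg = cfg, params = params,
                          drug_vocab = drug_vocab,
                          excluded_study = hold_out_study,
                          version = "1.0"),
                     class = "fm_model")
  by_sample <- split(seq_len(nrow(r)), paste(r$study_id, r$sample_id))
  by_sample <- by_sample[lengths(by_sample) >= cfg$context_range[1] + 2]
  if (length(by_sample) == 0) stop("no sample has enough measurements")

  state <- adam_init(params)
  trace <- numeric(cfg$n_steps)
  for (step in seq_len(cfg$n_steps)) {
    grads <- NULL
    loss_acc <- 0
    for (e in seq_len(cfg$batch_episodes)) {
      idx <- by_sample[[sample.int(length(by_sample), 1)]]
      nctx <- sample(seq(cfg$context_range[1],
                         min(cfg$context_range[2], length(idx) - 1)), 1)
      perm <- sample(idx)
      ctx_i <- perm[seq_len(nctx)]
      qry_i <- perm[nctx + seq_len(min(cfg$query_max, length(idx) - nctx))]
      context <- r[ctx_i, c("drug_id", "concentration_uM", "viability")]
      queries <- r[qry_i, c("drug_id", "concentration_uM")]
      target <- r$viability[qry_i]
      model$params <- params
      tok <- tokenize(model, context, queries)
      X0 <- rbind(tok$context, tok$queries)
      fwd <- fm_forward(model, X0, nrow(context), nrow(queries),
                        want_cache = TRUE)
      err <- fwd$pred - target
      loss_acc <- loss_acc + mean(err^2)
      dpred <- 2 * err / length(err)
      bk <- fm_backward(model, fwd, X0, nrow(context), nrow(queries), dpred)
      g <- fm_embed_backward(model, context, queries, bk$dX0, bk$grads)
      grads <- if (is.null(grads)) g else Map("+", grads, g)
    }
    grads <- lapply(grads, function(x) x / cfg$batch_episodes)
    trace[step] <- loss_acc / cfg$batch_episodes
    st <- adam_step(params, grads, state, cfg$lr)
    params <- st$params; state <- st$state
  }
  model$params <- params
  model$loss_trace <- trace
  model
}

#' Predict query viabilities from a few-shot context
#'
#' Runs the transformer over the tokenized context and query sets (queries
#' attend to the context and themselves; the context attends only to
#' itself) and applies the linear head to the final query representations.
#' Predictions are permutation-invariant in both sets and clipped to
#' [0, 2]. With an empty context the model falls back to prior-like
#' predictions (flagged via attribute `empty_context`).
#'
#' @param model an `fm_model`
#' @param context data.frame(drug_id, concentration_uM, viability)
#' @param queries data.frame(drug_id, concentration_uM)
#' @return numeric predictions, one per query row
#' @export
predict_query <- function(model, context, queries) {
  if (nrow(queries) == 0) return(numeric(0))
  tok <- tokenize(model, context, queries)
  X0 <- rbind(tok$context, tok$queries)
  fwd <- fm_forward(model, X0, nrow(tok$context), nrow(tok$queries))
  out <- pmin(pmax(fwd$pred, 0), 2)
  if (nrow(context) == 0) attr(out, "empty_context") <- TRUE
  out
}

#' Fine-tune a trained foundation model on few-shot records (FM++)
#'
#' Runs a few low-learning-rate gradient epochs on the supplied records
#' only, episodically split into context/query like training. The input
#' model is copied, never modified.
#'
#' @param model a trained `fm_model`
#' @param fewshot data.frame(drug_id, concentration_uM, viability)
#' @param n_epochs gradient epochs (0 returns an identical copy)
#' @param lr fine-tuning learning rate
#' @param seed RNG seed
#' @return a new `fm_model`
#' @export
finetune <- function(model, fewshot, n_epochs = 10, lr = 2e-4, seed = 1) {
  if (nrow(fewshot) == 0) stop("empty few-shot set")
  out <- model
  if (n_epochs == 0) return(out)
  params <- model$params
  state <- adam_init(params)
  set.seed(seed)
  n <- nrow(fewshot)
  for (ep in seq_len(n_epochs)) {
    perm <- sample.int(n)
    nctx <- max(1L, floor(n / 2))
    ctx <- fewshot[perm[seq_len(nctx)], ]
    qry <- fewshot[perm[(nctx + 1):n], , drop = FALSE]
    if (nrow(qry) == 0) next
    out$params <- params
    tok <- suppressWarnings(tokenize(out, ctx, qry[, c("drug_id",
                                                       "concentration_uM")]))
    X0 <- rbind(tok$context, tok$queries)
    fwd <- fm_forward(out, X0, nrow(ctx), nrow(qry), want_cache = TRUE)
    err <- fwd$pred - qry$viability
    dpred <- 2 * err / length(err)
    bk <- fm_backward(out, fwd, X0, nrow(ctx), nrow(qry), dpred)
    g <- suppressWarnings(
      fm_embed_backward(out, ctx, qry[, c("drug_id", "concentration_uM")],
                        bk$dX0, bk$grads))
    st <- adam_step(params, g, state, lr)
    params <- st$params; state <- st$state
  }
  out$params <- params
  out$finetuned <- TRUE
  out
}

#' Extract a sample embedding from a few-shot context
#'
#' Mean of the final-block context-token representations: deterministic,
#' permutation-invariant, length `hidden`.
#'
#' @param model an `fm_model`
#' @param context data.frame(drug_id, concentration_uM, viability), >= 1 row
#' @return numeric vector of length `model$cfg$hidden`
#' @export
extract_sample_embedding <- function(model, context) {
  if (nrow(context) == 0) stop("empty context")
  tok <- tokenize(model, context,
                  data.frame(drug_id = character(0),
                             concentration_uM = numeric(0)))
  fwd <- fm_forward(model, tok$context, nrow(tok$context), 0L)
  colMeans(fwd$X)
}
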