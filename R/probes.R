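#' Logistic-regression mutation probe on embeddings
#'
#' Predicts binary mutation status per gene from sample embeddings with a
#' logistic probe, evaluated by stratified 5-fold cross-validated AUROC.
#' Genes observed in a single class are skipped and reported.
#'
#' @param embeddings n x d matrix (rownames = sample ids)
#' @param labels n x genes 0/1 matrix, rows aligned with embeddings
#' @param folds cross-validation folds
#' @param seed fold-assignment seed
#' @param max_dim optional PCA compression of the embeddings before the
#'   probe (stabilizes small-n fits); NULL disables
#' @return data.frame (gene, auroc, n_mutant, skipped) with per-fold values
#'   in attribute `per_fold`
#' @export
probe_mutation <- function(embeddings, labels, folds = 5, seed = 1,
                           max_dim = 10) {
  X <- prep_probe_features(embeddings, max_dim)
  res <- list(); per_fold <- list()
  for (g in colnames(labels)) {
    y <- labels[, g]
    if (length(unique(y)) < 2 || min(table(y)) < folds) {
      res[[length(res) + 1L]] <- data.frame(gene = g, auroc = NA_real_,
                                            n_mutant = sum(y == 1),
                                            skipped = TRUE)
      next
    }
    fold_id <- stratified_folds(y, folds, seed)
    aucs <- numeric(folds)
    for (f in seq_len(folds)) {
      test <- fold_id == f
      fit <- suppressWarnings(glm(y[!test] ~ ., family = binomial(),
                                  data = data.frame(X[!test, , drop = FALSE])))
      prob <- suppressWarnings(
        predict(fit, newdata = data.frame(X[test, , drop = FALSE]),
                type = "response"))
      aucs[f] <- as.numeric(pROC::auc(pROC::roc(y[test], prob,
                                                quiet = TRUE,
                                                direction = "<",
                                                levels = c(0, 1))))
    }
    per_fold[[g]] <- aucs
    res[[length(res) + 1L]] <- data.frame(gene = g, auroc = mean(aucs),
                                          n_mutant = sum(y == 1),
                                          skipped = FALSE)
  }
  out <- do.call(rbind, res)
  attr(out, "per_fold") <- per_fold
  out
}

prep_probe_features <- function(embeddings, max_dim) {
  X <- as.matrix(embeddings)
  keep <- apply(X, 2, function(v) sd(v) > 1e-12)
  X <- X[, keep, drop = FALSE]
  if (!is.null(max_dim) && ncol(X) > max_dim) {
    X <- prcomp(X, center = TRUE, scale. = FALSE)$x[, seq_len(max_dim),
                                                    drop = FALSE]
  }
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  X
}

stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  fold_id <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

#' Pathway activity scores from an expression matrix
#'
#' Library-size normalizes, log(1 + x)-transforms, standardizes each gene,
#' then takes the first principal component across the member genes of the
#' gene set; the sign is oriented so the mean gene loading is positive.
#'
#' @param expression genes x samples matrix
#' @param gene_set character vector of member genes
#' @param min_genes minimum member genes present (set 1 with
#'   `allow_single = TRUE` to score a single-gene set)
#' @param allow_single leniency flag for single-gene sets
#' @return per-sample score vector
#' @export
pathway_score <- function(expression, gene_set, min_genes = 2,
                          allow_single = FALSE) {
  expression <- expression[!duplicated(rownames(expression)), , drop = FALSE]
  members <- intersect(rownames(expression), gene_set)
  if (length(members) < max(min_genes, if (allow_single) 1 else 2))
    stop("fewer than ", max(min_genes, 2), " member genes present")
  libsize <- colSums(expression)
  libsize[libsize == 0] <- 1
  norm <- sweep(expression, 2, libsize / mean(libsize), "/")
  lg <- log1p(norm[members, , drop = FALSE])
  std <- t(scale(t(lg)))
  std[!is.finite(std)] <- 0
  if (length(members) == 1) {
    sc <- as.vector(std)
    names(sc) <- colnames(expression)
    return(sc)
  }
  pc <- prcomp(t(std), center = FALSE, scale. = FALSE)
  score <- pc$x[, 1]
  if (mean(pc$rotation[, 1]) < 0) score <- -score
  stats::setNames(score, colnames(expression))
}

#' Ridge-regression pathway probe on embeddings
#'
#' Predicts pathway activity scores from sample embeddings with a ridge
#' probe (regularization chosen by inner cross-validation), evaluated by
#' 5-fold cross-validated Pearson correlation. Constant scores are skipped.
#'
#' @param embeddings n x d matrix
#' @param scores named list or matrix of per-sample pathway scores
#' @param folds outer folds
#' @param seed fold seed
#' @return data.frame (pathway, r, skipped), per-fold values in attribute
#'   `per_fold`
#' @export
probe_pathway <- function(embeddings, scores, folds = 5, seed = 1) {
  if (is.list(scores) && !is.data.frame(scores))
    scores <- do.call(cbind, scores)
  scores <- as.matrix(scores)
  X <- as.matrix(embeddings)
  res <- list(); per_fold <- list()
  for (pw in colnames(scores)) {
    y <- scores[, pw]
    if (sd(y) < 1e-12) {
      res[[length(res) + 1L]] <- data.frame(pathway = pw, r = NA_real_,
                                            skipped = TRUE)
      next
    }
    set.seed(seed)
    fold_id <- rep_len(seq_len(folds), length(y))[sample.int(length(y))]
    rs <- numeric(folds)
    for (f in seq_len(folds)) {
      test <- fold_id == f
      cv <- glmnet::cv.glmnet(X[!test, , drop = FALSE], y[!test],
                              alpha = 0, nfolds = 3)
      pred <- as.vector(predict(cv, X[test, , drop = FALSE],
                                s = "lambda.min"))
      rs[f] <- suppressWarnings(cor(pred, y[test]))
    }
    rs[!is.finite(rs)] <- 0
    per_fold[[pw]] <- rs
    res[[length(res) + 1L]] <- data.frame(pathway = pw, r = mean(rs),
                                          skipped = FALSE)
  }
  out <- do.call(rbind, res)
  attr(out, "per_fold") <- per_fold
  out
}

#' Joint cross-modality consistency test
#'
#' For each readout (mutation logit, pathway score, predicted AUC or any
#' other per-sample statistic), compares carriers and non-carriers of the
#' grouping gene by one-sided Mann-Whitney U tests over `n_repeats`
#' independent few-shot repeats, combining repeat p-values by Fisher's
#' method.
#'
#' @param readouts named list; each element is a list of per-repeat numeric
#'   vectors (one value per sample)
#' @param mutant logical per-sample carrier indicator
#' @param directions named character ("greater" or "less"), the alternative
#'   per readout: "greater" tests carriers > non-carriers
#' @return data.frame (readout, p_combined, n_repeats)
#' @export
joint_consistency <- function(readouts, mutant, directions) {
  if (!any(mutant) || all(mutant)) stop("both carrier groups must be non-empty")
  rows <- lapply(names(readouts), function(nm) {
    reps <- readouts[[nm]]
    ps <- vapply(reps, function(v) {
      suppressWarnings(wilcox.test(v[mutant], v[!mutant],
                                   alternative = directions[[nm]])$p.value)
    }, 0)
    data.frame(readout = nm, p_combined = fisher_method(ps),
               n_repeats = length(reps), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
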