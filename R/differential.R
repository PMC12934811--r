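#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment; a thin, validating wrapper over
#' `p.adjust(method = "BH")`.
#'
#' @param p p-values in [0, 1]
#' @return q-values, same length and order
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Two-sided permutation test on a difference of means
#'
#' p = (1 + #\{|stat_perm| >= |stat_obs|\}) / (B + 1), the add-one
#' permutation p-value; deterministic given `seed`.
#'
#' @param values_a,values_b numeric group values
#' @param B number of permutations (>= 1)
#' @param min_n minimum group size
#' @param seed RNG seed
#' @return list with statistic (mean a - mean b) and p
#' @export
permutation_test <- function(values_a, values_b, B = 999, min_n = 3,
                             seed = 1) {
  if (B < 1) stop("B must be >= 1")
  if (length(values_a) < min_n || length(values_b) < min_n)
    stop("group smaller than minimum size ", min_n)
  obs <- mean(values_a) - mean(values_b)
  pooled <- c(values_a, values_b)
  na <- length(values_a)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(length(pooled), na)
    stat <- mean(pooled[idx]) - mean(pooled[-idx])
    if (abs(stat) >= abs(obs)) exceed <- exceed + 1L
  }
  list(statistic = obs, p = (1 + exceed) / (B + 1))
}

#' Tissue-vs-rest differential drug sensitivity
#'
#' Restricts to primary (non-metastatic) samples, then for every
#' (tissue, drug) compares de-batched z-scores of the tissue's samples
#' against all other tissues pooled (Welch t-test), with BH correction
#' across all pairs.
#'
#' @param zmat samples x drugs z-score matrix ([zscore_matrix()])
#' @param annotations sample annotation data.frame
#' @param min_n minimum samples per tissue
#' @param fdr hit threshold on q
#' @return data.frame of per-(tissue, drug) effects with p, q, direction and
#'   `hit` flag
#' @export
tissue_vs_rest <- function(zmat, annotations, min_n = 3, fdr = 0.1) {
  ann <- annotations[match(rownames(zmat), annotations$sample_id), ]
  primary <- !isTRUE_vec(ann$is_metastasis)
  zmat <- zmat[primary, , drop = FALSE]
  tissue <- ann$primary_site[primary]
  counts <- table(tissue)
  tissues <- names(counts)[counts >= min_n]
  if (length(tissues) < 2) {
    warning("fewer than two eligible tissues")
    return(data.frame())
  }
  res <- list()
  for (tt in tissues) {
    in_t <- tissue == tt
    for (dg in colnames(zmat)) {
      za <- zmat[in_t, dg]; zb <- zmat[!in_t, dg]
      za <- za[is.finite(za)]; zb <- zb[is.finite(zb)]
      if (length(za) < min_n || length(zb) < min_n) next
      tst <- t.test(za, zb)  # Welch
      res[[length(res) + 1L]] <- data.frame(
        unit = dg, stratum = tt, effect = mean(za) - mean(zb),
        n_a = length(za), n_b = length(zb), p = tst$p.value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out$direction <- ifelse(out$effect > 0, "sensitive", "resistant")
  out$hit <- out$q < fdr
  out[order(out$q), ]
}

#' Metastatic-vs-primary comparison of absolute sensitivities (AUC)
#'
#' Per (disease, drug) with samples in both strata, computes the sign of
#' mean AUC(metastatic) - mean AUC(primary); a positive sign means the
#' metastatic samples are more resistant. Tests whether resistant signs
#' exceed one half by a one-sided binomial test. Optionally restricts a
#' second, two-sided Mann-Whitney U test on the per-pair AUC differences to
#' standard-of-care drugs.
#'
#' @param summaries curve summaries with auc
#' @param annotations sample annotations (oncotree_code, is_metastasis)
#' @param soc optional data.frame (oncotree_code, drug_id) of
#'   standard-of-care designations
#' @return list with `pairs` (per disease x drug table), `binomial_p`,
#'   `n_resistant`, `n_pairs`, and if `soc` given `soc_mw_p`
#' @export
met_vs_primary_auc <- function(summaries, annotations, soc = NULL) {
  ann <- annotations
  met <- isTRUE_vec(ann$is_metastasis)
  status <- ifelse(met[match(summaries$sample_id, ann$sample_id)],
                   "met", "primary")
  disease <- ann$oncotree_code[match(summaries$sample_id, ann$sample_id)]
  key <- paste(disease, summaries$drug_id, sep = "\r")
  rows <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    st <- status[idx]
    if (!all(c("met", "primary") %in% st)) next
    dm <- mean(summaries$auc[idx][st == "met"])
    dp <- mean(summaries$auc[idx][st == "primary"])
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    rows[[length(rows) + 1L]] <- data.frame(
      oncotree_code = parts[1], drug_id = parts[2],
      auc_met = dm, auc_primary = dp, diff = dm - dp,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no disease has samples in both strata")
  pairs <- do.call(rbind, rows)
  n_res <- sum(pairs$diff > 0)
  bt <- binom.test(n_res, nrow(pairs), p = 0.5, alternative = "greater")
  out <- list(pairs = pairs, n_resistant = n_res, n_pairs = nrow(pairs),
              binomial_p = bt$p.value)
  if (!is.null(soc)) {
    soc_key <- paste(soc$oncotree_code, soc$drug_id, sep = "\r")
    in_soc <- paste(pairs$oncotree_code, pairs$drug_id, sep = "\r") %in% soc_key
    if (sum(in_soc) >= 1 && sum(in_soc) < nrow(pairs)) {
      mw <- suppressWarnings(wilcox.test(pairs$auc_met[in_soc],
                                         pairs$auc_primary[in_soc],
                                         alternative = "two.sided"))
      out$soc_mw_p <- mw$p.value
      out$soc_n <- sum(in_soc)
    }
  }
  out
}

#' Metastatic-vs-primary relative sensitivity by drug group
#'
#' Within each disease with at least `min_met` metastatic samples, averages
#' z-scores per drug target group and takes the metastatic-minus-primary
#' difference as the relative increase in sensitivity. Per group:
#' Mann-Whitney U with BH across groups and a seeded percentile bootstrap
#' CI. Also returns average-linkage hierarchical clustering of diseases'
#' group-difference vectors on Pearson-correlation distance.
#'
#' @param zmat samples x drugs z matrix
#' @param annotations sample annotations
#' @param drug_groups named character: drug_id -> group (target or class)
#' @param min_met minimum metastatic samples per disease
#' @param n_boot bootstrap resamples
#' @param ci_level central CI level
#' @param seed RNG seed
#' @return list with `effects` (disease x group table incl. CI, p, q) and
#'   `clustering` (hclust over groups) with `leaf_order`
#' @export
met_vs_primary_zdiff <- function(zmat, annotations, drug_groups,
                                 min_met = 3, n_boot = 1000,
                                 ci_level = 0.9, seed = 1) {
  ann <- annotations[match(rownames(zmat), annotations$sample_id), ]
  met <- isTRUE_vec(ann$is_metastasis)
  eligible <- names(which(table(ann$oncotree_code[met]) >= min_met))
  eligible <- intersect(eligible,
                        unique(ann$oncotree_code[!met]))
  grp_of <- drug_groups[colnames(zmat)]
  groups <- sort(unique(stats::na.omit(grp_of)))
  set.seed(seed)
  alpha <- (1 - ci_level) / 2
  rows <- list()
  for (dis in eligible) {
    for (g in groups) {
      jj <- which(grp_of == g)
      im <- which(ann$oncotree_code == dis & met)
      ip <- which(ann$oncotree_code == dis & !met)
      vm <- rowMeans(zmat[im, jj, drop = FALSE], na.rm = TRUE)
      vp <- rowMeans(zmat[ip, jj, drop = FALSE], na.rm = TRUE)
      vm <- vm[is.finite(vm)]; vp <- vp[is.finite(vp)]
      if (length(vm) < min_met || length(vp) < 1) next
      eff <- mean(vm) - mean(vp)
      boot <- replicate(n_boot, mean(sample(vm, replace = TRUE)) -
                          mean(sample(vp, replace = TRUE)))
      ci <- quantile(boot, c(alpha, 1 - alpha), names = FALSE)
      pv <- suppressWarnings(wilcox.test(vm, vp)$p.value)
      rows[[length(rows) + 1L]] <- data.frame(
        oncotree_code = dis, group = g, effect = eff,
        ci_lo = ci[1], ci_hi = ci[2], n_met = length(vm),
        n_primary = length(vp), p = pv, stringsAsFactors = FALSE)
    }
  }
  effects <- do.call(rbind, rows)
  if (is.null(effects)) stop("no disease meets the metastatic minimum")
  effects$q <- bh_adjust(effects$p)

  # disease-wise difference vectors per group -> correlation clustering
  wide <- tapply(effects$effect,
                 list(effects$group, effects$oncotree_code), mean)
  clustering <- NULL; leaf_order <- rownames(wide)
  if (nrow(wide) >= 3) {
    cc <- suppressWarnings(cor(t(wide), use = "pairwise.complete.obs"))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 1
    clustering <- hclust(as.dist(1 - cc), method = "average")
    leaf_order <- rownames(wide)[clustering$order]
  }
  list(effects = effects, clustering = clustering, leaf_order = leaf_order)
}

#' Cell-line vs ex vivo drug-class deviations
#'
#' Within each (disease, primary/met status, drug class) stratum containing
#' both modalities, computes the mean z difference (cell line minus ex
#' vivo), a permutation test, BH across strata, and per-class cross-disease
#' aggregate p-values via Fisher's method. Also runs the paired per-disease
#' comparison of normalized rankings between a "cell cycling" and a "cell
#' signaling" drug group (two-tailed paired t-test) when both are named in
#' `class_axes`.
#'
#' @param zmat samples x drugs z matrix
#' @param annotations sample annotations (model_type, oncotree_code,
#'   is_metastasis)
#' @param drug_groups named character: drug_id -> class
#' @param min_n minimum samples per modality per stratum
#' @param B permutations per stratum
#' @param class_axes optional list(cycling = class names,
#'   signaling = class names) for the paired comparison
#' @param seed RNG seed
#' @return list with `effects`, `fisher` (per class), and optionally
#'   `paired` (t-test of cycling vs signaling normalized ranks)
#' @export
cellline_vs_exvivo <- function(zmat, annotations, drug_groups, min_n = 3,
                               B = 499, class_axes = NULL, seed = 1) {
  ann <- annotations[match(rownames(zmat), annotations$sample_id), ]
  is_cl <- ann$model_type == "cell_line"
  met <- isTRUE_vec(ann$is_metastasis)
  grp_of <- drug_groups[colnames(zmat)]
  groups <- sort(unique(stats::na.omit(grp_of)))
  rows <- list()
  sidx <- 0L
  for (dis in sort(unique(ann$oncotree_code))) {
    for (st in c("primary", "met")) {
      in_stratum <- ann$oncotree_code == dis & (met == (st == "met"))
      for (g in groups) {
        jj <- which(grp_of == g)
        vc <- rowMeans(zmat[in_stratum & is_cl, jj, drop = FALSE],
                       na.rm = TRUE)
        ve <- rowMeans(zmat[in_stratum & !is_cl, jj, drop = FALSE],
                       na.rm = TRUE)
        vc <- vc[is.finite(vc)]; ve <- ve[is.finite(ve)]
        if (length(vc) < min_n || length(ve) < min_n) next
        sidx <- sidx + 1L
        pt <- permutation_test(vc, ve, B = B, min_n = min_n,
                               seed = seed + sidx)
        rows[[length(rows) + 1L]] <- data.frame(
          oncotree_code = dis, status = st, class = g,
          effect = pt$statistic, n_cell_line = length(vc),
          n_ex_vivo = length(ve), p = pt$p, stringsAsFactors = FALSE)
      }
    }
  }
  effects <- do.call(rbind, rows)
  if (is.null(effects)) stop("no stratum contains both modalities")
  effects$q <- bh_adjust(effects$p)

  fisher <- do.call(rbind, lapply(split(effects, effects$class), function(e) {
    data.frame(class = e$class[1], k = nrow(e),
               p_fisher = fisher_method(e$p),
               mean_effect = mean(e$effect), stringsAsFactors = FALSE)
  }))
  rownames(fisher) <- NULL

  out <- list(effects = effects, fisher = fisher)
  if (!is.null(class_axes)) {
    out$paired <- paired_rank_comparison(zmat, ann, grp_of, class_axes,
                                         is_cl, min_n)
  }
  out
}

#' Combine p-values by Fisher's method
#'
#' chi-square statistic -2 * sum(log p) on 2k degrees of freedom.
#' @param p p-values
#' @return combined p-value
#' @export
fisher_method <- function(p) {
  p <- p[is.finite(p)]
  if (length(p) == 0) return(NA_real_)
  stat <- -2 * sum(log(pmax(p, .Machine$double.xmin)))
  pchisq(stat, df = 2 * length(p), lower.tail = FALSE)
}

# Per-disease paired comparison: each sample's drugs are ranked by z within
# its own screened panel and divided by panel size; group means of these
# normalized ranks are contrasted between the two modalities, and the
# per-disease (cycling - signaling) deviations compared by paired t-test.
paired_rank_comparison <- function(zmat, ann, grp_of, class_axes, is_cl,
                                   min_n) {
  norm_rank <- zmat
  for (r in seq_len(nrow(zmat))) {
    v <- zmat[r, ]
    ok <- is.finite(v)
    norm_rank[r, ] <- NA_real_
    norm_rank[r, ok] <- rank(v[ok]) / sum(ok)
  }
  group_score <- function(rows, classes) {
    jj <- which(grp_of %in% classes)
    v <- rowMeans(norm_rank[rows, jj, drop = FALSE], na.rm = TRUE)
    v[is.finite(v)]
  }
  dis_list <- sort(unique(ann$oncotree_code))
  cyc_dev <- sig_dev <- numeric(0)
  for (dis in dis_list) {
    rows_cl <- which(ann$oncotree_code == dis & is_cl)
    rows_ev <- which(ann$oncotree_code == dis & !is_cl)
    if (length(rows_cl) < min_n || length(rows_ev) < min_n) next
    cyc <- mean(group_score(rows_cl, class_axes$cycling)) -
      mean(group_score(rows_ev, class_axes$cycling))
    sg <- mean(group_score(rows_cl, class_axes$signaling)) -
      mean(group_score(rows_ev, class_axes$signaling))
    if (is.finite(cyc) && is.finite(sg)) {
      cyc_dev <- c(cyc_dev, cyc); sig_dev <- c(sig_dev, sg)
    }
  }
  if (length(cyc_dev) < 3) return(NULL)
  tt <- t.test(cyc_dev, sig_dev, paired = TRUE)
  list(cycling_deviation = cyc_dev, signaling_deviation = sig_dev,
       p = tt$p.value, mean_difference = mean(cyc_dev - sig_dev))
}

#' k-nearest-neighbor analyses of sample embeddings
#'
#' Euclidean-distance neighbor analyses over an embedding matrix:
#' \describe{
#'   \item{disease_purity}{per sample, does the majority label among the k
#'     nearest neighbors (default k = 5) match its own label; per-label
#'     fraction with a two-sided binomial test against the label's
#'     prevalence, BH-adjusted. With `any_match = TRUE`, a sample counts as
#'     pure if any neighbor matches.}
#'   \item{mutation_enrichment}{per gene, the fraction of samples whose
#'     nearest neighbor is mutated, stratified by own mutation status;
#'     two-sided Fisher exact test + BH.}
#'   \item{tmb_correlation}{Pearson r between own TMB and nearest-neighbor
#'     TMB, with a seeded percentile bootstrap CI.}
#' }
#'
#' @param embeddings n x d matrix with rownames = sample ids
#' @param labels per-sample labels (diseases), named or aligned to rows
#' @param k neighbors (disease_purity)
#' @param mode analysis mode
#' @param mutations samples x genes 0/1 matrix (mutation_enrichment)
#' @param tmb per-sample numeric (tmb_correlation)
#' @param any_match alternative purity rule
#' @param modality optional per-sample modality factor (e.g. cell_line vs
#'   ex vivo); adds a global two-sided Fisher exact test comparing purity
#'   between modalities (attribute `modality_fisher_p`)
#' @param n_boot,ci_level,seed bootstrap settings
#' @return mode-dependent data.frame / list
#' @export
knn_label_analysis <- function(embeddings, labels = NULL, k = 5,
                               mode = c("disease_purity",
                                        "mutation_enrichment",
                                        "tmb_correlation"),
                               mutations = NULL, tmb = NULL,
                               any_match = FALSE, modality = NULL,
                               n_boot = 1000, ci_level = 0.95, seed = 1) {
  mode <- match.arg(mode)
  n <- nrow(embeddings)
  if (k >= n) stop("k must be smaller than the number of samples")
  D <- as.matrix(dist(embeddings))
  diag(D) <- Inf
  nn_idx <- apply(D, 1, which.min)

  if (mode == "disease_purity") {
    knn <- t(apply(D, 1, function(dd) order(dd)[seq_len(k)]))
    own <- labels
    match_vec <- vapply(seq_len(n), function(i) {
      nb <- own[knn[i, ]]
      if (any_match) own[i] %in% nb else {
        tab <- sort(table(nb), decreasing = TRUE)
        # majority with deterministic tie-break toward own label
        winners <- names(tab)[tab == max(tab)]
        if (own[i] %in% winners) TRUE else FALSE
      }
    }, TRUE)
    res <- do.call(rbind, lapply(sort(unique(own)), function(lb) {
      idx <- which(own == lb)
      prev <- length(idx) / n
      bt <- binom.test(sum(match_vec[idx]), length(idx), p = prev)
      data.frame(label = lb, n = length(idx),
                 purity = mean(match_vec[idx]), prevalence = prev,
                 p = bt$p.value, stringsAsFactors = FALSE)
    }))
    res$q <- bh_adjust(res$p)
    attr(res, "per_sample") <- match_vec
    if (!is.null(modality) && length(unique(modality)) == 2)
      attr(res, "modality_fisher_p") <-
        fisher.test(table(match_vec, modality))$p.value
    return(res)
  }

  if (mode == "mutation_enrichment") {
    if (is.null(mutations)) stop("mutations matrix required")
    res <- list()
    for (g in colnames(mutations)) {
      own <- mutations[, g]
      if (length(unique(own)) < 2) next  # single-class gene: skipped
      nb_mut <- mutations[nn_idx, g]
      tab <- table(factor(own, c(0, 1)), factor(nb_mut, c(0, 1)))
      ft <- fisher.test(tab)
      res[[length(res) + 1L]] <- data.frame(
        gene = g,
        frac_nb_mut_in_mut = mean(nb_mut[own == 1]),
        frac_nb_mut_in_wt = mean(nb_mut[own == 0]),
        odds_ratio = unname(ft$estimate), p = ft$p.value,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, res)
    if (!is.null(out)) out$q <- bh_adjust(out$p)
    return(out)
  }

  # tmb_correlation
  if (is.null(tmb)) stop("tmb vector required")
  nb_tmb <- tmb[nn_idx]
  r <- cor(tmb, nb_tmb)
  set.seed(seed)
  alpha <- (1 - ci_level) / 2
  boot <- replicate(n_boot, {
    idx <- sample.int(n, replace = TRUE)
    suppressWarnings(cor(tmb[idx], nb_tmb[idx]))
  })
  ct <- stats::cor.test(tmb, nb_tmb)
  list(r = r, p = ct$p.value,
       ci = quantile(boot, c(alpha, 1 - alpha), names = FALSE, na.rm = TRUE))
}
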