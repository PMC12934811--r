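test_that("BH adjustment matches hand step-up values and a brute-force oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(17)
  for (i in 1:25) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("permutation p-values hit the add-one floor and control size", {
  a <- 1:20 + 100; b <- 1:20   # separation no random permutation can match
  res <- permutation_test(a, b, B = 999, seed = 1)
  expect_equal(res$p, 1 / 1000)
  expect_error(permutation_test(1:2, 1:5), "minimum")
  expect_error(permutation_test(1:5, 1:5, B = 0), "B must be")
  # determinism
  set.seed(30); x <- rnorm(5); y <- rnorm(5)
  expect_identical(permutation_test(x, y, B = 99, seed = 3),
                   permutation_test(x, y, B = 99, seed = 3))

  # size under the null across seeded repeats
  set.seed(2)
  rej <- vapply(1:200, function(s) {
    x <- rnorm(8); y <- rnorm(8)
    permutation_test(x, y, B = 99, seed = s)$p <= 0.05
  }, TRUE)
  expect_lt(mean(rej), 0.05 + 2 * sqrt(0.05 * 0.95 / 200) + 0.01)
})

test_that("tissue-vs-rest recovers a planted shift and excludes small tissues", {
  set.seed(9)
  n_per <- 6
  tissues <- rep(c("T1", "T2", "T3"), each = n_per)
  samples <- paste0("p", seq_along(tissues))
  drugs <- paste0("d", 1:10)
  zm <- matrix(rnorm(length(samples) * 10, 0, 0.5), length(samples), 10,
               dimnames = list(samples, drugs))
  zm[tissues == "T1", "d1"] <- zm[tissues == "T1", "d1"] + 2
  ann <- data.frame(sample_id = samples, primary_site = tissues,
                    is_metastasis = FALSE)
  hits <- tissue_vs_rest(zm, ann, min_n = 3, fdr = 0.1)
  top <- hits[1, ]
  expect_equal(top$stratum, "T1"); expect_equal(top$unit, "d1")
  expect_true(top$hit); expect_equal(top$direction, "sensitive")

  # a tissue below the minimum is excluded
  ann2 <- ann; ann2$primary_site[ann2$primary_site == "T3"][1:4] <- "T2"
  hits2 <- tissue_vs_rest(zm, ann2, min_n = 3)
  expect_false("T3" %in% hits2$stratum)
})

test_that("metastatic resistance binomial test matches closed forms", {
  mk <- function(n_res, n_tot) {
    # n_tot diseases, each with one drug; n_res of them met-resistant
    rows <- list()
    for (i in seq_len(n_tot)) {
      shift <- if (i <= n_res) 0.2 else -0.2
      rows[[i]] <- data.frame(
        sample_id = paste0(c("prim", "met"), i),
        drug_id = "dX", auc = c(0.5, 0.5 + shift))
    }
    do.call(rbind, rows)
  }
  ann <- function(n_tot) data.frame(
    sample_id = c(paste0("prim", 1:n_tot), paste0("met", 1:n_tot)),
    oncotree_code = rep(paste0("DIS", 1:n_tot), 2),
    is_metastasis = rep(c(FALSE, TRUE), each = n_tot))
  res10 <- met_vs_primary_auc(mk(10, 10), ann(10))
  expect_equal(res10$binomial_p, 2^-10, tolerance = 1e-12)
  res5 <- met_vs_primary_auc(mk(5, 10), ann(10))
  expect_equal(res5$binomial_p,
               sum(dbinom(5:10, 10, 0.5)), tolerance = 1e-12)
  expect_equal(res5$binomial_p, 0.623, tolerance = 1e-3)
  # a disease lacking one stratum is excluded from the pairs
  summ <- mk(10, 10)
  summ <- summ[summ$sample_id != "met3", ]
  res <- met_vs_primary_auc(summ, ann(10))
  expect_equal(res$n_pairs, 9)
})

test_that("met-vs-primary group effects carry bootstrap CIs and cluster structure", {
  set.seed(4)
  n_dis <- 3; per <- 8
  ann <- do.call(rbind, lapply(seq_len(n_dis), function(d) data.frame(
    sample_id = paste0("D", d, "_", 1:(2 * per)),
    oncotree_code = paste0("DIS", d),
    is_metastasis = rep(c(TRUE, FALSE), each = per))))
  drugs <- paste0("d", 1:12)
  groups <- setNames(rep(c("gA", "gB", "gC"), each = 4), drugs)
  zm <- matrix(rnorm(nrow(ann) * 12, 0, 0.3), nrow(ann), 12,
               dimnames = list(ann$sample_id, drugs))
  met <- ann$is_metastasis
  zm[met, groups[colnames(zm)] == "gA"] <-
    zm[met, groups[colnames(zm)] == "gA"] + 1.5
  # make gC's drugs an exact copy of gB's so their difference vectors are
  # identical -> the clustering must place them on adjacent leaves
  zm[, groups[colnames(zm)] == "gC"] <- zm[, groups[colnames(zm)] == "gB"]
  res <- met_vs_primary_zdiff(zm, ann, groups, min_met = 3, n_boot = 300,
                              seed = 2)
  eff <- res$effects
  gA <- eff[eff$group == "gA", ]
  expect_true(all(gA$effect > 0))
  expect_true(all(gA$ci_lo > 0))   # CI excludes 0 for the planted group
  ord <- res$leaf_order
  expect_equal(abs(match("gB", ord) - match("gC", ord)), 1)
})

test_that("Fisher's method matches the chi-square closed form", {
  expect_equal(fisher_method(c(0.5, 0.5)),
               pchisq(-2 * (log(0.5) + log(0.5)), df = 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(fisher_method(c(0.5, 0.5)), 0.5966, tolerance = 1e-3)
  # k identical repeats: chi2(2k) tail at -2k log p
  p <- 0.07; k <- 5
  expect_equal(fisher_method(rep(p, k)),
               pchisq(-2 * k * log(p), 2 * k, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("cell-line deviations recover a planted class shift with Fisher aggregation", {
  set.seed(6)
  n_dis <- 3; per <- 6
  ann <- do.call(rbind, lapply(seq_len(n_dis), function(d) data.frame(
    sample_id = paste0("D", d, "_", 1:(2 * per)),
    oncotree_code = paste0("DIS", d),
    is_metastasis = FALSE,
    model_type = rep(c("cell_line", "PDO"), each = per))))
  drugs <- paste0("d", 1:8)
  groups <- setNames(rep(c("cycling", "signaling"), each = 4), drugs)
  zm <- matrix(rnorm(nrow(ann) * 8, 0, 0.3), nrow(ann), 8,
               dimnames = list(ann$sample_id, drugs))
  cl <- ann$model_type == "cell_line"
  zm[cl, groups[colnames(zm)] == "cycling"] <-
    zm[cl, groups[colnames(zm)] == "cycling"] + 1.2
  res <- cellline_vs_exvivo(zm, ann, groups, min_n = 3, B = 199,
                            class_axes = list(cycling = "cycling",
                                              signaling = "signaling"))
  cyc <- res$effects[res$effects$class == "cycling", ]
  expect_true(all(cyc$effect > 0))
  expect_true(all(cyc$q < 0.1))
  fis <- res$fisher
  expect_lt(fis$p_fisher[fis$class == "cycling"], 0.01)
  expect_gt(fis$p_fisher[fis$class == "signaling"], 0.05)
  expect_false(is.null(res$paired))
  expect_lt(res$paired$p, 0.05)
  expect_gt(res$paired$mean_difference, 0)
})

test_that("k-NN purity, mutation and TMB analyses behave on constructed fixtures", {
  set.seed(8)
  # perfectly separated clusters -> purity 1 everywhere
  emb <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 10), 10, 2))
  rownames(emb) <- paste0("p", 1:20)
  lab <- rep(c("A", "B"), each = 10)
  pur <- knn_label_analysis(emb, lab, k = 5, mode = "disease_purity")
  expect_equal(pur$purity, c(1, 1))

  # shuffled labels -> purity near prevalence
  lab_sh <- sample(lab)
  pur_sh <- knn_label_analysis(emb, lab_sh, k = 5, mode = "disease_purity")
  expect_true(all(pur_sh$p > 1e-4))

  expect_error(knn_label_analysis(emb, lab, k = 20), "k must be")

  # TMB shared with neighbors through a latent coordinate
  lat <- seq(0, 100, length.out = 40)
  emb2 <- cbind(lat, 0); rownames(emb2) <- paste0("q", 1:40)
  tmb <- lat
  res <- knn_label_analysis(emb2, mode = "tmb_correlation", tmb = tmb,
                            n_boot = 100)
  expect_gt(res$r, 0.99)

  # mutation enrichment: mutants cluster -> neighbor of a mutant is mutant
  mut <- matrix(0L, 20, 2, dimnames = list(rownames(emb), c("g1", "g0")))
  mut[1:10, "g1"] <- 1L
  enr <- knn_label_analysis(emb, mode = "mutation_enrichment",
                            mutations = mut)
  expect_equal(enr$gene, "g1")  # g0 single-class: skipped
  expect_equal(enr$frac_nb_mut_in_mut, 1)
  expect_equal(enr$frac_nb_mut_in_wt, 0)
  expect_lt(enr$q, 0.01)
})
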