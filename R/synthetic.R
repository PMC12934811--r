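#' Configuration for the synthetic multi-study screen generator
#'
#' Defines the conditions a generated cohort of ex vivo / cell-line studies
#' emulates: per-study drug panels with partial overlap, per-study dose grids
#' (optionally a single-dose study), monotone Hill-type ground-truth curves,
#' tissue-by-mechanism sensitivity effects, mutation-driven effects,
#' metastatic resistance shifts, cell-line class shifts, and affine per-study
#' batch effects on the viability scale.
#'
#' @param n_studies number of studies
#' @param samples_per_study samples per study
#' @param n_drugs total drug pool size
#' @param n_tissues number of primary tissue sites (one disease per tissue)
#' @param n_mechanisms number of drug mechanism classes
#' @param doses_per_curve doses per curve in multi-dose studies
#' @param single_dose_studies indices of studies screened at one dose
#' @param cell_line_studies indices of studies whose samples are cell lines
#' @param panel_fraction fraction of the drug pool in each study's panel
#' @param conc_range_log10 log10(uM) range from which panel dose ranges draw
#' @param hill_slope_range range of Hill slopes
#' @param ic50_log10_range range of baseline per-drug log10 IC50 (uM)
#' @param tissue_mech_effects data.frame (tissue, mechanism, shift) of
#'   planted log10-IC50 shifts; negative = more sensitive
#' @param tissue_mech_effect_sd sd of background tissue-by-mechanism shifts
#' @param mutation_effects data.frame (gene, mechanism, shift) of
#'   mutation-driven log10-IC50 shifts in carriers
#' @param mutation_prevalence per-gene mutation probability
#' @param n_mut_genes number of mutated genes simulated
#' @param met_fraction fraction of metastatic samples
#' @param met_resistance_shift log10-IC50 shift added to metastatic samples
#' @param cellline_class_shift named numeric: mechanism -> log10-IC50 shift
#'   applied to cell-line samples (negative = cell lines more sensitive)
#' @param sample_noise_sd sd of per-sample log10-IC50 noise
#' @param batch_offset_sd,batch_scale_sd sd of per-study affine batch effects
#'   on the viability scale (offset additive, scale multiplicative around 1)
#' @param noise_sd sd of measurement noise on the viability scale
#' @param bottom_range range of Hill curve bottoms (top is fixed at 1)
#' @param seed mandatory RNG seed
#' @return a `synth_config` list
#' @export
synth_config <- function(n_studies = 6,
                         samples_per_study = 30,
                         n_drugs = 120,
                         n_tissues = 8,
                         n_mechanisms = 10,
                         doses_per_curve = 5,
                         single_dose_studies = n_studies,
                         cell_line_studies = integer(0),
                         panel_fraction = 0.5,
                         conc_range_log10 = c(-3, 1),
                         hill_slope_range = c(0.8, 2),
                         ic50_log10_range = c(-2.5, 0.5),
                         tissue_mech_effects = default_planted_effects(),
                         tissue_mech_effect_sd = 0,
                         mutation_effects = default_mutation_effects(),
                         mutation_prevalence = 0.25,
                         n_mut_genes = 6,
                         met_fraction = 0.3,
                         met_resistance_shift = 0.4,
                         cellline_class_shift = c(mech01 = -0.6, mech02 = 0.6),
                         sample_noise_sd = 0.25,
                         batch_offset_sd = 0.08,
                         batch_scale_sd = 0.08,
                         noise_sd = 0.07,
                         bottom_range = c(0, 0.3),
                         seed = 1) {
  if (is.null(seed)) stop("seed is mandatory")
  if (samples_per_study < 1) stop("samples_per_study must be >= 1")
  stopifnot(noise_sd >= 0, batch_offset_sd >= 0, batch_scale_sd >= 0,
            tissue_mech_effect_sd >= 0, sample_noise_sd >= 0)
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  cfg
}

#' @rdname synth_config
#' @export
default_planted_effects <- function() {
  data.frame(tissue = c("tissue1", "tissue3", "tissue5"),
             mechanism = c("mech01", "mech04", "mech07"),
             shift = c(-1.5, -1.5, 1.5),
             stringsAsFactors = FALSE)
}

#' @rdname synth_config
#' @export
default_mutation_effects <- function() {
  data.frame(gene = c("gene1", "gene2"),
             mechanism = c("mech02", "mech05"),
             shift = c(-1.2, 1.0),
             stringsAsFactors = FALSE)
}

#' Simulate the sample cohort
#'
#' Assigns each sample a study, tissue (uniformly cycled so tissues are
#' balanced), disease (one per tissue), primary/metastatic status, model type
#' (cell_line for configured studies, else PDO), and metastatic site.
#'
#' @param cfg a `synth_config`
#' @return data.frame of sample annotations plus a `tissue` column
#' @export
simulate_cohort <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_studies * cfg$samples_per_study
  study <- rep(paste0("study", seq_len(cfg$n_studies)),
               each = cfg$samples_per_study)
  tissues <- paste0("tissue", seq_len(cfg$n_tissues))
  tissue <- rep_len(tissues, n)
  # permute within study so tissue is not confounded with sample index
  for (s in unique(study)) {
    idx <- which(study == s)
    tissue[idx] <- sample(tissue[idx])
  }
  is_met <- runif(n) < cfg$met_fraction
  met_site <- ifelse(is_met, sample(tissues, n, replace = TRUE), NA_character_)
  model_type <- ifelse(study %in% paste0("study", cfg$cell_line_studies),
                       "cell_line", "PDO")
  is_met[model_type == "cell_line" & is.na(met_site)] <- FALSE
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             study_id = study,
             oncotree_code = toupper(sub("tissue", "DIS", tissue)),
             primary_site = tissue,
             metastatic_site = met_site,
             is_metastasis = is_met,
             model_type = model_type,
             tmb = stats::rpois(n, 10),
             stringsAsFactors = FALSE)
}

#' Simulate ground-truth Hill dose-response curves
#'
#' log10 IC50 for sample i, drug j is the drug's baseline plus the planted
#' and background tissue-by-mechanism effects, mutation effects for carried
#' genes, the metastatic resistance shift, the cell-line class shift, and
#' per-sample noise. Viability follows a descending Hill curve with top 1:
#' `v(c) = bottom + (1 - bottom) / (1 + 10^(slope * (log10 c - log10 IC50)))`.
#'
#' @param cfg a `synth_config`
#' @param cohort output of [simulate_cohort()]
#' @return a `synth_truth` list: drug table, mutation matrix, IC50/slope/
#'   bottom matrices (samples x drugs), batch offsets/scales
#' @export
simulate_true_curves <- function(cfg, cohort) {
  set.seed(cfg$seed + 1L)
  n <- nrow(cohort)
  mechs <- sprintf("mech%02d", seq_len(cfg$n_mechanisms))
  drugs <- data.frame(
    drug_id = sprintf("drug%03d", seq_len(cfg$n_drugs)),
    mechanism = rep_len(mechs, cfg$n_drugs),
    base_ic50 = runif(cfg$n_drugs, cfg$ic50_log10_range[1],
                      cfg$ic50_log10_range[2]),
    slope = runif(cfg$n_drugs, cfg$hill_slope_range[1],
                  cfg$hill_slope_range[2]),
    bottom = runif(cfg$n_drugs, cfg$bottom_range[1], cfg$bottom_range[2]),
    stringsAsFactors = FALSE)

  genes <- paste0("gene", seq_len(cfg$n_mut_genes))
  mut <- matrix(rbinom(n * cfg$n_mut_genes, 1, cfg$mutation_prevalence),
                n, cfg$n_mut_genes, dimnames = list(cohort$sample_id, genes))

  tm_bg <- matrix(rnorm(cfg$n_tissues * cfg$n_mechanisms, 0,
                        cfg$tissue_mech_effect_sd),
                  cfg$n_tissues, cfg$n_mechanisms,
                  dimnames = list(paste0("tissue", seq_len(cfg$n_tissues)),
                                  mechs))
  if (nrow(cfg$tissue_mech_effects) > 0) {
    for (r in seq_len(nrow(cfg$tissue_mech_effects))) {
      e <- cfg$tissue_mech_effects[r, ]
      if (e$tissue %in% rownames(tm_bg) && e$mechanism %in% colnames(tm_bg))
        tm_bg[e$tissue, e$mechanism] <- tm_bg[e$tissue, e$mechanism] + e$shift
    }
  }

  ic50 <- matrix(rep(drugs$base_ic50, each = n), n, cfg$n_drugs,
                 dimnames = list(cohort$sample_id, drugs$drug_id))
  ic50 <- ic50 + tm_bg[cbind(rep(match(cohort$primary_site, rownames(tm_bg)),
                                 cfg$n_drugs),
                             rep(match(drugs$mechanism, colnames(tm_bg)),
                                 each = n))]
  if (nrow(cfg$mutation_effects) > 0) {
    for (r in seq_len(nrow(cfg$mutation_effects))) {
      e <- cfg$mutation_effects[r, ]
      if (!e$gene %in% colnames(mut)) next
      hit_drugs <- which(drugs$mechanism == e$mechanism)
      carriers <- which(mut[, e$gene] == 1)
      ic50[carriers, hit_drugs] <- ic50[carriers, hit_drugs] + e$shift
    }
  }
  ic50[cohort$is_metastasis, ] <- ic50[cohort$is_metastasis, ] +
    cfg$met_resistance_shift
  if (length(cfg$cellline_class_shift) > 0) {
    cl <- cohort$model_type == "cell_line"
    for (m in names(cfg$cellline_class_shift)) {
      jj <- which(drugs$mechanism == m)
      ic50[cl, jj] <- ic50[cl, jj] + cfg$cellline_class_shift[[m]]
    }
  }
  ic50 <- ic50 + matrix(rnorm(n * cfg$n_drugs, 0, cfg$sample_noise_sd),
                        n, cfg$n_drugs)

  offsets <- rnorm(cfg$n_studies, 0, cfg$batch_offset_sd)
  scales <- exp(rnorm(cfg$n_studies, 0, cfg$batch_scale_sd))
  names(offsets) <- names(scales) <- paste0("study", seq_len(cfg$n_studies))

  structure(list(cfg = cfg, cohort = cohort, drugs = drugs,
                 mutations = mut, tissue_mech = tm_bg, ic50 = ic50,
                 batch_offset = offsets, batch_scale = scales),
            class = "synth_truth")
}

#' Evaluate a descending Hill curve
#'
#' @param log10_conc log10 concentration(s), uM
#' @param ic50_log10 log10 IC50
#' @param slope Hill slope (> 0)
#' @param bottom lower asymptote (top fixed at 1)
#' @return viability values
#' @export
hill_viability <- function(log10_conc, ic50_log10, slope, bottom = 0) {
  bottom + (1 - bottom) / (1 + 10^(slope * (log10_conc - ic50_log10)))
}

#' Emit an observed screen dataset from ground truth
#'
#' Subsamples a per-study drug panel, draws a per-study dose grid (one
#' concentration per curve in single-dose studies), and observes
#' `clip(scale_s * truth + offset_s + eps, 0, 2)` with Gaussian measurement
#' noise.
#'
#' @param cfg a `synth_config`
#' @param truth output of [simulate_true_curves()]
#' @return a `screen_dataset`; ground truth is attached as attribute `truth`
#' @export
emit_dataset <- function(cfg, truth) {
  set.seed(cfg$seed + 2L)
  cohort <- truth$cohort
  drugs <- truth$drugs
  panel_size <- max(1L, round(cfg$panel_fraction * cfg$n_drugs))
  if (panel_size > cfg$n_drugs) stop("infeasible panel configuration")
  recs <- vector("list", cfg$n_studies)
  for (s in seq_len(cfg$n_studies)) {
    sid <- paste0("study", s)
    panel <- sort(sample(drugs$drug_id, panel_size))
    n_dose <- if (s %in% cfg$single_dose_studies) 1L else cfg$doses_per_curve
    lo <- runif(1, cfg$conc_range_log10[1], cfg$conc_range_log10[1] + 0.5)
    hi <- runif(1, cfg$conc_range_log10[2] - 0.5, cfg$conc_range_log10[2])
    log_doses <- if (n_dose == 1L) mean(c(lo, hi)) else
      seq(lo, hi, length.out = n_dose)
    samp <- cohort$sample_id[cohort$study_id == sid]
    grid <- expand.grid(sample_id = samp, drug_id = panel,
                        log_conc = log_doses, stringsAsFactors = FALSE)
    i <- match(grid$sample_id, cohort$sample_id)
    j <- match(grid$drug_id, drugs$drug_id)
    v_true <- hill_viability(grid$log_conc, truth$ic50[cbind(i, j)],
                             drugs$slope[j], drugs$bottom[j])
    v_obs <- truth$batch_scale[[sid]] * v_true + truth$batch_offset[[sid]] +
      rnorm(nrow(grid), 0, cfg$noise_sd)
    recs[[s]] <- data.frame(study_id = sid, sample_id = grid$sample_id,
                            drug_id = grid$drug_id,
                            concentration_uM = 10^grid$log_conc,
                            viability = pmin(pmax(v_obs, 0), 2),
                            stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  drug_ann <- data.frame(drug_id = drugs$drug_id,
                         canonical_name = drugs$drug_id,
                         aliases = I(as.list(drugs$drug_id)),
                         mechanisms = I(as.list(drugs$mechanism)),
                         targets = I(replicate(nrow(drugs), character(0),
                                               simplify = FALSE)),
                         stringsAsFactors = FALSE)
  ds <- screen_dataset(records, samples = cohort, drugs = drug_ann)
  attr(ds, "truth") <- truth
  ds
}

#' Simulate omics consistent with the drug-response ground truth
#'
#' Emits the mutation table already used for the curve effects, plus an
#' expression matrix generated as pathway loadings times pathway activities
#' with Gaussian noise. The first pathway's activity is coupled to the first
#' mutation-effect gene (carriers shifted by `coupling`), so expression,
#' mutations and drug response share a common axis, and a GMT of pathway
#' memberships.
#'
#' @param cfg a `synth_config`
#' @param truth output of [simulate_true_curves()]
#' @param n_genes expressed genes
#' @param n_pathways pathways
#' @param genes_per_pathway members per pathway
#' @param coupling activity shift in carriers of the coupled mutation
#' @param expr_noise_sd expression noise sd
#' @return list with `mutations` (long data.frame), `expression`
#'   (genes x samples matrix), `gene_sets` (named list), `activities`
#' @export
simulate_omics <- function(cfg, truth, n_genes = 200, n_pathways = 5,
                           genes_per_pathway = 20, coupling = 1.5,
                           expr_noise_sd = 0.5) {
  set.seed(cfg$seed + 3L)
  n <- nrow(truth$cohort)
  acts <- matrix(rnorm(n * n_pathways), n, n_pathways)
  coupled_gene <- if (nrow(cfg$mutation_effects) > 0)
    cfg$mutation_effects$gene[1] else NULL
  if (!is.null(coupled_gene) && coupled_gene %in% colnames(truth$mutations))
    acts[, 1] <- acts[, 1] + coupling * truth$mutations[, coupled_gene]
  gene_names <- sprintf("EG%04d", seq_len(n_genes))
  load_mat <- matrix(0, n_genes, n_pathways)
  gene_sets <- list()
  for (p in seq_len(n_pathways)) {
    members <- ((p - 1) * genes_per_pathway + 1):(p * genes_per_pathway)
    load_mat[members, p] <- runif(genes_per_pathway, 0.5, 1.5)
    gene_sets[[paste0("PATHWAY_", p)]] <- gene_names[members]
  }
  expr <- load_mat %*% t(acts) +
    matrix(rnorm(n_genes * n, 0, expr_noise_sd), n_genes, n)
  expr <- expr - min(expr)  # keep counts-like nonnegative scale
  dimnames(expr) <- list(gene_names, truth$cohort$sample_id)
  mut_long <- data.frame(
    sample_id = rep(rownames(truth$mutations), ncol(truth$mutations)),
    gene = rep(colnames(truth$mutations), each = nrow(truth$mutations)),
    deleterious = as.vector(truth$mutations) == 1,
    stringsAsFactors = FALSE)
  list(mutations = mut_long, expression = expr, gene_sets = gene_sets,
       activities = acts)
}

#' Generate a complete synthetic screen dataset
#'
#' Convenience wrapper running [simulate_cohort()], [simulate_true_curves()]
#' and [emit_dataset()].
#'
#' @param cfg a `synth_config`
#' @return a `screen_dataset` with attribute `truth`
#' @export
simulate_screens <- function(cfg = synth_config()) {
  cohort <- simulate_cohort(cfg)
  truth <- simulate_true_curves(cfg, cohort)
  emit_dataset(cfg, truth)
}

#' Write a GMT gene-set file
#'
#' @param gene_sets named list of character vectors
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(n) {
    paste(c(n, "synthetic", gene_sets[[n]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Thin wrapper over [fgsea::gmtPathways()].
#' @param path GMT path
#' @return named list of character vectors
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
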