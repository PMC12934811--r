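#' @importFrom stats median mad sd cor quantile rnorm runif rbinom setNames
#'   t.test wilcox.test binom.test ks.test p.adjust hclust as.dist prcomp
#'   fisher.test pchisq pnorm qnorm glm predict binomial aggregate dist
#' @importFrom utils read.delim write.table head tail
NULL

REQUIRED_VIABILITY_COLS <- c("study_id", "sample_id", "drug_id",
                             "concentration_uM", "viability")

MODEL_TYPES <- c("PDC", "PDO", "PDXC", "cell_line")

#' Construct a harmonized screen dataset
#'
#' Bundles long-format viability records with sample and drug annotation
#' tables into a validated `screen_dataset` object. A "curve" is the set of
#' all records sharing (study_id, sample_id, drug_id); replicates at the same
#' concentration are kept as separate records and indexed.
#'
#' @param records data.frame with columns study_id, sample_id, drug_id,
#'   concentration_uM (positive, micromolar), viability (fraction of control,
#'   in [0, 2]) and optionally replicate.
#' @param samples optional data.frame of sample annotations (sample_id,
#'   study_id, oncotree_code, primary_site, metastatic_site, is_metastasis,
#'   model_type, tmb).
#' @param drugs optional data.frame of drug annotations (drug_id,
#'   canonical_name, aliases, mechanisms, targets, soc_diseases; list or
#'   semicolon-separated columns).
#' @param strict logical; if TRUE (default) invalid rows are an error, if
#'   FALSE they are dropped with a message.
#' @return A `screen_dataset`: list with elements `records`, `samples`,
#'   `drugs`.
#' @export
screen_dataset <- function(records, samples = NULL, drugs = NULL,
                           strict = TRUE) {
  missing_cols <- setdiff(REQUIRED_VIABILITY_COLS, names(records))
  if (length(missing_cols) > 0) {
    stop("viability table is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  records$concentration_uM <- as.numeric(records$concentration_uM)
  records$viability <- as.numeric(records$viability)

  bad_conc <- !is.finite(records$concentration_uM) | records$concentration_uM <= 0
  bad_via <- !is.finite(records$viability) | records$viability < 0 |
    records$viability > 2
  bad <- bad_conc | bad_via
  if (any(bad)) {
    rows <- which(bad)
    msg <- sprintf(
      "%d invalid row(s): rows %s (concentration must be > 0, viability in [0, 2])",
      length(rows), paste(head(rows, 10L), collapse = ", "))
    if (strict) stop(msg) else {
      message("dropping ", msg)
      records <- records[!bad, , drop = FALSE]
    }
  }

  if (!"replicate" %in% names(records) || all(is.na(records$replicate))) {
    key <- paste(records$study_id, records$sample_id, records$drug_id,
                 records$concentration_uM, sep = "\r")
    records$replicate <- stats::ave(seq_along(key), key,
                                    FUN = seq_along) - 1L
  }
  key <- paste(records$study_id, records$sample_id, records$drug_id,
               records$concentration_uM, records$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    if (strict) stop("duplicate (study, sample, drug, concentration, replicate) at rows ",
                     paste(head(dup, 10L), collapse = ", "))
    records <- records[!duplicated(key), , drop = FALSE]
  }
  rownames(records) <- NULL

  if (!is.null(samples)) {
    samples <- as.data.frame(samples, stringsAsFactors = FALSE)
    if (!is.null(samples$model_type)) {
      unknown <- setdiff(unique(samples$model_type), MODEL_TYPES)
      if (length(unknown) > 0)
        stop("unknown model_type value(s): ", paste(unknown, collapse = ", "))
    }
    if (all(c("is_metastasis", "metastatic_site") %in% names(samples))) {
      met <- isTRUE_vec(samples$is_metastasis)
      site_present <- !is.na(samples$metastatic_site) &
        nzchar(as.character(samples$metastatic_site))
      if (any(met != site_present)) {
        stop("metastatic_site must be present iff is_metastasis for sample(s): ",
             paste(head(samples$sample_id[met != site_present], 5L),
                   collapse = ", "))
      }
    }
    missing_s <- setdiff(unique(records$sample_id), samples$sample_id)
    if (length(missing_s) > 0)
      stop("records reference unannotated sample(s): ",
           paste(head(missing_s, 5L), collapse = ", "))
  }
  if (!is.null(drugs)) {
    drugs <- as.data.frame(drugs, stringsAsFactors = FALSE)
    missing_d <- setdiff(unique(records$drug_id), drugs$drug_id)
    if (length(missing_d) > 0)
      stop("records reference unannotated drug(s): ",
           paste(head(missing_d, 5L), collapse = ", "))
  }

  structure(list(records = records, samples = samples, drugs = drugs),
            class = "screen_dataset")
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  tolower(as.character(x)) %in% c("true", "1", "yes")
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat("screen_dataset:",
      nrow(x$records), "measurements,",
      length(unique(x$records$sample_id)), "samples,",
      length(unique(x$records$drug_id)), "drugs,",
      length(unique(x$records$study_id)), "studies\n")
  invisible(x)
}

#' Number of unique dose-response curves in a dataset
#'
#' A curve is the set of all records sharing (study_id, sample_id, drug_id).
#' @param ds a `screen_dataset`
#' @return integer count
#' @export
n_curves <- function(ds) {
  length(unique(curve_key(ds$records)))
}

curve_key <- function(records) {
  paste(records$study_id, records$sample_id, records$drug_id, sep = "\r")
}

#' Read a long-format viability table
#'
#' Expects tab-separated text with columns study_id, sample_id, drug_id,
#' concentration_uM, viability and optionally replicate. gzip-compressed
#' files are read transparently.
#'
#' @param path path to the viability TSV (optionally .gz)
#' @param samples_path,drugs_path optional annotation TSV paths
#' @param strict validation mode; see [screen_dataset()]
#' @return a `screen_dataset`
#' @export
load_viability_table <- function(path, samples_path = NULL, drugs_path = NULL,
                                 strict = TRUE) {
  records <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  samples <- if (!is.null(samples_path))
    read_sample_annotations(samples_path) else NULL
  drugs <- if (!is.null(drugs_path)) read_drug_annotations(drugs_path) else NULL
  screen_dataset(records, samples = samples, drugs = drugs, strict = strict)
}

#' @rdname load_viability_table
#' @export
read_sample_annotations <- function(path) {
  s <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if ("is_metastasis" %in% names(s)) s$is_metastasis <- isTRUE_vec(s$is_metastasis)
  if ("metastatic_site" %in% names(s)) {
    s$metastatic_site[!is.na(s$metastatic_site) &
                        !nzchar(s$metastatic_site)] <- NA_character_
  }
  if ("tmb" %in% names(s)) s$tmb <- suppressWarnings(as.integer(s$tmb))
  s
}

#' @rdname load_viability_table
#' @export
read_drug_annotations <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("aliases", "mechanisms", "targets", "soc_diseases")) {
    if (col %in% names(d)) d[[col]] <- strsplit(ifelse(is.na(d[[col]]), "",
                                                       d[[col]]), ";",
                                                fixed = TRUE)
  }
  d
}

#' Write a screen dataset to tab-separated files
#'
#' The inverse of [load_viability_table()]: `load(write(ds))` reproduces the
#' dataset record-for-record. List-valued annotation columns are written
#' semicolon-joined; absent optional fields become empty cells.
#'
#' @param ds a `screen_dataset`
#' @param path output path for the viability TSV
#' @param samples_path,drugs_path optional annotation output paths
#' @return `path`, invisibly
#' @export
write_dataset <- function(ds, path, samples_path = NULL, drugs_path = NULL) {
  write_tsv <- function(df, p) {
    for (col in names(df)) {
      if (is.list(df[[col]]))
        df[[col]] <- vapply(df[[col]], function(x) paste(x, collapse = ";"), "")
      if (is.logical(df[[col]])) df[[col]] <- ifelse(df[[col]], "TRUE", "FALSE")
    }
    con <- if (grepl("\\.gz$", p)) gzfile(p, "wb") else file(p, "wb")
    on.exit(close(con))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "", fileEncoding = "UTF-8")
  }
  write_tsv(ds$records, path)
  if (!is.null(samples_path) && !is.null(ds$samples))
    write_tsv(ds$samples, samples_path)
  if (!is.null(drugs_path) && !is.null(ds$drugs))
    write_tsv(ds$drugs, drugs_path)
  invisible(path)
}

#' Summarize a multi-study screen dataset
#'
#' Computes per-study counts, the per-drug study-occupancy histogram, the
#' percentage of drugs screened in exactly one study, and pairwise study
#' drug-panel overlap fractions (Jaccard on panels).
#'
#' @param ds a `screen_dataset`
#' @return list with `per_study`, `occupancy` (table of number of studies per
#'   drug), `single_study_pct`, `overlap` (study-by-study matrix)
#' @export
summarize_dataset <- function(ds) {
  r <- ds$records
  if (nrow(r) == 0) stop("cannot summarize an empty dataset")
  per_study <- do.call(rbind, lapply(split(r, r$study_id), function(s) {
    data.frame(study_id = s$study_id[1],
               n_samples = length(unique(s$sample_id)),
               n_drugs = length(unique(s$drug_id)),
               n_measurements = nrow(s),
               n_curves = length(unique(curve_key(s))),
               stringsAsFactors = FALSE)
  }))
  rownames(per_study) <- NULL

  drug_study <- unique(r[, c("drug_id", "study_id")])
  occ <- table(table(drug_study$drug_id))
  n_drugs <- length(unique(drug_study$drug_id))
  single_pct <- 100 * sum(table(drug_study$drug_id) == 1) / n_drugs

  studies <- sort(unique(r$study_id))
  panels <- lapply(studies, function(s) unique(r$drug_id[r$study_id == s]))
  overlap <- matrix(0, length(studies), length(studies),
                    dimnames = list(studies, studies))
  for (i in seq_along(studies)) for (j in seq_along(studies)) {
    overlap[i, j] <- length(intersect(panels[[i]], panels[[j]])) /
      length(union(panels[[i]], panels[[j]]))
  }

  list(per_study = per_study, occupancy = occ,
       n_drugs = n_drugs, single_study_pct = single_pct, overlap = overlap)
}

#' Build per-drug dose grids
#'
#' Each drug gets K grid points uniformly spaced in log10(micromolar) over
#' its observed concentration range pooled across studies. Drugs observed at
#' a single concentration c get a grid over
#' [log10(c) - span, log10(c) + span].
#'
#' @param ds a `screen_dataset`
#' @param K number of grid points (>= 2)
#' @param single_dose_span half-width in log10 units for single-dose drugs
#' @return named list drug_id -> numeric vector of K log10 concentrations
#' @export
build_dose_grids <- function(ds, K = 10, single_dose_span = 1.0) {
  if (K < 2) stop("K must be >= 2")
  lc <- log10(ds$records$concentration_uM)
  sp <- split(lc, ds$records$drug_id)
  lapply(sp, function(x) {
    lo <- min(x); hi <- max(x)
    if (hi - lo < 1e-12) { lo <- lo - single_dose_span; hi <- hi + single_dose_span }
    seq(lo, hi, length.out = K)
  })
}

#' Extract one curve's sorted doses and viabilities
#'
#' @param ds a `screen_dataset`
#' @param study_id,sample_id,drug_id curve identifiers
#' @return data.frame sorted by concentration
#' @export
get_curve <- function(ds, study_id, sample_id, drug_id) {
  r <- ds$records
  cur <- r[r$study_id == study_id & r$sample_id == sample_id &
             r$drug_id == drug_id, , drop = FALSE]
  cur[order(cur$concentration_uM, cur$replicate), , drop = FALSE]
}
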