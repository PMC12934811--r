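#' Normalized area under a dose-response curve
#'
#' Trapezoidal integral of viability over log10 concentration, divided by the
#' width of the concentration range, so a flat curve at viability 1 (no
#' effect) has AUC 1 and lower values mean more cytotoxicity.
#'
#' @param viability viabilities at the grid points
#' @param log10_conc strictly increasing log10 concentrations (same length)
#' @return normalized AUC
#' @export
auc <- function(viability, log10_conc) {
  if (length(viability) < 2) stop("AUC needs at least 2 points")
  if (any(diff(log10_conc) <= 0)) stop("doses must be strictly increasing")
  sum(viability * trap_weights(log10_conc))
}

# trapezoid quadrature weights normalized by the range width
trap_weights <- function(g) {
  K <- length(g)
  dx <- diff(g)
  w <- c(dx[1] / 2, (dx[-(K - 1)] + dx[-1]) / 2, dx[K - 1] / 2)
  if (K == 2) w <- c(dx / 2, dx / 2)
  w / (g[K] - g[1])
}

#' Interpolated IC50 of a monotone non-increasing curve
#'
#' Returns the log-linear interpolated first crossing of viability 0.5.
#' Curves that never reach 0.5 are censored `above_max` (reported at the top
#' of the range); curves already below 0.5 at the first point are censored
#' `below_min` (reported at the bottom).
#'
#' @param viability monotone non-increasing viabilities
#' @param log10_conc strictly increasing log10 concentrations
#' @param tol monotonicity tolerance
#' @return list with `ic50_log10` and `censored` ("" | "above_max" |
#'   "below_min")
#' @export
ic50 <- function(viability, log10_conc, tol = 1e-8) {
  if (any(diff(viability) > tol)) stop("IC50 requires a monotone non-increasing curve")
  K <- length(viability)
  if (min(viability) > 0.5)
    return(list(ic50_log10 = log10_conc[K], censored = "above_max"))
  if (viability[1] < 0.5)
    return(list(ic50_log10 = log10_conc[1], censored = "below_min"))
  k <- which(viability <= 0.5)[1]
  if (viability[k] == 0.5)
    return(list(ic50_log10 = log10_conc[k], censored = ""))
  # crossing between k-1 and k
  v0 <- viability[k - 1]; v1 <- viability[k]
  w <- (v0 - 0.5) / (v0 - v1)
  list(ic50_log10 = log10_conc[k - 1] + w * (log10_conc[k] - log10_conc[k - 1]),
       censored = "")
}

#' Robust empirical null of a sample's AUC distribution
#'
#' Estimates the "typical drug" AUC distribution for one sample, ignoring
#' outliers (drugs the sample is truly sensitive or resistant to): mu0 is
#' the median, sigma0 the scaled MAD (consistent for a Gaussian). With
#' `refine = TRUE`, one pass re-estimates mean/sd on values with provisional
#' |z| <= 2.5.
#'
#' @param aucs the sample's AUC values across drugs
#' @param min_n minimum number of drugs required
#' @param refine logical; one-pass trimmed refinement
#' @param trim_z provisional-|z| trim threshold
#' @return list with mu0, sigma0, n_drugs_used, trimmed_fraction
#' @export
fit_empirical_null <- function(aucs, min_n = 20, refine = TRUE,
                               trim_z = 2.5) {
  aucs <- aucs[is.finite(aucs)]
  if (length(aucs) < min_n)
    stop("cannot fit empirical null: ", length(aucs), " < min_n = ", min_n)
  mu0 <- median(aucs)
  sigma0 <- mad(aucs)  # constant = 1.4826 by default
  if (sigma0 <= 0) stop("degenerate spread: MAD of AUCs is zero")
  trimmed <- 0
  n_used <- length(aucs)
  if (refine) {
    z <- (aucs - mu0) / sigma0
    keep <- abs(z) <= trim_z
    trimmed <- mean(!keep)
    if (sum(keep) >= min_n) {
      mu0 <- mean(aucs[keep])
      sigma0 <- sd(aucs[keep])
      n_used <- sum(keep)
      if (!is.finite(sigma0) || sigma0 <= 0)
        stop("degenerate spread after refinement")
    }
  }
  list(mu0 = mu0, sigma0 = sigma0, n_drugs_used = n_used,
       trimmed_fraction = trimmed)
}

#' De-batched per-(sample, drug) sensitivity z-scores
#'
#' Standardizes each AUC against its sample's robust empirical null:
#' `z = (mu0 - auc) / sigma0`, so positive z means the drug is more
#' cytotoxic than the sample's typical drug. Because every sample is scored
#' against its own null, study-level assay differences cancel.
#'
#' @param summaries a `curve_summary` data.frame (sample_id, drug_id, auc,
#'   optionally source)
#' @param min_n minimum drugs per sample for a defined null
#' @param refine passed to [fit_empirical_null()]
#' @return data.frame with sample_id, drug_id, z, provenance; per-sample
#'   nulls in attribute `nulls`
#' @export
zscore_debatch <- function(summaries, min_n = 20, refine = TRUE) {
  sp <- split(seq_len(nrow(summaries)), summaries$sample_id)
  nulls <- list()
  z <- rep(NA_real_, nrow(summaries))
  for (sid in names(sp)) {
    idx <- sp[[sid]]
    nl <- tryCatch(fit_empirical_null(summaries$auc[idx], min_n = min_n,
                                      refine = refine),
                   error = function(e) NULL)
    if (is.null(nl)) next  # null undefined: cells stay NA
    nulls[[sid]] <- nl
    z[idx] <- (nl$mu0 - summaries$auc[idx]) / nl$sigma0
  }
  out <- data.frame(sample_id = summaries$sample_id,
                    drug_id = summaries$drug_id, z = z,
                    provenance = if ("source" %in% names(summaries))
                      summaries$source else "observed_fit",
                    stringsAsFactors = FALSE)
  attr(out, "nulls") <- nulls
  out
}

#' Global (pooled) z-scores of AUCs — comparison arm only
#'
#' Standardizes every AUC against the pooled mean and sd across all samples
#' and studies. Provided to demonstrate that pooled standardization does not
#' remove study-level batch effects, unlike [zscore_debatch()].
#'
#' @param summaries a `curve_summary` data.frame
#' @return data.frame with sample_id, drug_id, z
#' @export
global_zscore <- function(summaries) {
  v <- summaries$auc
  if (sum(is.finite(v)) < 2) stop("global z-scoring needs >= 2 values")
  s <- sd(v, na.rm = TRUE)
  if (s == 0) stop("constant AUCs: global z undefined")
  data.frame(sample_id = summaries$sample_id, drug_id = summaries$drug_id,
             z = (mean(v, na.rm = TRUE) - v) / s, stringsAsFactors = FALSE)
}

#' Pivot a long z-score table to a samples x drugs matrix
#'
#' @param z long data.frame (sample_id, drug_id, z)
#' @return numeric matrix, samples as rows
#' @export
zscore_matrix <- function(z) {
  samples <- sort(unique(z$sample_id)); drugs <- sort(unique(z$drug_id))
  m <- matrix(NA_real_, length(samples), length(drugs),
              dimnames = list(samples, drugs))
  m[cbind(match(z$sample_id, samples), match(z$drug_id, drugs))] <- z$z
  m
}
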