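## Minimal-residual-disease handling: categorical bins, continuous
## log-scale modelling, the threshold scan and per-trisomy distribution
## shifts. MRD values are fractions of cells (0.0001 = 0.01%). Zeros sit
## below the assay detection floor; before log transformation they are
## replaced by floor/2.

MRD_LEVELS <- c("0", "0 to <0.01", "0.01 to <0.1", "0.1 to <1.0", ">=1.0",
                "not available")

#' Categorise an MRD fraction into reporting bins
#'
#' Bins (in percent): exactly 0; (0, 0.01); \[0.01, 0.1); \[0.1, 1.0);
#' >= 1.0. The boundary 0.01% belongs to the "0.01 to <0.1" bin, and so on.
#' Missing values map to `"not available"`.
#'
#' @param fraction numeric vector of MRD fractions in `[0, 1]`, `NA`
#'   allowed.
#' @return factor with levels `"0"`, `"0 to <0.01"`, `"0.01 to <0.1"`,
#'   `"0.1 to <1.0"`, `">=1.0"`, `"not available"`.
#' @export
categorize_mrd <- function(fraction) {
  stopifnot(all(fraction >= 0 & fraction <= 1, na.rm = TRUE))
  pct <- fraction * 100
  out <- ifelse(is.na(pct), "not available",
         ifelse(pct == 0, "0",
         ifelse(pct < 0.01, "0 to <0.01",
         ifelse(pct < 0.1, "0.01 to <0.1",
         ifelse(pct < 1, "0.1 to <1.0", ">=1.0")))))
  factor(out, levels = MRD_LEVELS)
}

#' @keywords internal
neg_log10_mrd <- function(mrd, floor = 1e-5) {
  -log10(ifelse(mrd == 0, floor / 2, mrd))
}

#' Hazard ratio per log reduction of MRD
#'
#' Cox model of the endpoint on `-log10(MRD)` (zeros replaced by half the
#' detection floor), so a hazard ratio below 1 encodes benefit per log
#' reduction of residual disease.
#'
#' @param mrd MRD fractions (`NA` = unavailable; such patients are dropped).
#' @param time,status endpoint vectors.
#' @param floor detection floor used for zeros (fraction of cells).
#' @return one-row data.frame as from [cox_fit()].
#' @export
mrd_log_hr <- function(mrd, time, status, floor = 1e-5) {
  stopifnot(length(mrd) == length(time), length(time) == length(status))
  ok <- !is.na(mrd)
  if (!any(ok)) stop("all MRD values are missing", call. = FALSE)
  if (sum(status[ok]) < 10) stop("fewer than 10 events with MRD available",
                                 call. = FALSE)
  x <- neg_log10_mrd(mrd[ok], floor)
  if (stats::var(x) == 0) stop("MRD has no variance", call. = FALSE)
  cox_fit(time[ok], status[ok], data.frame(log_reduction = x))
}

#' Scan MRD thresholds for the optimal discriminative cutoff
#'
#' Candidate cutoffs are the unique observed MRD values. Each cutoff
#' dichotomises the cohort into `< cutoff` versus `>= cutoff`; cutoffs
#' leaving less than `min_arm_fraction` of patients in either arm are
#' dropped. The discrimination statistic is the log-rank chi-square on the
#' endpoint; the optimum is the admissible cutoff with the largest
#' statistic, ties going to the smaller cutoff. Because the dichotomies
#' depend only on ranks, the scan is invariant to monotone rescaling of the
#' MRD values.
#'
#' @param mrd MRD fractions (`NA` dropped).
#' @param time,status endpoint vectors.
#' @param min_arm_fraction minimum fraction of patients in each arm.
#' @return object of class `threshold_scan`: `thresholds` data.frame
#'   (`cutoff`, `chi2`, `p`, `n_low`, `n_high`), `optimal`, `optimal_chi2`,
#'   and `flat` (TRUE when even the best split is not significant at 0.05,
#'   signalling an unstable optimum).
#' @export
scan_thresholds <- function(mrd, time, status, min_arm_fraction = 0.10) {
  stopifnot(length(mrd) == length(time), length(time) == length(status),
            min_arm_fraction >= 0, min_arm_fraction < 0.5)
  ok <- !is.na(mrd)
  mrd <- mrd[ok]; time <- time[ok]; status <- status[ok]
  n <- length(mrd)
  cuts <- sort(unique(mrd))
  if (length(cuts) < 2) stop("need at least two distinct MRD values", call. = FALSE)
  n_high <- vapply(cuts, function(ct) sum(mrd >= ct), integer(1))
  n_low <- n - n_high
  admissible <- n_low >= max(1, ceiling(min_arm_fraction * n)) &
                n_high >= max(1, ceiling(min_arm_fraction * n))
  cuts <- cuts[admissible]
  if (length(cuts) == 0)
    stop("no cutoff satisfies the minimum arm fraction", call. = FALSE)
  rows <- lapply(cuts, function(ct) {
    grp <- mrd >= ct
    lr <- tryCatch(logrank(time, status, grp),
                   error = function(e) list(chi2 = NA_real_, p = NA_real_))
    data.frame(cutoff = ct, chi2 = lr$chi2, p = lr$p,
               n_low = sum(!grp), n_high = sum(grp))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[!is.na(tab$chi2), , drop = FALSE]
  if (nrow(tab) == 0) stop("no admissible cutoff could be tested", call. = FALSE)
  best <- which(tab$chi2 == max(tab$chi2))[1]  # ties: smaller cutoff (sorted)
  structure(list(thresholds = tab, optimal = tab$cutoff[best],
                 optimal_chi2 = tab$chi2[best],
                 flat = tab$chi2[best] < stats::qchisq(0.95, 1)),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat("<threshold_scan> ", nrow(x$thresholds), " admissible cutoffs; optimal ",
      format(x$optimal, digits = 3), " (", format(x$optimal * 100, digits = 3),
      "%), chi2 = ", round(x$optimal_chi2, 2),
      if (x$flat) " [flat profile: optimum unstable]" else "", "\n", sep = "")
  invisible(x)
}

#' MRD distribution shifts by trisomy
#'
#' For each chromosome, compares the log-MRD distribution of gain carriers
#' against non-carriers with a rank-based (Wilcoxon) test and reports the
#' direction of the shift. Chromosomes whose carrier or non-carrier stratum
#' has fewer than `min_n` patients with MRD available are skipped with a
#' warning.
#'
#' @inheritParams screen_trisomies
#' @param mrd MRD fractions (`NA` dropped).
#' @param min_n minimum per-stratum size.
#' @param floor detection floor for zeros.
#' @param alpha significance threshold for the `significant` flag.
#' @return data.frame: `chromosome`, `n_carrier`, `n_other`,
#'   `median_log10_carrier`, `median_log10_other`, `direction`
#'   (`"higher"`/`"lower"` MRD in carriers), `p`, `significant`.
#' @export
mrd_distribution_by_trisomy <- function(gains, mrd, min_n = 20, floor = 1e-5,
                                        alpha = 0.05) {
  g <- as_gain_matrix(gains)
  stopifnot(nrow(g) == length(mrd))
  ok <- !is.na(mrd)
  g <- g[ok, , drop = FALSE]
  x <- log10(ifelse(mrd[ok] == 0, floor / 2, mrd[ok]))
  skipped <- character()
  rows <- lapply(colnames(g), function(ch) {
    carrier <- g[, ch] > 0
    if (sum(carrier) < min_n || sum(!carrier) < min_n) {
      skipped <<- c(skipped, ch)
      return(NULL)
    }
    wt <- stats::wilcox.test(x[carrier], x[!carrier], exact = FALSE)
    data.frame(chromosome = ch,
               n_carrier = sum(carrier), n_other = sum(!carrier),
               median_log10_carrier = stats::median(x[carrier]),
               median_log10_other = stats::median(x[!carrier]),
               direction = ifelse(stats::median(x[carrier]) >=
                                  stats::median(x[!carrier]), "higher", "lower"),
               p = wt$p.value, stringsAsFactors = FALSE)
  })
  if (length(skipped) > 0)
    warning("stratum too small, skipped: ", paste(skipped, collapse = ", "),
            call. = FALSE)
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no chromosome had large enough strata", call. = FALSE)
  out$significant <- out$p < alpha
  out
}
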