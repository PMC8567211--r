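## Stratified reporting: association tests, relapse-capture proportions,
## classifier comparison, and Table-1-style stratified summaries.
## Percentages are rounded half-up to whole percent, matching clinical-table
## presentation.

#' Exact test of association for a contingency table
#'
#' Fisher's exact test for 2x2 tables; for larger tables an exact
#' Monte-Carlo p-value with a fixed seed (so reruns are deterministic).
#'
#' @param contingency matrix of non-negative integer counts, at least 2x2.
#' @param mc_seed,mc_b seed and replicate count for the Monte-Carlo p-value
#'   on tables larger than 2x2.
#' @return the two-sided p-value.
#' @export
categorical_association <- function(contingency, mc_seed = 1L, mc_b = 1e5) {
  tab <- as.matrix(contingency)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("table must be at least 2x2", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty margin in contingency table", call. = FALSE)
  if (nrow(tab) == 2 && ncol(tab) == 2) {
    stats::fisher.test(tab)$p.value
  } else {
    set.seed(mc_seed)
    stats::fisher.test(tab, simulate.p.value = TRUE, B = mc_b)$p.value
  }
}

#' Proportion of all relapses captured per group
#'
#' For each group (possibly overlapping classifier memberships), the share
#' of all relapses that occurred within the group, as a whole percent.
#'
#' @param groups either a factor/character vector (a partition) or a named
#'   list of logical membership vectors (overlapping groups).
#' @param relapsed logical/0-1 relapse indicator.
#' @return named integer percents.
#' @export
relapse_capture <- function(groups, relapsed) {
  relapsed <- as.logical(relapsed)
  total <- sum(relapsed)
  if (total < 1) stop("no relapses in the data", call. = FALSE)
  if (is.list(groups)) {
    vapply(groups, function(g) {
      stopifnot(length(g) == length(relapsed))
      proportion_pct(sum(relapsed & as.logical(g)), total)
    }, integer(1))
  } else {
    stopifnot(length(groups) == length(relapsed))
    vapply(split(relapsed, groups), function(r) proportion_pct(sum(r), total),
           integer(1))
  }
}

#' @keywords internal
auc_binary <- function(score, outcome) {
  pos <- score[outcome == 1]; neg <- score[outcome == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Compare risk classifiers on a cohort
#'
#' For each classifier (a good-risk membership vector) reports group size,
#' the 10-year relapse rate inside the group, the unadjusted and
#' MRD-adjusted hazard ratios of membership versus the remaining patients,
#' Harrell's C-index, and the AUC against the binary relapse-by-horizon
#' outcome (patients censored before the horizon without relapse are
#' excluded from the AUC). Classifiers with an empty (or full) group are
#' skipped with a warning.
#'
#' @param cohort a cohort data.frame with `time_relapse`, `ind_relapse` and
#'   (for the adjusted model) `mrd_fraction` columns.
#' @param classifiers named list of logical good-risk membership vectors;
#'   by default built from the gain columns: the UKALL-HeH profile, COG
#'   triple trisomy and COG double trisomy.
#' @param horizon rate/AUC horizon in years.
#' @param mrd_floor detection floor for the adjusted model.
#' @return data.frame, one row per classifier.
#' @export
compare_classifiers <- function(cohort, classifiers = NULL, horizon = 10,
                                mrd_floor = 1e-5) {
  stopifnot(all(c("time_relapse", "ind_relapse") %in% names(cohort)))
  if (is.null(classifiers)) {
    g <- gain_matrix_from_cohort(cohort)
    classifiers <- list(
      UKALL_HEH = ukall_heh_calls(g) == "GOOD",
      COG_TT = g[, "4"] > 0 & g[, "10"] > 0 & g[, "17"] > 0,
      COG_DT = g[, "4"] > 0 & g[, "10"] > 0)
  }
  t <- cohort$time_relapse; s <- cohort$ind_relapse
  n <- nrow(cohort)
  has_mrd <- "mrd_fraction" %in% names(cohort) && any(!is.na(cohort$mrd_fraction))
  rows <- lapply(names(classifiers), function(nm) {
    memb <- as.logical(classifiers[[nm]])
    stopifnot(length(memb) == n)
    if (all(memb) || !any(memb)) {
      warning("classifier ", nm, " has an empty group; skipped", call. = FALSE)
      return(NULL)
    }
    r <- suppressWarnings(rate_at(km_fit(t[memb], s[memb]), horizon,
                                  as_failure = TRUE))
    hr_un <- cox_fit(t, s, data.frame(good = as.numeric(memb)))
    hr_adj <- if (has_mrd) {
      ok <- !is.na(cohort$mrd_fraction)
      fit <- cox_fit(t[ok], s[ok],
                     data.frame(good = as.numeric(memb[ok]),
                                log_red = neg_log10_mrd(cohort$mrd_fraction[ok],
                                                        mrd_floor)))
      fit$hr[fit$term == "good"]
    } else NA_real_
    # binary relapse-by-horizon outcome; early censored without event excluded
    known <- s == 1 & t <= horizon | t >= horizon
    y10 <- as.integer(s == 1 & t <= horizon)[known]
    risk <- as.numeric(!memb)
    data.frame(classifier = nm, n_good = sum(memb),
               pct_good = proportion_pct(sum(memb), n),
               relapse_rate_10y = r$rate,
               hr_vs_rest = hr_un$hr, hr_vs_rest_p = hr_un$p,
               hr_mrd_adjusted = hr_adj,
               c_index = concordance_index(risk, t, s),
               auc = auc_binary(risk[known], y10),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Table-1-style stratified summary
#'
#' Counts and whole percents of each stratum level by risk group, with an
#' exact association p-value per stratum variable, and an outcome block of
#' rates at the horizon and hazard ratios per endpoint.
#'
#' @param cohort cohort data.frame.
#' @param group name of the grouping column (e.g. `"ukall_heh"`).
#' @param strata character vector of categorical column names to stratify.
#' @param endpoints named list of `c(time_col, ind_col)` pairs; defaults to
#'   relapse, EFS and OS columns when present.
#' @param horizon rate horizon in years.
#' @return object of class `stratified_table`: list with `strata` (one
#'   data.frame per variable with counts, percents and `p`) and `outcomes`.
#' @export
stratified_table <- function(cohort, group, strata, endpoints = NULL,
                             horizon = 10) {
  stopifnot(group %in% names(cohort), all(strata %in% names(cohort)))
  gr <- as.factor(cohort[[group]])
  strata_out <- lapply(strata, function(v) {
    tab <- table(cohort[[v]], gr)
    tot <- rowSums(tab)
    out <- data.frame(level = rownames(tab), total = as.integer(tot))
    for (gl in colnames(tab)) {
      out[[gl]] <- as.integer(tab[, gl])
      out[[paste0(gl, "_pct")]] <- proportion_pct(tab[, gl], sum(tab[, gl]))
    }
    attr(out, "p") <- categorical_association(as.matrix(tab))
    out
  })
  names(strata_out) <- strata
  if (is.null(endpoints)) {
    endpoints <- list()
    for (ep in c("relapse", "efs", "os")) {
      tc <- paste0("time_", ep); ic <- paste0("ind_", ep)
      if (all(c(tc, ic) %in% names(cohort))) endpoints[[ep]] <- c(tc, ic)
    }
  }
  outcomes <- lapply(names(endpoints), function(ep) {
    tc <- endpoints[[ep]][1]; ic <- endpoints[[ep]][2]
    as_fail <- ep == "relapse"
    per_group <- lapply(levels(gr), function(gl) {
      idx <- gr == gl
      r <- suppressWarnings(rate_at(km_fit(cohort[[tc]][idx], cohort[[ic]][idx]),
                                    horizon, as_failure = as_fail))
      data.frame(endpoint = ep, group = gl, n = sum(idx),
                 events = sum(cohort[[ic]][idx]),
                 rate = r$rate, ci_low = r$ci[1], ci_high = r$ci[2])
    })
    out <- do.call(rbind, per_group)
    if (nlevels(gr) == 2) {
      ref <- levels(gr)[1]
      cx <- cox_fit(cohort[[tc]], cohort[[ic]],
                    data.frame(grp = as.numeric(gr != ref)))
      out$hr <- cx$hr; out$hr_p <- cx$p
    }
    out
  })
  structure(list(strata = strata_out, outcomes = do.call(rbind, outcomes),
                 group = group, horizon = horizon),
            class = "stratified_table")
}

#' @export
print.stratified_table <- function(x, ...) {
  cat("<stratified_table> by", x$group, "\n")
  for (v in names(x$strata)) {
    cat("--", v, sprintf("(p = %.3g)", attr(x$strata[[v]], "p")), "\n")
    print(x$strata[[v]], row.names = FALSE)
  }
  cat("-- outcomes at", x$horizon, "years\n")
  print(x$outcomes, row.names = FALSE)
  invisible(x)
}
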