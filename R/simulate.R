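## Synthetic-cohort generator.
##
## Reproduces the statistical structure the analysis machinery assumes:
## chromosome gains are drawn from a correlated-binary model (Gaussian
## copula with block-exchangeable correlation specified on the binary phi
## scale), total gains are rejection-constrained to the high-hyperdiploid
## range (modal number 51-65), relapse times are exponential with
## group-specific rates set by the good/poor decision rule, independent
## death-in-remission and administrative censoring generate the three
## endpoints, and end-of-induction MRD is log-normal with configurable
## per-trisomy shifts and a configurable hazard link.

#' Default simulation configuration
#'
#' Marginal gain probabilities are high for the chromosomes that dominate
#' high-hyperdiploid aneuploidy (X, 4, 6, 10, 14, 17, 18, 21), moderate for
#' 5, 8, 9, 11, 12, 20 and 22 and low elsewhere, calibrated so that the
#' median modal chromosome number is about 55 and the good:poor split is
#' about 4:1 (most patients carry both +17 and +18). The poor-risk
#' relapse hazard ratio defaults to 3.8 and the good-risk 10-year relapse
#' probability to 5%; MRD is log10-normal (mean -4.25, sd 1.25 on the
#' fraction scale, detection floor 1e-5, 13% missing) with a hazard link of
#' 0.85 per log reduction of measured MRD. Per-trisomy MRD shifts
#' (`mrd_shift`) default to none: shifted-MRD cohorts are an opt-in
#' configuration because a shift combined with the MRD hazard link induces
#' real off-rule hazard effects for the shifted chromosomes.
#'
#' @param ... named overrides of any configuration entry (see Details).
#' @details Configuration entries: `n`, `seed`, `gain_prob` (named length-24
#'   vector), `blocks` (list of `list(chromosomes=, phi=)`), `rule_hazard`
#'   (`good_p10`, `poor_hr`), `death_in_remission_rate`,
#'   `relapse_death_prob`, `post_relapse_death_rate`, `mrd_mu`, `mrd_sigma`,
#'   `mrd_floor`, `mrd_missing_prob`, `mrd_shift` (named log10 shifts for
#'   gain carriers), `mrd_effect` (`type = "per_log"` with `hr`, or
#'   `type = "threshold"` with `cutoff` and `hr`, or `type = "none"`),
#'   `followup_years`, `accrual_jitter`.
#' @return a `SimulationConfig` list.
#' @export
default_config <- function(...) {
  gp <- c("1" = 0.048, "2" = 0.048, "3" = 0.048, "4" = 0.82, "5" = 0.22,
          "6" = 0.86, "7" = 0.048, "8" = 0.28, "9" = 0.28, "10" = 0.68,
          "11" = 0.28, "12" = 0.28, "13" = 0.048, "14" = 0.82, "15" = 0.048,
          "16" = 0.048, "17" = 0.72, "18" = 0.79, "19" = 0.048, "20" = 0.22,
          "21" = 0.94, "22" = 0.28, "X" = 0.78, "Y" = 0.04)
  cfg <- list(
    n = 725, seed = 2003, gain_prob = gp,
    blocks = list(
      list(chromosomes = c("17", "18"), phi = 0.25),
      list(chromosomes = c("4", "6", "10", "21"), phi = 0.30),
      list(chromosomes = c("X", "14"), phi = 0.25),
      list(chromosomes = c("8", "9", "11", "12", "22"), phi = 0.25),
      list(chromosomes = c("2", "3", "16"), phi = 0.20)),
    rule_hazard = list(good_p10 = 0.05, poor_hr = 3.8),
    death_in_remission_rate = 0.003,
    relapse_death_prob = 0.4, post_relapse_death_rate = 0.5,
    mrd_mu = -4.25, mrd_sigma = 1.25, mrd_floor = 1e-5,
    mrd_missing_prob = 0.13,
    mrd_shift = numeric(),
    mrd_effect = list(type = "per_log", hr = 0.85),
    followup_years = 12, accrual_jitter = 3)
  overrides <- list(...)
  if (length(overrides) > 0) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad) > 0 || is.null(names(overrides)))
      stop("unknown configuration entries: ", paste(bad, collapse = ", "),
           call. = FALSE)
    # wholesale replacement: recursive merging would silently skip unnamed
    # nested lists such as `blocks`
    cfg[names(overrides)] <- overrides
  }
  cfg
}

#' @keywords internal
validate_config <- function(cfg) {
  stopifnot(is.list(cfg), cfg$n >= 1,
            all(CHROM_LABELS %in% names(cfg$gain_prob)),
            all(cfg$gain_prob >= 0 & cfg$gain_prob <= 1),
            cfg$rule_hazard$good_p10 > 0, cfg$rule_hazard$good_p10 < 1,
            cfg$rule_hazard$poor_hr > 0,
            cfg$mrd_missing_prob >= 0, cfg$mrd_missing_prob <= 1,
            cfg$followup_years > 0, cfg$accrual_jitter >= 0,
            cfg$accrual_jitter < cfg$followup_years)
  blocked <- unlist(lapply(cfg$blocks, `[[`, "chromosomes"))
  if (anyDuplicated(blocked))
    stop("blocks must partition a subset of chromosome labels", call. = FALSE)
  assert_chrom_labels(blocked)
  cfg
}

# latent (tetrachoric-scale) correlation giving binary phi between two gains
#' @keywords internal
latent_rho <- function(p1, p2, phi) {
  t1 <- stats::qnorm(1 - p1); t2 <- stats::qnorm(1 - p2)
  target <- p1 * p2 + phi * sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  joint <- function(r) as.numeric(mvtnorm::pmvnorm(
    lower = c(t1, t2), upper = c(Inf, Inf),
    corr = matrix(c(1, r, r, 1), 2)))
  lo <- joint(-0.999); hi <- joint(0.999)
  if (target > hi + 1e-10 || target < lo - 1e-10) return(NA_real_)
  stats::uniroot(function(r) joint(r) - target, c(-0.999, 0.999),
                 tol = 1e-9)$root
}

#' @keywords internal
latent_corr_matrix <- function(cfg) {
  R <- diag(length(CHROM_LABELS))
  dimnames(R) <- list(CHROM_LABELS, CHROM_LABELS)
  for (b in seq_along(cfg$blocks)) {
    blk <- cfg$blocks[[b]]
    chs <- blk$chromosomes
    for (i in seq_along(chs)) for (j in seq_along(chs)) {
      if (i < j) {
        r <- latent_rho(cfg$gain_prob[[chs[i]]], cfg$gain_prob[[chs[j]]],
                        blk$phi)
        if (is.na(r))
          stop("infeasible phi ", blk$phi, " in block ", b, " ({",
               paste(chs, collapse = ","), "}) for chromosomes ", chs[i],
               " and ", chs[j], call. = FALSE)
        R[chs[i], chs[j]] <- r; R[chs[j], chs[i]] <- r
      }
    }
    ev <- eigen(R[chs, chs, drop = FALSE], symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("block ", b, " ({", paste(chs, collapse = ","),
           "}) yields a non-positive-definite latent correlation", call. = FALSE)
  }
  R
}

#' Generate a synthetic high-hyperdiploid cohort
#'
#' Draws correlated binary chromosome gains (Gaussian copula, rejection step
#' enforcing 51-65 total chromosomes), derives the latent good/poor label
#' with the UKALL-HeH rule, simulates relapse times as exponential with the
#' configured good-risk 10-year probability and poor-risk hazard ratio
#' (optionally modulated by MRD), adds independent death-in-remission,
#' post-relapse mortality and administrative censoring with staggered entry,
#' and draws log-normal MRD with per-trisomy shifts and missingness. Output
#' is bit-reproducible under a fixed seed.
#'
#' @param config a configuration from [default_config()].
#' @param n,seed convenience overrides of the config entries.
#' @return a data.frame of class `heh_cohort`: `patient_id`, `sex`, `age`,
#'   `wcc`, `gain_1` .. `gain_Y`, `modal_low`, `modal_high`, `mrd_fraction`,
#'   `time_relapse`/`ind_relapse`, `time_efs`/`ind_efs`,
#'   `time_os`/`ind_os`, plus latent truth columns `true_risk` and
#'   `true_log10_mrd` for recovery tests. The configuration is attached as
#'   attribute `"config"`.
#' @export
generate_cohort <- function(config = default_config(), n = NULL, seed = NULL) {
  cfg <- validate_config(config)
  if (!is.null(n)) cfg$n <- n
  if (!is.null(seed)) cfg$seed <- seed
  set.seed(cfg$seed)
  n <- cfg$n

  R <- latent_corr_matrix(cfg)
  L <- chol(R)
  thr <- stats::qnorm(1 - cfg$gain_prob[CHROM_LABELS])

  gains <- matrix(0L, 0, length(CHROM_LABELS))
  while (nrow(gains) < n) {
    b <- max(1000L, ceiling((n - nrow(gains)) * 1.3))
    Z <- matrix(stats::rnorm(b * length(CHROM_LABELS)), b) %*% L
    G <- t(t(Z) > thr)
    tot <- rowSums(G)
    gains <- rbind(gains, G[tot >= 5 & tot <= 19, , drop = FALSE] + 0L)
  }
  gains <- gains[seq_len(n), , drop = FALSE]
  colnames(gains) <- CHROM_LABELS
  modal <- 46L + rowSums(gains)
  good <- ukall_heh_calls(gains) == "GOOD"

  shift <- numeric(n)
  sh <- cfg$mrd_shift[names(cfg$mrd_shift) %in% CHROM_LABELS]
  if (length(sh) > 0)
    shift <- as.vector(gains[, names(sh), drop = FALSE] %*% sh)
  log10mrd <- cfg$mrd_mu + shift + stats::rnorm(n, 0, cfg$mrd_sigma)

  lam <- -log(1 - cfg$rule_hazard$good_p10) / 10 *
    ifelse(good, 1, cfg$rule_hazard$poor_hr)
  # the hazard link acts on measured MRD (zeros at floor/2), the same scale
  # the analysis models, so the configured effect is the recoverable truth
  mrd_measured <- pmin(10^log10mrd, 1)
  mrd_measured[mrd_measured < cfg$mrd_floor] <- 0
  eff <- cfg$mrd_effect
  if (identical(eff$type, "per_log")) {
    x <- neg_log10_mrd(mrd_measured, cfg$mrd_floor)
    lam <- lam * eff$hr^(x - (-cfg$mrd_mu))
  } else if (identical(eff$type, "threshold")) {
    lam <- lam * ifelse(mrd_measured >= eff$cutoff, eff$hr, 1)
  }

  mrd <- mrd_measured
  mrd[stats::runif(n) < cfg$mrd_missing_prob] <- NA

  t_rel <- stats::rexp(n, lam)
  t_dir <- stats::rexp(n, cfg$death_in_remission_rate)
  fatal <- stats::runif(n) < cfg$relapse_death_prob
  t_drel <- ifelse(fatal, t_rel + stats::rexp(n, cfg$post_relapse_death_rate),
                   Inf)
  cens <- cfg$followup_years - stats::runif(n, 0, cfg$accrual_jitter)

  t_death <- pmin(t_dir, t_drel)
  time_relapse <- pmin(t_rel, t_dir, cens)
  ind_relapse <- as.integer(t_rel <= pmin(t_dir, cens))
  t_ev <- pmin(t_rel, t_death)
  time_efs <- pmin(t_ev, cens)
  ind_efs <- as.integer(t_ev <= cens)
  time_os <- pmin(t_death, cens)
  ind_os <- as.integer(t_death <= cens)

  age_band <- sample(1:3, n, replace = TRUE, prob = c(0.85, 0.10, 0.05))
  age <- c(stats::runif(n, 1, 10), stats::runif(n, 10, 15),
           stats::runif(n, 15, 20))[(age_band - 1) * n + seq_len(n)]
  wcc <- 10^stats::rnorm(n, 1.055, 0.50)
  sex <- ifelse(stats::runif(n) < 0.48, "F", "M")

  out <- data.frame(patient_id = sprintf("P%05d", seq_len(n)),
                    sex = sex, age = round(age, 2), wcc = round(wcc, 1),
                    stringsAsFactors = FALSE)
  gm <- as.data.frame(gains)
  names(gm) <- paste0("gain_", CHROM_LABELS)
  out <- cbind(out, gm,
               data.frame(modal_low = modal, modal_high = modal,
                          mrd_fraction = mrd,
                          time_relapse = time_relapse, ind_relapse = ind_relapse,
                          time_efs = time_efs, ind_efs = ind_efs,
                          time_os = time_os, ind_os = ind_os,
                          true_risk = ifelse(good, "GOOD", "POOR"),
                          true_log10_mrd = log10mrd,
                          stringsAsFactors = FALSE))
  attr(out, "config") <- cfg
  class(out) <- c("heh_cohort", "data.frame")
  out
}

#' Write a cohort CSV with a sidecar JSON of true parameters
#'
#' @param cohort an `heh_cohort`.
#' @param path output CSV path.
#' @param params_path optional path for the JSON sidecar recording the
#'   generating configuration (for recovery tests).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, params_path = NULL) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  if (!is.null(params_path)) {
    cfg <- attr(cohort, "config")
    jsonlite::write_json(cfg, params_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a cohort CSV
#'
#' @param path CSV written by [write_cohort()] or following the same schema.
#' @return a data.frame of class `heh_cohort`.
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("heh_cohort", "data.frame")
  out
}
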