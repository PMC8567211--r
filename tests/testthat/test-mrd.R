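test_that("categorize_mrd partitions a dense grid straddling every bin edge", {
  expect_equal(as.character(categorize_mrd(0)), "0")
  expect_equal(as.character(categorize_mrd(1e-4)), "0.01 to <0.1")   # boundary
  expect_equal(as.character(categorize_mrd(0.02)), ">=1.0")
  expect_equal(as.character(categorize_mrd(NA)), "not available")
  # independent binning oracle on a grid straddling each printed edge
  grid <- sort(c(10^seq(-7, -0.5, by = 0.25),
                 1e-4 * (1 + c(-1e-9, 0, 1e-9)),
                 1e-3 * (1 + c(-1e-9, 0, 1e-9)),
                 1e-2 * (1 + c(-1e-9, 0, 1e-9))))
  oracle <- cut(grid * 100, breaks = c(-Inf, 0.01, 0.1, 1, Inf), right = FALSE,
                labels = c("0 to <0.01", "0.01 to <0.1", "0.1 to <1.0", ">=1.0"))
  got <- categorize_mrd(grid)
  expect_equal(as.character(got), as.character(oracle))
  # exactly one bin per value
  expect_false(anyNA(got))
  expect_error(categorize_mrd(1.5))
})

test_that("mrd_log_hr encodes benefit per log reduction and validates input", {
  co <- generate_cohort(default_config(), n = 5000, seed = 101)
  fit <- mrd_log_hr(co$mrd_fraction, co$time_relapse, co$ind_relapse)
  expect_true(fit$lcl < 0.85 && 0.85 < fit$ucl)
  expect_lt(fit$hr, 1)
  # null: hazard independent of MRD
  co0 <- generate_cohort(default_config(mrd_effect = list(type = "none")),
                         n = 5000, seed = 102)
  fit0 <- mrd_log_hr(co0$mrd_fraction, co0$time_relapse, co0$ind_relapse)
  expect_true(fit0$lcl < 1 && 1 < fit0$ucl)
  expect_error(mrd_log_hr(rep(NA_real_, 10), rexp(10), rbinom(10, 1, 1)),
               "missing")
  expect_error(mrd_log_hr(rep(1e-4, 50), rexp(50) + 1, rep(1, 50)),
               "variance")
})

test_that("scan_thresholds recovers a planted cutoff between separated groups", {
  # two well-separated log-normal groups, quantised to a quarter-log grid as
  # qPCR reporting does, with the hazard jumping at a planted cutoff
  set.seed(7)
  n <- 2000
  raw <- c(rnorm(n / 2, -5, 0.5), rnorm(n / 2, -2.75, 0.5))
  mrd <- 10^(round(raw * 4) / 4)
  cutoff <- 10^-3.75
  lam <- ifelse(mrd >= cutoff, 0.02 * 2.5, 0.02)
  t <- rexp(n, lam); s <- as.integer(t <= 10); t <- pmin(t, 10)
  scan <- scan_thresholds(mrd, t, s)
  cuts <- scan$thresholds$cutoff
  target <- which.min(abs(log10(cuts) - log10(cutoff)))
  expect_lte(abs(which(cuts == scan$optimal) - target), 1)
  expect_false(scan$flat)
})

test_that("scan_thresholds is invariant to monotone rescaling", {
  set.seed(8)
  n <- 400
  mrd <- 10^rnorm(n, -4, 1)
  t <- rexp(n, 0.02 * ifelse(mrd > 1e-4, 2, 1)); s <- as.integer(t <= 10)
  t <- pmin(t, 10)
  a <- scan_thresholds(mrd, t, s)
  b <- scan_thresholds(rank(mrd) / n, t, s)
  expect_equal(rank(a$thresholds$chi2), rank(b$thresholds$chi2))
  expect_equal(which(a$thresholds$cutoff == a$optimal),
               which(b$thresholds$cutoff == b$optimal))
})

test_that("scan_thresholds equals brute-force maximal separation as the arm bound vanishes", {
  set.seed(9)
  n <- 150
  mrd <- 10^rnorm(n, -4, 1)
  t <- rexp(n, 0.03 * ifelse(mrd > 10^-3.8, 2.2, 1)); s <- as.integer(t <= 10)
  t <- pmin(t, 10)
  scan <- scan_thresholds(mrd, t, s, min_arm_fraction = 0)
  # oracle: hand log-rank over every dichotomy
  cuts <- sort(unique(mrd))
  chi <- vapply(cuts, function(ct) {
    grp <- mrd >= ct
    if (all(grp) || !any(grp)) return(NA_real_)
    brute_logrank_chi2(t, s, grp)
  }, numeric(1))
  expect_equal(scan$optimal, cuts[which.max(chi)])
  expect_equal(scan$optimal_chi2, max(chi, na.rm = TRUE), tolerance = 1e-6)
})

test_that("scan_thresholds handles two-value and degenerate inputs", {
  mrd <- rep(c(1e-5, 1e-3), each = 30)
  t <- c(rexp(30, 0.01), rexp(30, 0.05)); s <- rep(1, 60)
  scan <- scan_thresholds(mrd, t, s)
  expect_equal(nrow(scan$thresholds), 1)
  expect_equal(scan$optimal, 1e-3)
  expect_error(scan_thresholds(rep(1e-4, 60), t, s), "distinct")
  expect_error(scan_thresholds(mrd, t, s, min_arm_fraction = 0.6), "arm")
})

test_that("per-trisomy MRD distribution shifts are detected with direction", {
  cfg <- default_config(mrd_shift = c("18" = -0.6, "9" = 0.6))
  co <- generate_cohort(cfg, n = 3000, seed = 15)
  g <- cohort_gains(co)
  res <- mrd_distribution_by_trisomy(g, co$mrd_fraction)
  r18 <- res[res$chromosome == "18", ]
  expect_true(r18$significant)
  expect_equal(r18$direction, "lower")
  r9 <- res[res$chromosome == "9", ]
  expect_true(r9$significant)
  expect_equal(r9$direction, "higher")
  # small strata are skipped with a warning
  g2 <- g; g2[, "13"] <- c(rep(1, 5), rep(0, nrow(g2) - 5))
  expect_warning(res2 <- mrd_distribution_by_trisomy(g2, co$mrd_fraction),
                 "skipped")
  expect_false("13" %in% res2$chromosome)
})

test_that("per-trisomy shift tests are calibrated without planted shifts", {
  co <- generate_cohort(default_config(), n = 3000, seed = 16)
  res <- suppressWarnings(mrd_distribution_by_trisomy(cohort_gains(co),
                                                      co$mrd_fraction))
  expect_lt(mean(res$significant), 0.25)
})
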