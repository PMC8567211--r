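make_disc_cohort <- function(n = 2000, seed = 1, ...) {
  co <- generate_cohort(default_config(...), n = n, seed = seed)
  list(g = cohort_gains(co), time = co$time_relapse, status = co$ind_relapse,
       cohort = co)
}

test_that("enumerate_subsets counts, orders and bounds are exact", {
  expect_length(enumerate_subsets(as.character(1:10), 4), choose(10, 4))
  expect_length(enumerate_subsets(c("5", "17", "18", "20"), 4), 1)
  expect_equal(enumerate_subsets(c("20", "5", "18", "17"), 1),
               list("5", "17", "18", "20"))
  set.seed(2)
  for (rep in 1:10) {
    n <- sample(3:12, 1); k <- sample(seq_len(n), 1)
    expect_length(enumerate_subsets(as.character(seq_len(n)), k), choose(n, k))
  }
  expect_error(enumerate_subsets(c("1", "2"), 3), "between")
  expect_error(enumerate_subsets(c("1", "2"), 0), "between")
})

test_that("screen_trisomies flags planted chromosomes and skips constant columns", {
  d <- make_disc_cohort(n = 2000, seed = 14)
  g <- d$g
  g[, "21"] <- 1  # gained by everyone
  expect_warning(scr <- screen_trisomies(g, d$time, d$status), "constant")
  expect_false("21" %in% scr$chromosome)
  top4 <- scr$chromosome[order(scr$p)][1:4]
  expect_true(all(c("17", "18") %in% top4))
  expect_true(all(c("5", "20") %in% scr$chromosome[order(scr$p)][1:8]))
  expect_true(all(scr$hr[scr$chromosome %in% c("17", "18")] < 1))
  expect_true(all(scr$hr[scr$chromosome %in% c("5", "20")] > 1))
})

test_that("screen_trisomies is calibrated under the null", {
  # hazard unrelated to gains: ~5% of chromosomes significant at 0.05
  set.seed(91)
  n <- 1500
  g <- matrix(rbinom(n * 24, 1, 0.4), n, 24, dimnames = list(NULL, labs_all))
  hits <- integer(0)
  for (rep in 1:8) {
    t <- rexp(n, 0.05); s <- as.integer(t < 12); t <- pmin(t, 12)
    scr <- screen_trisomies(g, t, s)
    hits <- c(hits, sum(scr$significant))
  }
  expect_lt(mean(hits) / 24, 0.12)
})

test_that("cluster_gains recovers planted blocks and reports phi-1 pairs together", {
  blocks <- list(list(chromosomes = c("1", "2", "3", "4", "5"), phi = 0.6),
                 list(chromosomes = c("6", "7", "8", "9"), phi = 0.6),
                 list(chromosomes = c("10", "11", "12"), phi = 0.6),
                 list(chromosomes = c("13", "14", "15", "16"), phi = 0.6),
                 list(chromosomes = c("17", "18", "19", "20"), phi = 0.6))
  gp <- setNames(rep(0.4, 24), labs_all)
  co <- generate_cohort(default_config(gain_prob = gp, blocks = blocks),
                        n = 2000, seed = 5)
  g <- cohort_gains(co)[, as.character(1:20)]
  cl <- cluster_gains(g, 5)
  planted <- rep(1:5, c(5, 4, 3, 4, 4))
  expect_gte(adjusted_rand_index(cl$assignment, planted), 0.9)
  expect_true(cl$stable)
  # two chromosomes always co-gained share a group at any cut
  g2 <- cbind(g[, 1:6], dup = g[, 1])
  colnames(g2) <- c(as.character(1:6), "21")
  for (k in 2:4) {
    cl2 <- cluster_gains(g2, k)
    expect_equal(cl2$assignment[["1"]], cl2$assignment[["21"]])
  }
  expect_error(cluster_gains(g[, 1:3], 5), "exceeds")
})

test_that("independent gain columns yield an unstable clustering", {
  set.seed(33)
  g <- matrix(rbinom(12000, 1, 0.5), 1000, 12,
              dimnames = list(NULL, as.character(1:12)))
  cl <- cluster_gains(g, 5)
  expect_false(cl$stable)
})

test_that("cluster_gains attaches per-group relapse hazard ratios", {
  blocks <- list(list(chromosomes = c("4", "6", "10", "21"), phi = 0.5),
                 list(chromosomes = c("8", "9", "11", "12"), phi = 0.5),
                 list(chromosomes = c("17", "18", "14"), phi = 0.5),
                 list(chromosomes = c("1", "2", "3"), phi = 0.5),
                 list(chromosomes = c("5", "20", "22"), phi = 0.5))
  gp <- setNames(rep(0.4, 24), labs_all)
  co <- generate_cohort(default_config(gain_prob = gp, blocks = blocks),
                        n = 3000, seed = 6)
  g <- cohort_gains(co)[, as.character(1:22)]
  cl <- suppressWarnings(cluster_gains(g, 5, co$time_relapse, co$ind_relapse))
  expect_equal(length(cl$patient_group), 3000)
  if (!is.null(cl$per_group_hr)) {
    expect_s3_class(cl$per_group_hr, "data.frame")
    expect_true(all(cl$per_group_hr$hr > 0))
  }
})

test_that("best_subset_cp satisfies the full-model identity and finds planted truth", {
  d <- make_disc_cohort(n = 1500, seed = 41)
  cands <- c("5", "17", "18", "20", "8", "11")
  full <- best_subset_cp(d$g, d$status, k = 6, candidates = cands)
  expect_equal(full$cp, 7, tolerance = 1e-9)  # Cp = p + 1 exactly
  # low-noise linear truth: response driven by a known subset
  set.seed(42)
  g <- matrix(rbinom(600 * 6, 1, 0.5), 600, 6,
              dimnames = list(NULL, c("5", "17", "18", "20", "8", "11")))
  y <- as.integer(g[, "17"] + g[, "18"] - g[, "5"] + rnorm(600, 0, 0.1) > 1)
  ranked <- best_subset_cp(g, y, k = 3)
  expect_equal(sort(strsplit(ranked$subset[1], ",")[[1]]),
               c("17", "18", "5"))
  # aliased column detection
  g2 <- cbind(g, dup = g[, 1]); colnames(g2)[7] <- "6"
  g2[, "6"] <- g2[, "5"]
  expect_error(best_subset_cp(g2, y, k = 2), "aliased|singular")
})

test_that("stepwise_bic equals the exhaustive best-BIC subset over 5 candidates", {
  d <- make_disc_cohort(n = 1200, seed = 19)
  cands <- c("5", "11", "17", "18", "20")
  stp <- stepwise_bic(d$g, d$time, d$status, candidates = cands)
  # oracle: exhaustive search over all 31 non-empty subsets through the
  # formula interface (independent fitting path)
  nev <- sum(d$status)
  best_bic <- Inf; best_sub <- NULL
  for (k in 1:5) for (sub in combn(cands, k, simplify = FALSE)) {
    dat <- data.frame(t = d$time, s = d$status, d$g[, sub, drop = FALSE])
    fit <- survival::coxph(survival::Surv(t, s) ~ ., data = dat, ties = "efron")
    bic <- -2 * fit$loglik[2] + k * log(nev)
    if (bic < best_bic) { best_bic <- bic; best_sub <- sub }
  }
  expect_setequal(stp$chosen_subset, best_sub)
  expect_equal(min(stp$bic_trace$bic), best_bic, tolerance = 1e-6)
})

test_that("stepwise_bic returns an empty set under the null with a warning", {
  set.seed(55)
  n <- 800
  g <- matrix(rbinom(n * 5, 1, 0.4), n, 5,
              dimnames = list(NULL, c("1", "2", "3", "4", "5")))
  t <- rexp(n, 0.05); s <- as.integer(t < 12); t <- pmin(t, 12)
  expect_warning(stp <- stepwise_bic(g, t, s), "null model")
  expect_length(stp$chosen_subset, 0)
})

test_that("select_subset_size obeys the degenerate epsilon rule and column-order invariance", {
  d <- make_disc_cohort(n = 1500, seed = 3)
  sel1 <- select_subset_size(d$g, d$time, d$status, epsilon = 1.0)
  expect_equal(sel1$chosen_k, 1)
  sel <- select_subset_size(d$g, d$time, d$status, k_max = 4)
  perm <- d$g[, sample(ncol(d$g))]
  sel2 <- select_subset_size(perm, d$time, d$status, k_max = 4)
  expect_equal(sel2$chosen_k, sel$chosen_k)
  expect_equal(sel2$per_size$subset, sel$per_size$subset)
  # too few events for k_max (near-degenerate fits also warn; collect all)
  idx <- c(which(d$status == 1)[1:6], which(d$status == 0)[1:100])
  w <- capture_warnings(
    sel3 <- select_subset_size(d$g[idx, ], d$time[idx], d$status[idx],
                               k_max = 20, max_candidates = 4))
  expect_true(any(grepl("k_max reduced", w)))
  expect_lte(max(sel3$per_size$k), sum(d$status[idx]))
})

test_that("derive_rule recovers the generating profile on a large cohort", {
  d <- make_disc_cohort(n = 5000, seed = 23)
  rule <- derive_rule(d$g[, c("5", "17", "18", "20")], d$time, d$status)
  expect_true(rule_matches_ukall(rule))
  expect_equal(rule$low_label, "GOOD")
  # pattern table covers the observed patterns and counts every patient
  expect_equal(sum(rule$pattern_table$n), 5000)
  # the kmeans variant also produces a valid (possibly noisier) rule object
  rule2 <- derive_rule(d$g[, c("5", "17", "18", "20")], d$time, d$status,
                       method = "kmeans")
  expect_s3_class(rule2, "heh_rule")
  expect_true(all(vapply(rule2$clauses, function(cl)
    all(c(cl$pos, cl$neg) %in% c("5", "17", "18", "20")), logical(1))))
})

test_that("derive_rule errors when no discriminating split exists", {
  # identical relapse behaviour in every pattern
  set.seed(10)
  g <- cbind("17" = rep(c(0, 1), each = 40), "18" = rep(c(0, 1), 40))
  t <- rep(c(2, 11), 40); s <- rep(0, 80)
  expect_error(derive_rule(g, t, s), "no discriminating|no events")
  # single observed pattern violates the precondition
  g1 <- cbind("17" = rep(1, 50), "18" = rep(1, 50))
  expect_error(derive_rule(g1, rexp(50) + 1, rbinom(50, 1, 0.5)),
               "two observed")
  # equal rates across patterns, kmeans route
  g2 <- cbind("17" = rep(c(0, 1), each = 50), "18" = 0)
  t2 <- rep(c(1, 11), 50); s2 <- rep(c(1, 0), 50)
  expect_error(derive_rule(g2, t2, s2, method = "kmeans"),
               "no discriminating")
})

test_that("apply_rule and rule_to_string agree with the clause structure", {
  d <- make_disc_cohort(n = 5000, seed = 23)
  rule <- derive_rule(d$g[, c("5", "17", "18", "20")], d$time, d$status)
  expect_equal(apply_rule(rule, c("17", "18")), "GOOD")
  expect_equal(apply_rule(rule, c("17", "5")), "POOR")
  calls <- apply_rule(rule, d$g[1:50, c("5", "17", "18", "20")])
  expect_equal(unname(calls), d$cohort$true_risk[1:50])
  expect_match(rule_to_string(rule), "\\+17")
  expect_false(grepl("no\\+\\)", rule_to_string(rule)))
})

test_that("the discovery pipeline returns a coherent result object", {
  d <- make_disc_cohort(n = 4000, seed = 2)
  disc <- suppressWarnings(discover_profile(d$g, d$time, d$status))
  expect_s3_class(disc$selection, "subset_selection")
  expect_true(all(disc$rule_candidates %in% disc$selection$candidates))
  expect_true(all(c("17", "18") %in% disc$rule_candidates))
  expect_s3_class(disc$rule, "heh_rule")
  expect_gte(disc$selection$chosen_k, 1)
})
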