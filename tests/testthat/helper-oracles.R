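# Independent oracles and small fixture builders used across the suite.
# Every oracle here is a separate code path from the implementation it
# checks (brute force, closed form, or hand arithmetic).

labs_all <- hehprofile::CHROM_LABELS

# brute-force Harrell C: exhaustive pair enumeration with 0.5 for ties
brute_concordance <- function(risk, time, status) {
  n <- length(risk)
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    # usable pair: the smaller time must be an event
    if (time[i] == time[j] && status[i] && status[j]) next
    a <- if (time[i] < time[j] || (time[i] == time[j] && status[i] && !status[j])) i
         else if (time[j] < time[i] || (time[i] == time[j] && status[j] && !status[i])) j
         else next
    if (!status[a]) next
    b <- setdiff(c(i, j), a)
    den <- den + 1
    if (risk[a] > risk[b]) num <- num + 1
    else if (risk[a] == risk[b]) num <- num + 0.5
  }
  num / den
}

# hand log-rank chi-square for two groups (observed - expected over the
# hypergeometric variance), no package calls
brute_logrank_chi2 <- function(time, status, group) {
  g <- as.integer(as.factor(group))
  ev_times <- sort(unique(time[status == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    d <- sum(status == 1 & time == t)
    n1 <- sum(at_risk & g == 1); ntot <- sum(at_risk)
    d1 <- sum(status == 1 & time == t & g == 1)
    O <- O + d1
    E <- E + d * n1 / ntot
    if (ntot > 1)
      V <- V + d * (n1 / ntot) * (1 - n1 / ntot) * (ntot - d) / (ntot - 1)
  }
  (O - E)^2 / V
}

# Breslow/Efron partial log-likelihood for one binary covariate with no
# tied event times (both tie corrections coincide)
brute_cox_loglik <- function(beta, time, status, x) {
  ll <- 0
  for (i in which(status == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# exact two-sided Fisher p for a 2x2 table by hypergeometric summation
brute_fisher_p <- function(tab) {
  m <- tab[1, 1] + tab[2, 1]; n <- tab[1, 2] + tab[2, 2]
  k <- tab[1, 1] + tab[1, 2]
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# the published decision tree, written out pattern by pattern
fig2a_call <- function(has5, has17, has18, has20) {
  if (has17 && has18) return("GOOD")
  if ((has17 || has18) && !(has5 || has20)) return("GOOD")
  "POOR"
}

# cohort gain matrix helper
cohort_gains <- function(cohort) {
  g <- as.matrix(cohort[, paste0("gain_", labs_all)])
  colnames(g) <- labs_all
  g
}

# small two-group exponential survival fixture
make_exp_cohort <- function(n, hr, rate0 = 0.03, censor = 10, seed = 1) {
  set.seed(seed)
  grp <- rep(0:1, length.out = n)
  t <- rexp(n, rate0 * hr^grp)
  list(time = pmin(t, censor), status = as.integer(t <= censor), group = grp)
}
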