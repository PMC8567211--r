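## Profile-discovery pipeline: univariate screening of chromosome gains,
## correlation clustering, exhaustive subset search scored by Harrell's C,
## Mallows' Cp on a linear-probability model, forward-stepwise selection by
## Cox BIC, and derivation of a boolean decision rule from the selected
## trisomies.

# fast internal Cox fit on a numeric design matrix; returns coefficients,
# partial log-likelihood and Harrell's C of the linear predictor
fit_cox_subset <- function(X, y, cindex = TRUE) {
  X <- as.matrix(X); storage.mode(X) <- "numeric"
  fit <- survival::coxph.fit(X, y, strata = NULL, offset = NULL, init = NULL,
                             control = survival::coxph.control(),
                             weights = NULL, method = "efron", rownames = NULL)
  cidx <- if (cindex) {
    lp <- as.vector(X %*% fit$coefficients)
    as.numeric(survival::concordancefit(y, lp, reverse = TRUE)$concordance)
  } else NA_real_
  list(coef = fit$coefficients, loglik = fit$loglik[2], c_index = cidx)
}

#' @keywords internal
as_gain_matrix <- function(gains) {
  g <- as.matrix(gains)
  colnames(g) <- sub("^gain_", "", colnames(g))
  storage.mode(g) <- "numeric"
  if (is.null(colnames(g))) stop("gain matrix must have column names", call. = FALSE)
  g
}

#' Univariate per-chromosome outcome screen
#'
#' Fits one univariate Cox model per chromosome comparing carriers of the
#' gain against non-carriers on the given endpoint. Columns that are
#' constant (gained by everyone or no one) are skipped with a warning.
#'
#' @param gains binary patients x chromosomes matrix (columns named by
#'   chromosome label, optionally prefixed `gain_`).
#' @param time,status endpoint time and indicator vectors.
#' @param alpha significance threshold for the `significant` flag.
#' @return data.frame: `chromosome`, `n_gained`, `hr`, `lcl`, `ucl`, `p`,
#'   `significant`, ordered by chromosome.
#' @export
screen_trisomies <- function(gains, time, status, alpha = 0.05) {
  g <- as_gain_matrix(gains)
  stopifnot(nrow(g) == length(time), length(time) == length(status))
  y <- survival::Surv(time, status)
  keep <- apply(g, 2, function(v) length(unique(v)) > 1)
  if (any(!keep))
    warning("skipping constant gain column(s): ",
            paste(colnames(g)[!keep], collapse = ", "), call. = FALSE)
  rows <- lapply(colnames(g)[keep], function(ch) {
    x <- g[, ch, drop = FALSE]
    fit <- survival::coxph.fit(x, y, strata = NULL, offset = NULL, init = NULL,
                               control = survival::coxph.control(),
                               weights = NULL, method = "efron", rownames = NULL)
    b <- fit$coefficients[1]; se <- sqrt(fit$var[1, 1])
    data.frame(chromosome = ch, n_gained = sum(x),
               hr = exp(b), lcl = exp(b - 1.96 * se), ucl = exp(b + 1.96 * se),
               p = 2 * stats::pnorm(-abs(b / se)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p < alpha
  out[order(chrom_order(out$chromosome)), , drop = FALSE]
}

#' Cluster chromosome gains by phi correlation
#'
#' Pairwise phi coefficients between binary gain columns, average-linkage
#' hierarchical clustering, cut into `n_groups`. Groups are labelled I, II,
#' ... in order of their first chromosome in cytogenetic order. If endpoint
#' data are supplied, each patient is assigned to the group in which they
#' carry the largest fraction of that group's chromosomes (ties to the
#' lower group id) and per-group relapse hazard ratios versus group I are
#' estimated.
#'
#' The clustering is flagged unstable when the linkage-height gap at the cut
#' is small relative to the height range (no clear group structure).
#'
#' @inheritParams screen_trisomies
#' @param n_groups number of clusters to cut.
#' @param time,status optional endpoint for per-group hazard ratios.
#' @return object of class `cluster_result`: `n_groups`, `assignment`
#'   (named integer vector), `linkage_heights`, `stable`, `patient_group`,
#'   `per_group_hr`.
#' @export
cluster_gains <- function(gains, n_groups, time = NULL, status = NULL) {
  g <- as_gain_matrix(gains)
  keep <- apply(g, 2, function(v) stats::var(v) > 0)
  if (sum(keep) < n_groups)
    stop("n_groups (", n_groups, ") exceeds chromosomes with variance (",
         sum(keep), ")", call. = FALSE)
  g <- g[, keep, drop = FALSE]
  phi <- suppressWarnings(stats::cor(g))
  hc <- stats::hclust(stats::as.dist(1 - phi), method = "average")
  cut <- stats::cutree(hc, k = n_groups)
  # relabel groups contiguously in cytogenetic order of first member
  ord <- order(chrom_order(names(cut)))
  first_seen <- unique(cut[ord])
  assignment <- match(cut, first_seen)
  names(assignment) <- names(cut)
  h <- hc$height
  p <- length(h) + 1L
  gap <- if (p - n_groups >= 1L && p - n_groups + 1L <= length(h))
    h[p - n_groups + 1L] - h[p - n_groups] else NA_real_
  stable <- !is.na(gap) && max(h) > 0 && gap >= 0.1 * max(h)

  patient_group <- NULL; per_group_hr <- NULL
  if (!is.null(time)) {
    stopifnot(length(time) == nrow(g), length(status) == length(time))
    score <- sapply(seq_len(n_groups), function(k) {
      cols <- names(assignment)[assignment == k]
      rowMeans(g[, cols, drop = FALSE])
    })
    patient_group <- max.col(score, ties.method = "first")
    if (length(unique(patient_group)) > 1) {
      grp <- factor(patient_group, levels = sort(unique(patient_group)))
      per_group_hr <- tryCatch({
        cx <- cox_fit(time, status,
                      as.data.frame(stats::model.matrix(~grp)[, -1, drop = FALSE]))
        cx$term <- sub("^grp", "group ", cx$term)
        cx
      }, error = function(e) {
        warning("per-group hazard ratios unavailable: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    }
  }
  structure(list(n_groups = n_groups, assignment = assignment,
                 linkage_heights = h, stable = stable,
                 patient_group = patient_group, per_group_hr = per_group_hr),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result>", x$n_groups, "groups",
      if (!x$stable) "(unstable cut)" else "", "\n")
  for (k in seq_len(x$n_groups))
    cat("  ", as.character(utils::as.roman(k)), ": ",
        paste(sort_chrom(names(x$assignment)[x$assignment == k]), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Enumerate chromosome subsets of a given size
#'
#' All `choose(|candidates|, k)` subsets, in deterministic lexicographic
#' order over candidates sorted cytogenetically.
#'
#' @param candidates character vector of chromosome labels.
#' @param k subset size, `1 <= k <= length(candidates)`.
#' @return list of character vectors.
#' @export
enumerate_subsets <- function(candidates, k) {
  candidates <- sort_chrom(unique(as.character(candidates)))
  assert_chrom_labels(candidates)
  if (k < 1 || k > length(candidates))
    stop("k must be between 1 and ", length(candidates), call. = FALSE)
  utils::combn(candidates, k, simplify = FALSE)
}

#' @keywords internal
candidate_pool <- function(g, time, status, min_freq, max_candidates) {
  freq <- colMeans(g)
  cands <- colnames(g)[freq >= min_freq & freq <= 1 - min_freq]
  if (length(cands) > max_candidates) {
    scr <- screen_trisomies(g[, cands, drop = FALSE], time, status)
    cands <- scr$chromosome[order(scr$p)][seq_len(max_candidates)]
  }
  sort_chrom(cands)
}

#' Optimal trisomy-subset size by C-index plateau
#'
#' For each subset size k up to `k_max`, finds the best subset of the
#' candidate chromosomes by the Harrell C-index of a Cox model on the
#' subset's gain indicators (relapse endpoint), then picks the smallest k
#' after which the best C-index improves by less than `epsilon` - the size
#' after which no additional benefit is gained from adding more
#' chromosomes. Mallows' Cp (linear-probability model of the event
#' indicator) and the Cox BIC are recorded per best subset for
#' cross-checking.
#'
#' Candidates are the chromosomes gained in at least `min_freq` and at most
#' `1 - min_freq` of patients; if more than `max_candidates` qualify, those
#' with the smallest univariate p-values are kept, mirroring a univariate
#' pre-screen.
#'
#' @inheritParams screen_trisomies
#' @param k_max largest subset size tried (reduced with a warning if it
#'   exceeds the event count or the candidate pool).
#' @param epsilon plateau threshold in C-index units.
#' @param min_freq marginal frequency bound for candidate chromosomes.
#' @param max_candidates cap on the candidate pool.
#' @return object of class `subset_selection`: `per_size` data.frame
#'   (`k`, `subset`, `c_index`, `cp`, `bic`), `chosen_k`, `chosen_subset`,
#'   `candidates`, `epsilon`.
#' @export
select_subset_size <- function(gains, time, status, k_max = 6, epsilon = 0.005,
                               min_freq = 0.05, max_candidates = 10) {
  stopifnot(k_max >= 2)
  g <- as_gain_matrix(gains)
  stopifnot(nrow(g) == length(time), length(time) == length(status))
  cands <- candidate_pool(g, time, status, min_freq, max_candidates)
  if (length(cands) < 2) stop("fewer than two candidate chromosomes", call. = FALSE)
  nev <- sum(status)
  if (k_max > min(nev, length(cands))) {
    k_max <- min(nev, length(cands))
    warning("k_max reduced to ", k_max, call. = FALSE)
  }
  y <- survival::Surv(time, status)

  # residual variance of the full-candidate linear-probability model, for Cp
  Xfull <- cbind(1, g[, cands, drop = FALSE])
  lmfull <- stats::lm.fit(Xfull, status)
  s2 <- sum(lmfull$residuals^2) / (nrow(g) - ncol(Xfull))
  n <- nrow(g)
  cp_of <- function(subset) {
    Xs <- cbind(1, g[, subset, drop = FALSE])
    sse <- sum(stats::lm.fit(Xs, status)$residuals^2)
    sse / s2 - n + 2 * ncol(Xs)
  }

  per <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    best_c <- -Inf; best_sub <- NULL; best_ll <- NA_real_
    for (sub in enumerate_subsets(cands, k)) {
      f <- fit_cox_subset(g[, sub, drop = FALSE], y)
      if (f$c_index > best_c + 1e-12) {   # ties keep lexicographic first
        best_c <- f$c_index; best_sub <- sub; best_ll <- f$loglik
      }
    }
    per[[k]] <- data.frame(k = k, subset = paste(best_sub, collapse = ","),
                           c_index = best_c, cp = cp_of(best_sub),
                           bic = -2 * best_ll + k * log(nev),
                           stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, per)
  chosen_k <- k_max
  for (k in seq_len(k_max - 1)) {
    if (per$c_index[k + 1] - per$c_index[k] < epsilon) { chosen_k <- k; break }
  }
  structure(list(per_size = per, chosen_k = chosen_k,
                 chosen_subset = strsplit(per$subset[chosen_k], ",")[[1]],
                 candidates = cands, epsilon = epsilon),
            class = "subset_selection")
}

#' @export
print.subset_selection <- function(x, ...) {
  cat("<subset_selection> chosen k =", x$chosen_k, "->",
      paste(x$chosen_subset, collapse = ", "), "\n")
  print(x$per_size, row.names = FALSE)
  invisible(x)
}

#' Best-subset ranking by Mallows' Cp
#'
#' Ranks all subsets of size `k` of the candidate chromosomes by Mallows'
#' Cp computed on a linear-probability model of the binary event indicator:
#' `Cp = SSE_p / s^2 - n + 2 (p + 1)`, with `s^2` the residual mean square
#' of the full-candidate model. The subset equal to the full candidate set
#' has `Cp = p + 1` exactly.
#'
#' @inheritParams screen_trisomies
#' @param event binary event indicator used as the regression response.
#' @param k subset size.
#' @param candidates optional candidate labels (default: all non-constant
#'   columns).
#' @return data.frame of `subset`, `cp`, ascending in `cp` (ties broken
#'   lexicographically by enumeration order).
#' @export
best_subset_cp <- function(gains, event, k, candidates = NULL) {
  g <- as_gain_matrix(gains)
  stopifnot(nrow(g) == length(event), all(event %in% c(0, 1)))
  if (is.null(candidates))
    candidates <- colnames(g)[apply(g, 2, function(v) stats::var(v) > 0)]
  candidates <- sort_chrom(candidates)
  Xfull <- cbind(1, g[, candidates, drop = FALSE])
  qrf <- qr(Xfull)
  if (qrf$rank < ncol(Xfull)) {
    aliased <- colnames(Xfull)[-seq_len(qrf$rank)]
    stop("singular full model; aliased columns: ",
         paste(setdiff(candidates, colnames(Xfull)[qrf$pivot[seq_len(qrf$rank)]]),
               collapse = ", "), call. = FALSE)
  }
  n <- nrow(g)
  s2 <- sum(qr.resid(qrf, event)^2) / (n - ncol(Xfull))
  rows <- lapply(enumerate_subsets(candidates, k), function(sub) {
    sse <- sum(stats::lm.fit(cbind(1, g[, sub, drop = FALSE]), event)$residuals^2)
    data.frame(subset = paste(sub, collapse = ","),
               cp = sse / s2 - n + 2 * (length(sub) + 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$cp), , drop = FALSE]
}

#' @keywords internal
cox_bic <- function(loglik, p, n_events) -2 * loglik + p * log(n_events)

#' Forward-stepwise Cox selection by BIC
#'
#' Starts from the null model and greedily adds the candidate chromosome
#' that most lowers `BIC = -2 logPL + p log(n_events)`, stopping when no
#' addition lowers it. Returns an empty subset with a warning when no
#' candidate improves on the null model.
#'
#' @inheritParams screen_trisomies
#' @param candidates optional candidate labels (default: all non-constant
#'   columns).
#' @return list with `chosen_subset` (cytogenetically ordered), `bic_trace`
#'   data.frame (`step`, `added`, `bic`) and `null_bic`.
#' @export
stepwise_bic <- function(gains, time, status, candidates = NULL) {
  g <- as_gain_matrix(gains)
  stopifnot(nrow(g) == length(time), length(time) == length(status))
  if (is.null(candidates))
    candidates <- colnames(g)[apply(g, 2, function(v) stats::var(v) > 0)]
  candidates <- sort_chrom(candidates)
  if (length(candidates) < 2) stop("need at least two candidates", call. = FALSE)
  y <- survival::Surv(time, status)
  nev <- sum(status)
  # null partial likelihood from any single-covariate fit's first iterate
  ll0 <- survival::coxph.fit(g[, candidates[1], drop = FALSE], y, strata = NULL,
                             offset = NULL, init = NULL,
                             control = survival::coxph.control(), weights = NULL,
                             method = "efron", rownames = NULL)$loglik[1]
  current <- character()
  bic_cur <- cox_bic(ll0, 0, nev)
  trace <- data.frame(step = 0L, added = "(null)", bic = bic_cur,
                      stringsAsFactors = FALSE)
  repeat {
    remaining <- setdiff(candidates, current)
    if (length(remaining) == 0) break
    bics <- vapply(remaining, function(ch) {
      f <- fit_cox_subset(g[, c(current, ch), drop = FALSE], y)
      cox_bic(f$loglik, length(current) + 1L, nev)
    }, numeric(1))
    if (min(bics) >= bic_cur) break
    add <- remaining[which.min(bics)]
    current <- c(current, add)
    bic_cur <- min(bics)
    trace <- rbind(trace, data.frame(step = length(current), added = add,
                                     bic = bic_cur, stringsAsFactors = FALSE))
  }
  if (length(current) == 0)
    warning("no candidate improves on the null model; empty subset returned",
            call. = FALSE)
  list(chosen_subset = sort_chrom(current), bic_trace = trace,
       null_bic = trace$bic[1])
}

## ---- decision-rule derivation -------------------------------------------

# clause representation: integer vector over variables, 0 = absent,
# 1 = positive literal, 2 = negated literal
clause_covers <- function(clause, bits) {
  all(bits[clause == 1L] == 1L) && all(bits[clause == 2L] == 0L)
}

clause_to_list <- function(clause, vars) {
  list(pos = vars[clause == 1L], neg = vars[clause == 2L])
}

#' Derive a boolean decision rule from trisomy patterns
#'
#' Tabulates relapse outcomes for every observed presence/absence pattern of
#' the supplied chromosomes and returns a good/poor decision rule in
#' disjunctive normal form over the gain indicators, together with the
#' per-pattern rate table.
#'
#' Two search strategies are available. The default, `method = "penalized"`,
#' scores every candidate rule (all DNFs of up to `max_clauses` conjunctive
#' clauses) by the two-group exponential (events and person-time truncated
#' at `horizon`) log-likelihood of the patient split it induces, minus a
#' complexity penalty of `penalty` per literal, and returns the
#' highest-scoring rule; this pools evidence across patterns, so rare
#' patterns cannot destabilise the rule unless the data genuinely support
#' the extra complexity. `method = "kmeans"` first splits the observed
#' patterns into low/high clusters by 2-means on their per-pattern
#' Kaplan-Meier relapse rates (patterns with fewer than `min_pattern_n`
#' patients are left unassigned as don't-cares) and then returns the
#' smallest DNF consistent with the split. In both cases an error is raised
#' when no rule discriminates (e.g. all pattern rates equal).
#'
#' @param gains binary matrix restricted to the selected chromosomes
#'   (2 to 6 columns).
#' @param time,status relapse endpoint.
#' @param horizon rate horizon in years.
#' @param method `"penalized"` or `"kmeans"` (see Details).
#' @param penalty complexity penalty per literal on the 2-log-likelihood
#'   scale (default 2, AIC-like).
#' @param max_clauses maximum number of conjunctive clauses searched.
#' @param min_pattern_n (kmeans method) patterns with fewer patients are
#'   left unassigned.
#' @return object of class `heh_rule`: `clauses` (list of `pos`/`neg`
#'   label sets), `variables`, `pattern_table` (with per-pattern `n`,
#'   `events`, `km_rate` and the rule's `cluster`), `unassigned`,
#'   `low_label`.
#' @export
derive_rule <- function(gains, time, status, horizon = 10,
                        method = c("penalized", "kmeans"), penalty = 2,
                        max_clauses = 3, min_pattern_n = 1) {
  method <- match.arg(method)
  g <- as_gain_matrix(gains)
  stopifnot(ncol(g) >= 2, ncol(g) <= 6,
            nrow(g) == length(time), length(time) == length(status))
  vars <- colnames(g)
  m <- ncol(g)
  key <- apply(g, 1, paste, collapse = "")
  obs <- sort(unique(key))
  if (length(obs) < 2)
    stop("at least two observed gain patterns are required", call. = FALSE)

  km_rate <- function(idx) {
    if (sum(status[idx]) == 0) return(0)
    suppressWarnings(rate_at(km_fit(time[idx], status[idx]), horizon,
                             as_failure = TRUE)$rate)
  }
  tab <- data.frame(pattern = obs,
                    n = as.integer(table(key)[obs]),
                    events = vapply(obs, function(p) sum(status[key == p]),
                                    numeric(1)),
                    persontime = vapply(obs, function(p) sum(time[key == p]),
                                        numeric(1)),
                    km_rate = vapply(obs, function(p) km_rate(key == p),
                                     numeric(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  pat_bits <- lapply(strsplit(obs, ""), as.integer)

  # conjunctive clauses: ternary slots per variable (0 absent, 1 positive,
  # 2 negated); for > 4 variables restrict clause length to keep the DNF
  # enumeration tractable
  grid <- as.matrix(expand.grid(rep(list(0:2), m)))[-1, , drop = FALSE]
  storage.mode(grid) <- "integer"
  nlit_all <- rowSums(grid != 0L)
  max_lit <- if (m <= 4) m else if (m == 5) 3L else 2L
  grid <- grid[nlit_all <= max_lit, , drop = FALSE]
  nlit_all <- rowSums(grid != 0L)
  clause_mask <- t(apply(grid, 1, function(cl)
    vapply(pat_bits, function(b) clause_covers(cl, b), logical(1))))

  if (method == "penalized") {
    res <- search_rule_penalized(grid, nlit_all, clause_mask, tab,
                                 penalty, max_clauses)
    best_clauses <- res$clauses_idx
    low_mask <- res$low_mask
    cluster <- ifelse(low_mask, "low", "high")
    unassigned <- character()
  } else {
    r <- tab$km_rate
    assignable <- tab$n >= min_pattern_n
    if (diff(range(r[assignable])) < 1e-10)
      stop("no discriminating rule: all pattern relapse rates are equal",
           call. = FALSE)
    km2 <- stats::kmeans(r[assignable], centers = matrix(range(r[assignable])),
                         algorithm = "Lloyd")
    low_id <- which.min(km2$centers)
    cluster <- rep(NA_character_, nrow(tab))
    cluster[assignable] <- ifelse(km2$cluster == low_id, "low", "high")
    best_clauses <- cover_minimal_dnf(grid, nlit_all, clause_mask,
                                      which(!is.na(cluster) & cluster == "low"),
                                      which(!is.na(cluster) & cluster == "high"))
    unassigned <- tab$pattern[is.na(cluster)]
  }
  tab$cluster <- cluster
  clauses <- lapply(best_clauses, function(i) clause_to_list(grid[i, ], vars))

  structure(list(clauses = clauses, variables = vars,
                 pattern_table = tab, unassigned = unassigned,
                 low_label = "GOOD", horizon = horizon, method = method),
            class = "heh_rule")
}

# exhaustive penalized DNF search over unions of 1..max_clauses conjunctive
# clauses: score = 2 * (two-group exponential log-likelihood) -
# penalty * literals, maximised; ties broken by fewer literals then
# enumeration order
#' @keywords internal
search_rule_penalized <- function(grid, nlit, clause_mask, tab, penalty,
                                  max_clauses) {
  ev <- tab$events; pt <- tab$persontime
  Etot <- sum(ev); Ttot <- sum(pt)
  if (Etot == 0) stop("no events: no discriminating rule", call. = FALSE)
  pois_ll <- function(e, t) ifelse(e > 0, e * log(e / t) - e, 0)
  null_ll <- pois_ll(Etot, Ttot)

  # deduplicate clauses with identical pattern coverage (keep fewest
  # literals, first in enumeration order)
  covkey <- apply(clause_mask, 1, paste, collapse = "")
  ord <- order(covkey, nlit)
  keep_idx <- ord[!duplicated(covkey[ord])]
  keep_idx <- sort(keep_idx)
  clause_mask <- clause_mask[keep_idx, , drop = FALSE]
  nlit_k <- nlit[keep_idx]
  nc <- nrow(clause_mask)
  Cnum <- clause_mask * 1

  best_score <- -Inf; best_combo <- NULL; best_nlit <- Inf
  for (size in seq_len(min(max_clauses, nc))) {
    M <- utils::combn(nc, size)
    U <- Cnum[M[1, ], , drop = FALSE]
    if (size > 1) for (r in 2:size) U <- U + Cnum[M[r, ], , drop = FALSE]
    U <- U > 0
    ncov <- rowSums(U)
    valid <- ncov > 0 & ncov < ncol(U)
    e1 <- as.vector(U %*% ev); t1 <- as.vector(U %*% pt)
    e0 <- Etot - e1; t0 <- Ttot - t1
    valid <- valid & (e1 / t1 <= e0 / t0)   # covered side must be lower-rate
    if (!any(valid)) next
    ll <- pois_ll(e1, t1) + pois_ll(e0, t0)
    lits <- colSums(matrix(nlit_k[M], nrow = size))
    score <- ifelse(valid, 2 * (ll - null_ll) - penalty * lits, -Inf)
    i <- order(-score, lits)[1]
    if (score[i] > best_score + 1e-9 ||
        (score[i] > best_score - 1e-9 && lits[i] < best_nlit)) {
      best_score <- score[i]; best_combo <- keep_idx[M[, i]]
      best_nlit <- lits[i]; best_mask <- U[i, ]
    }
  }
  if (is.null(best_combo) || best_score <= 0)
    stop("no discriminating rule: no split improves on the pooled model",
         call. = FALSE)
  list(clauses_idx = best_combo, low_mask = best_mask, score = best_score)
}

# smallest DNF (fewest clauses, then fewest literals) consistent with a
# low/high pattern assignment; unassigned patterns are don't-cares
#' @keywords internal
cover_minimal_dnf <- function(grid, nlit, clause_mask, low_idx, high_idx) {
  if (length(low_idx) == 0 || length(high_idx) == 0)
    stop("no discriminating rule: a cluster is empty", call. = FALSE)
  admissible <- rowSums(clause_mask[, high_idx, drop = FALSE]) == 0
  grid <- grid[admissible, , drop = FALSE]
  covmat <- clause_mask[admissible, low_idx, drop = FALSE]
  nlit <- nlit[admissible]
  useful <- rowSums(covmat) > 0
  grid <- grid[useful, , drop = FALSE]
  covmat <- covmat[useful, , drop = FALSE]
  nlit <- nlit[useful]
  if (nrow(grid) == 0 || !all(colSums(covmat) > 0))
    stop("no discriminating rule found over the observed patterns",
         call. = FALSE)
  keep <- which(admissible)[useful]
  # prime clauses: drop those strictly dominated in coverage
  dominated <- vapply(seq_len(nrow(covmat)), function(i) {
    any(vapply(seq_len(nrow(covmat)), function(j) {
      j != i && all(covmat[j, ] >= covmat[i, ]) &&
        (sum(covmat[j, ]) > sum(covmat[i, ]) || nlit[j] < nlit[i])
    }, logical(1)))
  }, logical(1))
  covmat <- covmat[!dominated, , drop = FALSE]
  nlit <- nlit[!dominated]
  keep <- keep[!dominated]
  for (size in seq_len(nrow(covmat))) {
    combos <- utils::combn(nrow(covmat), size, simplify = FALSE)
    ok <- Filter(function(ix) all(colSums(covmat[ix, , drop = FALSE]) > 0),
                 combos)
    if (length(ok) > 0) {
      lits <- vapply(ok, function(ix) sum(nlit[ix]), numeric(1))
      return(keep[ok[[which.min(lits)]]])
    }
  }
  stop("no covering rule found", call. = FALSE)
}

#' Apply a derived rule to gain sets
#'
#' @param rule an `heh_rule`.
#' @param gains a character vector of gained chromosome labels, or a binary
#'   matrix with columns covering the rule's variables.
#' @return `"GOOD"`/`"POOR"` call(s).
#' @export
apply_rule <- function(rule, gains) {
  stopifnot(inherits(rule, "heh_rule"))
  eval_one <- function(present) {
    hit <- any(vapply(rule$clauses, function(cl)
      all(cl$pos %in% present) && !any(cl$neg %in% present), logical(1)))
    if (hit) rule$low_label else "POOR"
  }
  if (is.character(gains)) return(eval_one(gains))
  g <- as_gain_matrix(gains)
  apply(g, 1, function(row) eval_one(colnames(g)[row > 0]))
}

#' Human-readable disjunctive normal form of a rule
#'
#' @param rule an `heh_rule`.
#' @return a single string such as `"(+17 & +18) | (+18 & no+5 & no+20)"`.
#' @export
rule_to_string <- function(rule) {
  stopifnot(inherits(rule, "heh_rule"))
  paste(vapply(rule$clauses, function(cl) {
    lits <- c(paste0("+", cl$pos, recycle0 = TRUE),
              paste0("no+", cl$neg, recycle0 = TRUE))
    paste0("(", paste(lits, collapse = " & "), ")")
  }, character(1)), collapse = " | ")
}

#' @export
print.heh_rule <- function(x, ...) {
  cat("<heh_rule> ", x$low_label, " iff ", rule_to_string(x), "\n", sep = "")
  invisible(x)
}

#' Is a derived rule equivalent to the UKALL-HeH profile?
#'
#' Enumerates all 16 presence/absence patterns of chromosomes 5, 17, 18 and
#' 20 and compares the rule's call with [classify_ukall_heh()]. Rules over a
#' superset of those four chromosomes are evaluated with the extra
#' chromosomes absent and, additionally, must not reference them in any
#' clause.
#'
#' @param rule an `heh_rule`.
#' @return `TRUE`/`FALSE`.
#' @export
rule_matches_ukall <- function(rule) {
  core <- c("5", "17", "18", "20")
  extra <- setdiff(rule$variables, core)
  uses_extra <- any(vapply(rule$clauses, function(cl)
    any(c(cl$pos, cl$neg) %in% extra), logical(1)))
  if (uses_extra) return(FALSE)
  for (i in 0:15) {
    bits <- as.integer(intToBits(i))[1:4]
    present <- core[bits == 1L]
    if (apply_rule(rule, present) != classify_ukall_heh(present)$call)
      return(FALSE)
  }
  TRUE
}

#' Run the full profile-discovery pipeline
#'
#' Screens chromosomes univariately on the relapse endpoint, finds the
#' optimal subset size by the C-index plateau rule, selects the chromosome
#' combination by forward-stepwise Cox BIC, and derives the boolean
#' decision rule. Rule derivation uses the most informative chromosomes
#' from the univariate screen (the `rule_vars` lowest p-values, five by
#' default, mirroring a univariate pre-selection before multivariate
#' modelling); the penalized rule search simply ignores variables that do
#' not earn their complexity, so a superset of the truly prognostic
#' chromosomes is safe. The stepwise-BIC set and the per-size best subsets
#' are returned alongside as cross-checks of the selected combination.
#'
#' @inheritParams select_subset_size
#' @param horizon rate horizon for rule derivation.
#' @param rule_vars number of screen-ranked chromosomes offered to the rule
#'   search (2-5).
#' @return object of class `heh_discovery`: `screen`, `selection`,
#'   `stepwise`, `final_set` (the stepwise choice), `rule`.
#' @export
discover_profile <- function(gains, time, status, k_max = 6, epsilon = 0.005,
                             min_freq = 0.05, max_candidates = 10,
                             horizon = 10, rule_vars = 5) {
  stopifnot(rule_vars >= 2, rule_vars <= 5)
  g <- as_gain_matrix(gains)
  scr <- suppressWarnings(screen_trisomies(g, time, status))
  sel <- select_subset_size(g, time, status, k_max = k_max, epsilon = epsilon,
                            min_freq = min_freq, max_candidates = max_candidates)
  stp <- stepwise_bic(g, time, status, candidates = sel$candidates)
  scr_pool <- scr[scr$chromosome %in% sel$candidates, ]
  top <- scr_pool$chromosome[order(scr_pool$p)][seq_len(min(rule_vars,
                                                            nrow(scr_pool)))]
  rule <- derive_rule(g[, sort_chrom(top), drop = FALSE], time, status,
                      horizon = horizon)
  structure(list(screen = scr, selection = sel, stepwise = stp,
                 final_set = stp$chosen_subset, rule_candidates = sort_chrom(top),
                 rule = rule),
            class = "heh_discovery")
}

#' @export
print.heh_discovery <- function(x, ...) {
  cat("<heh_discovery>\n  chosen size:", x$selection$chosen_k,
      "\n  stepwise set:", paste(x$stepwise$chosen_subset, collapse = ", "),
      "\n  rule:", rule_to_string(x$rule), "\n")
  invisible(x)
}
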