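## Trisomy-based risk classifiers.
##
## All classifiers evaluate gains as presence (>= 1 extra copy); copy-number
## multiplicity is ignored, matching decision rules written over "+N"
## presence.

#' UKALL high-hyperdiploid risk profile
#'
#' The good-risk profile comprises karyotypes with both +17 and +18, or with
#' exactly one of +17/+18 in the absence of both +5 and +20. Everything else
#' is poor risk. Cases with both +17 and +18 are good risk regardless of
#' +5/+20 status.
#'
#' @param gains character vector of gained chromosome labels (from
#'   `1..22`, `X`, `Y`); multiplicity irrelevant.
#' @return an object of class `risk_call`: list with `classifier`
#'   (`"UKALL_HEH"`), `call` (`"GOOD"` or `"POOR"`) and `basis`, the
#'   presence/absence evidence that determined the call (absence markers are
#'   written `"no+N"`).
#' @examples
#' classify_ukall_heh(c("4", "10", "17", "18", "21"))$call  # GOOD
#' classify_ukall_heh(c("6", "17", "20"))$call              # POOR
#' @export
classify_ukall_heh <- function(gains) {
  gains <- unique(as.character(gains))
  assert_chrom_labels(gains)
  has17 <- "17" %in% gains; has18 <- "18" %in% gains
  has5  <- "5"  %in% gains; has20 <- "20" %in% gains
  if (has17 && has18) {
    call <- "GOOD"; basis <- c("+17", "+18")
  } else if (xor(has17, has18) && !has5 && !has20) {
    call <- "GOOD"
    basis <- c(if (has17) "+17" else "+18", "no+5", "no+20")
  } else if (has17 || has18) {
    call <- "POOR"
    basis <- c(if (has17) "+17" else "+18",
               if (has5) "+5", if (has20) "+20")
  } else {
    call <- "POOR"; basis <- c("no+17", "no+18")
  }
  structure(list(classifier = "UKALL_HEH", call = call, basis = basis),
            class = "risk_call")
}

#' @export
print.risk_call <- function(x, ...) {
  cat("<risk_call> ", x$classifier, ": ", x$call,
      " (basis: ", paste(x$basis, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' COG double and triple trisomy status
#'
#' Double trisomy is the joint presence of +4 and +10; triple trisomy adds
#' +17. Triple trisomy implies double trisomy by construction.
#'
#' @inheritParams classify_ukall_heh
#' @return list with logical `double_trisomy` and `triple_trisomy`.
#' @export
classify_cog <- function(gains) {
  gains <- unique(as.character(gains))
  assert_chrom_labels(gains)
  dt <- all(c("4", "10") %in% gains)
  list(double_trisomy = dt, triple_trisomy = dt && "17" %in% gains)
}

#' NCI risk group
#'
#' Standard risk requires age under 10 years and presenting white cell count
#' under 50 x 10^9/L; all other patients are high risk.
#'
#' @param age_years numeric age(s), >= 0.
#' @param wcc white cell count(s) in 10^9 cells per litre, >= 0.
#' @return character vector of `"STANDARD"`/`"HIGH"`.
#' @export
classify_nci <- function(age_years, wcc) {
  stopifnot(length(age_years) == length(wcc))
  if (any(age_years < 0, na.rm = TRUE) || any(wcc < 0, na.rm = TRUE))
    stop("age and white cell count must be non-negative", call. = FALSE)
  ifelse(age_years < 10 & wcc < 50, "STANDARD", "HIGH")
}

#' @keywords internal
gain_matrix_from_cohort <- function(data) {
  cols <- paste0("gain_", CHROM_LABELS)
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L)
    stop("missing gain columns: ", paste(missing, collapse = ", "), call. = FALSE)
  m <- as.matrix(data[, cols])
  storage.mode(m) <- "numeric"
  colnames(m) <- CHROM_LABELS
  m
}

#' Vectorised UKALL-HeH calls over a binary gain matrix
#'
#' @param gains binary matrix or data.frame with columns named by chromosome
#'   label (or `gain_<label>`).
#' @return character vector of `"GOOD"`/`"POOR"`.
#' @export
ukall_heh_calls <- function(gains) {
  gains <- as.matrix(gains)
  colnames(gains) <- sub("^gain_", "", colnames(gains))
  pick <- function(ch) if (ch %in% colnames(gains)) gains[, ch] > 0 else
    rep(FALSE, nrow(gains))
  h17 <- pick("17"); h18 <- pick("18"); h5 <- pick("5"); h20 <- pick("20")
  ifelse((h17 & h18) | (xor(h17, h18) & !h5 & !h20), "GOOD", "POOR")
}

#' Append risk-call columns to a cohort table
#'
#' Adds `ukall_heh`, `cog_dt`, `cog_tt`, and where the inputs are available
#' `modal_cat` (from `modal_low`/`modal_high`) and `nci_risk` (from `age`
#' and `wcc`).
#'
#' @param data cohort data.frame with `gain_1` .. `gain_Y` columns.
#' @return the data.frame with classifier columns appended.
#' @export
classify_cohort <- function(data) {
  g <- gain_matrix_from_cohort(data)
  data$ukall_heh <- ukall_heh_calls(g)
  data$cog_dt <- as.integer(g[, "4"] > 0 & g[, "10"] > 0)
  data$cog_tt <- as.integer(data$cog_dt == 1L & g[, "17"] > 0)
  if (all(c("modal_low", "modal_high") %in% names(data))) {
    data$modal_cat <- vapply(seq_len(nrow(data)), function(i) {
      k <- new_karyotype("", data$modal_low[i], data$modal_high[i], "XX",
                         character(), character(), FALSE,
                         if (data$modal_low[i] < data$modal_high[i]) "MODAL_RANGE"
                         else character())
      modal_category(k)
    }, character(1))
  }
  if (all(c("age", "wcc") %in% names(data)))
    data$nci_risk <- classify_nci(data$age, data$wcc)
  data
}
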