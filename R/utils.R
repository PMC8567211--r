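#' Chromosome labels in cytogenetic order
#'
#' The 24 chromosome labels, autosomes 1-22 followed by X and Y. All gain
#' matrices, serialised tables and subset enumerations use this ordering.
#'
#' @export
CHROM_LABELS <- c(as.character(1:22), "X", "Y")

#' @keywords internal
chrom_order <- function(labels) match(as.character(labels), CHROM_LABELS)

#' @keywords internal
assert_chrom_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), CHROM_LABELS)
  if (length(bad) > 0L) {
    stop("invalid chromosome label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Round to whole percent, half away from zero
#'
#' Rounds the way clinical tables are typically presented (53.19 -> 53,
#' 59.65 -> 60, 54.5 -> 55), unlike [round()]'s round-half-even.
#'
#' @param x numeric vector of percentages.
#' @return integer vector.
#' @export
percent_int <- function(x) as.integer(floor(x + 0.5))

#' Whole-percent proportion from a numerator and denominator
#'
#' @param num numerator count.
#' @param den denominator count, > 0.
#' @return integer percent, rounded half-up.
#' @export
proportion_pct <- function(num, den) {
  stopifnot(is.numeric(num), is.numeric(den), den > 0)
  percent_int(100 * num / den)
}

#' Adjusted Rand index between two partitions
#'
#' Agreement between two cluster assignments, corrected for chance; 1 for
#' identical partitions, ~0 for independent ones.
#'
#' @param a,b vectors of cluster labels over the same items.
#' @return numeric in (-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  ntot <- choose(sum(tab), 2)
  expected <- ai * bj / ntot
  maxidx <- (ai + bj) / 2
  if (maxidx == expected) return(1)
  (nij - expected) / (maxidx - expected)
}
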