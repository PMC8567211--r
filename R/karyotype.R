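## ISCN karyotype parsing and cohort screening.
##
## Only the stem (first) clone is parsed: risk classification is made on the
## stem clone and sub-clone handling is intentionally out of scope. The
## supported dialect covers the tokens needed for high-hyperdiploidy work:
## a modal-number prefix (single value or "a-b" range), a sex-chromosome
## field, whole-chromosome "+"/"-" tokens (with multiplicity), "idem",
## "[n]" cell counts (stripped), and the common structural rearrangement
## tokens, which are flagged but never counted as whole-chromosome gains.

STRUCTURAL_RE <- "^[+-]?(t|del|dup|add|der|i|inv|ins|dic|r|trp|hsr)\\("
KARYOTYPE_FLAGS <- c("MASKED_HYPODIPLOID_SUSPECT", "UNPARSEABLE_TOKENS", "MODAL_RANGE")

new_karyotype <- function(raw, modal_low, modal_high, sex, gains, losses,
                          has_structural, flags, subclones = character()) {
  k <- structure(
    list(raw = raw, modal_low = as.integer(modal_low),
         modal_high = as.integer(modal_high), sex = sex,
         gains = as.character(gains), losses = as.character(losses),
         has_structural = isTRUE(has_structural),
         flags = sort(unique(flags)), subclones = subclones),
    class = "heh_karyotype")
  validate_karyotype(k)
}

validate_karyotype <- function(k) {
  assert_chrom_labels(c(k$gains, k$losses))
  stopifnot(k$modal_low <= k$modal_high,
            all(k$flags %in% KARYOTYPE_FLAGS))
  if (("MODAL_RANGE" %in% k$flags) != (k$modal_low < k$modal_high))
    stop("MODAL_RANGE flag inconsistent with modal numbers", call. = FALSE)
  k
}

#' Parse an ISCN karyotype string
#'
#' Parses the stem (first) clone of an ISCN karyotype into a structured
#' record: modal chromosome number (single value or range), whole-chromosome
#' gains and losses with multiplicity (a tetrasomy is a gain of multiplicity
#' 2), and a flag for the presence of structural rearrangements. Sub-clones
#' after "/" are kept as unparsed text with a warning. Cell counts in square
#' brackets are stripped. Unknown tokens set the `UNPARSEABLE_TOKENS` flag
#' rather than failing; a missing or non-numeric modal-number prefix is an
#' error.
#'
#' Karyotypes whose gain pattern looks like a doubled near-haploid or
#' low-hypodiploid clone (at least 60% of distinct gained autosomes present
#' in four or more copies) are flagged `MASKED_HYPODIPLOID_SUSPECT` for
#' exclusion and manual review.
#'
#' @param text a single ISCN karyotype string, e.g.
#'   `"55,XY,+4,+6,+10,+14,+17,+18,+21,+21,+X"`.
#' @return an object of class `heh_karyotype` with fields `raw`,
#'   `modal_low`, `modal_high`, `sex`, `gains`, `losses`, `has_structural`,
#'   `flags` and `subclones`.
#' @examples
#' k <- parse_iscn("55,XY,+4,+6,+10,+14,+17,+18,+21,+21,+X")
#' k$modal_low
#' k$gains
#' @export
parse_iscn <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("karyotype must be a single non-empty string", call. = FALSE)
  raw <- text
  s <- gsub("\\[[0-9]+\\]", "", text)   # strip cell counts
  s <- gsub("[[:space:]]+", "", s)
  clones <- strsplit(s, "/", fixed = TRUE)[[1]]
  subclones <- character()
  if (length(clones) > 1L) {
    subclones <- clones[-1]
    warning("sub-clone(s) after '/' ignored; classification uses the stem clone",
            call. = FALSE)
  }
  toks <- strsplit(clones[1], ",", fixed = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L)
    stop("empty karyotype after normalisation: ", raw, call. = FALSE)

  m <- regmatches(toks[1], regexec("^([0-9]+)(?:[-~]([0-9]+))?$", toks[1]))[[1]]
  if (length(m) == 0L)
    stop("modal-number prefix absent or non-numeric: token '", toks[1], "'",
         call. = FALSE)
  modal_low <- as.integer(m[2])
  modal_high <- if (nzchar(m[3])) as.integer(m[3]) else modal_low
  if (modal_high < modal_low)
    stop("modal range reversed in token '", toks[1], "'", call. = FALSE)

  toks <- toks[-1]
  gains <- character(); losses <- character()
  has_structural <- FALSE
  flags <- character()
  sex <- "XX"

  # optional sex-chromosome field; extra/missing sex chromosomes relative to
  # the inferred constitution (XY if Y present, else XX) become gains/losses
  if (length(toks) > 0L && grepl("^[XY]+$", toks[1])) {
    sx <- strsplit(toks[1], "")[[1]]
    sex <- if ("Y" %in% sx) "XY" else "XX"
    ref <- if ("Y" %in% sx) c(X = 1L, Y = 1L) else c(X = 2L)
    cnt <- c(X = sum(sx == "X"), Y = sum(sx == "Y"))
    for (ch in c("X", "Y")) {
      d <- cnt[[ch]] - if (ch %in% names(ref)) ref[[ch]] else 0L
      if (d > 0L) gains <- c(gains, rep(ch, d))
      if (d < 0L) losses <- c(losses, rep(ch, -d))
    }
    toks <- toks[-1]
  }

  for (tok in toks) {
    if (tok == "idem") next
    if (grepl("^\\+([0-9]+|X|Y)$", tok)) {
      lab <- sub("^\\+", "", tok)
      if (lab %in% CHROM_LABELS) gains <- c(gains, lab)
      else flags <- c(flags, "UNPARSEABLE_TOKENS")
      next
    }
    if (grepl("^[-−–]([0-9]+|X|Y)$", tok)) {
      lab <- sub("^[-−–]", "", tok)
      if (lab %in% CHROM_LABELS) losses <- c(losses, lab)
      else flags <- c(flags, "UNPARSEABLE_TOKENS")
      next
    }
    if (grepl(STRUCTURAL_RE, tok) || grepl("mar", tok, fixed = TRUE)) {
      has_structural <- TRUE
      next
    }
    flags <- c(flags, "UNPARSEABLE_TOKENS")
  }

  if (modal_low < modal_high) flags <- c(flags, "MODAL_RANGE")

  # doubled-clone signature: most gained autosomes tetrasomic
  aut <- gains[gains %in% as.character(1:22)]
  if (length(aut) > 0L) {
    mult <- table(aut)
    if (mean(mult >= 2L) >= 0.6) flags <- c(flags, "MASKED_HYPODIPLOID_SUSPECT")
  }

  k <- new_karyotype(raw, modal_low, modal_high, sex, gains, losses,
                     has_structural, flags, subclones)

  if (!k$has_structural && k$modal_low == k$modal_high &&
      !("UNPARSEABLE_TOKENS" %in% k$flags)) {
    implied <- 46L + length(k$gains) - length(k$losses)
    if (implied != k$modal_low)
      warning("modal number ", k$modal_low, " inconsistent with gain/loss count (",
              implied, ") in: ", raw, call. = FALSE)
  }
  k
}

#' @export
print.heh_karyotype <- function(x, ...) {
  modal <- if (x$modal_low == x$modal_high) x$modal_low
           else paste0(x$modal_low, "-", x$modal_high)
  cat("<heh_karyotype> modal ", modal, ", gains {",
      paste(sort_chrom(x$gains), collapse = ","), "}, losses {",
      paste(sort_chrom(x$losses), collapse = ","), "}",
      if (x$has_structural) ", structural" else "",
      if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ";"), "]") else "",
      "\n", sep = "")
  invisible(x)
}

#' @keywords internal
sort_chrom <- function(labels) labels[order(chrom_order(labels))]

#' Serialise a karyotype record back to canonical ISCN
#'
#' Writes the modal number (or range), the constitutional sex field, then
#' gains and losses in cytogenetic order (1-22, X, Y) with multiplicity.
#' Structural detail is not retained, so karyotypes with structural
#' rearrangements serialise without them.
#'
#' @param k an `heh_karyotype`.
#' @return a single ISCN string.
#' @export
karyotype_to_iscn <- function(k) {
  stopifnot(inherits(k, "heh_karyotype"))
  modal <- if (k$modal_low == k$modal_high) as.character(k$modal_low)
           else paste0(k$modal_low, "-", k$modal_high)
  parts <- c(modal, k$sex,
             paste0("+", sort_chrom(k$gains)),
             paste0("-", sort_chrom(k$losses)))
  paste(parts[nzchar(sub("^[+-]$", "", parts))], collapse = ",")
}

#' Modal chromosome number category
#'
#' Assigns a karyotype to one of the predefined modal-number categories
#' 51-53, 54-57 and 58-65 used for high hyperdiploidy. Karyotypes entirely
#' outside the high-hyperdiploid range (modal high < 51 or modal low > 67)
#' are `"not_heh"`; a modal range that straddles a category boundary (or a
#' modal number of 66-67, which belongs to no category) is
#' `"unclassifiable"`.
#'
#' @param k an `heh_karyotype`.
#' @return one of `"51-53"`, `"54-57"`, `"58-65"`, `"unclassifiable"`,
#'   `"not_heh"`.
#' @export
modal_category <- function(k) {
  stopifnot(inherits(k, "heh_karyotype"))
  if (k$modal_high < 51L || k$modal_low > 67L) return("not_heh")
  cat_of <- function(m) {
    if (m >= 51 && m <= 53) "51-53"
    else if (m >= 54 && m <= 57) "54-57"
    else if (m >= 58 && m <= 65) "58-65"
    else NA_character_
  }
  lo <- cat_of(k$modal_low); hi <- cat_of(k$modal_high)
  if (!is.na(lo) && !is.na(hi) && lo == hi) lo else "unclassifiable"
}

#' Apply cohort inclusion/exclusion screens
#'
#' Excludes records with a concomitant primary fusion (BCR-ABL1,
#' ETV6-RUNX1, KMT2A, TCF3-PBX1 or any other recorded fusion), suspected
#' masked hypodiploidy, or a modal number outside the high-hyperdiploid
#' range. Every exclusion is logged with a reason; the partition property
#' |included| + |excluded| = |input| always holds.
#'
#' @param karyotypes a list of `heh_karyotype` objects.
#' @param fusion optional character vector of fusion labels, one per record;
#'   `NA` or `""` means fusion-negative.
#' @return a list with elements `included` (list of karyotypes),
#'   `included_idx` (their positions in the input), `excluded` (data.frame
#'   of `index`, `reason`) and `counts` (named exclusion counts).
#' @export
screen_cohort <- function(karyotypes, fusion = NULL) {
  if (inherits(karyotypes, "heh_karyotype")) karyotypes <- list(karyotypes)
  n <- length(karyotypes)
  if (!is.null(fusion)) stopifnot(length(fusion) == n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    k <- karyotypes[[i]]
    stopifnot(inherits(k, "heh_karyotype"))
    if (!is.null(fusion) && !is.na(fusion[i]) && nzchar(fusion[i])) {
      reason[i] <- "fusion"
    } else if ("MASKED_HYPODIPLOID_SUSPECT" %in% k$flags) {
      reason[i] <- "masked_hypodiploidy"
    } else if (modal_category(k) == "not_heh") {
      reason[i] <- "not_heh"
    }
  }
  excl <- which(!is.na(reason))
  incl <- which(is.na(reason))
  counts <- c(included = length(incl),
              fusion = sum(reason == "fusion", na.rm = TRUE),
              masked_hypodiploidy = sum(reason == "masked_hypodiploidy", na.rm = TRUE),
              not_heh = sum(reason == "not_heh", na.rm = TRUE))
  list(included = karyotypes[incl], included_idx = incl,
       excluded = data.frame(index = excl, reason = reason[excl],
                             stringsAsFactors = FALSE),
       counts = counts)
}

#' Tabulate karyotypes as a binary gains table
#'
#' One row per karyotype with 24 binary gain columns `gain_1` .. `gain_22`,
#' `gain_X`, `gain_Y` (1 when at least one extra copy is present, so
#' tetrasomies count as gained), plus `modal_low`, `modal_high` and a
#' semicolon-joined `flags` column.
#'
#' @param karyotypes a list of `heh_karyotype` objects.
#' @param ids optional identifiers (default `K1..Kn`).
#' @return a data.frame.
#' @export
gains_table <- function(karyotypes, ids = NULL) {
  if (inherits(karyotypes, "heh_karyotype")) karyotypes <- list(karyotypes)
  n <- length(karyotypes)
  if (is.null(ids)) ids <- paste0("K", seq_len(n))
  g <- matrix(0L, n, length(CHROM_LABELS),
              dimnames = list(NULL, paste0("gain_", CHROM_LABELS)))
  lo <- integer(n); hi <- integer(n); fl <- character(n)
  for (i in seq_len(n)) {
    k <- karyotypes[[i]]
    g[i, paste0("gain_", unique(k$gains))] <- 1L
    lo[i] <- k$modal_low; hi[i] <- k$modal_high
    fl[i] <- paste(k$flags, collapse = ";")
  }
  cbind(data.frame(id = ids, stringsAsFactors = FALSE),
        as.data.frame(g),
        data.frame(modal_low = lo, modal_high = hi, flags = fl,
                   stringsAsFactors = FALSE))
}

#' Read one-karyotype-per-line text files
#'
#' @param path text file with one ISCN string per line; blank lines and
#'   lines starting with `#` are skipped.
#' @return a list of `heh_karyotype` objects.
#' @export
read_iscn_lines <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, parse_iscn)
}

#' Write a normalised gains table CSV
#'
#' @param karyotypes a list of `heh_karyotype` objects.
#' @param path output CSV path.
#' @param ids optional identifiers.
#' @return the table, invisibly.
#' @export
write_gains_table <- function(karyotypes, path, ids = NULL) {
  tab <- gains_table(karyotypes, ids)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
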