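test_that("parse_iscn handles hyperdiploid, range and diploid karyotypes", {
  k <- parse_iscn("55,XY,+4,+6,+10,+14,+17,+18,+21,+21,+X")
  expect_equal(k$modal_low, 55L)
  expect_equal(k$modal_high, 55L)
  expect_setequal(k$gains, c("4", "6", "10", "14", "17", "18", "21", "21", "X"))
  expect_equal(sum(k$gains == "21"), 2)  # tetrasomy = multiplicity 2
  expect_length(k$losses, 0)
  expect_false(k$has_structural)

  r <- parse_iscn("51-53,XX,+4,+10,+17,+18,+21")
  expect_equal(r$modal_low, 51L)
  expect_equal(r$modal_high, 53L)
  expect_true("MODAL_RANGE" %in% r$flags)

  d <- parse_iscn("46,XY")
  expect_equal(d$modal_low, 46L)
  expect_length(d$gains, 0)
  expect_length(d$losses, 0)
})

test_that("parse_iscn handles losses, structural tokens, cell counts and clones", {
  k <- parse_iscn("45,XX,-7[12]")
  expect_equal(k$losses, "7")
  k2 <- parse_iscn("47,XY,+21,t(9;22)(q34;q11)")
  expect_true(k2$has_structural)
  expect_equal(k2$gains, "21")
  expect_warning(k3 <- parse_iscn("55,XY,+4,+6,+10,+14,+17,+18,+21,+21,+X/46,XY"),
                 "stem clone")
  expect_equal(k3$modal_low, 55L)
  expect_equal(k3$subclones, "46,XY")
  # sex-field anomalies
  kx <- parse_iscn("45,X")
  expect_equal(kx$losses, "X")
  kxxy <- parse_iscn("47,XXY")
  expect_equal(kxxy$gains, "X")
})

test_that("parse_iscn errors on a bad modal prefix and flags unknown tokens", {
  expect_error(parse_iscn("XY,+4"), "modal-number prefix")
  expect_error(parse_iscn(""), "non-empty")
  k <- parse_iscn("47,XY,+21,wtf(3)")
  expect_true("UNPARSEABLE_TOKENS" %in% k$flags)
  k2 <- parse_iscn("47,XY,+23")  # not a chromosome label
  expect_true("UNPARSEABLE_TOKENS" %in% k2$flags)
})

test_that("doubled near-haploid signatures are flagged as masked hypodiploidy", {
  # doubled 27-chromosome near-haploid clone: retained disomies become
  # tetrasomies after doubling
  k <- parse_iscn("54,XX,+4,+4,+6,+6,+10,+10,+14,+21")
  expect_true("MASKED_HYPODIPLOID_SUSPECT" %in% k$flags)
  # genuine high hyperdiploidy with one duplicated gain is not flagged
  k2 <- parse_iscn("55,XY,+4,+6,+10,+14,+17,+18,+21,+21,+X")
  expect_false("MASKED_HYPODIPLOID_SUSPECT" %in% k2$flags)
})

test_that("modal_category reproduces the predefined bins and edge rules", {
  cat_of <- function(s) modal_category(parse_iscn(s))
  expect_equal(cat_of("55,XY,+4,+6,+10,+14,+17,+18,+21,+21,+X"), "54-57")
  expect_equal(cat_of("51-53,XX,+4,+10,+17,+18,+21"), "51-53")
  expect_equal(cat_of("46,XY"), "not_heh")
  # range straddling a category boundary
  k <- parse_iscn("53-55,XX,+4,+10,+17,+18,+21")
  expect_equal(modal_category(k), "unclassifiable")
  # 66-67 is hyperdiploid but belongs to no reporting category
  k66 <- suppressWarnings(parse_iscn("66,XY"))
  expect_equal(modal_category(k66), "unclassifiable")
  expect_equal(modal_category(suppressWarnings(parse_iscn("68,XY"))), "not_heh")
})

test_that("screen_cohort excludes fusions, masked hypodiploidy and non-HeH", {
  ks <- list(parse_iscn("55,XY,+4,+6,+10,+14,+17,+18,+21,+21,+X"),
             parse_iscn("54,XX,+5,+6,+8,+10,+14,+17,+18,+21"),
             parse_iscn("54,XX,+4,+4,+6,+6,+10,+10,+14,+21"),   # masked
             parse_iscn("46,XY"))                               # not HeH
  fusion <- c(NA, "ETV6-RUNX1", NA, NA)
  scr <- screen_cohort(ks, fusion)
  expect_equal(length(scr$included), 1)
  expect_equal(scr$excluded$reason, c("fusion", "masked_hypodiploidy", "not_heh"))
  # partition property
  expect_equal(length(scr$included) + nrow(scr$excluded), length(ks))
  # empty input
  empty <- screen_cohort(list())
  expect_equal(length(empty$included), 0)
  expect_equal(nrow(empty$excluded), 0)
})

test_that("karyotypes round-trip through canonical ISCN serialisation", {
  set.seed(11)
  for (rep in 1:25) {
    n_gain <- sample(5:12, 1)
    gains <- sample(c(as.character(1:22), "X"), n_gain, replace = TRUE)
    modal <- 46L + n_gain
    sex <- sample(c("XX", "XY"), 1)
    s <- paste(c(modal, sex, paste0("+", gains[order(match(gains, labs_all))])),
               collapse = ",")
    k <- parse_iscn(s)
    k2 <- parse_iscn(karyotype_to_iscn(k))
    expect_equal(k2$modal_low, k$modal_low)
    expect_equal(sort(k2$gains), sort(k$gains))
    expect_equal(k2$flags, k$flags)
    # modal arithmetic invariant for numeric karyotypes
    expect_equal(k$modal_low, 46L + length(k$gains) - length(k$losses))
  }
})

test_that("gains tables have the full 24-column layout and survive CSV round trips", {
  ks <- list(parse_iscn("55,XY,+4,+6,+10,+14,+17,+18,+21,+21,+X"),
             parse_iscn("52,XX,+5,+8,+17,+18,+20,+21"))
  tab <- gains_table(ks, ids = c("a", "b"))
  expect_true(all(paste0("gain_", labs_all) %in% names(tab)))
  expect_equal(tab$gain_21, c(1L, 1L))
  expect_equal(tab$gain_5, c(0L, 1L))
  tmp <- tempfile(fileext = ".csv")
  write_gains_table(ks, tmp, ids = c("a", "b"))
  back <- read.csv(tmp)
  expect_equal(back$gain_17, tab$gain_17)
  unlink(tmp)
})

test_that("one-karyotype-per-line files are read with comments skipped", {
  tmp <- tempfile(fileext = ".txt")
  writeLines(c("# header", "55,XY,+4,+6,+10,+14,+17,+18,+21,+21,+X", "",
               "46,XY"), tmp)
  ks <- read_iscn_lines(tmp)
  expect_length(ks, 2)
  expect_equal(ks[[1]]$modal_low, 55L)
  unlink(tmp)
})
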