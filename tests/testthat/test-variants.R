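# read_variants on hand-built VCF fixtures (positions sit inside the default
# panel's DNMT3A intervals: chr2:25234301-25235300 in 1-based coordinates)

test_that("VAF is computed from AD/DP per sample", {
  vcf <- write_test_vcf(
    withr::local_tempfile(fileext = ".vcf"),
    paste(c("chr2", "25234400", ".", "A", "G", ".", "PASS", ".", "GT:DP:AD",
            "0/1:2000:1960,40", "0/1:1800:1620,180"), collapse = "\t"))
  calls <- read_variants(vcf, load_panel(), make_test_meta())
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$vaf[calls$timepoint == 1L], 0.02)
  expect_equal(calls$vaf[calls$timepoint == 2L], 0.1)
  expect_equal(calls$gene, c("DNMT3A", "DNMT3A"))
  expect_equal(calls$individual_id, c("A", "A"))
})

test_that("calls outside every panel interval get gene = NA", {
  vcf <- write_test_vcf(
    withr::local_tempfile(fileext = ".vcf"),
    paste(c("chr2", "999", ".", "A", "G", ".", "PASS", ".", "GT:DP:AD",
            "0/1:2000:1960,40", "./.:.:."), collapse = "\t"))
  calls <- read_variants(vcf, load_panel(), make_test_meta())
  expect_equal(nrow(calls), 1L)  # the ./. sample contributes no call
  expect_true(is.na(calls$gene))
})

test_that("multi-allelic records decompose into one call per alt allele", {
  vcf <- write_test_vcf(
    withr::local_tempfile(fileext = ".vcf"),
    paste(c("chr2", "25234400", ".", "A", "G,T", ".", "PASS", ".", "GT:DP:AD",
            "0/1:2000:1900,60,40", "./.:.:."), collapse = "\t"))
  calls <- read_variants(vcf, load_panel(), make_test_meta())
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$alt, c("G", "T"))
  expect_equal(calls$vaf, c(0.03, 0.02))
  expect_equal(calls$depth, c(2000L, 2000L))
})

test_that("missing FORMAT fields and unmappable samples are errors", {
  vcf <- write_test_vcf(
    withr::local_tempfile(fileext = ".vcf"),
    paste(c("chr2", "25234400", ".", "A", "G", ".", "PASS", ".", "GT:DP",
            "0/1:2000", "0/1:1800"), collapse = "\t"))
  expect_error(read_variants(vcf, load_panel(), make_test_meta()),
               "chr2:25234400")

  vcf2 <- write_test_vcf(
    withr::local_tempfile(fileext = ".vcf"),
    paste(c("chr2", "25234400", ".", "A", "G", ".", "PASS", ".", "GT:DP:AD",
            "0/1:2000:1960,40", "0/1:1800:1620,180"), collapse = "\t"),
    samples = c("A_T1", "UNKNOWN"))
  expect_error(read_variants(vcf2, load_panel(), make_test_meta()), "UNKNOWN")
})

test_that("empty VCF yields an empty, well-typed call table", {
  vcf <- write_test_vcf(withr::local_tempfile(fileext = ".vcf"), character(0))
  calls <- read_variants(vcf, load_panel(), make_test_meta())
  expect_equal(nrow(calls), 0L)
  expect_true(all(c("individual_id", "vaf", "gene") %in% names(calls)))
})

# --- filter_chip -----------------------------------------------------------

test_that("filter boundaries: >= passes, below-threshold rules remove", {
  base <- make_calls(1, seed = 1)[rep(1, 4), ]
  base$gene <- "DNMT3A"
  base$depth <- c(2000L, 99L, 2000L, 100L)
  base$alt_reads <- c(40L, 40L, 2L, 3L)
  base$vaf <- base$alt_reads / base$depth
  base$vaf[4] <- 0.02
  kept <- filter_chip(base, quiet = TRUE)
  # row 1: all rules pass at/above threshold; row 2: depth 99 < 100;
  # row 3: alt 2 < 3 and vaf 0.001 < 2%; row 4: exact boundary passes
  expect_equal(which(seq_len(4) %in% which(oracle_filter_keep(base, chip_filter_policy()))),
               c(1L, 4L))
  expect_equal(nrow(kept), 2L)
  stats <- attr(kept, "filter_stats")
  expect_equal(stats$retained, 2L)
  expect_equal(stats$fail_depth, 1L)
  expect_equal(stats$fail_alt_reads, 1L)
})

test_that("filtering equals the per-record predicate oracle and is idempotent", {
  for (seed in 1:3) {
    calls <- make_calls(2000, seed = seed)
    kept <- filter_chip(calls, quiet = TRUE)
    oracle <- calls[oracle_filter_keep(calls, chip_filter_policy()), ]
    key <- function(df) paste(df$individual_id, df$timepoint, df$pos,
                              df$alt_reads, df$depth)
    expect_setequal(key(kept), key(oracle))
    again <- filter_chip(kept, quiet = TRUE)
    expect_equal(as.data.frame(again), as.data.frame(kept),
                 ignore_attr = TRUE)
  }
})

test_that("filtering an empty call set returns an empty set with zero stats", {
  empty <- make_calls(1, seed = 1)[0, ]
  out <- filter_chip(empty, quiet = TRUE)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "filter_stats")$total, 0L)
})

# --- pair_timepoints -------------------------------------------------------

two_tp_vcf <- function(dp1, ad1, dp2, ad2, pos = 25234400,
                       .env = parent.frame()) {
  write_test_vcf(
    withr::local_tempfile(fileext = ".vcf", .local_envir = .env),
    paste(c("chr2", pos, ".", "A", "G", ".", "PASS", ".", "GT:DP:AD",
            sprintf("0/1:%d:%d,%d", dp1, dp1 - ad1, ad1),
            sprintf("0/1:%d:%d,%d", dp2, dp2 - ad2, ad2)),
          collapse = "\t"))
}

test_that("mutations passing at both timepoints pair directly", {
  vcf <- two_tp_vcf(2000, 80, 2000, 120)
  calls <- read_variants(vcf, load_panel(), make_test_meta(dt_years = 5))
  retained <- filter_chip(calls, quiet = TRUE)
  pairs <- pair_timepoints(retained, calls, make_test_meta(dt_years = 5))
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$vaf1, 0.04)
  expect_equal(pairs$vaf2, 0.06)
  expect_true(pairs$pass_t1 && pairs$pass_t2)
  expect_false(pairs$imputed_t1 || pairs$imputed_t2)
  expect_equal(pairs$dt_years, round(5 * 365.25) / 365.25)
})

test_that("a mutation absent at one timepoint is imputed at the 0.001 floor", {
  # t1 sample has zero alt reads -> no rescue possible -> floor
  vcf <- two_tp_vcf(2000, 0, 2000, 100)
  calls <- read_variants(vcf, load_panel(), make_test_meta())
  retained <- filter_chip(calls, quiet = TRUE)
  pairs <- pair_timepoints(retained, calls, make_test_meta())
  expect_equal(pairs$vaf1, 0.001)
  expect_equal(pairs$vaf2, 0.05)
  expect_true(pairs$imputed_t1)
  expect_false(pairs$pass_t1)
  expect_true(pairs$pass_t2)
})

test_that("sub-threshold calls at the other timepoint are rescued, not imputed", {
  # t2 has vaf 0.012 (< 2%) with 24 alt reads (>= 3): rescue supplies 0.012
  vcf <- two_tp_vcf(2000, 60, 2000, 24)
  calls <- read_variants(vcf, load_panel(), make_test_meta())
  retained <- filter_chip(calls, quiet = TRUE)
  pairs <- pair_timepoints(retained, calls, make_test_meta())
  expect_equal(pairs$vaf1, 0.03)
  expect_equal(pairs$vaf2, 0.012)
  expect_false(pairs$imputed_t2)
  expect_false(pairs$pass_t2)

  # with rescue disabled the same mutation falls back to the floor
  policy <- chip_filter_policy(rescue_cross_timepoint = FALSE)
  pairs2 <- pair_timepoints(retained, calls, make_test_meta(), policy)
  expect_equal(pairs2$vaf2, 0.001)
  expect_true(pairs2$imputed_t2)
})

test_that("rescued VAFs are floored so every pair stays in [floor_vaf, 1]", {
  # 3 alt reads at depth 10000 gives raw vaf 3e-4 < floor 0.001
  vcf <- two_tp_vcf(2000, 60, 10000, 3)
  calls <- read_variants(vcf, load_panel(), make_test_meta())
  retained <- filter_chip(calls, quiet = TRUE)
  pairs <- pair_timepoints(retained, calls, make_test_meta())
  expect_equal(pairs$vaf2, 0.001)
  expect_true(all(pairs$vaf1 >= 0.001 & pairs$vaf1 <= 1))
  expect_true(pairs$vaf1 >= 0.02 | pairs$vaf2 >= 0.02)
})

test_that("blood-cancer individuals are dropped and dt errors are raised", {
  vcf <- two_tp_vcf(2000, 80, 2000, 120)
  meta <- make_test_meta()
  calls <- read_variants(vcf, load_panel(), meta)
  retained <- filter_chip(calls, quiet = TRUE)

  meta_bc <- meta
  meta_bc$blood_cancer_flag <- TRUE
  expect_equal(nrow(pair_timepoints(retained, calls, meta_bc)), 0L)

  meta_one_tp <- meta[meta$timepoint == 1L, ]
  expect_warning(
    out <- pair_timepoints(retained, calls, meta_one_tp),
    "without two dated timepoints")
  expect_equal(nrow(out), 0L)

  meta_neg <- meta
  meta_neg$draw_date[meta_neg$timepoint == 2L] <- "2009-01-01"
  expect_error(pair_timepoints(retained, calls, meta_neg), "non-positive")
})

test_that("ages stand in for draw dates when dates are missing", {
  vcf <- two_tp_vcf(2000, 80, 2000, 120)
  meta <- make_test_meta(dt_years = 5)
  meta$draw_date <- NA_character_
  calls <- read_variants(vcf, load_panel(), meta)
  retained <- filter_chip(calls, quiet = TRUE)
  pairs <- pair_timepoints(retained, calls, meta)
  expect_equal(pairs$dt_years, 5)
})
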