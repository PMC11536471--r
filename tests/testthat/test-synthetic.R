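test_that("identical config and seed give identical cohorts and fixture bytes", {
  cfg <- sim_config(n_individuals = 25)
  c1 <- simulate_cohort(cfg, seed = 11)
  c2 <- simulate_cohort(cfg, seed = 11)
  expect_equal(c1$clones, c2$clones)
  expect_equal(c1$observed, c2$observed)
  expect_equal(c1$individuals, c2$individuals)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_fixtures(c1, d1); p2 <- write_fixtures(c2, d2)
  for (f in names(p1)) {
    expect_identical(unname(tools::md5sum(p1[[f]])),
                     unname(tools::md5sum(p2[[f]])), label = f)
  }
  c3 <- simulate_cohort(cfg, seed = 12)
  expect_false(identical(c1$clones$true_cf, c3$clones$true_cf))
})

test_that("degenerate configs behave as specified", {
  cfg1 <- sim_config(n_individuals = 40, mutation_count_probs = c(1, 0, 0))
  c1 <- simulate_cohort(cfg1, seed = 2)
  expect_true(all(c1$individuals$n_mutations == 1L))
  expect_equal(nrow(c1$clones), 40L)

  # zero growth-rate variance: every clone of the gene has exactly the mean
  # rate (VAF cap not binding at these sizes/horizons)
  cfg2 <- sim_config(n_individuals = 30,
                     gene_frequencies = c(DNMT3A = 1),
                     gene_growth = list(DNMT3A = c(0.08, 0)),
                     vaf1_range = c(0.02, 0.05),
                     mutation_count_probs = c(1, 0, 0))
  c2 <- simulate_cohort(cfg2, seed = 3)
  expect_equal(c2$clones$true_cf, rep(0.08, 30), tolerance = 1e-10)
})

test_that("invalid probability vectors are rejected", {
  expect_error(sim_config(mutation_count_probs = c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(sim_config(gene_frequencies = c(DNMT3A = 0.5)), "sum to 1")
})

test_that("mutation-count mix matches 66/26/8% within binomial error at n = 500", {
  cohort <- simulate_cohort(sim_config(n_individuals = 500), seed = 19)
  frac <- as.numeric(table(factor(cohort$individuals$n_mutations, 1:3)) / 500)
  for (k in 1:3) {
    p <- c(0.66, 0.26, 0.08)[k]
    expect_lt(abs(frac[k] - p), 3 * sqrt(p * (1 - p) / 500))
  }
})

test_that("nested sub-clones never outgrow their parent clone", {
  cohort <- simulate_cohort(sim_config(n_individuals = 300,
                                       architecture_prob = 1,
                                       mutation_count_probs = c(0, 1, 0)),
                            seed = 23)
  cl <- cohort$clones
  for (id in unique(cl$individual_id)) {
    rows <- cl[cl$individual_id == id, ]
    parent <- rows[rows$role == "parent", ]; child <- rows[rows$role == "child", ]
    expect_lte(child$true_vaf1, parent$true_vaf1)
    expect_lte(child$true_vaf2, parent$true_vaf2)
  }
  expect_true(all(cohort$individuals$true_architecture == "sub-clone"))
})

test_that("sequencing noise model has the binomial mean and zero-VAF identity", {
  reads0 <- sample_reads(rep(0, 200), 2000, seed = 5)
  expect_true(all(reads0$alt_reads == 0L))

  reads <- sample_reads(rep(0.01, 20000), 2000, seed = 6)
  expect_equal(mean(reads$alt_reads), 20, tolerance = 0.05)
  expect_true(all(reads$alt_reads <= reads$depth))
})

test_that("dilution series: expected VAF is linear in the mixing ratio", {
  dil <- simulate_dilution_series(ratios = c(1, 0.02, 0.006), depth_mean = 2000,
                                  n_replicates = 2000, seed = 7)
  expect_equal(dil$expected_vaf, c(0.5, 0.01, 0.003))
  # detection degrades below 1% expected VAF but persists near 0.3%
  expect_gt(dil$detection_rate[dil$expected_vaf == 0.01],
            dil$detection_rate[dil$expected_vaf == 0.003])
  expect_gt(dil$detection_rate[dil$expected_vaf == 0.01], 0.99)
  expect_gt(dil$detection_rate[dil$expected_vaf == 0.003], 0.8)
  # relative VAF error grows as the expected VAF shrinks
  expect_gt(dil$rel_vaf_error[3], dil$rel_vaf_error[1])
})

test_that("fixtures round-trip losslessly through the VCF reader", {
  cohort <- simulate_cohort(sim_config(n_individuals = 20), seed = 31)
  paths <- write_fixtures(cohort, withr::local_tempdir())
  calls <- read_variants(paths$vcf, load_panel(),
                         read_sample_metadata(paths$metadata))
  obs <- cohort$observed
  key <- function(df) paste(df$individual_id, df$timepoint, df$contig, df$pos,
                            df$ref, df$alt)
  calls <- calls[match(key(obs), key(calls)), ]
  expect_false(anyNA(calls$depth))
  expect_equal(calls$depth, obs$depth)
  expect_equal(calls$alt_reads, obs$alt_reads)
  expect_equal(calls$gene, obs$gene)  # gene re-derived from panel intervals
})

test_that("estimated growth rates converge to truth at very high depth", {
  cfg <- sim_config(n_individuals = 60, depth_mean = 1e5,
                    mutation_count_probs = c(1, 0, 0),
                    vaf1_range = c(0.05, 0.3))
  cohort <- simulate_cohort(cfg, seed = 41)
  paths <- write_fixtures(cohort, withr::local_tempdir())
  meta <- read_sample_metadata(paths$metadata)
  calls <- read_variants(paths$vcf, load_panel(), meta)
  pairs <- pair_timepoints(filter_chip(calls, quiet = TRUE), calls, meta)
  est <- compute_growth_rate(pairs$vaf1, pairs$vaf2, pairs$dt_years)
  truth <- cohort$clones$true_cf[match(
    paste(pairs$individual_id, pairs$mutation_key),
    paste(cohort$clones$individual_id, cohort$clones$mutation_key))]
  expect_gt(length(est), 50)
  expect_gt(cor(est, truth), 0.999)
  expect_lt(mean(abs(est - truth)), 0.005)
})

test_that("architecture calls beat chance on strongly separated cohorts", {
  # sub-clones drawn with near-identical growth, distinct clones with widely
  # spread growth: the z-gap heuristic should recover the true label well
  # above the 50% chance line. The rate is reported, not promised: it is an
  # upper bound on real-data accuracy, where separation is weaker.
  cfg <- sim_config(n_individuals = 120,
                    mutation_count_probs = c(0, 1, 0),
                    architecture_prob = 0.5,
                    gene_growth = list(DNMT3A = c(0.10, 0.60)),
                    default_growth = c(0.10, 0.60),
                    subclone_cf_jitter = 0.005,
                    depth_mean = 5000)
  cohort <- simulate_cohort(cfg, seed = 53)
  paths <- write_fixtures(cohort, withr::local_tempdir())
  meta <- read_sample_metadata(paths$metadata)
  calls <- read_variants(paths$vcf, load_panel(), meta)
  pairs <- pair_timepoints(filter_chip(calls, quiet = TRUE), calls, meta)
  a <- zscore_within_class(classify_trajectories(pairs))
  arch <- call_architectures(a)
  truth <- cohort$individuals$true_architecture[
    match(arch$individual_id, cohort$individuals$individual_id)]
  accuracy <- mean(arch$architecture == truth)
  message(sprintf("architecture recovery on separated cohort: %.1f%% of %d",
                  100 * accuracy, nrow(arch)))
  expect_gt(nrow(arch), 100)
  expect_gt(accuracy, 0.5)
})

test_that("a clone crossing 2% between draws enters the pipeline via rescue", {
  cfg <- sim_config(n_individuals = 30, vaf1_range = c(0.010, 0.014),
                    gene_frequencies = c(DNMT3A = 1),
                    gene_growth = list(DNMT3A = c(1.0, 0)),
                    mutation_count_probs = c(1, 0, 0),
                    dt_range = c(3, 8))
  cohort <- simulate_cohort(cfg, seed = 47)
  paths <- write_fixtures(cohort, withr::local_tempdir())
  meta <- read_sample_metadata(paths$metadata)
  calls <- read_variants(paths$vcf, load_panel(), meta)
  pairs <- pair_timepoints(filter_chip(calls, quiet = TRUE), calls, meta)
  crossed <- pairs[!pairs$pass_t1 & pairs$pass_t2, ]
  expect_gt(nrow(crossed), 0)
  # at ~1725x a 1%-VAF clone has >= 3 alt reads essentially always: the t1
  # VAF must come from rescue, not the imputation floor
  expect_true(all(!crossed$imputed_t1))
  expect_true(all(crossed$vaf1 < 0.02))
})
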