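# Brute-force reference implementations and fixture builders shared across
# tests. The oracles deliberately use naive per-record loops / O(n^2)
# selection so they stay independent of the vectorized package code paths.

# --- filtering oracle: evaluate the three-clause predicate per record ------
oracle_filter_keep <- function(calls, policy) {
  keep <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    keep[i] <- calls$depth[i] >= policy$min_depth &&
      calls$alt_reads[i] >= policy$min_alt_reads &&
      calls$vaf[i] >= policy$min_vaf &&
      !is.na(calls$gene[i])
  }
  keep
}

# --- trajectory oracle: repeated minimum selection on (|cf|, id, key) ------
oracle_trajectories <- function(df, stagnant_fraction = 0.10) {
  n <- nrow(df)
  lt <- function(i, j) {
    if (abs(df$cf[i]) != abs(df$cf[j])) return(abs(df$cf[i]) < abs(df$cf[j]))
    if (df$individual_id[i] != df$individual_id[j]) {
      return(df$individual_id[i] < df$individual_id[j])
    }
    df$mutation_key[i] < df$mutation_key[j]
  }
  remaining <- seq_len(n)
  stagnant <- integer(0)
  for (s in seq_len(ceiling(stagnant_fraction * n))) {
    best <- remaining[1L]
    for (i in remaining) if (lt(i, best)) best <- i
    stagnant <- c(stagnant, best)
    remaining <- setdiff(remaining, best)
  }
  traj <- ifelse(df$cf > 0, "expansion", "reduction")
  traj[df$cf == 0] <- "expansion"
  traj[stagnant] <- "stagnant"
  traj
}

oracle_zscores <- function(cf, trajectory) {
  z <- numeric(length(cf))
  for (cls in unique(trajectory)) {
    idx <- which(trajectory == cls)
    if (length(idx) < 2L) { z[idx] <- 0; next }
    m <- sum(cf[idx]) / length(idx)
    s <- sqrt(sum((cf[idx] - m)^2) / (length(idx) - 1L))
    z[idx] <- if (s > 0) (cf[idx] - m) / s else 0
  }
  z
}

oracle_architecture <- function(traj, z, threshold = 0.6) {
  if (traj[1L] != traj[2L]) return("distinct")
  if (abs(z[1L] - z[2L]) >= threshold) "distinct" else "sub-clone"
}

# --- fixture builders ------------------------------------------------------
make_calls <- function(n, seed = 1) {
  withr::with_seed(seed, {
    depth <- sample(c(20:200, 1000:2500), n, replace = TRUE)
    alt_reads <- rbinom(n, depth, runif(n, 0, 0.06))
    tibble::tibble(
      individual_id = sprintf("I%03d", sample(60, n, replace = TRUE)),
      timepoint = sample(1:2, n, replace = TRUE),
      sample_id = "s",
      contig = "chr2",
      pos = sample(25234301:25235300, n, replace = TRUE),
      ref = "A", alt = "G",
      depth = as.integer(depth),
      alt_reads = as.integer(alt_reads),
      vaf = alt_reads / depth,
      gene = sample(c("DNMT3A", "TET2", "JAK2", NA), n, replace = TRUE,
                    prob = c(0.4, 0.3, 0.2, 0.1)),
      protein_change = NA_character_,
      consequence = NA_character_)
  })
}

# minimal two-timepoint, one-individual VCF fixture
write_test_vcf <- function(path, records, samples = c("A_T1", "A_T2")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr2>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

make_test_meta <- function(ids = "A", dt_years = 5) {
  n <- length(ids)
  tibble::tibble(
    sample_id = c(paste0(ids, "_T1"), paste0(ids, "_T2")),
    individual_id = rep(ids, 2L),
    timepoint = rep(1:2, each = n),
    draw_date = c(rep("2010-01-01", n),
                  as.character(as.Date("2010-01-01") +
                                 round(rep(dt_years, length.out = n) * 365.25))),
    age = c(rep(60, n), 60 + rep(dt_years, length.out = n)),
    sex = "female", race = "Caucasian", ethnicity = "Not Hispanic",
    bmi = 25, height = 170, blood_cancer_flag = FALSE)
}

# random small cohorts of clone assignments for classifier equivalence tests
random_clone_cohort <- function(n, seed) {
  withr::with_seed(seed, {
    n_ind <- max(1L, ceiling(n / 2))
    ids <- sprintf("P%02d", sample(n_ind, n, replace = TRUE))
    tibble::tibble(
      individual_id = ids,
      mutation_key = sprintf("chr1:%d:A:T", sample(1e6, n)),
      gene = sample(c("DNMT3A", "TET2", "JAK2"), n, replace = TRUE),
      cf = round(rnorm(n, 0.1, 0.5), 3))   # rounding provokes |cf| ties
  })
}
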