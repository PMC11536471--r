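#' Synthetic cohort configuration
#'
#' Parameters of the ground-truthed cohort generator. The defaults emulate a
#' two-timepoint biobank CHIP/CCUS cohort: a driver-gene distribution skewed
#' toward DNMT3A and TET2; 66% / 26% / 8% of individuals carrying one / two /
#' three driver mutations; gene-specific annual growth (e.g. JAK2 fast at
#' 1.09/yr, DNMT3A slow at 0.08/yr); first-draw ages around 65 +/- 15 years;
#' 1 to 12.5 years between draws; and sequencing at a mean depth of 1725x.
#' Within-gene growth-rate SDs are generator settings chosen for testability
#' (no empirical within-gene variance is assumed); see the package vignette.
#'
#' @param n_individuals Number of individuals (default 101).
#' @param gene_frequencies Named probabilities of each driver gene.
#' @param gene_growth Named list, gene -> c(mean, sd) annual growth rate.
#' @param default_growth c(mean, sd) for genes missing from `gene_growth`.
#' @param mutation_count_probs Probabilities of 1, 2, 3 driver mutations.
#' @param age_mean,age_sd First-draw age distribution (years).
#' @param age_range Ages truncated to this range.
#' @param dt_range Years between draws, uniform over this range.
#' @param depth_mean Mean sequencing depth (Poisson).
#' @param vaf1_range True VAF at the first draw, log-uniform over this range.
#' @param architecture_prob Probability that a two-mutation individual is a
#'   nested sub-clone (rather than two distinct clones).
#' @param subclone_cf_jitter SD of the child-vs-parent growth-rate offset for
#'   nested sub-clones (they share the parent's trajectory plus a small
#'   increment).
#' @param female_prob,caucasian_prob,hispanic_prob Demographic mix.
#' @param bmi_mean,bmi_sd,height_mean,height_sd Anthropometrics.
#' @param seed Default seed used by [simulate_cohort()] when none is given.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 101L,
                       gene_frequencies = c(DNMT3A = 0.50, TET2 = 0.18,
                                            JAK2 = 0.08, PPM1D = 0.07,
                                            ASXL1 = 0.05, SF3B1 = 0.03,
                                            TP53 = 0.03, SRSF2 = 0.02,
                                            GNB1 = 0.02, KRAS = 0.02),
                       gene_growth = list(DNMT3A = c(0.08, 0.20),
                                          TET2 = c(0.10, 0.20),
                                          JAK2 = c(1.09, 0.60),
                                          PPM1D = c(0.15, 0.25),
                                          ASXL1 = c(0.05, 0.30)),
                       default_growth = c(0.10, 0.25),
                       mutation_count_probs = c(0.66, 0.26, 0.08),
                       age_mean = 65, age_sd = 15, age_range = c(18, 91),
                       dt_range = c(1, 12.5),
                       depth_mean = 1725,
                       vaf1_range = c(0.02, 0.30),
                       architecture_prob = 14 / 26,
                       subclone_cf_jitter = 0.02,
                       female_prob = 0.60, caucasian_prob = 0.81,
                       hispanic_prob = 0.04,
                       bmi_mean = 28, bmi_sd = 5,
                       height_mean = 170, height_sd = 10,
                       seed = 1L) {
  stopifnot(n_individuals >= 1, depth_mean > 0, all(dt_range > 0),
            length(mutation_count_probs) == 3L,
            all(mutation_count_probs >= 0))
  if (abs(sum(mutation_count_probs) - 1) > 1e-8) {
    stop("mutation_count_probs must sum to 1", call. = FALSE)
  }
  if (abs(sum(gene_frequencies) - 1) > 1e-8) {
    stop("gene_frequencies must sum to 1", call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

gene_growth_params <- function(config, gene) {
  gp <- config$gene_growth[[gene]]
  if (is.null(gp)) config$default_growth else gp
}

# truncated-normal growth draw; a clone cannot shrink below -95%/yr
draw_cf <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  while (any(bad <- out <= -0.95)) out[bad] <- rnorm(sum(bad), mean, sd)
  out
}

#' Simulate a ground-truthed two-timepoint CHIP cohort
#'
#' Draws per-individual mutation counts, driver genes, true first-draw VAFs
#' (log-uniform), and true annual growth rates (gene-specific normal,
#' truncated above -0.95), then projects each clone's true VAF to the second
#' draw under the exponential model. Two-mutation individuals are assigned a
#' true architecture: nested sub-clones share the parent's growth direction
#' (parent growth plus a small jitter) with the child's cell fraction capped
#' at the parent's; distinct clones are drawn independently. True VAF equals
#' half the mutant cell fraction (heterozygous autosomal mutations), capped
#' at 0.5. Observed reads are then sampled per clone and timepoint: depth ~
#' Poisson(`depth_mean`), alt reads ~ Binomial(depth, true VAF).
#'
#' Everything is deterministic given (`config`, `seed`).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param panel A `chip_panel` in which mutation positions are placed.
#' @return Object of class `sim_cohort`: list with `individuals` (metadata +
#'   true architecture), `clones` (truth table: `true_vaf1`, `true_vaf2`,
#'   `true_cf`, `role`), `observed` (per clone x timepoint read counts), and
#'   the `config` echo.
#' @export
simulate_cohort <- function(config = sim_config(), seed = config$seed,
                            panel = load_panel()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(as.integer(seed), {
    n <- config$n_individuals
    ids <- sprintf("IND%04d", seq_len(n))

    age1 <- pmin(pmax(rnorm(n, config$age_mean, config$age_sd),
                      config$age_range[1]), config$age_range[2])
    dt_days <- round(runif(n, config$dt_range[1], config$dt_range[2]) * 365.25)
    date1 <- as.Date("2005-01-01") + round(runif(n, 0, 3652))
    date2 <- date1 + dt_days
    dt_years <- dt_days / 365.25
    sex <- ifelse(runif(n) < config$female_prob, "female", "male")
    race <- ifelse(runif(n) < config$caucasian_prob, "Caucasian", "Other")
    ethnicity <- ifelse(runif(n) < config$hispanic_prob,
                        "Hispanic", "Not Hispanic")
    bmi <- pmax(rnorm(n, config$bmi_mean, config$bmi_sd), 15)
    height <- rnorm(n, config$height_mean, config$height_sd)
    n_mut <- sample(1:3, n, replace = TRUE, prob = config$mutation_count_probs)

    individuals <- tibble::tibble(
      individual_id = ids, sex = sex, race = race, ethnicity = ethnicity,
      bmi = round(bmi, 1), height = round(height, 1),
      age_t1 = round(age1, 1), age_t2 = round(age1 + dt_years, 1),
      draw_date_t1 = date1, draw_date_t2 = date2, dt_years = dt_years,
      blood_cancer_flag = FALSE, n_mutations = n_mut,
      true_architecture = NA_character_)

    genes <- names(config$gene_frequencies)
    clone_rows <- vector("list", n)
    for (i in seq_len(n)) {
      k <- n_mut[i]
      g <- sample(genes, k, replace = TRUE,
                  prob = as.numeric(config$gene_frequencies))
      vaf1 <- exp(runif(k, log(config$vaf1_range[1]),
                        log(config$vaf1_range[2])))
      cf <- unname(vapply(g, function(gg) {
        p <- gene_growth_params(config, gg); draw_cf(1L, p[1], p[2])
      }, 0))
      role <- rep("single", k)
      if (k == 2L) {
        nested <- runif(1) < config$architecture_prob
        individuals$true_architecture[i] <-
          if (nested) "sub-clone" else "distinct"
        if (nested) {
          parent <- which.max(vaf1)
          child <- 3L - parent
          vaf1[child] <- vaf1[parent] * runif(1, 0.2, 0.9)
          cf[child] <- cf[parent] + rnorm(1, 0, config$subclone_cf_jitter)
          if (cf[child] <= -0.95) cf[child] <- -0.9
          role[parent] <- "parent"; role[child] <- "child"
        } else {
          role[] <- "distinct"
        }
      } else if (k >= 3L) {
        role[] <- "distinct"
      }
      vaf2 <- pmin(vaf1 * exp(dt_years[i] * log1p(cf)), 0.5)
      if (k == 2L && individuals$true_architecture[i] == "sub-clone") {
        child <- which(role == "child"); parent <- which(role == "parent")
        # nested clone cannot outgrow its parent's cell fraction
        vaf2[child] <- min(vaf2[child], vaf2[parent])
      }
      true_cf <- compute_growth_rate(vaf1, vaf2, dt_years[i])

      loc <- draw_positions(panel, g)
      clone_rows[[i]] <- tibble::tibble(
        individual_id = ids[i], gene = g,
        contig = loc$contig, pos = loc$pos, ref = loc$ref, alt = loc$alt,
        protein_change = loc$protein_change, consequence = loc$consequence,
        true_vaf1 = vaf1, true_vaf2 = vaf2, true_cf = true_cf, role = role,
        dt_years = dt_years[i])
    }
    clones <- dplyr::bind_rows(clone_rows)
    clones$mutation_key <- paste(clones$contig, clones$pos, clones$ref,
                                 clones$alt, sep = ":")

    obs <- tibble::tibble(
      individual_id = rep(clones$individual_id, 2L),
      timepoint = rep(1:2, each = nrow(clones)),
      contig = rep(clones$contig, 2L), pos = rep(clones$pos, 2L),
      ref = rep(clones$ref, 2L), alt = rep(clones$alt, 2L),
      gene = rep(clones$gene, 2L),
      protein_change = rep(clones$protein_change, 2L),
      consequence = rep(clones$consequence, 2L),
      true_vaf = c(clones$true_vaf1, clones$true_vaf2))
    reads <- sample_reads(obs$true_vaf, config$depth_mean)
    obs$depth <- reads$depth
    obs$alt_reads <- reads$alt_reads
    obs$vaf <- reads$vaf

    structure(list(individuals = individuals, clones = clones,
                   observed = obs, config = config, seed = as.integer(seed)),
              class = "sim_cohort")
  })
}

# place mutations inside a gene's panel intervals (unique sites per call set)
draw_positions <- function(panel, genes) {
  bases <- c("A", "C", "G", "T")
  hotspots <- list(
    DNMT3A = function() sample(c("R882H", "R882C"), 1L),
    JAK2 = function() "V617F")
  k <- length(genes)
  contig <- character(k); pos <- integer(k)
  protein_change <- rep(NA_character_, k)
  consequence <- character(k)
  for (j in seq_len(k)) {
    iv <- panel$intervals[panel$intervals$gene == genes[j], , drop = FALSE]
    if (nrow(iv) == 0L) stop("gene not in panel: ", genes[j], call. = FALSE)
    repeat {
      row <- iv[sample.int(nrow(iv), 1L, prob = iv$end - iv$start), ]
      p <- row$start + sample.int(row$end - row$start, 1L)
      if (!any(contig[seq_len(j - 1L)] == row$contig &
               pos[seq_len(j - 1L)] == p)) break
    }
    contig[j] <- row$contig; pos[j] <- p
    hs <- hotspots[[genes[j]]]
    if (!is.null(hs) && runif(1) < 0.55) {
      protein_change[j] <- hs()
      consequence[j] <- "missense"
    } else {
      consequence[j] <- sample(c("missense", "loss-of-function"), 1L,
                               prob = c(0.75, 0.25))
    }
  }
  ref <- sample(bases, k, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  tibble::tibble(contig = contig, pos = pos, ref = ref, alt = unname(alt),
                 protein_change = protein_change, consequence = consequence)
}

#' Sample sequencing reads for a true VAF
#'
#' Sequencing noise model: total depth is Poisson around the mean depth (at
#' least 1 read), and alt-supporting reads are Binomial(depth, true VAF).
#'
#' @param true_vaf True variant allele fraction(s) in \[0, 1\]. Vectorized.
#' @param depth_mean Mean sequencing depth.
#' @param seed Optional seed; when NULL the current RNG state is used.
#' @return Tibble: `depth`, `alt_reads`, `vaf` (= alt_reads / depth).
#' @export
sample_reads <- function(true_vaf, depth_mean, seed = NULL) {
  stopifnot(all(true_vaf >= 0), all(true_vaf <= 1), depth_mean > 0)
  draw <- function() {
    n <- length(true_vaf)
    depth <- pmax(rpois(n, depth_mean), 1L)
    alt <- rbinom(n, depth, true_vaf)
    tibble::tibble(depth = as.integer(depth), alt_reads = as.integer(alt),
                   vaf = alt / depth)
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Simulate a limiting-dilution series (in-silico detection limit)
#'
#' Emulates the wet-lab validation in which a heterozygous DNA sample is
#' mixed at fixed ratios into a second sample: the expected VAF at mixing
#' ratio r is `het_vaf * r`. For each ratio, reads are sampled under the
#' binomial noise model and the detection rate (alt reads >= `min_alt_reads`)
#' and the relative VAF error are estimated, alongside the analytic binomial
#' tail probability at the mean depth for cross-checking.
#'
#' @param het_vaf VAF of the undiluted heterozygous variant (default 0.5).
#' @param ratios Mixing fractions in (0, 1].
#' @param depth_mean Mean sequencing depth.
#' @param n_replicates Monte-Carlo replicates per ratio.
#' @param min_alt_reads Detection threshold on alt-supporting reads.
#' @param seed Seed.
#' @return Tibble: `ratio`, `expected_vaf`, `detection_rate`,
#'   `p_detect_analytic` (binomial tail at fixed depth `depth_mean`),
#'   `mean_observed_vaf`, `rel_vaf_error` (mean |obs - expected| / expected
#'   among detected replicates).
#' @export
simulate_dilution_series <- function(het_vaf = 0.5,
                                     ratios = c(1, 0.5, 0.2, 0.1, 0.04,
                                                0.02, 0.006),
                                     depth_mean = 2000, n_replicates = 10000L,
                                     min_alt_reads = 3L, seed = 1L) {
  stopifnot(all(ratios > 0), all(ratios <= 1))
  withr::with_seed(as.integer(seed), {
    rows <- lapply(ratios, function(r) {
      ev <- het_vaf * r
      reads <- sample_reads(rep(ev, n_replicates), depth_mean)
      detected <- reads$alt_reads >= min_alt_reads
      tibble::tibble(
        ratio = r,
        expected_vaf = ev,
        detection_rate = mean(detected),
        p_detect_analytic = pbinom(min_alt_reads - 1L, round(depth_mean),
                                   ev, lower.tail = FALSE),
        mean_observed_vaf = mean(reads$vaf),
        rel_vaf_error = if (any(detected))
          mean(abs(reads$vaf[detected] - ev)) / ev else NA_real_)
    })
    dplyr::bind_rows(rows)
  })
}

#' Write a simulated cohort to pipeline-ready fixture files
#'
#' Emits a multi-sample VCF 4.2 (two samples per individual, `GT:DP:AD`
#' FORMAT, gene / protein change / consequence as INFO tags), a sample
#' metadata TSV, and ground-truth TSVs for the clones and individuals. The
#' files read back losslessly through [read_variants()].
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @param out_dir Output directory (created if missing).
#' @return Named list of file paths, invisibly.
#' @export
write_fixtures <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- list(vcf = file.path(out_dir, "cohort.vcf"),
                metadata = file.path(out_dir, "metadata.tsv"),
                truth_clones = file.path(out_dir, "truth_clones.tsv"),
                truth_individuals = file.path(out_dir, "truth_individuals.tsv"))

  write_cohort_vcf(cohort, paths$vcf)

  ind <- cohort$individuals
  meta <- tibble::tibble(
    sample_id = c(paste0(ind$individual_id, "_T1"),
                  paste0(ind$individual_id, "_T2")),
    individual_id = rep(ind$individual_id, 2L),
    timepoint = rep(1:2, each = nrow(ind)),
    draw_date = as.character(c(ind$draw_date_t1, ind$draw_date_t2)),
    age = c(ind$age_t1, ind$age_t2),
    sex = rep(ind$sex, 2L), race = rep(ind$race, 2L),
    ethnicity = rep(ind$ethnicity, 2L),
    bmi = rep(ind$bmi, 2L), height = rep(ind$height, 2L),
    blood_cancer_flag = rep(ind$blood_cancer_flag, 2L))
  meta <- meta[order(meta$individual_id, meta$timepoint), ]
  write_tsv_plain(meta, paths$metadata)
  write_tsv_plain(cohort$clones, paths$truth_clones)
  write_tsv_plain(ind, paths$truth_individuals)
  invisible(paths)
}

write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (inherits(df[[j]], "Date")) df[[j]] <- as.character(df[[j]])
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.10g", df[[j]])
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_cohort_vcf <- function(cohort, path) {
  ind <- cohort$individuals$individual_id
  samples <- as.vector(rbind(paste0(ind, "_T1"), paste0(ind, "_T2")))
  obs <- cohort$observed
  obs$sample_id <- paste0(obs$individual_id, "_T", obs$timepoint)

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=chipdyn.simulate_cohort",
    sprintf("##contig=<ID=%s>", unique(obs$contig[order(obs$contig)])),
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Panel gene symbol\">",
    "##INFO=<ID=PCHANGE,Number=1,Type=String,Description=\"Protein change (HGVS-p short)\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))

  site_key <- paste(obs$contig, obs$pos, obs$ref, obs$alt, sep = "\r")
  sites <- split(obs, site_key)
  ord <- order(vapply(sites, function(s) s$contig[1L], ""),
               vapply(sites, function(s) s$pos[1L], 1L))
  sites <- sites[ord]

  sample_idx <- setNames(seq_along(samples), samples)
  body <- vapply(sites, function(s) {
    cells <- rep("./.:.:.", length(samples))
    entry <- sprintf("0/1:%d:%d,%d", s$depth, s$depth - s$alt_reads,
                     s$alt_reads)
    cells[sample_idx[s$sample_id]] <- entry
    info <- sprintf("GENE=%s%s;CSQ=%s", s$gene[1L],
                    ifelse(is.na(s$protein_change[1L]), "",
                           paste0(";PCHANGE=", s$protein_change[1L])),
                    s$consequence[1L])
    paste(c(s$contig[1L], s$pos[1L], ".", s$ref[1L], s$alt[1L], ".", "PASS",
            info, "GT:DP:AD", cells), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "Simulated CHIP cohort: %d individuals, %d clones (seed %d, mean depth %gx)\n",
    nrow(x$individuals), nrow(x$clones), x$seed, x$config$depth_mean))
  invisible(x)
}
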