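#' Pipeline run configuration
#'
#' Bundles all inputs and stage options of a full run. Can also be loaded
#' from YAML via [run_config_from_yaml()].
#'
#' @param vcf Path to the multi-sample VCF of somatic calls.
#' @param metadata Path to the sample metadata TSV.
#' @param out_dir Output directory.
#' @param panel_bed,panel_yaml Panel definition paths (default: shipped
#'   22-gene panel).
#' @param filter A [chip_filter_policy()].
#' @param dynamics A [dynamics_config()].
#' @param min_gene_n Minimum clones per gene for ranking (default 10).
#' @param covariates Metadata columns tested against growth rate.
#' @param cooccurrence_n_perm Permutation replicates for the co-occurrence
#'   test.
#' @param seed Seed for all randomized stages.
#' @return A list of class `chip_run_config`.
#' @export
run_config <- function(vcf, metadata, out_dir,
                       panel_bed = chipdyn_default_panel_bed(),
                       panel_yaml = NULL,
                       filter = chip_filter_policy(),
                       dynamics = dynamics_config(),
                       min_gene_n = 10L,
                       covariates = c("age", "sex", "race", "ethnicity",
                                      "bmi", "height"),
                       cooccurrence_n_perm = 2000L,
                       seed = 1L) {
  for (p in c(vcf, metadata, panel_bed, panel_yaml)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input file not found: ", p, call. = FALSE)
    }
  }
  structure(list(vcf = vcf, metadata = metadata, out_dir = out_dir,
                 panel_bed = panel_bed, panel_yaml = panel_yaml,
                 filter = filter, dynamics = dynamics,
                 min_gene_n = as.integer(min_gene_n),
                 covariates = covariates,
                 cooccurrence_n_perm = as.integer(cooccurrence_n_perm),
                 seed = as.integer(seed)),
            class = "chip_run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognized top-level keys: `vcf`, `metadata`, `out_dir`, `panel_bed`,
#' `panel_yaml`, `seed`, `min_gene_n`, `covariates`, `cooccurrence_n_perm`,
#' plus `filter` and `dynamics` maps whose entries are passed to
#' [chip_filter_policy()] and [dynamics_config()].
#'
#' @param path YAML file.
#' @return A `chip_run_config`.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("vcf", "metadata", "out_dir", "panel_bed",
                                  "panel_yaml", "min_gene_n", "covariates",
                                  "cooccurrence_n_perm", "seed"))]
  if (!is.null(y$filter)) args$filter <- do.call(chip_filter_policy, y$filter)
  if (!is.null(y$dynamics)) args$dynamics <- do.call(dynamics_config, y$dynamics)
  do.call(run_config, args)
}

#' Run the full clonal-dynamics pipeline
#'
#' Executes call reading, CHIP filtering, timepoint pairing, growth-rate
#' estimation, trajectory classification, within-class z-scoring,
#' architecture calls, per-gene summaries (full and single-mutation
#' sensitivity), the driver-gene co-occurrence test, and covariate
#' association regressions, writing one TSV/JSON per stage plus a run
#' manifest (input checksums, configuration echo, per-stage counts). Given
#' identical inputs, config and seed, reruns produce byte-identical stage
#' outputs.
#'
#' @param config A [run_config()] or path to a YAML accepted by
#'   [run_config_from_yaml()].
#' @param quiet Suppress stage progress messages.
#' @return Invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- run_config_from_yaml(config)
  stopifnot(inherits(config, "chip_run_config"))
  if (!dir.exists(config$out_dir) &&
      !dir.create(config$out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", config$out_dir, call. = FALSE)
  }
  say <- function(...) if (!quiet) message("[chipdyn] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  out_path <- function(f) file.path(config$out_dir, f)

  panel <- stage("load_panel",
                 load_panel(config$panel_bed, config$panel_yaml))
  say("panel: %d genes, %.1f kb", nrow(panel$genes), panel$target_bp / 1e3)

  metadata <- stage("metadata", read_sample_metadata(config$metadata))
  calls <- stage("read_variants",
                 read_variants(config$vcf, panel, metadata))
  say("read %d calls from %s", nrow(calls), config$vcf)

  retained <- stage("filter_chip",
                    filter_chip(calls, config$filter, quiet = quiet))
  fstats <- attr(retained, "filter_stats")
  write_tsv_plain(retained, out_path("retained_calls.tsv"))

  pairs <- stage("pair_timepoints",
                 pair_timepoints(retained, calls, metadata, config$filter))
  write_tsv_plain(pairs, out_path("clone_pairs.tsv"))
  say("%d clone pairs across %d individuals", nrow(pairs),
      length(unique(pairs$individual_id)))

  assignments <- stage("trajectories", {
    a <- classify_trajectories(pairs, config$dynamics)
    zscore_within_class(a)
  })
  write_tsv_plain(assignments, out_path("clone_trajectories.tsv"))

  architecture <- stage("architecture",
                        call_architectures(assignments, config$dynamics))
  write_tsv_plain(architecture, out_path("architecture_calls.tsv"))

  gene_summary <- stage("gene_summary",
                        summarize_by_gene(assignments, config$min_gene_n))
  write_tsv_plain(gene_summary, out_path("gene_summary.tsv"))
  single_summary <- stage("sensitivity_single_mutation",
                          sensitivity_single_mutation(assignments,
                                                      config$min_gene_n))
  write_tsv_plain(single_summary, out_path("gene_summary_single_mutation.tsv"))

  cooccurrence <- NULL
  n_two <- if (nrow(assignments) > 0L) {
    sum(table(assignments$individual_id) == 2L)
  } else 0L
  if (n_two > 0L) {
    cooccurrence <- stage("cooccurrence",
                          cooccurrence_test(assignments, method = "both",
                                            n_perm = config$cooccurrence_n_perm,
                                            seed = config$seed))
    write_tsv_plain(cooccurrence$pairs, out_path("cooccurrence_cells.tsv"))
    jsonlite::write_json(
      list(chi2 = cooccurrence$chi2, df = cooccurrence$df,
           p_analytic = cooccurrence$p_analytic,
           p_permutation = cooccurrence$p_permutation,
           n_pairs = cooccurrence$n_pairs),
      out_path("cooccurrence.json"), auto_unbox = TRUE, digits = NA)
  } else {
    say("no two-mutation individuals; co-occurrence test skipped")
  }

  associations <- NULL
  covs <- intersect(config$covariates, names(metadata))
  if (nrow(assignments) > 0L && length(covs) > 0L) {
    associations <- stage("associations",
                          associate_covariates(assignments, metadata, covs))
    write_tsv_plain(associations, out_path("associations.tsv"))
  }

  counts <- list(
    calls_read = nrow(calls),
    calls_retained = if (is.null(fstats)) 0L else fstats$retained,
    clone_pairs = nrow(pairs),
    individuals = length(unique(pairs$individual_id)),
    trajectory_counts = as.list(table(assignments$trajectory)),
    architecture_calls = nrow(architecture),
    two_mutation_individuals = n_two)
  manifest <- list(
    package_version = as.character(utils::packageVersion("chipdyn")),
    inputs = list(
      vcf = unname(tools::md5sum(config$vcf)),
      metadata = unname(tools::md5sum(config$metadata)),
      panel_bed = unname(tools::md5sum(config$panel_bed))),
    config = list(
      filter = unclass(config$filter),
      dynamics = unclass(config$dynamics),
      min_gene_n = config$min_gene_n,
      covariates = covs,
      cooccurrence_n_perm = config$cooccurrence_n_perm,
      seed = config$seed),
    stagnant_cutoff = attr(assignments, "stagnant_cutoff"),
    counts = counts)
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  say("done: outputs in %s", config$out_dir)

  invisible(list(panel = panel, calls = calls, retained = retained,
                 pairs = pairs, assignments = assignments,
                 architecture = architecture, gene_summary = gene_summary,
                 single_mutation_summary = single_summary,
                 cooccurrence = cooccurrence, associations = associations,
                 manifest = manifest))
}
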