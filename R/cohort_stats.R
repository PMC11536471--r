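#' Per-gene growth-rate summaries
#'
#' Arithmetic mean and SD of the annual growth rate per driver gene, with
#' trajectory-class counts and the mean rate among reduction clones. Genes
#' with fewer than `min_n` clones are reported but flagged `below_threshold`
#' and should be excluded from between-gene ranking.
#'
#' @param assignments Output of [classify_trajectories()] (needs `gene`,
#'   `cf`, `trajectory`).
#' @param min_n Minimum clone count for a gene to enter rankings (default 10).
#' @return Tibble: `gene`, `n_clones`, `mean_cf`, `sd_cf`, `n_expansion`,
#'   `n_reduction`, `n_stagnant`, `mean_reduction_rate`, `below_threshold`,
#'   sorted by descending `mean_cf`.
#' @export
summarize_by_gene <- function(assignments, min_n = 10L) {
  empty <- tibble::tibble(
    gene = character(), n_clones = integer(), mean_cf = double(),
    sd_cf = double(), n_expansion = integer(), n_reduction = integer(),
    n_stagnant = integer(), mean_reduction_rate = double(),
    below_threshold = logical())
  if (nrow(assignments) == 0L) return(empty)
  out <- assignments |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_clones = dplyr::n(),
      mean_cf = mean(.data$cf),
      sd_cf = sd(.data$cf),
      n_expansion = sum(.data$trajectory == "expansion"),
      n_reduction = sum(.data$trajectory == "reduction"),
      n_stagnant = sum(.data$trajectory == "stagnant"),
      mean_reduction_rate = if (any(.data$trajectory == "reduction"))
        mean(.data$cf[.data$trajectory == "reduction"]) else NA_real_,
      .groups = "drop") |>
    dplyr::mutate(below_threshold = .data$n_clones < min_n) |>
    dplyr::arrange(dplyr::desc(.data$mean_cf))
  out
}

#' Sensitivity analysis restricted to single-mutation individuals
#'
#' Re-runs [summarize_by_gene()] on the clones of individuals carrying
#' exactly one retained mutation, removing any skew from multi-clone
#' individuals. The fractions removed by the restriction are attached as
#' attributes `fraction_removed` (clones) and `fraction_individuals_removed`.
#'
#' @inheritParams summarize_by_gene
#' @return As [summarize_by_gene()].
#' @export
sensitivity_single_mutation <- function(assignments, min_n = 10L) {
  if (nrow(assignments) == 0L) {
    out <- summarize_by_gene(assignments, min_n)
    attr(out, "fraction_removed") <- NA_real_
    attr(out, "fraction_individuals_removed") <- NA_real_
    return(out)
  }
  counts <- table(assignments$individual_id)
  singles <- names(counts)[counts == 1L]
  restricted <- assignments[assignments$individual_id %in% singles, , drop = FALSE]
  out <- summarize_by_gene(restricted, min_n)
  attr(out, "fraction_removed") <- 1 - nrow(restricted) / nrow(assignments)
  attr(out, "fraction_individuals_removed") <-
    1 - length(singles) / length(counts)
  out
}

#' Driver-gene co-occurrence test against a prevalence-controlled null
#'
#' Each individual with exactly two retained mutations contributes one
#' unordered driver-gene pair. Under the null that the two drivers are drawn
#' independently from the cohort's driver-gene prevalence `p` (marginal gene
#' frequencies among all retained mutations), the expected count of the
#' unordered pair \{g, h\} is `n * 2 * p_g * p_h` for g != h and `n * p_g^2`
#' for g = h. The statistic is the usual `sum((O - E)^2 / E)` over all
#' unordered pairs of genes with positive prevalence. Because expected cells
#' are tiny at realistic cohort sizes, the analytic chi-square tail
#' (df = cells - 1) is complemented by a seeded permutation p-value that
#' resamples pairs from the prevalence distribution.
#'
#' @param assignments All retained clone assignments (needs `individual_id`,
#'   `gene`); prevalence is computed from every row, pairs from two-mutation
#'   individuals.
#' @param method `"analytic"`, `"permutation"`, or `"both"`.
#' @param n_perm Permutation replicates (default 10000).
#' @param seed Seed for the permutation null; required when permuting.
#' @return Object of class `chip_cooccurrence`: list with `pairs` (tibble of
#'   observed/expected per cell), `chi2`, `df`, `p_analytic`,
#'   `p_permutation`, `n_pairs`, `prevalence`.
#' @export
cooccurrence_test <- function(assignments,
                              method = c("both", "analytic", "permutation"),
                              n_perm = 10000L, seed = NULL) {
  method <- match.arg(method)
  per <- table(assignments$individual_id)
  two <- names(per)[per == 2L]
  if (length(two) == 0L) {
    stop("no two-mutation individuals: co-occurrence test undefined",
         call. = FALSE)
  }
  prevalence <- prop.table(table(assignments$gene))
  genes <- names(prevalence)

  sub <- assignments[assignments$individual_id %in% two, , drop = FALSE]
  pair_of <- function(g) paste(sort(g), collapse = "|")
  obs_pairs <- vapply(split(sub$gene, sub$individual_id), pair_of, "")
  n_pairs <- length(obs_pairs)

  cells <- expand.grid(g = genes, h = genes, stringsAsFactors = FALSE)
  cells <- cells[cells$g <= cells$h, , drop = FALSE]
  cells$expected <- ifelse(
    cells$g == cells$h,
    n_pairs * prevalence[cells$g]^2,
    n_pairs * 2 * prevalence[cells$g] * prevalence[cells$h])
  cell_key <- paste(cells$g, cells$h, sep = "|")
  obs_tab <- table(factor(obs_pairs, levels = cell_key))
  cells$observed <- as.integer(obs_tab)

  chi2_stat <- function(obs) sum((obs - cells$expected)^2 / cells$expected)
  chi2 <- chi2_stat(cells$observed)
  df <- nrow(cells) - 1L
  p_analytic <- pchisq(chi2, df = df, lower.tail = FALSE)

  p_permutation <- NA_real_
  if (method %in% c("both", "permutation")) {
    if (is.null(seed)) stop("permutation method requires a seed", call. = FALSE)
    p_permutation <- withr::with_seed(seed, {
      exceed <- 0L
      for (b in seq_len(n_perm)) {
        draw <- matrix(sample(genes, 2L * n_pairs, replace = TRUE,
                              prob = as.numeric(prevalence)),
                       ncol = 2L)
        keys <- paste(pmin(draw[, 1L], draw[, 2L]),
                      pmax(draw[, 1L], draw[, 2L]), sep = "|")
        stat <- chi2_stat(as.integer(table(factor(keys, levels = cell_key))))
        if (stat >= chi2) exceed <- exceed + 1L
      }
      (1 + exceed) / (n_perm + 1)
    })
  }

  structure(
    list(pairs = tibble::tibble(gene1 = cells$g, gene2 = cells$h,
                                observed = cells$observed,
                                expected = as.numeric(cells$expected)),
         chi2 = chi2, df = df,
         p_analytic = if (method == "permutation") NA_real_ else p_analytic,
         p_permutation = p_permutation,
         n_pairs = n_pairs,
         prevalence = prevalence),
    class = "chip_cooccurrence")
}

#' @export
print.chip_cooccurrence <- function(x, ...) {
  cat(sprintf(
    "Driver-gene co-occurrence over %d two-mutation individuals\n  chi2 = %.2f (df = %d), analytic p = %.3g, permutation p = %.3g\n",
    x$n_pairs, x$chi2, x$df, x$p_analytic, x$p_permutation))
  invisible(x)
}

#' Test associations between clonal growth rate and participant covariates
#'
#' For each covariate, fits a regression of the clonal growth rate on that
#' covariate with driver-gene indicator terms as covariates (one row per
#' clone). Numeric covariates and two-level factors wider than the gene
#' labels use ordinary least squares on `cf ~ covariate + gene`, reporting
#' the covariate coefficient; binary covariates may alternatively be
#' modeled by logistic regression of the covariate on `cf + gene`
#' (`binary_model = "logistic"`), reporting the `cf` effect. Factors with
#' three or more levels report the covariate's overall F-test p-value.
#'
#' @param assignments Clone assignments with `individual_id`, `gene`, `cf`.
#' @param metadata Individual- or sample-level metadata (data frame or TSV
#'   path); joined on `individual_id`, first row per individual.
#' @param covariates Character vector of metadata column names to test.
#' @param binary_model `"linear"` (default) or `"logistic"` for two-level
#'   covariates.
#' @return Tibble: `covariate`, `model`, `term`, `estimate`, `se`,
#'   `statistic`, `p`, `n`, `note`. Covariates with zero variance are
#'   skipped with a warning; designs collinear with the gene terms are
#'   flagged in `note`, never silently dropped.
#' @export
associate_covariates <- function(assignments, metadata, covariates,
                                 binary_model = c("linear", "logistic")) {
  binary_model <- match.arg(binary_model)
  if (is.character(metadata) && length(metadata) == 1L) {
    metadata <- read_sample_metadata(metadata)
  }
  meta1 <- metadata[!duplicated(metadata$individual_id), , drop = FALSE]
  df <- dplyr::left_join(
    assignments[, c("individual_id", "gene", "cf")], meta1,
    by = "individual_id")
  df$gene <- factor(df$gene)
  multi_gene <- nlevels(df$gene) > 1L

  out <- lapply(covariates, function(cv) {
    if (!cv %in% names(df)) {
      warning("covariate not found in metadata, skipped: ", cv, call. = FALSE)
      return(NULL)
    }
    x <- df[[cv]]
    keep <- !is.na(x) & !is.na(df$cf)
    x <- x[keep]
    sub <- df[keep, , drop = FALSE]
    n <- nrow(sub)
    if (n < 3L || length(unique(x)) < 2L) {
      warning("covariate with zero variance (or too few observations) skipped: ",
              cv, call. = FALSE)
      return(NULL)
    }
    is_num <- is.numeric(x)
    x_f <- if (is_num) x else factor(x)
    n_levels <- if (is_num) Inf else nlevels(x_f)
    sub$.x <- if (is_num) x else x_f

    if (!is_num && n_levels == 2L && binary_model == "logistic") {
      fml <- if (multi_gene) .x ~ cf + gene else .x ~ cf
      fit <- glm(fml, data = sub, family = stats::binomial())
      sm <- summary(fit)$coefficients
      row <- sm["cf", ]
      return(tibble::tibble(
        covariate = cv, model = "logistic", term = "cf",
        estimate = row[["Estimate"]], se = row[["Std. Error"]],
        statistic = row[["z value"]], p = row[["Pr(>|z|)"]],
        n = n, note = NA_character_))
    }

    fml <- if (multi_gene) cf ~ .x + gene else cf ~ .x
    fit <- lm(fml, data = sub)
    aliased <- names(coef(fit))[is.na(coef(fit))]
    note <- NA_character_
    if (length(aliased) > 0L) {
      note <- paste0("collinear design: aliased term(s) ",
                     paste(aliased, collapse = ", "))
      warning("covariate '", cv, "' yields a collinear design (", note, ")",
              call. = FALSE)
    }
    sm <- summary(fit)$coefficients
    x_terms <- grep("^\\.x", rownames(sm), value = TRUE)
    if (length(x_terms) == 0L) {
      return(tibble::tibble(
        covariate = cv, model = "linear", term = cv, estimate = NA_real_,
        se = NA_real_, statistic = NA_real_, p = NA_real_, n = n,
        note = note %||% "covariate fully aliased by gene terms"))
    }
    if (is_num || n_levels == 2L) {
      row <- sm[x_terms[1L], ]
      term_lab <- if (is_num) cv else
        paste0(cv, "=", sub("^\\.x", "", x_terms[1L]))
      tibble::tibble(
        covariate = cv, model = "linear", term = term_lab,
        estimate = row[["Estimate"]], se = row[["Std. Error"]],
        statistic = row[["t value"]], p = row[["Pr(>|t|)"]],
        n = n, note = note)
    } else {
      an <- anova(fit)
      tibble::tibble(
        covariate = cv, model = "linear (overall F)", term = cv,
        estimate = NA_real_, se = NA_real_,
        statistic = an[".x", "F value"], p = an[".x", "Pr(>F)"],
        n = n, note = note)
    }
  })
  dplyr::bind_rows(out)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
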