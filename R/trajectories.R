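#' Clonal dynamics configuration
#'
#' @param stagnant_fraction Fraction of clones (by smallest absolute growth
#'   rate, cohort-wide) labeled stagnant (default 0.10).
#' @param z_gap_threshold Minimum within-class z-score gap for two
#'   same-direction clones to be called distinct rather than sub-clonal
#'   (default 0.6).
#' @param floor_vaf Detection-floor VAF used for imputation (default 0.001).
#' @return A list of class `dynamics_config`.
#' @export
dynamics_config <- function(stagnant_fraction = 0.10, z_gap_threshold = 0.6,
                            floor_vaf = 0.001) {
  stopifnot(stagnant_fraction > 0, stagnant_fraction < 1, z_gap_threshold > 0)
  structure(list(stagnant_fraction = stagnant_fraction,
                 z_gap_threshold = z_gap_threshold,
                 floor_vaf = floor_vaf),
            class = "dynamics_config")
}

#' Classify clone trajectories as stagnant, expansion or reduction
#'
#' Cohort-level rule: the `ceiling(stagnant_fraction * n)` clones with the
#' smallest absolute growth rate are labeled `stagnant` (nearest-rank
#' quantile); among the rest, positive growth is `expansion` and negative
#' growth is `reduction`. Ties in |cf| are broken deterministically by
#' (`individual_id`, `mutation_key`) lexicographic order, so assignments do
#' not depend on input order. The implied |cf| cutoff (the largest stagnant
#' |cf|) is attached as attribute `stagnant_cutoff`.
#'
#' @param pairs Tibble of clone pairs; must carry `cf`, or `vaf1`, `vaf2`
#'   and `dt_years` from which `cf` is computed.
#' @param config A [dynamics_config()].
#' @return `pairs` with columns `cf` and `trajectory` (factor-like character:
#'   stagnant/expansion/reduction), ordered as the input.
#' @export
classify_trajectories <- function(pairs, config = dynamics_config()) {
  stopifnot(inherits(config, "dynamics_config"))
  if (!"cf" %in% names(pairs)) {
    pairs$cf <- compute_growth_rate(pairs$vaf1, pairs$vaf2, pairs$dt_years)
  }
  n <- nrow(pairs)
  if (n == 0L) {
    pairs$trajectory <- character()
    attr(pairs, "stagnant_cutoff") <- NA_real_
    return(pairs)
  }
  iid <- if ("individual_id" %in% names(pairs)) pairs$individual_id else ""
  mkey <- if ("mutation_key" %in% names(pairs)) pairs$mutation_key else
    as.character(seq_len(n))
  ord <- order(abs(pairs$cf), iid, mkey)
  n_stagnant <- ceiling(config$stagnant_fraction * n)
  stagnant_idx <- ord[seq_len(n_stagnant)]

  trajectory <- ifelse(pairs$cf > 0, "expansion", "reduction")
  trajectory[pairs$cf == 0] <- "expansion"  # measure-zero tie; see vignette
  trajectory[stagnant_idx] <- "stagnant"
  pairs$trajectory <- trajectory
  attr(pairs, "stagnant_cutoff") <- max(abs(pairs$cf[stagnant_idx]))
  pairs
}

#' Standardize growth rates within each trajectory class
#'
#' Z-scores clones within their trajectory class: `z = (cf - class mean) /
#' class SD` with the sample (n-1) standard deviation. Degenerate classes
#' (a single clone, or zero SD) receive z = 0 so that z-gap comparisons
#' remain defined.
#'
#' @param assignments Output of [classify_trajectories()].
#' @return `assignments` with a `zscore` column.
#' @export
zscore_within_class <- function(assignments) {
  stopifnot(all(c("cf", "trajectory") %in% names(assignments)))
  z <- rep(0, nrow(assignments))
  for (cls in unique(assignments$trajectory)) {
    sel <- assignments$trajectory == cls
    if (sum(sel) >= 2L) {
      s <- sd(assignments$cf[sel])
      if (is.finite(s) && s > 0) {
        z[sel] <- (assignments$cf[sel] - mean(assignments$cf[sel])) / s
      }
    }
  }
  assignments$zscore <- z
  assignments
}

#' Classify a two-clone individual as sub-clone or distinct clones
#'
#' Two driver mutations in one individual may sit in the same cells (a
#' sub-clone nested in the parent clone) or in separate cell populations
#' (distinct clones). Clones in different trajectory classes are growing in
#' different directions and are called `distinct`. Clones in the same class
#' are compared by their within-class z-scores: a gap below
#' `z_gap_threshold` means concordant growth and a `sub-clone` call; a gap at
#' or above the threshold means `distinct`.
#'
#' @param clones A two-row tibble (one individual) with `trajectory` and
#'   `zscore` from [zscore_within_class()].
#' @param config A [dynamics_config()].
#' @return One-row tibble: `individual_id`, `architecture`, `z_gap` (NA for
#'   cross-class pairs, where z-scores are not comparable).
#' @export
classify_architecture <- function(clones, config = dynamics_config()) {
  stopifnot(inherits(config, "dynamics_config"))
  if (nrow(clones) != 2L) {
    stop("classify_architecture requires exactly two clones; individuals with ",
         "3+ mutations are excluded from architecture calls", call. = FALSE)
  }
  iid <- if ("individual_id" %in% names(clones)) clones$individual_id[1L] else NA_character_
  if (clones$trajectory[1L] != clones$trajectory[2L]) {
    return(tibble::tibble(individual_id = iid, architecture = "distinct",
                          z_gap = NA_real_))
  }
  gap <- abs(clones$zscore[1L] - clones$zscore[2L])
  tibble::tibble(
    individual_id = iid,
    architecture = if (gap < config$z_gap_threshold) "sub-clone" else "distinct",
    z_gap = gap)
}

#' Architecture calls for every two-clone individual in a cohort
#'
#' Applies [classify_architecture()] to each individual carrying exactly two
#' retained mutations. Individuals with one or with three or more mutations
#' are excluded (their count is attached as attribute `n_excluded`).
#'
#' @param assignments Output of [zscore_within_class()].
#' @param config A [dynamics_config()].
#' @return Tibble with one row per two-clone individual.
#' @export
call_architectures <- function(assignments, config = dynamics_config()) {
  empty <- tibble::tibble(individual_id = character(),
                          architecture = character(), z_gap = double())
  if (nrow(assignments) == 0L) {
    attr(empty, "n_excluded") <- 0L
    return(empty)
  }
  per <- split(assignments, assignments$individual_id)
  two <- per[vapply(per, nrow, 1L) == 2L]
  out <- if (length(two) == 0L) empty else
    dplyr::bind_rows(lapply(two, classify_architecture, config = config))
  out <- out[order(out$individual_id), , drop = FALSE]
  attr(out, "n_excluded") <- length(per) - length(two)
  out
}
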