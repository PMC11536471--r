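#' CHIP variant filter policy
#'
#' Thresholds for calling a somatic variant CHIP: minimum total read depth,
#' minimum alt-supporting reads, and minimum variant allele fraction (VAF).
#' Calls failing any rule are removed. When pairing timepoints, a mutation
#' that passes at only one timepoint can have its other-timepoint VAF
#' *rescued* from a sub-threshold raw call (if it has at least
#' `min_alt_reads` supporting reads) or, failing that, imputed at
#' `floor_vaf`, reflecting the assay's lower detection limit.
#'
#' @param min_depth Minimum total read depth (default 100; depths below 100
#'   are removed).
#' @param min_alt_reads Minimum alt-supporting reads (default 3).
#' @param min_vaf Minimum VAF to call CHIP (default 0.02; VAF >= 2% passes).
#' @param rescue_cross_timepoint Use sub-threshold raw calls at the other
#'   timepoint instead of imputing (default TRUE).
#' @param floor_vaf VAF imputed when a mutation is undetected at one
#'   timepoint (default 0.001).
#' @return A list of class `chip_filter_policy`.
#' @export
chip_filter_policy <- function(min_depth = 100L, min_alt_reads = 3L,
                               min_vaf = 0.02, rescue_cross_timepoint = TRUE,
                               floor_vaf = 0.001) {
  stopifnot(min_depth >= 1, min_alt_reads >= 1,
            floor_vaf > 0, floor_vaf < min_vaf, min_vaf <= 1)
  structure(list(min_depth = as.integer(min_depth),
                 min_alt_reads = as.integer(min_alt_reads),
                 min_vaf = min_vaf,
                 rescue_cross_timepoint = isTRUE(rescue_cross_timepoint),
                 floor_vaf = floor_vaf),
            class = "chip_filter_policy")
}

variant_call_columns <- function() {
  tibble::tibble(individual_id = character(), timepoint = integer(),
                 sample_id = character(), contig = character(),
                 pos = integer(), ref = character(), alt = character(),
                 depth = integer(), alt_reads = integer(), vaf = double(),
                 gene = character(), protein_change = character(),
                 consequence = character())
}

#' Read somatic variant calls from a VCF
#'
#' Parses a (possibly multi-sample) VCF 4.2 with per-sample `DP` and `AD`
#' FORMAT fields, as produced by Mutect2-style somatic callers. One call is
#' emitted per alt allele per sample with a non-missing genotype; VAF is
#' computed as `AD[alt] / DP` rather than taken from caller-specific AF tags,
#' so results are identical across callers. Calls outside the panel's
#' targeted intervals are kept but flagged with `gene = NA`.
#'
#' @param vcf_path Path to a VCF (plain text or bgzipped).
#' @param panel A `chip_panel` from [load_panel()].
#' @param sample_map Sample metadata: a data frame (or TSV path readable by
#'   [read_sample_metadata()]) with at least `sample_id`, `individual_id`,
#'   `timepoint`. Every VCF sample name must map to one row.
#' @return A tibble of variant calls, one row per alt allele per sample:
#'   `individual_id`, `timepoint`, `sample_id`, `contig`, `pos` (1-based),
#'   `ref`, `alt`, `depth`, `alt_reads`, `vaf`, `gene`, `protein_change`,
#'   `consequence`.
#' @export
read_variants <- function(vcf_path, panel, sample_map) {
  stopifnot(inherits(panel, "chip_panel"))
  if (is.character(sample_map) && length(sample_map) == 1L) {
    sample_map <- read_sample_metadata(sample_map)
  }
  need <- c("sample_id", "individual_id", "timepoint")
  if (!all(need %in% names(sample_map))) {
    stop("sample_map must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }

  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(fix) || nrow(vcf@fix) == 0L) return(variant_call_columns())
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCFs drop to a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)

  gt <- vcf@gt
  samples <- colnames(gt)[-1L]
  unmapped <- setdiff(samples, sample_map$sample_id)
  if (length(unmapped) > 0L) {
    stop("VCF sample(s) not present in sample metadata: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  smap <- sample_map[match(samples, sample_map$sample_id), ]

  fmt <- strsplit(gt[, "FORMAT"], ":", fixed = TRUE)
  has_dp <- vapply(fmt, function(f) "DP" %in% f, logical(1))
  has_ad <- vapply(fmt, function(f) "AD" %in% f, logical(1))
  if (!all(has_dp & has_ad)) {
    i <- which(!(has_dp & has_ad))[1L]
    stop(sprintf("record %s:%s lacks DP and/or AD in FORMAT",
                 fix$CHROM[i], fix$POS[i]), call. = FALSE)
  }

  dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP",
                                          as.numeric = TRUE))
  ad <- vcfR::extract.gt(vcf, element = "AD")
  info <- vcf@fix[, "INFO"]
  pchange <- extract_info_field(info, "PCHANGE")
  csq <- extract_info_field(info, "CSQ")

  alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  pos <- as.integer(fix$POS)

  rows <- vector("list", length(samples))
  for (j in seq_along(samples)) {
    called <- which(!is.na(ad[, j]) & ad[, j] != ".")
    if (length(called) == 0L) next
    ad_parts <- strsplit(ad[called, j], ",", fixed = TRUE)
    n_alt <- lengths(alt_list[called])
    rec <- rep(called, n_alt)
    alt_idx <- unlist(lapply(n_alt, seq_len), use.names = FALSE)
    alt_reads <- suppressWarnings(as.integer(mapply(
      function(parts, k) if (length(parts) > k) parts[[k + 1L]] else NA_character_,
      ad_parts[match(rec, called)], alt_idx
    )))
    depth <- as.integer(dp[rec, j])
    if (anyNA(depth) || anyNA(alt_reads)) {
      i <- rec[which(is.na(depth) | is.na(alt_reads))[1L]]
      stop(sprintf("record %s:%s sample %s: malformed or missing DP/AD value",
                   fix$CHROM[i], fix$POS[i], samples[j]), call. = FALSE)
    }
    rows[[j]] <- tibble::tibble(
      individual_id = as.character(smap$individual_id[j]),
      timepoint = as.integer(smap$timepoint[j]),
      sample_id = samples[j],
      contig = fix$CHROM[rec],
      pos = pos[rec],
      ref = fix$REF[rec],
      alt = vapply(seq_along(rec),
                   function(k) alt_list[[rec[k]]][alt_idx[k]], ""),
      depth = depth,
      alt_reads = alt_reads,
      vaf = alt_reads / depth,
      protein_change = pchange[rec],
      consequence = csq[rec]
    )
  }
  calls <- dplyr::bind_rows(rows)
  if (nrow(calls) == 0L) return(variant_call_columns())
  calls$gene <- panel_gene_at(panel, calls$contig, calls$pos)
  calls[, names(variant_call_columns())]
}

extract_info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2L) x[[2L]] else NA_character_, "")
}

#' Read sample metadata from TSV
#'
#' @param path TSV with columns `sample_id`, `individual_id`, `timepoint`,
#'   and optionally `draw_date`, `age`, `sex`, `race`, `ethnicity`, `bmi`,
#'   `height`, `blood_cancer_flag`.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  tibble::as_tibble(df)
}

#' Apply CHIP filters to variant calls
#'
#' A call is retained iff `depth >= min_depth`, `alt_reads >= min_alt_reads`,
#' `vaf >= min_vaf`, and the site lies inside the panel (`gene` not NA).
#' Per-rule removal counts are attached as the `filter_stats` attribute and
#' reported via [message()].
#'
#' @param calls Tibble from [read_variants()].
#' @param policy A [chip_filter_policy()].
#' @param quiet Suppress the summary message.
#' @return The retained calls, with attribute `filter_stats`.
#' @export
filter_chip <- function(calls, policy = chip_filter_policy(), quiet = FALSE) {
  stopifnot(inherits(policy, "chip_filter_policy"))
  if (nrow(calls) == 0L) {
    out <- calls
    attr(out, "filter_stats") <- tibble::tibble(
      total = 0L, fail_depth = 0L, fail_alt_reads = 0L, fail_vaf = 0L,
      off_panel = 0L, retained = 0L)
    return(out)
  }
  ok_depth <- calls$depth >= policy$min_depth
  ok_alt <- calls$alt_reads >= policy$min_alt_reads
  ok_vaf <- calls$vaf >= policy$min_vaf
  on_panel <- !is.na(calls$gene)
  keep <- ok_depth & ok_alt & ok_vaf & on_panel

  stats <- tibble::tibble(
    total = nrow(calls),
    fail_depth = sum(!ok_depth),
    fail_alt_reads = sum(!ok_alt),
    fail_vaf = sum(!ok_vaf),
    off_panel = sum(!on_panel),
    retained = sum(keep)
  )
  if (!quiet) {
    message(sprintf(
      "filter_chip: retained %d/%d calls (removed: %d depth<%d, %d alt<%d, %d vaf<%g, %d off-panel)",
      stats$retained, stats$total, stats$fail_depth, policy$min_depth,
      stats$fail_alt_reads, policy$min_alt_reads, stats$fail_vaf,
      policy$min_vaf, stats$off_panel))
  }
  out <- calls[keep, , drop = FALSE]
  attr(out, "filter_stats") <- stats
  out
}

# Elapsed years between the two timepoints of each individual.
# Draw dates take precedence over ages (days / 365.25); ages are a fallback.
individual_dt_years <- function(metadata) {
  need <- c("individual_id", "timepoint")
  stopifnot(all(need %in% names(metadata)))
  per <- split(metadata, metadata$individual_id)
  out <- lapply(per, function(df) {
    tps <- sort(unique(df$timepoint))
    if (length(tps) < 2L) {
      return(tibble::tibble(individual_id = df$individual_id[1L],
                            dt_years = NA_real_))
    }
    r1 <- df[df$timepoint == tps[1L], ][1L, ]
    r2 <- df[df$timepoint == tps[2L], ][1L, ]
    dt <- NA_real_
    if (!is.null(df$draw_date) && !is.na(r1$draw_date) && !is.na(r2$draw_date)) {
      dt <- as.numeric(as.Date(r2$draw_date) - as.Date(r1$draw_date)) / 365.25
    } else if (!is.null(df$age) && !is.na(r1$age) && !is.na(r2$age)) {
      dt <- r2$age - r1$age
    }
    tibble::tibble(individual_id = df$individual_id[1L], dt_years = dt)
  })
  dplyr::bind_rows(out)
}

#' Pair mutations across two timepoints into clone trajectories
#'
#' For every mutation key (individual, contig, pos, ref, alt) that passes the
#' CHIP filters at one or both timepoints, emits one clone pair carrying the
#' VAF at both timepoints and the elapsed time. When a mutation passes at
#' only one timepoint, the other timepoint's VAF is taken from a matching
#' sub-threshold raw call with at least `min_alt_reads` supporting reads
#' (cross-timepoint rescue); if no such call exists, it is imputed at
#' `floor_vaf`, the assay's effective lower detection limit. Rescued VAFs are
#' floored at `floor_vaf`.
#'
#' Individuals flagged `blood_cancer_flag` in the metadata are dropped before
#' pairing (such individuals have blood cancer rather than CHIP). Individuals
#' without two timepoints in the metadata are skipped with a warning.
#'
#' @param retained Calls that passed [filter_chip()].
#' @param all_calls All raw calls from [read_variants()] (rescue source).
#' @param metadata Sample metadata (data frame or TSV path); needs
#'   `individual_id`, `timepoint`, and `draw_date` and/or `age`; optional
#'   `blood_cancer_flag`.
#' @param policy The [chip_filter_policy()] used for filtering.
#' @return Tibble of clone pairs: `individual_id`, `gene`, `contig`, `pos`,
#'   `ref`, `alt`, `mutation_key`, `protein_change`, `consequence`, `vaf1`,
#'   `vaf2`, `dt_years`, `pass_t1`, `pass_t2`, `imputed_t1`, `imputed_t2`.
#' @export
pair_timepoints <- function(retained, all_calls, metadata,
                            policy = chip_filter_policy()) {
  stopifnot(inherits(policy, "chip_filter_policy"))
  if (is.character(metadata) && length(metadata) == 1L) {
    metadata <- read_sample_metadata(metadata)
  }

  empty <- tibble::tibble(
    individual_id = character(), gene = character(), contig = character(),
    pos = integer(), ref = character(), alt = character(),
    mutation_key = character(), protein_change = character(),
    consequence = character(), vaf1 = double(), vaf2 = double(),
    dt_years = double(), pass_t1 = logical(), pass_t2 = logical(),
    imputed_t1 = logical(), imputed_t2 = logical())
  if (nrow(retained) == 0L) return(empty)

  if (!is.null(metadata$blood_cancer_flag)) {
    excluded <- unique(metadata$individual_id[
      as.logical(metadata$blood_cancer_flag) %in% TRUE])
    if (length(excluded) > 0L) {
      retained <- retained[!retained$individual_id %in% excluded, , drop = FALSE]
      all_calls <- all_calls[!all_calls$individual_id %in% excluded, , drop = FALSE]
      metadata <- metadata[!metadata$individual_id %in% excluded, , drop = FALSE]
    }
    if (nrow(retained) == 0L) return(empty)
  }

  dts <- individual_dt_years(metadata)
  no_dt <- dts$individual_id[is.na(dts$dt_years)]
  affected <- intersect(unique(retained$individual_id), no_dt)
  if (length(affected) > 0L) {
    warning("skipping individual(s) without two dated timepoints: ",
            paste(affected, collapse = ", "), call. = FALSE)
    retained <- retained[!retained$individual_id %in% affected, , drop = FALSE]
  }
  if (nrow(retained) == 0L) return(empty)
  dts <- dts[!is.na(dts$dt_years), , drop = FALSE]
  if (any(dts$dt_years <= 0)) {
    stop("non-positive elapsed time between timepoints for individual(s): ",
         paste(dts$individual_id[dts$dt_years <= 0], collapse = ", "),
         call. = FALSE)
  }

  keyify <- function(df) {
    paste(df$individual_id, df$contig, df$pos, df$ref, df$alt, sep = "\r")
  }
  retained$.key <- keyify(retained)
  rescue <- all_calls[all_calls$alt_reads >= policy$min_alt_reads, , drop = FALSE]
  rescue_vaf <- setNames(rescue$vaf, paste(keyify(rescue), rescue$timepoint))

  per_key <- split(retained, retained$.key)
  rows <- lapply(per_key, function(df) {
    first <- df[1L, ]
    pass1 <- any(df$timepoint == 1L)
    pass2 <- any(df$timepoint == 2L)
    lookup <- function(tp, passed) {
      if (passed) {
        v <- df$vaf[df$timepoint == tp][1L]
        return(c(vaf = v, imputed = 0))
      }
      if (policy$rescue_cross_timepoint) {
        v <- rescue_vaf[paste(first$.key, tp)]
        if (!is.na(v)) return(c(vaf = max(v, policy$floor_vaf), imputed = 0))
      }
      c(vaf = policy$floor_vaf, imputed = 1)
    }
    v1 <- lookup(1L, pass1); v2 <- lookup(2L, pass2)
    tibble::tibble(
      individual_id = first$individual_id, gene = first$gene,
      contig = first$contig, pos = first$pos, ref = first$ref,
      alt = first$alt,
      mutation_key = paste(first$contig, first$pos, first$ref, first$alt,
                           sep = ":"),
      protein_change = first$protein_change, consequence = first$consequence,
      vaf1 = unname(v1["vaf"]), vaf2 = unname(v2["vaf"]),
      dt_years = dts$dt_years[match(first$individual_id, dts$individual_id)],
      pass_t1 = pass1, pass_t2 = pass2,
      imputed_t1 = v1["imputed"] == 1, imputed_t2 = v2["imputed"] == 1)
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$individual_id, out$mutation_key), , drop = FALSE]
}
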