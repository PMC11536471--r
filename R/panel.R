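#' Load a CHIP panel definition
#'
#' Reads a BED file of targeted intervals (0-based, half-open) plus an
#' optional YAML side file giving a panel version label and per-gene capture
#' mode (`full-gene` or `hotspot-region`). Intervals are merged per gene and
#' the total targeted territory is computed.
#'
#' The default shipped panel targets the 22 genes commonly used for CHIP
#' calling (ASXL1, ASXL2, BRCC3, CBL, DNMT3A, ETNK1, GNAS, GNB1, IDH1, IDH2,
#' JAK2, KIT, KRAS, MPL, NRAS, PPM1D, SETBP1, SF3B1, SRSF2, TET2, TP53,
#' U2AF1) over roughly 45 kb. The shipped interval coordinates are
#' representative regions, not a vendor capture design: real deployments
#' should supply their own BED.
#'
#' @param bed_path Path to a 4+ column BED file (contig, start, end, gene).
#'   Lines starting with `#`, `track` or `browser` are skipped.
#' @param config_path Optional YAML file with `version` and a `capture_mode`
#'   map keyed by gene symbol. Defaults to the YAML shipped alongside the
#'   default BED when `bed_path` is the default.
#' @return An object of class `chip_panel`: a list with `genes` (tibble:
#'   `gene`, `capture_mode`, `n_intervals`, `bp`), `intervals` (tibble:
#'   `gene`, `contig`, `start`, `end`; merged, 0-based half-open),
#'   `target_bp`, and `version`.
#' @examples
#' panel <- load_panel()
#' nrow(panel$genes)    # 22
#' panel$target_bp
#' @export
load_panel <- function(bed_path = chipdyn_default_panel_bed(),
                       config_path = NULL) {
  if (!file.exists(bed_path)) {
    stop("panel BED not found: ", bed_path, call. = FALSE)
  }
  if (is.null(config_path) &&
      normalizePath(bed_path) == normalizePath(chipdyn_default_panel_bed())) {
    config_path <- chipdyn_default_panel_yaml()
  }

  lines <- readLines(bed_path)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) stop("panel BED contains no records", call. = FALSE)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 4L)
  if (length(bad) > 0L) {
    stop("malformed BED record (need >= 4 tab-separated fields) at line ",
         line_no[bad[1L]], " of ", bed_path, call. = FALSE)
  }
  contig <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  gene <- vapply(fields, `[[`, "", 4L)
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad) > 0L) {
    stop("malformed BED interval (non-numeric or end <= start) at line ",
         line_no[bad[1L]], " of ", bed_path, call. = FALSE)
  }

  raw <- tibble::tibble(gene = gene, contig = contig, start = start, end = end)
  intervals <- merge_gene_intervals(raw)

  version <- "unversioned"
  capture_mode <- NULL
  if (!is.null(config_path)) {
    if (!file.exists(config_path)) {
      stop("panel config not found: ", config_path, call. = FALSE)
    }
    cfg <- yaml::read_yaml(config_path)
    if (!is.null(cfg$version)) version <- as.character(cfg$version)
    capture_mode <- cfg$capture_mode
    if (!is.null(capture_mode)) {
      modes <- unlist(capture_mode)
      bad_mode <- setdiff(unique(modes), c("full-gene", "hotspot-region"))
      if (length(bad_mode) > 0L) {
        stop("invalid capture_mode value(s): ",
             paste(bad_mode, collapse = ", "), call. = FALSE)
      }
      if (anyDuplicated(names(capture_mode))) {
        dup <- unique(names(capture_mode)[duplicated(names(capture_mode))])
        conflicting <- vapply(dup, function(g) {
          length(unique(modes[names(modes) == g])) > 1L
        }, logical(1))
        if (any(conflicting)) {
          stop("gene(s) listed with conflicting capture_mode: ",
               paste(dup[conflicting], collapse = ", "), call. = FALSE)
        }
      }
    }
  }

  genes <- intervals |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_intervals = dplyr::n(),
                     bp = sum(.data$end - .data$start),
                     .groups = "drop")
  genes$capture_mode <- if (is.null(capture_mode)) {
    "full-gene"
  } else {
    mode <- unlist(capture_mode)[genes$gene]
    ifelse(is.na(mode), "full-gene", mode)
  }
  genes <- genes[, c("gene", "capture_mode", "n_intervals", "bp")]

  structure(
    list(genes = genes,
         intervals = intervals,
         target_bp = sum(genes$bp),
         version = version),
    class = "chip_panel"
  )
}

# Merge per-gene (and per-contig) intervals; BED coordinates are 0-based
# half-open, IRanges is 1-based closed -- the conversion lives only here.
merge_gene_intervals <- function(raw) {
  pieces <- split(raw, paste(raw$gene, raw$contig, sep = "\r"))
  merged <- lapply(pieces, function(df) {
    ir <- IRanges::reduce(IRanges::IRanges(start = df$start + 1L, end = df$end))
    tibble::tibble(gene = df$gene[1L], contig = df$contig[1L],
                   start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  })
  out <- dplyr::bind_rows(merged)
  out[order(out$contig, out$start, out$gene), , drop = FALSE]
}

#' Write a panel definition back to BED
#'
#' Inverse of [load_panel()] for the interval component; used for
#' round-tripping panel definitions between tools.
#'
#' @param panel A `chip_panel`.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_panel_bed <- function(panel, path) {
  stopifnot(inherits(panel, "chip_panel"))
  df <- panel$intervals[, c("contig", "start", "end", "gene")]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.chip_panel <- function(x, ...) {
  cat(sprintf("CHIP panel '%s': %d genes, %d intervals, %.1f kb targeted\n",
              x$version, nrow(x$genes), nrow(x$intervals), x$target_bp / 1e3))
  invisible(x)
}

#' Path to the shipped default panel BED
#' @return File path.
#' @export
chipdyn_default_panel_bed <- function() {
  system.file("extdata", "chip_panel.bed", package = "chipdyn", mustWork = TRUE)
}

#' Path to the shipped default panel YAML config
#' @return File path.
#' @export
chipdyn_default_panel_yaml <- function() {
  system.file("extdata", "chip_panel.yaml", package = "chipdyn", mustWork = TRUE)
}

# Map 1-based VCF positions onto a panel: returns the gene symbol covering
# each position, or NA when off-target. A VCF position `pos` falls in a
# half-open BED interval [start, end) iff start < pos <= end.
panel_gene_at <- function(panel, contig, pos) {
  stopifnot(inherits(panel, "chip_panel"))
  out <- rep(NA_character_, length(pos))
  iv <- panel$intervals
  for (ctg in unique(contig)) {
    sel <- which(contig == ctg)
    sub <- iv[iv$contig == ctg, , drop = FALSE]
    if (nrow(sub) == 0L) next
    hit <- IRanges::findOverlaps(
      IRanges::IRanges(start = pos[sel], width = 1L),
      IRanges::IRanges(start = sub$start + 1L, end = sub$end),
      select = "first"
    )
    out[sel] <- sub$gene[hit]
  }
  out
}
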