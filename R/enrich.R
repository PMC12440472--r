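# Enrichment (capture-probe) coverage: base-level interval arithmetic over
# target regions, with the high/low (>= 90%) per-region classification.

#' Build per-variant target regions around a panel
#'
#' Convenience builder for enrichment analysis when explicit target regions
#' are not supplied: one region per panel variant, centred on it, extending
#' `flank_bp` bases to each side. Regions are BED-convention 0-based
#' half-open, so a variant at 1-based position p gives
#' `[p - 1 - flank_bp, p + flank_bp)` of length `2 * flank_bp + 1`.
#'
#' @param panel Variant panel tibble.
#' @param flank_bp Flank size in bases (default 100).
#' @return Tibble of target regions: `gene`, `region_id` (the rsID), `chrom`,
#'   `start`, `end`.
#' @examples
#' target_regions(adme_panel())
#' @export
target_regions <- function(panel, flank_bp = 100) {
  panel <- as_variant_panel(panel)
  stopifnot(flank_bp >= 0)
  tibble(
    gene = panel$gene,
    region_id = panel$rsid,
    chrom = panel$chrom,
    start = pmax(0, panel$pos - 1 - flank_bp),
    end = panel$pos + flank_bp
  )
}

as_target_regions <- function(regions) {
  req <- c("region_id", "chrom", "start", "end")
  missing_cols <- setdiff(req, names(regions))
  if (length(missing_cols) > 0) {
    abort(paste0("regions are missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "admecov_schema_error")
  }
  regions <- as_tibble(regions)
  if (!"gene" %in% names(regions)) regions$gene <- regions$region_id
  regions <- regions[, c("gene", "region_id", "chrom", "start", "end")]
  if (nrow(regions) < 1) {
    abort("at least one target region is required", class = "admecov_invalid")
  }
  regions$chrom <- normalize_chrom(regions$chrom)
  if (any(regions$end <= regions$start | regions$start < 0)) {
    abort("regions must satisfy 0 <= start < end", class = "admecov_invalid")
  }
  dup <- unique(regions$region_id[duplicated(regions$region_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate region_id(s): ", paste(dup, collapse = ", ")),
          class = "admecov_duplicate_error")
  }
  regions
}

# GRanges from 0-based half-open tibble intervals; a shared seqlevel
# universe keeps chromosome-disjoint overlap queries quiet
intervals_to_granges <- function(df, seqlevels = unique(df$chrom)) {
  GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end)
  )
}

#' Base-level probe coverage of target regions
#'
#' For each region, the fraction of its bases lying in the union of the
#' probe intervals: overlapping probes never count a base twice, so the
#' fraction is invariant under splitting a probe into adjacent pieces and
#' monotone non-decreasing as probes are added.
#'
#' @param regions Target regions tibble (`gene`, `region_id`, `chrom`,
#'   `start`, `end`) — see [target_regions()].
#' @param probes Probe design tibble (`chrom`, `start`, `end`), BED
#'   convention.
#' @return Tibble with one row per region: `gene`, `region_id`, `length`,
#'   `covered_bases`, `base_fraction` in `[0, 1]`.
#' @examples
#' regions <- tibble::tibble(gene = "G", region_id = "r1",
#'                           chrom = "7", start = 0, end = 100)
#' probes <- tibble::tibble(chrom = "7", start = c(0, 40), end = c(50, 90))
#' region_base_coverage(regions, probes)
#' @export
region_base_coverage <- function(regions, probes) {
  regions <- as_target_regions(regions)
  probes <- as_probe_design(probes)
  chroms <- unique(c(regions$chrom, probes$chrom))
  reg_gr <- intervals_to_granges(regions, chroms)
  covered <- rep(0, nrow(regions))
  if (nrow(probes) > 0) {
    probe_union <- GenomicRanges::reduce(intervals_to_granges(probes, chroms))
    hits <- GenomicRanges::findOverlaps(reg_gr, probe_union)
    if (length(hits) > 0) {
      inter <- IRanges::pintersect(
        reg_gr[S4Vectors::queryHits(hits)],
        probe_union[S4Vectors::subjectHits(hits)]
      )
      w <- tapply(GenomicRanges::width(inter), S4Vectors::queryHits(hits), sum)
      covered[as.integer(names(w))] <- as.numeric(w)
    }
  }
  len <- regions$end - regions$start
  tibble(
    gene = regions$gene,
    region_id = regions$region_id,
    length = len,
    covered_bases = covered,
    base_fraction = covered / len
  )
}

#' Enrichment-design coverage with high/low classification
#'
#' Classifies each target region as high coverage when the probe union
#' covers at least `high_threshold` of its bases (inclusive, per the
#' ">= 90%" convention), then aggregates per gene and overall. The overall
#' percentage is the share of regions classified high.
#'
#' @inheritParams region_base_coverage
#' @param high_threshold Base-fraction cut-off for "high coverage"
#'   (default 0.90, compared inclusively).
#' @param design Optional label for the probe design.
#' @return An `enrichment_result`: list with
#'   * `per_region`: region table with `base_fraction` and `is_high`;
#'   * `per_gene`: `gene`, `regions_n`, `high_n`, `low_n`, `percent_high`;
#'   * `overall`: one-row tibble `covered_n`, `total_n`, `percent`.
#' @export
enrichment_coverage <- function(regions, probes, high_threshold = 0.90,
                                design = "probes") {
  stopifnot(high_threshold >= 0, high_threshold <= 1)
  per_region <- region_base_coverage(regions, probes)
  per_region$is_high <- per_region$base_fraction >= high_threshold
  per_gene <- per_region |>
    group_by(.data$gene) |>
    summarise(
      regions_n = dplyr::n(),
      high_n = sum(.data$is_high),
      low_n = sum(!.data$is_high),
      percent_high = percent_coverage(sum(.data$is_high), dplyr::n()),
      .groups = "drop"
    )
  overall <- tibble(
    covered_n = sum(per_region$is_high),
    total_n = nrow(per_region),
    percent = percent_coverage(sum(per_region$is_high), nrow(per_region))
  )
  structure(
    list(design = design, high_threshold = high_threshold,
         per_region = per_region, per_gene = per_gene, overall = overall),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %s: %d/%d regions at >= %.0f%% base coverage (%.2f%%)\n",
              x$design, x$overall$covered_n, x$overall$total_n,
              x$high_threshold * 100, x$overall$percent))
  print(x$per_gene)
  invisible(x)
}

#' @describeIn enrichment_coverage Per-region table.
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.enrichment_result <- function(x, ...) x$per_region

#' @describeIn enrichment_coverage One-row overall summary.
#' @exportS3Method generics::glance
glance.enrichment_result <- function(x, ...) {
  tibble(design = x$design, high_threshold = x$high_threshold,
         covered_n = x$overall$covered_n, total_n = x$overall$total_n,
         percent = x$overall$percent)
}

#' Per-gene high-coverage bar chart for an enrichment result
#'
#' @param object An `enrichment_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.enrichment_result <- function(object, ...) {
  ggplot2::ggplot(object$per_gene,
                  ggplot2::aes(x = .data$gene, y = .data$percent_high)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = NULL,
                  y = sprintf("%% regions at >= %.0f%% base coverage",
                              object$high_threshold * 100)) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}
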