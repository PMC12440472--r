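# Coverage statistics: physical (direct) coverage, LD-adjusted coverage,
# the multi-platform boolean matrix, and the uncovered-variant analysis.
#
# The statistic throughout is
#   %coverage = |interest list  ∩  target list| * 100 / |target list|
# computed on (chrom, pos) identity; rounding happens only at presentation.

new_coverage_result <- function(platform, mode, per_variant) {
  covered_n <- sum(per_variant$covered, na.rm = TRUE)
  total_n <- nrow(per_variant)
  structure(
    list(platform = platform, mode = mode, per_variant = per_variant,
         covered_n = covered_n, total_n = total_n,
         percent = covered_n * 100 / total_n),
    class = "coverage_result"
  )
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("<coverage_result> %s (%s): %d/%d variants covered (%.2f%%)\n",
              x$platform, x$mode, x$covered_n, x$total_n,
              round_half_up(x$percent, 2)))
  invisible(x)
}

#' @describeIn physical_coverage Per-variant coverage flags as a tibble.
#' @param x A `coverage_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.coverage_result <- function(x, ...) {
  out <- as_tibble(x$per_variant)
  out$platform <- x$platform
  out$mode <- x$mode
  out
}

#' @describeIn physical_coverage One-row summary: platform, mode, counts and
#'   percent (half-up, 2 decimals).
#' @exportS3Method generics::glance
glance.coverage_result <- function(x, ...) {
  tibble(platform = x$platform, mode = x$mode,
         covered_n = x$covered_n, total_n = x$total_n,
         percent = round_half_up(x$percent, 2))
}

#' Physical (direct) coverage of a variant panel by a platform manifest
#'
#' A panel variant is covered when its exact `(chrom, pos)` is interrogated
#' by the platform. If the manifest carries rsIDs, `rsid_fallback = TRUE`
#' additionally covers variants whose rsID appears on the manifest (useful
#' when a manifest lists identifiers for a different build).
#'
#' @param panel Variant panel tibble (`gene`, `rsid`, `chrom`, `pos`).
#' @param manifest Platform manifest (see [as_platform_manifest()]); an empty
#'   manifest yields 0% coverage.
#' @param platform Platform label; defaults to the manifest's `"platform"`
#'   attribute.
#' @param rsid_fallback Also match by rsID where the manifest provides one.
#' @return A `coverage_result`: per-variant flags plus `covered_n`, `total_n`
#'   and the exact `percent`. Use [glance()] for the presentation summary and
#'   [tidy()] for the per-variant table.
#' @examples
#' panel <- adme_panel()
#' manifest <- as_platform_manifest(panel[1:8, c("chrom", "pos")], "toy")
#' physical_coverage(panel, manifest)
#' @export
physical_coverage <- function(panel, manifest, platform = NULL,
                              rsid_fallback = FALSE) {
  panel <- as_variant_panel(panel)
  manifest <- as_platform_manifest(manifest, name = platform)
  covered <- pos_key(panel$chrom, panel$pos) %in%
    pos_key(manifest$chrom, manifest$pos)
  if (rsid_fallback && "rsid" %in% names(manifest)) {
    covered <- covered | panel$rsid %in% manifest$rsid[!is.na(manifest$rsid)]
  }
  per_variant <- panel
  per_variant$covered <- covered
  per_variant$status <- ifelse(covered, "direct", "uncovered")
  new_coverage_result(attr(manifest, "platform"), "direct", per_variant)
}

#' LD-adjusted coverage of a variant panel by a platform manifest
#'
#' Extends [physical_coverage()] with tag-SNP capture: an uncovered variant
#' counts as captured if a manifest SNP within `config$window_kb` of it has
#' r-squared at least `config$r2_min` with it in the phased haplotype
#' panel(s) (see [ld_tag_coverage()]). Because every directly assayed
#' polymorphic variant tags itself at r-squared 1, LD-adjusted coverage is
#' never below physical coverage on the same inputs.
#'
#' Unassessable variants (absent from every haplotype panel) carry `NA`
#' flags and do not count as covered.
#'
#' @inheritParams physical_coverage
#' @param haplotypes A [hap_panel()] or list of them (one per population).
#' @param config An [ld_config()].
#' @return A `coverage_result` with `mode = "ld"`.
#' @export
ld_adjusted_coverage <- function(panel, manifest, haplotypes,
                                 config = ld_config(), platform = NULL) {
  manifest <- as_platform_manifest(manifest, name = platform)
  per_variant <- ld_tag_coverage(panel, manifest, haplotypes, config)
  new_coverage_result(attr(manifest, "platform"), "ld", per_variant)
}

#' Assemble a variants x (platform, mode) coverage matrix
#'
#' Binds per-platform coverage results into the boolean matrix underlying
#' multi-platform summary tables and heatmaps: one row per panel variant,
#' one column per (platform, mode) pair, in the order given.
#'
#' @param panel The variant panel shared by all results.
#' @param results Non-empty list of `coverage_result` objects computed on
#'   `panel`.
#' @return An object of class `coverage_matrix`.
#' @export
build_matrix <- function(panel, results) {
  panel <- as_variant_panel(panel)
  if (inherits(results, "coverage_result")) results <- list(results)
  if (length(results) == 0) {
    abort("at least one coverage result is required", class = "admecov_invalid")
  }
  cols <- lapply(results, function(r) {
    if (!inherits(r, "coverage_result")) {
      abort("results must be coverage_result objects", class = "admecov_invalid")
    }
    if (!identical(r$per_variant$rsid, panel$rsid)) {
      abort(sprintf("result '%s (%s)' was not computed on this panel",
                    r$platform, r$mode),
            class = "admecov_alignment_error")
    }
    r$per_variant$covered
  })
  cells <- do.call(cbind, cols)
  storage.mode(cells) <- "logical"
  columns <- tibble(
    platform = vapply(results, `[[`, "", "platform"),
    mode = vapply(results, `[[`, "", "mode")
  )
  new_coverage_matrix(panel, columns, cells)
}

new_coverage_matrix <- function(panel, columns, cells) {
  columns$label <- paste0(columns$platform,
                          ifelse(columns$mode == "ld", " (LD)", ""))
  rownames(cells) <- panel$rsid
  colnames(cells) <- columns$label
  structure(list(panel = panel, columns = columns, cells = cells),
            class = "coverage_matrix")
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat(sprintf("<coverage_matrix> %d variants x %d platform columns\n",
              nrow(x$cells), ncol(x$cells)))
  print(summarize_matrix(x))
  invisible(x)
}

#' Long-format view of a coverage matrix
#'
#' One row per (variant, platform, mode) with its coverage flag — the layout
#' heatmap tools expect.
#'
#' @param x A `coverage_matrix`.
#' @param ... Unused.
#' @return Tibble with `gene`, `rsid`, `chrom`, `pos`, `platform`, `mode`,
#'   `covered`.
#' @exportS3Method generics::tidy
tidy.coverage_matrix <- function(x, ...) {
  long <- lapply(seq_len(nrow(x$columns)), function(j) {
    out <- x$panel
    out$platform <- x$columns$platform[j]
    out$mode <- x$columns$mode[j]
    out$covered <- x$cells[, j]
    out
  })
  bind_rows(long)
}

#' @exportS3Method generics::glance
glance.coverage_matrix <- function(x, ...) summarize_matrix(x)

#' Per-column coverage summary of a coverage matrix
#'
#' Counts and percentages per (platform, mode) column — the multi-platform
#' summary table. Percentages are rounded half-up to `digits` decimals
#' (`digits = NULL` for exact values).
#'
#' @param matrix A `coverage_matrix`.
#' @param digits Decimal places for the percentage (default 2).
#' @return Tibble with `platform`, `mode`, `covered_n`, `total_n`, `percent`.
#' @examples
#' mat <- read_coverage_matrix(
#'   system.file("extdata", "platform_coverage_matrix.tsv", package = "admecov"),
#'   adme_panel()
#' )
#' summarize_matrix(mat)
#' @export
summarize_matrix <- function(matrix, digits = 2) {
  stopifnot(inherits(matrix, "coverage_matrix"))
  covered_n <- colSums(matrix$cells, na.rm = TRUE)
  total_n <- nrow(matrix$cells)
  tibble(
    platform = matrix$columns$platform,
    mode = matrix$columns$mode,
    covered_n = as.integer(covered_n),
    total_n = as.integer(total_n),
    percent = percent_coverage(covered_n, total_n, digits)
  )
}

#' Variants uncovered by every platform and mode
#'
#' Panel variants whose matrix row is all-false (or `NA`) across every
#' (platform, mode) column, in panel order.
#'
#' @param matrix A `coverage_matrix`.
#' @return Tibble of panel rows (possibly empty).
#' @export
uncovered_variants <- function(matrix) {
  stopifnot(inherits(matrix, "coverage_matrix"))
  any_cov <- rowSums(matrix$cells, na.rm = TRUE) > 0
  matrix$panel[!any_cov, ]
}

#' Heatmap of a coverage matrix
#'
#' Variants on the vertical axis (panel order, grouped by gene), platform
#' columns on the horizontal, tiles filled by coverage.
#'
#' @param object A `coverage_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.coverage_matrix <- function(object, ...) {
  long <- tidy(object)
  long$label <- paste0(long$platform, ifelse(long$mode == "ld", " (LD)", ""))
  long$label <- factor(long$label, levels = object$columns$label)
  long$rsid <- factor(long$rsid, levels = rev(object$panel$rsid))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$rsid,
                                     fill = .data$covered)) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "#f7f7f7"),
                               na.value = "grey60", name = "covered") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar chart comparing direct and LD-adjusted coverage per platform
#'
#' @param summary A summary tibble as returned by [summarize_matrix()] or
#'   by binding [glance()] rows of coverage results.
#' @return A ggplot object.
#' @export
plot_coverage_summary <- function(summary) {
  stopifnot(all(c("platform", "mode", "percent") %in% names(summary)))
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$platform, y = .data$percent,
                                        fill = .data$mode)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of panel variants covered", fill = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}
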