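# Domain types and coordinate conventions shared by all stages.
#
# Panel and manifest positions are 1-based (as printed in array annotation
# tables); probe/region intervals are 0-based half-open (BED convention).
# A variant at 1-based position p lies in [start, end) iff start <= p - 1 < end.
# Strand is ignored throughout: all coordinates are forward-strand Hg19.

#' Normalise a chromosome label
#'
#' Strips a leading `"chr"` prefix (case-insensitive) so that mixed-dialect
#' inputs (`"chr7"`, `"7"`) compare equal. The canonical form carries no
#' prefix.
#'
#' @param chrom Character vector of chromosome labels.
#' @return Character vector of canonical labels.
#' @examples
#' normalize_chrom(c("chr7", "7", "chrX"))
#' @export
normalize_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  if (any(is.na(chrom) | chrom == "")) {
    abort("chromosome labels must be non-empty", class = "admecov_invalid")
  }
  sub("^[Cc][Hh][Rr]", "", chrom)
}

#' Parse a "chrom:pos" genomic position
#'
#' Positions are 1-based on the Hg19 build, written `"7:99270539"`. Parsing
#' and [format_chrpos()] round-trip exactly for every valid position.
#'
#' @param text Character vector, each element `"chrom:pos"`.
#' @return A tibble with columns `chrom` (canonical label) and `pos`
#'   (integer-valued double, >= 1).
#' @examples
#' parse_chrpos("7:99270539")
#' parse_chrpos(c("22:42526694", "chr10:96818119"))
#' @export
parse_chrpos <- function(text) {
  text <- as.character(text)
  parts <- strsplit(text, ":", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    abort(
      paste0("malformed position (expected 'chrom:pos'): ",
             paste0("'", text[bad], "'", collapse = ", ")),
      class = "admecov_parse_error"
    )
  }
  chrom <- normalize_chrom(vapply(parts, `[[`, "", 1L))
  pos_chr <- vapply(parts, `[[`, "", 2L)
  if (any(!grepl("^[0-9]+$", pos_chr))) {
    offenders <- text[!grepl("^[0-9]+$", pos_chr)]
    abort(
      paste0("non-integer position in: ",
             paste0("'", offenders, "'", collapse = ", ")),
      class = "admecov_parse_error"
    )
  }
  pos <- as.numeric(pos_chr)
  if (any(pos < 1)) {
    abort(
      paste0("position must be >= 1 (1-based): ",
             paste0("'", text[pos < 1], "'", collapse = ", ")),
      class = "admecov_parse_error"
    )
  }
  tibble(chrom = chrom, pos = pos)
}

#' Format genomic positions as "chrom:pos"
#'
#' @param chrom Chromosome labels (normalised on the way out).
#' @param pos 1-based positions.
#' @return Character vector `"chrom:pos"`.
#' @examples
#' format_chrpos("7", 99270539)
#' @export
format_chrpos <- function(chrom, pos) {
  paste0(normalize_chrom(chrom), ":", format(pos, scientific = FALSE, trim = TRUE))
}

# numeric-aware chromosome ordering key: autosomes numerically, then X, Y, MT,
# then anything else lexically after those.
chrom_order_key <- function(chrom) {
  chrom <- normalize_chrom(chrom)
  n <- suppressWarnings(as.numeric(chrom))
  special <- c(X = 100, Y = 101, MT = 102, M = 102)
  key <- ifelse(!is.na(n), n, unname(special[toupper(chrom)]))
  ifelse(is.na(key), 1000 + as.numeric(factor(chrom)), key)
}

#' Order genomic positions
#'
#' Orders by chromosome (numeric-aware: 1..22, X, Y, MT, then others) and then
#' by position. Equality of positions is equality of the `(chrom, pos)` pair.
#'
#' @param chrom,pos Parallel vectors of labels and 1-based positions.
#' @return An integer permutation, as from [order()].
#' @export
order_positions <- function(chrom, pos) {
  order(chrom_order_key(chrom), pos)
}

#' LD-search configuration
#'
#' Parameters governing tag-SNP discovery: the minimum squared correlation
#' `r2_min` for a manifest SNP to count as a proxy, the search window around
#' the target, and how multiple population haplotype panels are aggregated.
#'
#' The 250 kb default window matches the documented default of the tagging
#' step this engine mirrors; `pooled` merges all haplotype panels into one
#' before computing LD, `per_population_any` accepts a tag found in at least
#' one population, `per_population_all` requires one in every population.
#'
#' @param r2_min Minimum r-squared in `[0, 1]`; default `0.8`.
#' @param window_kb Search window half-width in kilobases (> 0); default `250`.
#' @param pop_mode One of `"pooled"`, `"per_population_any"`,
#'   `"per_population_all"`.
#' @return An object of class `ld_config`.
#' @examples
#' ld_config(r2_min = 0.9, window_kb = 100)
#' @export
ld_config <- function(r2_min = 0.8, window_kb = 250,
                      pop_mode = c("pooled", "per_population_any",
                                   "per_population_all")) {
  pop_mode <- match.arg(pop_mode)
  stopifnot(is.numeric(r2_min), length(r2_min) == 1L, r2_min >= 0, r2_min <= 1,
            is.numeric(window_kb), length(window_kb) == 1L, window_kb > 0)
  structure(
    list(r2_min = r2_min, window_kb = window_kb, pop_mode = pop_mode),
    class = "ld_config"
  )
}

#' @export
print.ld_config <- function(x, ...) {
  cat(sprintf("<ld_config> r2_min = %g, window_kb = %g, pop_mode = %s\n",
              x$r2_min, x$window_kb, x$pop_mode))
  invisible(x)
}

# ---- validators for the tabular domain types --------------------------------

#' Validate a variant panel
#'
#' A variant panel is a tibble with one row per target variant and columns
#' `gene`, `rsid`, `chrom`, `pos`. rsIDs must match `rs[0-9]+` and both rsIDs
#' and `(chrom, pos)` pairs must be unique within the panel.
#'
#' @param panel A data frame with columns `gene`, `rsid`, `chrom`, `pos`.
#' @return The validated panel as a tibble, chromosome labels normalised,
#'   in the input row order.
#' @export
as_variant_panel <- function(panel) {
  req <- c("gene", "rsid", "chrom", "pos")
  missing_cols <- setdiff(req, names(panel))
  if (length(missing_cols) > 0) {
    abort(paste0("panel is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "admecov_schema_error")
  }
  panel <- as_tibble(panel)[, req]
  if (nrow(panel) < 1) {
    abort("panel must contain at least one variant", class = "admecov_invalid")
  }
  panel$chrom <- normalize_chrom(panel$chrom)
  panel$pos <- as.numeric(panel$pos)
  if (any(is.na(panel$pos) | panel$pos < 1 | panel$pos != floor(panel$pos))) {
    abort("panel positions must be positive integers (1-based)",
          class = "admecov_invalid")
  }
  if (any(!grepl("^rs[0-9]+$", panel$rsid))) {
    bad <- panel$rsid[!grepl("^rs[0-9]+$", panel$rsid)]
    abort(paste0("invalid rsIDs: ", paste(bad, collapse = ", ")),
          class = "admecov_invalid")
  }
  if (any(is.na(panel$gene) | panel$gene == "")) {
    abort("gene symbols must be non-empty", class = "admecov_invalid")
  }
  dup_rs <- unique(panel$rsid[duplicated(panel$rsid)])
  if (length(dup_rs) > 0) {
    abort(paste0("duplicate rsIDs in panel: ", paste(dup_rs, collapse = ", ")),
          class = "admecov_duplicate_error")
  }
  key <- format_chrpos(panel$chrom, panel$pos)
  dup_pos <- unique(key[duplicated(key)])
  if (length(dup_pos) > 0) {
    abort(paste0("duplicate positions in panel: ",
                 paste(dup_pos, collapse = ", ")),
          class = "admecov_duplicate_error")
  }
  panel
}

#' Validate a platform manifest
#'
#' A manifest is the set of variant sites a genotyping array interrogates:
#' a tibble with columns `chrom`, `pos` and optionally `rsid`. Duplicate
#' positions are collapsed with a warning.
#'
#' @param manifest Data frame with `chrom`, `pos` (and optional `rsid`).
#' @param name Platform label stored in the `"platform"` attribute.
#' @return Validated tibble of unique sites.
#' @export
as_platform_manifest <- function(manifest, name = NULL) {
  req <- c("chrom", "pos")
  missing_cols <- setdiff(req, names(manifest))
  if (length(missing_cols) > 0) {
    abort(paste0("manifest is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "admecov_schema_error")
  }
  manifest <- as_tibble(manifest)
  keep <- intersect(c("chrom", "pos", "rsid"), names(manifest))
  manifest <- manifest[, keep]
  if (nrow(manifest) > 0) {
    manifest$chrom <- normalize_chrom(manifest$chrom)
    manifest$pos <- as.numeric(manifest$pos)
    if (any(is.na(manifest$pos) | manifest$pos < 1)) {
      abort("manifest positions must be >= 1", class = "admecov_invalid")
    }
    key <- format_chrpos(manifest$chrom, manifest$pos)
    n_dup <- sum(duplicated(key))
    if (n_dup > 0) {
      warn(sprintf("manifest: collapsed %d duplicate position(s)", n_dup),
           class = "admecov_duplicate_warning")
      manifest <- manifest[!duplicated(key), ]
    }
  }
  name <- name %||% attr(manifest, "platform", exact = TRUE) %||% "manifest"
  attr(manifest, "platform") <- name
  manifest
}

#' Validate a probe design
#'
#' Probe/amplicon intervals in BED convention: 0-based half-open
#' `[start, end)`, so interval length is `end - start`. Overlapping probes
#' are retained as-is; union lengths are computed downstream.
#'
#' @param probes Data frame with columns `chrom`, `start`, `end`.
#' @return Validated tibble.
#' @export
as_probe_design <- function(probes) {
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(probes))
  if (length(missing_cols) > 0) {
    abort(paste0("probe design is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "admecov_schema_error")
  }
  probes <- as_tibble(probes)[, req]
  if (nrow(probes) > 0) {
    probes$chrom <- normalize_chrom(probes$chrom)
    probes$start <- as.numeric(probes$start)
    probes$end <- as.numeric(probes$end)
    bad <- which(!(probes$start >= 0 & probes$end > probes$start))
    if (length(bad) > 0) {
      abort(paste0("invalid interval(s) (need 0 <= start < end) at row(s): ",
                   paste(bad, collapse = ", ")),
            class = "admecov_invalid")
    }
  }
  probes
}

# shared join key for (chrom, pos) matching
pos_key <- function(chrom, pos) paste0(normalize_chrom(chrom), ":", pos)

# round half up at `digits` decimals; base round() is round-half-even
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Coverage percentage
#'
#' The coverage statistic used throughout: `covered_n * 100 / total_n`,
#' i.e. the percentage of the target list intersected by the interest list.
#' Presentation rounding is half-up to two decimals.
#'
#' @param covered_n,total_n Integer counts.
#' @param digits Decimal places for half-up rounding; `NULL` for the exact
#'   value.
#' @return Numeric percentage.
#' @examples
#' percent_coverage(18, 34)
#' @export
percent_coverage <- function(covered_n, total_n, digits = 2) {
  pct <- covered_n * 100 / total_n
  if (is.null(digits)) pct else round_half_up(pct, digits)
}
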