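# Readers and writers for the formats the pipeline touches: TSV panels and
# manifests, BED probe designs, phased VCF haplotypes, the 0/1 coverage
# matrix, and TSV/JSON reports. Reader warnings are counted and surfaced,
# never silent; read(write(x)) round-trips for every tabular type.

#' The packaged 34-variant ADME core panel
#'
#' The pharmacogene target list shipped with the package: 34 variants in
#' CYP2C8, CYP2D6, CYP3A4 and CYP3A5 involved in drug absorption,
#' distribution, metabolism and excretion, with Hg19 coordinates.
#'
#' @return A variant panel tibble (`gene`, `rsid`, `chrom`, `pos`).
#' @examples
#' adme_panel()
#' @export
adme_panel <- function() {
  read_panel(system.file("extdata", "adme_core_34.tsv", package = "admecov"))
}

#' Read a variant panel from TSV
#'
#' Expects a header `gene  rsid  chrom  pos` and one row per target variant;
#' positions are 1-based Hg19. rsIDs and positions must be unique.
#'
#' @param path Path to the TSV file.
#' @return A validated variant panel tibble in file order.
#' @export
read_panel <- function(path) {
  df <- read_tsv_checked(path, c("gene", "rsid", "chrom", "pos"))
  as_variant_panel(df)
}

#' Write a variant panel to TSV
#' @param panel Variant panel tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  panel <- as_variant_panel(panel)
  readr::write_tsv(panel, path)
  invisible(path)
}

#' Read a platform manifest from TSV
#'
#' Expects columns `chrom` and `pos` (1-based), optionally `rsid`. Duplicate
#' positions are collapsed with a warning; the number of unique sites kept
#' is reported via `message()`.
#'
#' @param path Path to the TSV file.
#' @param name Platform label (defaults to the file name without extension).
#' @return A platform manifest tibble with a `"platform"` attribute.
#' @export
read_manifest <- function(path, name = NULL) {
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  df <- read_tsv_checked(path, c("chrom", "pos"))
  if (nrow(df) == 0) {
    abort(paste0("empty manifest file: ", path), class = "admecov_empty_error")
  }
  m <- as_platform_manifest(df, name = name)
  inform(sprintf("manifest '%s': %d unique site(s)", name, nrow(m)))
  m
}

#' Write a platform manifest to TSV
#' @param manifest Manifest tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_tsv(as_tibble(manifest), path)
  invisible(path)
}

#' Read an enrichment probe design from BED
#'
#' Three or more tab-separated columns, no header: chrom, start, end in the
#' BED convention (0-based half-open). Intervals with `end <= start` are
#' rejected with their line numbers; overlapping intervals are retained
#' as-is (the union is computed downstream).
#'
#' @param path Path to the BED file.
#' @return A probe design tibble (`chrom`, `start`, `end`).
#' @export
read_probe_bed <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "admecov_io_error")
  }
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(as_probe_design(tibble(chrom = character(), start = numeric(),
                                  end = numeric())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3)) {
    abort(paste0("BED line(s) with fewer than 3 columns: ",
                 paste(which(lengths(fields) < 3), collapse = ", ")),
          class = "admecov_parse_error")
  }
  df <- tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.numeric(vapply(fields, `[[`, "", 2L)),
    end = as.numeric(vapply(fields, `[[`, "", 3L))
  )
  bad <- which(is.na(df$start) | is.na(df$end) | df$end <= df$start)
  if (length(bad) > 0) {
    abort(paste0("invalid BED interval(s) at line(s): ",
                 paste(bad, collapse = ", ")),
          class = "admecov_invalid")
  }
  as_probe_design(df)
}

#' Write a probe design to BED3
#' @param probes Probe design tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_bed <- function(probes, path) {
  probes <- as_probe_design(probes)
  readr::write_tsv(probes, path, col_names = FALSE)
  invisible(path)
}

#' Read phased haplotypes from a VCF
#'
#' Builds a `2 x n_samples` haplotype by site allele matrix from the phased
#' genotypes of a VCF. Only phased ("|"-separated), biallelic SNP records
#' with no missing alleles are used; skipped records are counted per reason
#' and surfaced in a single warning. No imputation or statistical phasing is
#' attempted: unphased records are skipped, not phased.
#'
#' @param path Path to a VCF (plain or gzipped).
#' @param region Optional region restriction, `"chrom:start-end"` with
#'   1-based inclusive bounds.
#' @param population Optional population label attached to the panel.
#' @return A [hap_panel()].
#' @export
read_vcf_haplotypes <- function(path, region = NULL, population = NULL) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "admecov_io_error")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    abort("VCF contains no records", class = "admecov_empty_panel")
  }
  chrom <- normalize_chrom(fix$CHROM)
  pos <- as.numeric(fix$POS)
  keep <- rep(TRUE, nrow(fix))
  if (!is.null(region)) {
    rg <- parse_region(region)
    keep <- chrom == rg$chrom & pos >= rg$start & pos <= rg$end
  }
  skipped <- c(multiallelic_or_indel = 0L, unphased = 0L, missing = 0L)

  is_snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) & fix$ALT %in% c("A", "C", "G", "T")
  skipped["multiallelic_or_indel"] <- sum(keep & !is_snp)
  keep <- keep & is_snp

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  no_missing <- apply(gt, 1L, function(g) {
    all(!is.na(g)) && !any(grepl(".", g, fixed = TRUE))
  })
  skipped["missing"] <- sum(keep & !no_missing)
  keep <- keep & no_missing
  phased <- apply(gt, 1L, function(g) {
    all(!is.na(g) & grepl("|", g, fixed = TRUE))
  })
  skipped["unphased"] <- sum(keep & !phased)
  keep <- keep & phased

  if (sum(skipped) > 0) {
    warn(sprintf(
      "read_vcf_haplotypes: skipped %d record(s) (%s)", sum(skipped),
      paste(names(skipped)[skipped > 0], skipped[skipped > 0],
            sep = "=", collapse = ", ")),
      class = "admecov_skip_warning")
  }
  if (!any(keep)) {
    abort("no phased biallelic SNP records in the requested region",
          class = "admecov_empty_panel")
  }
  gt <- gt[keep, , drop = FALSE]
  halves <- strsplit(as.vector(t(gt)), "|", fixed = TRUE)
  if (any(lengths(halves) != 2L)) {
    abort("non-diploid GT field encountered", class = "admecov_parse_error")
  }
  n_samp <- ncol(gt)
  n_site <- nrow(gt)
  # halves is site-major with samples varying fastest; rebuild as (hap x site)
  al1 <- matrix(vapply(halves, function(h) as.integer(h[1L]), 0L),
                nrow = n_samp, ncol = n_site, byrow = FALSE)
  al2 <- matrix(vapply(halves, function(h) as.integer(h[2L]), 0L),
                nrow = n_samp, ncol = n_site, byrow = FALSE)
  alleles <- matrix(0L, nrow = 2L * n_samp, ncol = n_site)
  alleles[seq(1L, 2L * n_samp, by = 2L), ] <- al1
  alleles[seq(2L, 2L * n_samp, by = 2L), ] <- al2
  ids <- fix$ID[keep]
  ids[ids == "."] <- NA_character_
  hap_panel(
    alleles,
    tibble(chrom = chrom[keep], pos = pos[keep], id = ids),
    population = population
  )
}

parse_region <- function(region) {
  m <- regmatches(region,
                  regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1L]]
  if (length(m) != 4L) {
    abort(paste0("malformed region (expected 'chrom:start-end'): ", region),
          class = "admecov_parse_error")
  }
  list(chrom = normalize_chrom(m[2L]), start = as.numeric(m[3L]),
       end = as.numeric(m[4L]))
}

#' Write a haplotype panel as a minimal phased VCF
#'
#' Emits a VCFv4.2 file with one phased diploid sample per pair of haplotype
#' rows (rows 1-2 become sample 1, and so on), REF/ALT placeholders A/G, and
#' GT-only FORMAT — the dialect [read_vcf_haplotypes()] consumes, so
#' generator output can feed the pipeline. The haplotype count must be even.
#'
#' @param panel A [hap_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_haplotypes <- function(panel, path) {
  stopifnot(inherits(panel, "hap_panel"))
  n_hap <- n_haplotypes(panel)
  if (n_hap %% 2L != 0L) {
    abort("haplotype count must be even (two per diploid sample)",
          class = "admecov_invalid")
  }
  n_samp <- n_hap %/% 2L
  samples <- sprintf("S%04d", seq_len(n_samp))
  ord <- order_positions(panel$sites$chrom, panel$sites$pos)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=admecov-simulated-haplotypes",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  recs <- vapply(ord, function(j) {
    a <- panel$alleles[, j]
    gt <- paste(a[seq(1L, n_hap, by = 2L)], a[seq(2L, n_hap, by = 2L)],
                sep = "|")
    id <- panel$sites$id[j]
    paste(c(panel$sites$chrom[j],
            format(panel$sites$pos[j], scientific = FALSE, trim = TRUE),
            if (is.na(id)) "." else id,
            "A", "G", ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, "")
  readr::write_lines(c(header, recs), path)
  invisible(path)
}

#' Read a variants x (platform, mode) coverage matrix from TSV
#'
#' The file has an `rsid` column plus one 0/1 column per (platform, mode),
#' named `<platform>_direct` or `<platform>_ld`. Rows are keyed and aligned
#' by rsID and must match the panel exactly; unknown or missing rsIDs raise
#' an alignment error. The packaged matrix
#' `system.file("extdata", "platform_coverage_matrix.tsv", package = "admecov")`
#' holds the published coverage of the 34-variant ADME core panel by four
#' Omni chips and the Axiom array, directly and with LD.
#'
#' @param path Path to the TSV file.
#' @param panel The variant panel the matrix rows describe.
#' @return A `coverage_matrix` aligned to panel order.
#' @export
read_coverage_matrix <- function(path, panel) {
  panel <- as_variant_panel(panel)
  df <- read_tsv_checked(path, "rsid")
  value_cols <- setdiff(names(df), "rsid")
  if (length(value_cols) == 0) {
    abort("coverage matrix has no platform columns",
          class = "admecov_schema_error")
  }
  extra <- setdiff(df$rsid, panel$rsid)
  missing_rs <- setdiff(panel$rsid, df$rsid)
  if (length(extra) > 0 || length(missing_rs) > 0) {
    abort(paste0(
      "coverage matrix rows do not match panel",
      if (length(extra) > 0)
        paste0("; unknown rsID(s): ", paste(extra, collapse = ", ")),
      if (length(missing_rs) > 0)
        paste0("; missing rsID(s): ", paste(missing_rs, collapse = ", "))),
      class = "admecov_alignment_error")
  }
  df <- df[match(panel$rsid, df$rsid), ]
  cells <- as.matrix(df[, value_cols])
  if (!all(cells %in% c(0, 1))) {
    abort("coverage matrix cells must be 0 or 1", class = "admecov_invalid")
  }
  mode <- ifelse(grepl("_ld$", value_cols), "ld", "direct")
  platform <- sub("_(ld|direct)$", "", value_cols)
  cells <- cells == 1
  new_coverage_matrix(panel, tibble(platform = platform, mode = mode), cells)
}

#' Write a coverage matrix to TSV
#'
#' Inverse of [read_coverage_matrix()]: `rsid` column plus one 0/1 column
#' per (platform, mode) named `<platform>_direct` / `<platform>_ld`.
#'
#' @param matrix A `coverage_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "coverage_matrix"))
  df <- as.data.frame(matrix$cells * 1L)
  names(df) <- paste0(matrix$columns$platform,
                      ifelse(matrix$columns$mode == "ld", "_ld", "_direct"))
  df <- cbind(tibble(rsid = matrix$panel$rsid), df)
  readr::write_tsv(as_tibble(df), path)
  invisible(path)
}

#' Write a coverage report to TSV or JSON
#'
#' Serialises one or more coverage results as a machine-readable report.
#' The TSV form has one row per (platform, mode) with `covered_n`,
#' `total_n` and the percentage formatted half-up to two decimals; the JSON
#' form additionally nests the per-variant flags
#' (`{platform, mode, covered_n, total_n, percent, per_variant: [{rsid, covered}]}`).
#'
#' @param results A `coverage_result` or list of them.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (inherits(results, "coverage_result")) results <- list(results)
  stopifnot(all(vapply(results, inherits, TRUE, "coverage_result")))
  summary <- bind_rows(lapply(results, glance))
  if (format == "tsv") {
    summary$percent <- sprintf("%.2f", summary$percent)
    readr::write_tsv(summary, path)
  } else {
    obj <- lapply(results, function(r) {
      list(platform = r$platform, mode = r$mode,
           covered_n = r$covered_n, total_n = r$total_n,
           percent = round_half_up(r$percent, 2),
           per_variant = lapply(seq_len(nrow(r$per_variant)), function(i) {
             list(rsid = r$per_variant$rsid[i],
                  covered = r$per_variant$covered[i])
           }))
    })
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  invisible(path)
}

# read a TSV and check required header columns; reports file and missing names
read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "admecov_io_error")
  }
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0(basename(path), ": missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "admecov_schema_error")
  }
  df
}
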