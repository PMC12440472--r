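# Report front end tying the stages together: each function mirrors one
# result table of a platform-coverage study (physical, LD-adjusted, probe
# enrichment, combined matrix), reads its inputs through the io module,
# writes TSV/JSON reports into an output directory, and returns the result
# objects invisibly. Logging goes to stderr via message(); warnings raised
# along the way are counted and surfaced in the run summary.

#' Assemble a run configuration for the report commands
#'
#' @param panel_path Path to the variant-panel TSV.
#' @param manifest_paths Named character vector of platform manifest TSVs.
#' @param vcf_paths Named character vector of phased VCFs (one per
#'   population).
#' @param probe_paths Named character vector of probe BED files.
#' @param ld An [ld_config()].
#' @param high_threshold Base-fraction cut-off for high region coverage.
#' @param flank_bp Flank for [target_regions()] when regions are built from
#'   the panel.
#' @param output_dir Directory the reports are written to (created if
#'   needed).
#' @param format `"tsv"` or `"json"`.
#' @param seed Optional integer seed (recorded; used by simulation-backed
#'   runs).
#' @return A `run_config` list.
#' @export
run_config <- function(panel_path, manifest_paths = character(),
                       vcf_paths = character(), probe_paths = character(),
                       ld = ld_config(), high_threshold = 0.90,
                       flank_bp = 100, output_dir = ".",
                       format = c("tsv", "json"), seed = NULL) {
  format <- match.arg(format)
  structure(
    list(panel_path = panel_path, manifest_paths = manifest_paths,
         vcf_paths = vcf_paths, probe_paths = probe_paths, ld = ld,
         high_threshold = high_threshold, flank_bp = flank_bp,
         output_dir = output_dir, format = format, seed = seed),
    class = "run_config"
  )
}

report_path <- function(config, name) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  file.path(config$output_dir, paste0(name, ".", config$format))
}

# run an expression counting the warnings it raises; returns list(value, n)
with_warning_count <- function(expr) {
  n <- 0L
  value <- withCallingHandlers(expr, warning = function(w) {
    n <<- n + 1L
    invokeRestart("muffleWarning")
  })
  list(value = value, n_warnings = n)
}

#' Physical-coverage report over one or more platform manifests
#'
#' Computes [physical_coverage()] of the panel against every manifest in
#' the configuration and writes a one-row-per-platform report.
#'
#' @param config A [run_config()] with `panel_path` and `manifest_paths`.
#' @return Invisibly, a list with `results` (coverage results), `summary`
#'   tibble, `files` written, and `n_warnings`.
#' @export
cmd_physical <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (length(config$manifest_paths) == 0) {
    abort("cmd_physical needs at least one manifest", class = "admecov_invalid")
  }
  run <- with_warning_count({
    panel <- read_panel(config$panel_path)
    results <- imap(as.list(config$manifest_paths), function(p, nm) {
      physical_coverage(panel, read_manifest(p, name = nm))
    })
    results
  })
  results <- run$value
  out <- report_path(config, "physical_coverage")
  write_report(unname(results), out, config$format)
  summary <- bind_rows(lapply(results, glance))
  message(sprintf("cmd_physical: %d platform(s), %d warning(s) -> %s",
                  length(results), run$n_warnings, out))
  invisible(list(results = results, summary = summary, files = out,
                 n_warnings = run$n_warnings))
}

#' Direct plus LD-adjusted coverage report
#'
#' For every manifest, computes both [physical_coverage()] and
#' [ld_adjusted_coverage()] against the phased haplotypes in
#' `config$vcf_paths`, and writes the platform summary plus a per-variant
#' tag listing (best proxy rsID, r-squared, distance). Unassessable
#' variants are listed with status `"unassessable"`; the run still
#' succeeds.
#'
#' @param config A [run_config()] with panel, manifests and at least one
#'   VCF.
#' @return Invisibly, a list with `results`, `summary`, `tags` (per-variant
#'   tibble), `files`, `n_warnings`.
#' @export
cmd_ld <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (length(config$manifest_paths) == 0 || length(config$vcf_paths) == 0) {
    abort("cmd_ld needs manifests and at least one VCF",
          class = "admecov_invalid")
  }
  run <- with_warning_count({
    panel <- read_panel(config$panel_path)
    haps <- imap(as.list(config$vcf_paths), function(p, nm) {
      read_vcf_haplotypes(p, population = nm)
    })
    results <- list()
    tags <- list()
    for (nm in names(config$manifest_paths)) {
      manifest <- read_manifest(config$manifest_paths[[nm]], name = nm)
      results[[paste0(nm, "_direct")]] <- physical_coverage(panel, manifest)
      ld_res <- ld_adjusted_coverage(panel, manifest, haps, config$ld)
      results[[paste0(nm, "_ld")]] <- ld_res
      tags[[nm]] <- tidy(ld_res)
    }
    list(results = results, tags = bind_rows(tags))
  })
  results <- run$value$results
  out <- report_path(config, "ld_coverage")
  write_report(unname(results), out, config$format)
  tag_file <- report_path(config, "tag_listing")
  tag_cols <- c("platform", "gene", "rsid", "chrom", "pos", "covered",
                "status", "best_tag_id", "best_tag_pos", "best_r2",
                "distance_bp")
  tag_tbl <- run$value$tags[, intersect(tag_cols, names(run$value$tags))]
  if (config$format == "json") {
    jsonlite::write_json(tag_tbl, tag_file, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  } else {
    readr::write_tsv(tag_tbl, tag_file)
  }
  summary <- bind_rows(lapply(results, glance))
  message(sprintf("cmd_ld: %d result column(s), %d warning(s) -> %s",
                  length(results), run$n_warnings, out))
  invisible(list(results = results, summary = summary, tags = tag_tbl,
                 files = c(out, tag_file), n_warnings = run$n_warnings))
}

#' Enrichment (probe) coverage report
#'
#' Builds per-variant target regions from the panel (`flank_bp`) and
#' classifies each against every probe design in the configuration,
#' writing per-region, per-gene and overall tables.
#'
#' @param config A [run_config()] with panel and `probe_paths`.
#' @return Invisibly, a list with `results` (enrichment results), `summary`,
#'   `files`, `n_warnings`.
#' @export
cmd_enrich <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (length(config$probe_paths) == 0) {
    abort("cmd_enrich needs at least one probe BED", class = "admecov_invalid")
  }
  run <- with_warning_count({
    panel <- read_panel(config$panel_path)
    regions <- target_regions(panel, flank_bp = config$flank_bp)
    imap(as.list(config$probe_paths), function(p, nm) {
      probes <- read_probe_bed(p)
      if (nrow(probes) == 0) {
        warn(sprintf("probe design '%s' is empty: 0%% coverage everywhere", nm),
             class = "admecov_empty_warning")
      }
      enrichment_coverage(regions, probes,
                          high_threshold = config$high_threshold, design = nm)
    })
  })
  results <- run$value
  files <- character(0)
  for (nm in names(results)) {
    per_gene <- results[[nm]]$per_gene
    f <- report_path(config, paste0("enrichment_", nm))
    if (config$format == "json") {
      jsonlite::write_json(
        list(design = nm, per_gene = per_gene,
             per_region = results[[nm]]$per_region,
             overall = results[[nm]]$overall),
        f, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    } else {
      readr::write_tsv(per_gene, f)
    }
    files <- c(files, f)
  }
  summary <- bind_rows(lapply(results, glance))
  message(sprintf("cmd_enrich: %d design(s), %d warning(s)",
                  length(results), run$n_warnings))
  invisible(list(results = results, summary = summary, files = files,
                 n_warnings = run$n_warnings))
}

#' Combined coverage-matrix report
#'
#' Loads a precomputed variants x (platform, mode) matrix (e.g. the
#' packaged one) or builds it from coverage results, then writes the
#' per-column summary, the uncovered-variant list, and the long-format
#' export heatmap tools consume.
#'
#' @param config A [run_config()]; `manifest_paths["matrix"]` may point to a
#'   coverage-matrix TSV, otherwise results must be supplied.
#' @param matrix_path Path to a coverage-matrix TSV (defaults to the
#'   packaged platform matrix).
#' @param results Optional list of `coverage_result` objects to build the
#'   matrix from instead of reading `matrix_path`.
#' @return Invisibly, a list with `matrix`, `summary`, `uncovered`, `files`,
#'   `n_warnings`.
#' @export
cmd_matrix <- function(config, matrix_path = NULL, results = NULL) {
  stopifnot(inherits(config, "run_config"))
  run <- with_warning_count({
    panel <- read_panel(config$panel_path)
    if (!is.null(results)) {
      build_matrix(panel, results)
    } else {
      matrix_path <- matrix_path %||%
        system.file("extdata", "platform_coverage_matrix.tsv",
                    package = "admecov")
      read_coverage_matrix(matrix_path, panel)
    }
  })
  mat <- run$value
  summary <- summarize_matrix(mat)
  uncovered <- uncovered_variants(mat)
  f_sum <- report_path(config, "matrix_summary")
  f_unc <- report_path(config, "uncovered_variants")
  f_long <- report_path(config, "matrix_long")
  if (config$format == "json") {
    jsonlite::write_json(summary, f_sum, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    jsonlite::write_json(uncovered, f_unc, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    jsonlite::write_json(tidy(mat), f_long, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  } else {
    sum_out <- summary
    sum_out$percent <- sprintf("%.2f", sum_out$percent)
    readr::write_tsv(sum_out, f_sum)
    readr::write_tsv(uncovered, f_unc)
    readr::write_tsv(tidy(mat), f_long)
  }
  message(sprintf(
    "cmd_matrix: %d column(s), %d uncovered variant(s), %d warning(s)",
    ncol(mat$cells), nrow(uncovered), run$n_warnings))
  invisible(list(matrix = mat, summary = summary, uncovered = uncovered,
                 files = c(f_sum, f_unc, f_long),
                 n_warnings = run$n_warnings))
}
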