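# Phased haplotype panels: the substrate for LD calculations.

#' Construct a phased haplotype panel
#'
#' A haplotype panel holds a 0/1 allele matrix with one row per haplotype
#' (two per diploid sample) and one column per biallelic site, together with
#' per-site position metadata. Allele 1 is the alternate allele.
#'
#' @param alleles Matrix of 0/1 values, haplotypes x sites.
#' @param sites Data frame with one row per column of `alleles` and columns
#'   `chrom`, `pos`, and optionally `id` (rsID).
#' @param population Optional population label.
#' @return An object of class `hap_panel`.
#' @examples
#' hp <- hap_panel(
#'   matrix(c(0, 0, 1, 1, 0, 1, 0, 1), nrow = 4),
#'   tibble::tibble(chrom = "7", pos = c(100, 200), id = c("rs1", "rs2"))
#' )
#' hp
#' @export
hap_panel <- function(alleles, sites, population = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (!all(alleles %in% c(0L, 1L))) {
    abort("haplotype alleles must be 0 or 1", class = "admecov_invalid")
  }
  sites <- as_tibble(sites)
  if (!all(c("chrom", "pos") %in% names(sites))) {
    abort("sites must have columns chrom, pos", class = "admecov_schema_error")
  }
  if (nrow(sites) != ncol(alleles)) {
    abort("sites must have one row per allele-matrix column",
          class = "admecov_invalid")
  }
  sites$chrom <- normalize_chrom(sites$chrom)
  sites$pos <- as.numeric(sites$pos)
  if (any(sites$pos < 1)) {
    abort("site positions must be >= 1", class = "admecov_invalid")
  }
  if (!"id" %in% names(sites)) sites$id <- NA_character_
  structure(
    list(alleles = alleles, sites = sites[, c("chrom", "pos", "id")],
         population = population),
    class = "hap_panel"
  )
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("<hap_panel> %d haplotypes x %d sites%s\n",
              n_haplotypes(x), n_sites(x),
              if (is.null(x$population)) "" else paste0(" [", x$population, "]")))
  invisible(x)
}

#' Number of haplotypes / sites in a panel
#' @param panel A `hap_panel`.
#' @return Integer count.
#' @export
n_haplotypes <- function(panel) nrow(panel$alleles)

#' @rdname n_haplotypes
#' @export
n_sites <- function(panel) ncol(panel$alleles)

#' Alternate-allele frequency at panel sites
#'
#' Frequency of allele 1 among haplotypes: `(count of 1s) / n_haplotypes`.
#'
#' @param panel A `hap_panel`.
#' @param sites Site indices (default: all sites).
#' @return Numeric vector of frequencies in `[0, 1]`.
#' @examples
#' hp <- hap_panel(matrix(c(0, 0, 1, 1), ncol = 1),
#'                 tibble::tibble(chrom = "1", pos = 100))
#' allele_frequency(hp, 1)
#' @export
allele_frequency <- function(panel, sites = seq_len(n_sites(panel))) {
  check_site_index(panel, sites)
  unname(colMeans(panel$alleles[, sites, drop = FALSE]))
}

check_site_index <- function(panel, sites) {
  if (length(sites) == 0 || any(sites < 1 | sites > n_sites(panel))) {
    abort("site index out of range", class = "admecov_invalid")
  }
  invisible(TRUE)
}

# index of the site matching (chrom, pos), or NA if absent
match_site <- function(panel, chrom, pos) {
  match(pos_key(chrom, pos), pos_key(panel$sites$chrom, panel$sites$pos))
}

#' Merge haplotype panels over their shared sites
#'
#' Stacks the haplotype rows of several panels, restricted to the sites
#' (by chromosome and position) present in every panel. Sites dropped from
#' any panel are reported in a warning. Used by the `pooled` population mode.
#'
#' @param panels A list of `hap_panel` objects (a single panel is returned
#'   unchanged).
#' @return A single `hap_panel`.
#' @export
merge_hap_panels <- function(panels) {
  if (inherits(panels, "hap_panel")) return(panels)
  stopifnot(is.list(panels), length(panels) >= 1)
  if (length(panels) == 1L) return(panels[[1L]])
  keys <- lapply(panels, function(p) pos_key(p$sites$chrom, p$sites$pos))
  common <- Reduce(intersect, keys)
  if (length(common) == 0) {
    abort("haplotype panels share no sites; cannot merge",
          class = "admecov_empty_panel")
  }
  n_dropped <- sum(vapply(keys, function(k) sum(!k %in% common), 0L))
  if (n_dropped > 0) {
    warn(sprintf("merge_hap_panels: dropped %d site(s) not shared by all panels",
                 n_dropped),
         class = "admecov_merge_warning")
  }
  mats <- Map(function(p, k) p$alleles[, match(common, k), drop = FALSE],
              panels, keys)
  sites <- panels[[1L]]$sites[match(common, keys[[1L]]), ]
  hap_panel(do.call(rbind, mats), sites, population = "pooled")
}
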