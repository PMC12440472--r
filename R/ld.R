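# Linkage-disequilibrium engine: haplotype-frequency D, D', r-squared, and
# tag-SNP discovery over a platform manifest.
#
# Because inputs are phased, LD is computed by direct haplotype counting —
# no EM/composite estimator. Unphased input is rejected upstream, not phased.

#' Pairwise linkage disequilibrium between two panel sites
#'
#' From phased haplotype counts: with `p_A`, `p_B` the allele-1 frequencies
#' and `p_AB` the frequency of haplotypes carrying allele 1 at both sites,
#' \deqn{D = p_{AB} - p_A p_B, \qquad r^2 = \frac{D^2}{p_A(1-p_A)\,p_B(1-p_B)}}
#' and `D' = |D| / D_max`, where `D_max = min(p_A(1-p_B), (1-p_A)p_B)` when
#' `D > 0` and `min(p_A p_B, (1-p_A)(1-p_B))` when `D < 0` (`D' = 0` at
#' `D = 0`). The result is symmetric under swapping the sites and invariant
#' under relabelling 0 and 1 at either site.
#'
#' @param panel A [hap_panel()].
#' @param site_a,site_b Site indices.
#' @return One-row tibble with columns `site_a`, `site_b`, `p_a`, `p_b`,
#'   `d`, `d_prime`, `r2`.
#' @examples
#' hp <- hap_panel(
#'   cbind(c(1, 1, 1, 0, 0, 0, 1, 0), c(1, 1, 1, 0, 0, 0, 0, 1)),
#'   tibble::tibble(chrom = "1", pos = c(100, 200))
#' )
#' pairwise_r2(hp, 1, 2) # r2 = 0.25
#' @export
pairwise_r2 <- function(panel, site_a, site_b) {
  check_site_index(panel, c(site_a, site_b))
  a <- panel$alleles[, site_a]
  b <- panel$alleles[, site_b]
  p_a <- mean(a)
  p_b <- mean(b)
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) {
    abort(
      sprintf("LD undefined: site %d monomorphic",
              if (p_a %in% c(0, 1)) site_a else site_b),
      class = "admecov_monomorphic"
    )
  }
  # integer haplotype counts keep r2 exact for the rational it is:
  # r2 = (n*n_AB - n_A*n_B)^2 / (n_A(n-n_A) n_B(n-n_B)) is a single
  # correctly-rounded division, symmetric in the two sites by construction
  n <- length(a)
  n_a <- sum(a)
  n_b <- sum(b)
  n_ab <- sum(a == 1L & b == 1L)
  num <- as.numeric(n) * n_ab - as.numeric(n_a) * n_b
  d <- num / (as.numeric(n) * n)
  r2 <- min(1, num^2 / ((as.numeric(n_a) * (n - n_a)) *
                          (as.numeric(n_b) * (n - n_b))))
  d_max <- if (d > 0) {
    min(p_a * (1 - p_b), (1 - p_a) * p_b)
  } else if (d < 0) {
    min(p_a * p_b, (1 - p_a) * (1 - p_b))
  } else {
    NA_real_
  }
  d_prime <- if (d == 0) 0 else min(1, abs(d) / d_max)
  tibble(site_a = site_a, site_b = site_b, p_a = p_a, p_b = p_b,
         d = d, d_prime = d_prime, r2 = r2)
}

# vectorised r2 of one target column against many candidate columns, same
# integer-count arithmetic as pairwise_r2; monomorphic candidates return NA
r2_against <- function(panel, target_site, candidate_sites) {
  a <- panel$alleles[, target_site]
  n <- length(a)
  n_a <- sum(a)
  m <- panel$alleles[, candidate_sites, drop = FALSE]
  n_b <- colSums(m)
  n_ab <- colSums(m * a)
  num <- as.numeric(n) * n_ab - as.numeric(n_a) * n_b
  denom <- (as.numeric(n_a) * (n - n_a)) * (as.numeric(n_b) * (n - n_b))
  out <- pmin(1, num^2 / denom)
  out[denom == 0] <- NA_real_
  unname(out)
}

#' Find tag SNPs for a target variant
#'
#' Scans a candidate set (typically the manifest sites present in the
#' haplotype panel) for proxies of the target: candidates on the same
#' chromosome within `window_kb` of the target whose pairwise r-squared with
#' it is at least `r2_min`. Candidates monomorphic in the panel are excluded
#' (their LD is undefined). Tags are ordered by r-squared descending, then
#' position ascending, so output is deterministic.
#'
#' An empty tag set is a valid result ("no tags found"); a target position
#' absent from the panel raises a `admecov_target_unassayed` error, and a
#' monomorphic target an `admecov_monomorphic` error — neither is silently 0.
#'
#' @param panel A [hap_panel()] containing the target site.
#' @param target_pos Target position: a `"chrom:pos"` string or a one-row
#'   data frame / list with `chrom` and `pos`.
#' @param candidate_sites Integer site indices to scan.
#' @param config An [ld_config()].
#' @return An object of class `tag_set`: list with `target` (one-row tibble),
#'   `tags` (tibble `site`, `id`, `chrom`, `pos`, `r2`, `distance_bp`),
#'   `r2_min`, `window_kb`.
#' @export
find_tags <- function(panel, target_pos, candidate_sites,
                      config = ld_config()) {
  tp <- normalize_target(target_pos)
  idx <- match_site(panel, tp$chrom, tp$pos)
  if (is.na(idx)) {
    abort(sprintf("target %s not assayed in haplotype panel",
                  format_chrpos(tp$chrom, tp$pos)),
          class = "admecov_target_unassayed")
  }
  p_t <- allele_frequency(panel, idx)
  if (p_t %in% c(0, 1)) {
    abort(sprintf("LD undefined: target %s monomorphic in panel",
                  format_chrpos(tp$chrom, tp$pos)),
          class = "admecov_monomorphic")
  }
  candidate_sites <- unique(as.integer(candidate_sites))
  if (length(candidate_sites) > 0) check_site_index(panel, candidate_sites)
  cand <- panel$sites[candidate_sites, , drop = FALSE]
  in_window <- cand$chrom == tp$chrom &
    abs(cand$pos - tp$pos) <= config$window_kb * 1000
  candidate_sites <- candidate_sites[in_window]
  tags <- tibble(site = integer(), id = character(), chrom = character(),
                 pos = numeric(), r2 = numeric(), distance_bp = numeric())
  if (length(candidate_sites) > 0) {
    r2 <- r2_against(panel, idx, candidate_sites)
    keep <- !is.na(r2) & r2 >= config$r2_min
    if (any(keep)) {
      sites_kept <- candidate_sites[keep]
      tags <- tibble(
        site = sites_kept,
        id = panel$sites$id[sites_kept],
        chrom = panel$sites$chrom[sites_kept],
        pos = panel$sites$pos[sites_kept],
        r2 = r2[keep],
        distance_bp = abs(panel$sites$pos[sites_kept] - tp$pos)
      )
      tags <- tags[order(-tags$r2, tags$pos), ]
    }
  }
  structure(
    list(
      target = tibble(site = idx, chrom = tp$chrom, pos = tp$pos,
                      id = panel$sites$id[idx]),
      tags = tags,
      r2_min = config$r2_min,
      window_kb = config$window_kb
    ),
    class = "tag_set"
  )
}

#' @export
print.tag_set <- function(x, ...) {
  cat(sprintf("<tag_set> target %s: %d tag(s) at r2 >= %g within %g kb\n",
              format_chrpos(x$target$chrom, x$target$pos),
              nrow(x$tags), x$r2_min, x$window_kb))
  if (nrow(x$tags) > 0) print(x$tags)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.tag_set <- function(x, ...) x$tags

normalize_target <- function(target_pos) {
  if (is.character(target_pos) && length(target_pos) == 1L) {
    return(parse_chrpos(target_pos))
  }
  if (is.list(target_pos) && all(c("chrom", "pos") %in% names(target_pos))) {
    return(tibble(chrom = normalize_chrom(target_pos$chrom[[1L]]),
                  pos = as.numeric(target_pos$pos[[1L]])))
  }
  abort("target_pos must be 'chrom:pos' or have fields chrom and pos",
        class = "admecov_invalid")
}

#' Per-variant LD tag coverage of a panel by a platform manifest
#'
#' A panel variant is flagged covered if it is directly on the manifest
#' (matching by chromosome and position), or if [find_tags()] over the
#' manifest sites present in the haplotype panel(s) returns a non-empty tag
#' set. Population panels are aggregated according to `config$pop_mode`:
#' `pooled` merges them into one panel first; `per_population_any` covers a
#' variant tagged in at least one population; `per_population_all` requires a
#' tag in every population.
#'
#' A variant absent from every haplotype panel cannot be assessed for LD:
#' its `covered` flag is `NA` and its status `"unassessable"` (distinct from
#' uncovered), with a warning. A variant monomorphic in the panel has
#' undefined LD; coverage falls back to direct presence only, with a warning.
#'
#' @param panel Variant panel (tibble with `gene`, `rsid`, `chrom`, `pos`).
#' @param manifest Platform manifest ([as_platform_manifest()]).
#' @param haplotypes A [hap_panel()] or (optionally named) list of them, one
#'   per population.
#' @param config An [ld_config()].
#' @return Tibble with one row per panel variant: `gene`, `rsid`, `chrom`,
#'   `pos`, `direct`, `covered` (logical; `NA` = unassessable), `status`
#'   (`"direct"`, `"tagged"`, `"uncovered"`, `"monomorphic"`,
#'   `"unassessable"`), `best_tag_id`, `best_tag_pos`, `best_r2`,
#'   `distance_bp`.
#' @export
ld_tag_coverage <- function(panel, manifest, haplotypes,
                            config = ld_config()) {
  panel <- as_variant_panel(panel)
  manifest <- as_platform_manifest(manifest)
  if (inherits(haplotypes, "hap_panel")) haplotypes <- list(haplotypes)
  stopifnot(length(haplotypes) >= 1)
  pops <- if (config$pop_mode == "pooled") {
    list(merge_hap_panels(haplotypes))
  } else {
    haplotypes
  }

  rows <- lapply(seq_len(nrow(panel)), function(i) {
    v <- panel[i, ]
    direct <- pos_key(v$chrom, v$pos) %in% pos_key(manifest$chrom, manifest$pos)
    best <- tibble(best_tag_id = NA_character_, best_tag_pos = NA_real_,
                   best_r2 = NA_real_, distance_bp = NA_real_)
    if (direct) {
      return(cbind(v, tibble(direct = TRUE, covered = TRUE,
                             status = "direct"), best))
    }
    per_pop <- lapply(pops, function(hp) variant_tag_status(v, manifest, hp, config))
    status <- vapply(per_pop, `[[`, "", "status")
    if (all(status == "absent")) {
      warn(sprintf("variant %s absent from all haplotype panels: unassessable",
                   v$rsid),
           class = "admecov_unassessable_warning")
      return(cbind(v, tibble(direct = FALSE, covered = NA,
                             status = "unassessable"), best))
    }
    if (all(status %in% c("absent", "monomorphic"))) {
      warn(sprintf("variant %s monomorphic in haplotype panel(s): LD undefined, using direct presence only",
                   v$rsid),
           class = "admecov_monomorphic_warning")
      return(cbind(v, tibble(direct = FALSE, covered = FALSE,
                             status = "monomorphic"), best))
    }
    assessed <- per_pop[status == "tagged" | status == "untagged"]
    tagged <- vapply(assessed, function(x) x$status == "tagged", TRUE)
    covered <- switch(config$pop_mode,
      pooled = any(tagged),
      per_population_any = any(tagged),
      per_population_all = all(tagged) &&
        all(status %in% c("tagged", "untagged"))
    )
    if (covered) {
      bests <- bind_rows(lapply(assessed[tagged], function(x) x$best))
      bests <- bests[order(-bests$best_r2, bests$best_tag_pos), ]
      best <- bests[1L, ]
    }
    cbind(v, tibble(direct = FALSE, covered = covered,
                    status = if (covered) "tagged" else "uncovered"), best)
  })
  as_tibble(bind_rows(rows))
}

# status of one non-direct variant in one haplotype panel:
# "absent", "monomorphic", "tagged" (with best tag), or "untagged"
variant_tag_status <- function(v, manifest, hp, config) {
  idx <- match_site(hp, v$chrom, v$pos)
  if (is.na(idx)) return(list(status = "absent"))
  if (allele_frequency(hp, idx) %in% c(0, 1)) {
    return(list(status = "monomorphic"))
  }
  cand <- which(pos_key(hp$sites$chrom, hp$sites$pos) %in%
                  pos_key(manifest$chrom, manifest$pos))
  cand <- setdiff(cand, idx)
  if (length(cand) == 0) return(list(status = "untagged"))
  ts <- find_tags(hp, v, cand, config)
  if (nrow(ts$tags) == 0) return(list(status = "untagged"))
  list(status = "tagged",
       best = tibble(best_tag_id = ts$tags$id[1L],
                     best_tag_pos = ts$tags$pos[1L],
                     best_r2 = ts$tags$r2[1L],
                     distance_bp = ts$tags$distance_bp[1L]))
}
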