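# Synthetic-data generator: phased haplotype panels with controlled block-LD
# structure, manifests with known ground-truth coverage, and probe tilings
# hitting requested base-coverage fractions.
#
# LD is induced by a copy-with-flip block model, not a coalescent simulator:
# every site in a block is an independently flipped copy of a latent founder
# column, which gives exact ground truth for tag discovery (all within-block
# pairs share r = 1 when the flip rate is zero) while keeping cross-block
# sites independent. All randomness flows from a single seed through
# withr::with_seed; no global RNG state is left behind.

#' Simulation configuration for haplotype panels
#'
#' @param n_samples Number of diploid samples (haplotypes = `2 * n_samples`).
#' @param n_sites Number of biallelic sites (>= 2).
#' @param block_sizes Positive integers summing to `n_sites`; each block is
#'   an LD unit sharing one founder.
#' @param within_block_r Target pairwise Pearson correlation between sites of
#'   a block, in `[0, 1]` (1 = exact copies, 0 = independent).
#' @param maf_range Founder minor-allele-frequency range, a sub-interval of
#'   `(0, 0.5]`.
#' @param site_spacing_bp Distance between consecutive sites in bases.
#' @param chrom Chromosome label for all sites.
#' @param start_pos 1-based position of the first site.
#' @param seed Integer seed; identical configs give bit-identical panels.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples, n_sites, block_sizes = rep(1L, n_sites),
                       within_block_r = 1, maf_range = c(0.1, 0.5),
                       site_spacing_bp = 1000, chrom = "1",
                       start_pos = 1e6, seed = 1L) {
  stopifnot(n_samples >= 1, n_sites >= 2,
            all(block_sizes >= 1), sum(block_sizes) == n_sites,
            within_block_r >= 0, within_block_r <= 1,
            length(maf_range) == 2, maf_range[1] > 0,
            maf_range[2] <= 0.5, maf_range[1] <= maf_range[2],
            site_spacing_bp >= 1)
  structure(
    list(n_samples = as.integer(n_samples), n_sites = as.integer(n_sites),
         block_sizes = as.integer(block_sizes),
         within_block_r = within_block_r, maf_range = maf_range,
         site_spacing_bp = site_spacing_bp, chrom = as.character(chrom),
         start_pos = start_pos, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Flip rate giving a target correlation r between two symmetric-flip copies
# of a Bernoulli(p) founder. With flip rate e and a = 1 - 2e, each copy has
# mean m = e + p*a and the pair has Cov = p(1-p)a^2, hence
#   corr(e) = p(1-p) a^2 / (m (1 - m)),
# which decreases from 1 at e = 0 to 0 at e = 1/2; solved by uniroot.
flip_rate_for_r <- function(r, p) {
  stopifnot(r >= 0, r <= 1, p > 0, p < 1)
  if (r >= 1) return(0)
  corr_at <- function(e) {
    a <- 1 - 2 * e
    m <- e + p * a
    p * (1 - p) * a^2 / (m * (1 - m))
  }
  if (r <= 0) return(0.5)
  uniroot(function(e) corr_at(e) - r, c(1e-9, 0.5 - 1e-9),
          tol = 1e-10)$root
}

#' Simulate a phased haplotype panel with block LD structure
#'
#' Within each block, every site is a copy of a latent founder column with
#' per-haplotype allele flips at the rate implied by `within_block_r`
#' (see the package vignette for the calibration); across blocks, founders
#' are drawn independently with MAF uniform on `maf_range`. Positions are
#' `start_pos + (0:(n_sites-1)) * site_spacing_bp`. Founders are redrawn
#' (bounded retries) if monomorphic in the sample, so blocks are usable for
#' LD at small n.
#'
#' @param config A [sim_config()].
#' @return List with `haplotypes` (a [hap_panel()]) and `truth` (list with
#'   `block_assignment`, a tibble `site`, `block`, and `founder_maf` per
#'   block).
#' @examples
#' sim <- simulate_haplotypes(sim_config(n_samples = 50, n_sites = 4,
#'                                       block_sizes = c(2, 2)))
#' sim$haplotypes
#' @export
simulate_haplotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_hap <- 2L * config$n_samples
  withr::with_seed(config$seed, {
    eps <- NA_real_
    block_of <- rep(seq_along(config$block_sizes), config$block_sizes)
    founder_maf <- numeric(length(config$block_sizes))
    alleles <- matrix(0L, nrow = n_hap, ncol = config$n_sites)
    for (b in seq_along(config$block_sizes)) {
      p <- runif(1, config$maf_range[1], config$maf_range[2])
      founder <- rbinom(n_hap, 1L, p)
      tries <- 0L
      while (length(unique(founder)) == 1L && tries < 100L) {
        founder <- rbinom(n_hap, 1L, p)
        tries <- tries + 1L
      }
      if (length(unique(founder)) == 1L) {
        abort("could not draw a polymorphic founder; increase n_samples or MAF",
              class = "admecov_sim_error")
      }
      founder_maf[b] <- p
      eps <- flip_rate_for_r(config$within_block_r, p)
      for (j in which(block_of == b)) {
        if (eps == 0) {
          alleles[, j] <- founder
        } else {
          flip <- rbinom(n_hap, 1L, eps)
          alleles[, j] <- as.integer(xor(founder, flip))
        }
      }
    }
    sites <- tibble(
      chrom = config$chrom,
      pos = config$start_pos +
        (seq_len(config$n_sites) - 1L) * config$site_spacing_bp,
      id = sprintf("rs9%07d", seq_len(config$n_sites))
    )
    list(
      haplotypes = hap_panel(alleles, sites),
      truth = list(
        block_assignment = tibble(site = seq_len(config$n_sites),
                                  block = block_of),
        founder_maf = founder_maf
      )
    )
  })
}

#' Simulate a platform manifest with designed coverage ground truth
#'
#' Places panel variants on a manifest according to a truth specification
#' `c(n_direct, n_taggable, n_untagged)`: `n_direct` variants appear on the
#' manifest at their own positions; for `n_taggable` variants a proxy site
#' within `config$window_kb` with realised r-squared `>= config$r2_min` is
#' put on the manifest instead; `n_untagged` variants get neither (and the
#' construction verifies that no manifest site accidentally tags them). Any
#' panel variants beyond the three counts are treated as designed-untagged.
#' Role assignment is a seeded draw, so the design is reproducible.
#'
#' All panel positions must be sites of `haplotypes`. If no qualifying proxy
#' exists for a taggable variant, or a designed-untagged variant turns out
#' tagged, the design is infeasible and an error is raised.
#'
#' @param panel Variant panel tibble; positions must exist in `haplotypes`.
#' @param haplotypes A [hap_panel()], typically from [simulate_haplotypes()].
#' @param truth_spec Integer triple `c(n_direct, n_taggable, n_untagged)`
#'   with sum at most `nrow(panel)`.
#' @param seed Integer seed for the role assignment.
#' @param config [ld_config()] defining the window and threshold the design
#'   must satisfy.
#' @return List with `manifest` (platform manifest tibble) and `truth`
#'   (list of rsID vectors `designed_direct`, `designed_taggable`,
#'   `designed_untagged`, and tibble `proxy_map`).
#' @export
simulate_manifest <- function(panel, haplotypes, truth_spec, seed = 1L,
                              config = ld_config()) {
  panel <- as_variant_panel(panel)
  stopifnot(length(truth_spec) == 3, all(truth_spec >= 0),
            sum(truth_spec) <= nrow(panel))
  v_idx <- vapply(seq_len(nrow(panel)), function(i) {
    match_site(haplotypes, panel$chrom[i], panel$pos[i])
  }, 0L)
  if (any(is.na(v_idx))) {
    abort(paste0("panel variants absent from haplotype panel: ",
                 paste(panel$rsid[is.na(v_idx)], collapse = ", ")),
          class = "admecov_invalid")
  }
  n <- nrow(panel)
  roles <- withr::with_seed(seed, {
    r <- rep("untagged", n)
    shuffled <- sample.int(n)
    r[shuffled[seq_len(truth_spec[1])]] <- "direct"
    if (truth_spec[2] > 0) {
      r[shuffled[truth_spec[1] + seq_len(truth_spec[2])]] <- "taggable"
    }
    r
  })
  panel_keys <- pos_key(panel$chrom, panel$pos)
  site_keys <- pos_key(haplotypes$sites$chrom, haplotypes$sites$pos)

  manifest_sites <- integer(0)
  proxy_map <- tibble(rsid = character(), proxy_id = character(),
                      proxy_pos = numeric(), r2 = numeric())
  for (i in which(roles == "direct")) {
    manifest_sites <- c(manifest_sites, v_idx[i])
  }
  for (i in which(roles == "taggable")) {
    cand <- which(
      haplotypes$sites$chrom == panel$chrom[i] &
        abs(haplotypes$sites$pos - panel$pos[i]) <= config$window_kb * 1000 &
        !(site_keys %in% panel_keys)
    )
    cand <- setdiff(cand, manifest_sites)
    if (length(cand) == 0) {
      abort(sprintf("no in-window proxy site available for %s", panel$rsid[i]),
            class = "admecov_sim_error")
    }
    r2 <- r2_against(haplotypes, v_idx[i], cand)
    ok <- which(!is.na(r2) & r2 >= config$r2_min)
    if (length(ok) == 0) {
      abort(sprintf(
        "infeasible spec: no proxy with r2 >= %g for %s (max realised %.3f)",
        config$r2_min, panel$rsid[i], max(r2, na.rm = TRUE)),
        class = "admecov_sim_error")
    }
    pick <- ok[order(-r2[ok], haplotypes$sites$pos[cand[ok]])][1L]
    manifest_sites <- c(manifest_sites, cand[pick])
    proxy_map <- bind_rows(proxy_map, tibble(
      rsid = panel$rsid[i],
      proxy_id = haplotypes$sites$id[cand[pick]],
      proxy_pos = haplotypes$sites$pos[cand[pick]],
      r2 = r2[pick]
    ))
  }
  manifest <- as_platform_manifest(
    tibble(chrom = haplotypes$sites$chrom[manifest_sites],
           pos = haplotypes$sites$pos[manifest_sites],
           rsid = haplotypes$sites$id[manifest_sites]),
    name = "simulated"
  )
  # verify designed-untagged variants really have no qualifying manifest tag
  for (i in which(roles == "untagged")) {
    p_v <- allele_frequency(haplotypes, v_idx[i])
    if (p_v %in% c(0, 1)) next
    ts <- find_tags(haplotypes, panel[i, ],
                    setdiff(manifest_sites, v_idx[i]), config)
    if (nrow(ts$tags) > 0) {
      abort(sprintf(
        "infeasible spec: designed-untagged %s is tagged at r2 = %.3f; use more samples or smaller blocks",
        panel$rsid[i], ts$tags$r2[1L]),
        class = "admecov_sim_error")
    }
  }
  list(
    manifest = manifest,
    truth = list(
      designed_direct = panel$rsid[roles == "direct"],
      designed_taggable = panel$rsid[roles == "taggable"],
      designed_untagged = panel$rsid[roles == "untagged"],
      proxy_map = proxy_map
    )
  )
}

#' Simulate probe tilings hitting requested base-coverage fractions
#'
#' For each target region emits one probe interval whose length is the
#' requested fraction of the region length rounded to the nearest base
#' (so realised coverage is within one base of the request), placed at a
#' seeded random offset inside the region. A fraction of 0 emits no probe.
#'
#' @param regions Target regions tibble (see [target_regions()]).
#' @param target_fractions Numeric vector in `[0, 1]`, one per region.
#' @param seed Integer seed for probe placement.
#' @return A probe design tibble.
#' @export
simulate_probes <- function(regions, target_fractions, seed = 1L) {
  regions <- as_target_regions(regions)
  stopifnot(length(target_fractions) == nrow(regions),
            all(target_fractions >= 0), all(target_fractions <= 1))
  withr::with_seed(seed, {
    rows <- lapply(seq_len(nrow(regions)), function(i) {
      len <- regions$end[i] - regions$start[i]
      covered <- round(target_fractions[i] * len)
      if (covered == 0) return(NULL)
      offset <- if (covered < len) sample.int(len - covered + 1L, 1L) - 1L else 0L
      tibble(chrom = regions$chrom[i],
             start = regions$start[i] + offset,
             end = regions$start[i] + offset + covered)
    })
    as_probe_design(bind_rows(rows))
  })
}

#' Simulate a complete coverage study with known ground truth
#'
#' End-to-end convenience wrapper: builds a synthetic variant panel shaped
#' like the ADME core list (gene block sizes 5/4/20/5 by default), a phased
#' haplotype panel in which each variant owns a two-site LD block (the
#' variant plus one candidate proxy), and a manifest realising a
#' `c(n_direct, n_taggable, n_untagged)` design. Running
#' [physical_coverage()] and [ld_adjusted_coverage()] on the output recovers
#' the designed counts (exactly, when `within_block_r = 1`).
#'
#' @param truth_spec Integer triple `c(n_direct, n_taggable, n_untagged)`
#'   summing to the panel size.
#' @param genes Named integer vector of variants per gene; the default
#'   mirrors the ADME core panel (34 variants).
#' @param n_samples Diploid sample count for the haplotype panel.
#' @param within_block_r Within-block target correlation (see
#'   [sim_config()]).
#' @param maf_range Founder MAF range.
#' @param site_spacing_bp Spacing between consecutive simulated sites.
#' @param seed Integer seed driving panel, haplotypes and manifest.
#' @param config [ld_config()] for the manifest design.
#' @return List with `panel`, `haplotypes`, `manifest`, `truth` (from
#'   [simulate_manifest()]), and `sim_truth` (from [simulate_haplotypes()]).
#' @examples
#' study <- simulate_coverage_study(c(3, 2, 1), genes = c(GENE1 = 6),
#'                                  n_samples = 100, seed = 7)
#' glance(physical_coverage(study$panel, study$manifest))
#' @export
simulate_coverage_study <- function(truth_spec,
                                    genes = c(CYP3A5 = 5L, CYP3A4 = 4L,
                                              CYP2D6 = 20L, CYP2C8 = 5L),
                                    n_samples = 250, within_block_r = 1,
                                    maf_range = c(0.1, 0.5),
                                    site_spacing_bp = 1000,
                                    seed = 1L, config = ld_config()) {
  n_var <- sum(genes)
  stopifnot(length(truth_spec) == 3, sum(truth_spec) <= n_var)
  cfg <- sim_config(
    n_samples = n_samples, n_sites = 2L * n_var,
    block_sizes = rep(2L, n_var), within_block_r = within_block_r,
    maf_range = maf_range, site_spacing_bp = site_spacing_bp,
    seed = seed
  )
  sim <- simulate_haplotypes(cfg)
  hp <- sim$haplotypes
  variant_sites <- seq(1L, 2L * n_var, by = 2L) # first site of each block
  panel <- tibble(
    gene = rep(names(genes), genes),
    rsid = sprintf("rs8%07d", seq_len(n_var)),
    chrom = hp$sites$chrom[variant_sites],
    pos = hp$sites$pos[variant_sites]
  )
  man <- simulate_manifest(panel, hp, truth_spec, seed = seed + 1L,
                           config = config)
  c(list(panel = panel, haplotypes = hp, sim_truth = sim$truth), man)
}
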