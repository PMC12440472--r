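# Shared helpers: tiny in-code fixtures and independent LD oracles.

fixture_matrix_path <- function() {
  system.file("extdata", "platform_coverage_matrix.tsv", package = "admecov")
}

# independent r2 oracle: enumerate the four haplotype classes and use the
# determinant form r2 = (n_AB n_ab - n_Ab n_aB)^2 / (n_A n_a n_B n_b)
# (the implementation works from allele/haplotype frequencies instead);
# integer class counts keep the oracle exact at threshold boundaries
oracle_r2 <- function(a, b) {
  n_AB <- sum(a == 1 & b == 1)
  n_Ab <- sum(a == 1 & b == 0)
  n_aB <- sum(a == 0 & b == 1)
  n_ab <- sum(a == 0 & b == 0)
  n_A <- n_AB + n_Ab; n_a <- n_aB + n_ab
  n_B <- n_AB + n_aB; n_b <- n_Ab + n_ab
  denom <- (as.numeric(n_A) * n_a) * (as.numeric(n_B) * n_b)
  if (denom == 0) return(NA_real_)
  min(1, (as.numeric(n_AB) * n_ab - as.numeric(n_Ab) * n_aB)^2 / denom)
}

# independent tag scan: all-pairs oracle_r2 over candidates, window and
# threshold applied directly, ordered r2 desc then position asc
oracle_find_tags <- function(hp, target_site, candidate_sites, config) {
  t_pos <- hp$sites$pos[target_site]
  t_chrom <- hp$sites$chrom[target_site]
  hits <- data.frame(site = integer(), r2 = numeric(), pos = numeric())
  for (s in candidate_sites) {
    if (hp$sites$chrom[s] != t_chrom) next
    if (abs(hp$sites$pos[s] - t_pos) > config$window_kb * 1000) next
    p <- mean(hp$alleles[, s])
    if (p == 0 || p == 1) next
    r2 <- oracle_r2(hp$alleles[, target_site], hp$alleles[, s])
    if (!is.na(r2) && r2 >= config$r2_min) {
      hits <- rbind(hits,
                    data.frame(site = s, r2 = r2, pos = hp$sites$pos[s]))
    }
  }
  hits[order(-hits$r2, hits$pos), , drop = FALSE]
}

# random small haplotype panel with a polymorphic first site (the target)
random_small_panel <- function(n_hap, n_site, chrom = "1", spacing = 1000) {
  al <- matrix(stats::rbinom(n_hap * n_site, 1L, stats::runif(1, 0.2, 0.8)),
               nrow = n_hap)
  while (length(unique(al[, 1])) == 1L) {
    al[, 1] <- stats::rbinom(n_hap, 1L, 0.5)
  }
  hap_panel(al, tibble::tibble(chrom = chrom,
                               pos = 1e6 + (seq_len(n_site) - 1) * spacing,
                               id = paste0("rs", seq_len(n_site))))
}

# two-block panel in perfect within-block LD: sites 1-2 copy block A,
# sites 3-4 copy block B (independent draws)
two_block_panel <- function(n_hap = 40, seed = 11) {
  withr::with_seed(seed, {
    a <- stats::rbinom(n_hap, 1L, 0.5)
    b <- stats::rbinom(n_hap, 1L, 0.5)
    while (length(unique(a)) == 1L) a <- stats::rbinom(n_hap, 1L, 0.5)
    while (length(unique(b)) == 1L || oracle_r2(a, b) >= 0.5) {
      b <- stats::rbinom(n_hap, 1L, 0.5)
    }
    hap_panel(cbind(a, a, b, b),
              tibble::tibble(chrom = "1", pos = c(1000, 2000, 3000, 4000),
                             id = paste0("rs", 1:4)))
  })
}

write_tmp_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# minimal phased VCF text fixture
tmp_vcf <- function(records, samples = c("S1", "S2")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(c(header, records), path)
  path
}
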