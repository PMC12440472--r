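test_that("allele frequency is the share of alternate alleles", {
  hp <- hap_panel(cbind(c(0, 0, 1, 1), c(1, 1, 1, 1)),
                  tibble::tibble(chrom = "1", pos = c(1, 2)))
  expect_equal(allele_frequency(hp, 1), 0.5)
  expect_equal(allele_frequency(hp, 2), 1.0)
  hp8 <- hap_panel(matrix(c(1, 1, 1, 0, 0, 0, 0, 0), ncol = 1),
                   tibble::tibble(chrom = "1", pos = 1))
  expect_equal(allele_frequency(hp8, 1), 0.375)
  expect_error(allele_frequency(hp, 3), class = "admecov_invalid")
})

test_that("pairwise r2 matches direct haplotype-class counting", {
  # 8 haplotypes: AB x3, ab x3, Ab x1, aB x1 -> p_AB=3/8, p_A=p_B=1/2,
  # D = 1/8, r2 = (1/64)/(1/16) = 0.25
  hp <- hap_panel(
    cbind(c(1, 1, 1, 0, 0, 0, 1, 0), c(1, 1, 1, 0, 0, 0, 0, 1)),
    tibble::tibble(chrom = "1", pos = c(100, 200))
  )
  res <- pairwise_r2(hp, 1, 2)
  expect_equal(res$r2, 0.25)
  expect_equal(res$d, 1 / 8)
  expect_equal(res$p_a, 0.5)
  # D' = |D| / Dmax, Dmax = min(pA(1-pB), (1-pA)pB) = 1/4
  expect_equal(res$d_prime, 0.5)
})

test_that("r2 is 1 for identical and complemented copies of a site", {
  a <- c(0, 1, 1, 0, 1, 0)
  hp <- hap_panel(cbind(a, a, 1 - a),
                  tibble::tibble(chrom = "1", pos = c(1, 2, 3)))
  expect_equal(pairwise_r2(hp, 1, 2)$r2, 1)
  expect_equal(pairwise_r2(hp, 1, 2)$d_prime, 1)
  expect_equal(pairwise_r2(hp, 1, 3)$r2, 1)
})

test_that("r2 is symmetric, relabeling-invariant, in [0,1], and matches cor^2", {
  withr::with_seed(42, {
    for (i in 1:25) {
      hp <- random_small_panel(n_hap = 2 * sample(3:6, 1), n_site = 2)
      a <- hp$alleles[, 1]; b <- hp$alleles[, 2]
      if (length(unique(b)) == 1L) next
      r_ab <- pairwise_r2(hp, 1, 2)
      r_ba <- pairwise_r2(hp, 2, 1)
      expect_identical(r_ab$r2, r_ba$r2)
      expect_gte(r_ab$r2, 0); expect_lte(r_ab$r2, 1)
      expect_gte(r_ab$d_prime, 0); expect_lte(r_ab$d_prime, 1)
      expect_equal(r_ab$r2, oracle_r2(a, b))
      # r2 equals the squared Pearson correlation of the 0/1 columns
      expect_equal(r_ab$r2, suppressWarnings(stats::cor(a, b))^2,
                   tolerance = 1e-12)
      # flip allele coding at either site
      flip <- hap_panel(cbind(1 - a, b),
                        tibble::tibble(chrom = "1", pos = c(1, 2)))
      expect_equal(pairwise_r2(flip, 1, 2)$r2, r_ab$r2)
    }
  })
})

test_that("monomorphic sites raise an undefined-LD error, never a silent zero", {
  hp <- hap_panel(cbind(c(0, 1, 0, 1), c(1, 1, 1, 1)),
                  tibble::tibble(chrom = "1", pos = c(1, 2)))
  expect_error(pairwise_r2(hp, 1, 2), "monomorphic",
               class = "admecov_monomorphic")
})

test_that("independent sites have r2 near zero at large n", {
  mean_r2 <- withr::with_seed(7, {
    vals <- replicate(20, {
      a <- stats::rbinom(2000, 1, 0.4)
      b <- stats::rbinom(2000, 1, 0.4)
      hp <- hap_panel(cbind(a, b), tibble::tibble(chrom = "1", pos = c(1, 2)))
      pairwise_r2(hp, 1, 2)$r2
    })
    mean(vals)
  })
  expect_lt(mean_r2, 0.05)
})

test_that("find_tags honours the window boundary, self-tags, and orders deterministically", {
  cfg <- ld_config(r2_min = 0.8, window_kb = 1)
  a <- c(0, 1, 1, 0, 1, 0, 0, 1)
  # site 2 in perfect LD 1000 bp away (inside +/-1 kb), site 3 identical but
  # 1001 bp away (outside by one base)
  hp <- hap_panel(cbind(a, a, a),
                  tibble::tibble(chrom = "1", pos = c(10000, 11000, 11001),
                                 id = paste0("rs", 1:3)))
  ts <- find_tags(hp, "1:10000", candidate_sites = 2:3, config = cfg)
  expect_equal(ts$tags$site, 2L)

  # the target itself among candidates tags at exactly r2 = 1
  ts_self <- find_tags(hp, "1:10000", candidate_sites = 1:3, config = cfg)
  expect_equal(ts_self$tags$site[1], 1L)
  expect_equal(ts_self$tags$r2[1], 1)
  # tie on r2 broken by ascending position
  expect_equal(ts_self$tags$site, c(1L, 2L))

  expect_error(find_tags(hp, "1:99", 2:3, cfg),
               class = "admecov_target_unassayed")
  mono <- hap_panel(cbind(rep(1, 8), a),
                    tibble::tibble(chrom = "1", pos = c(1, 2)))
  expect_error(find_tags(mono, "1:1", 2, cfg),
               class = "admecov_monomorphic")
})

test_that("find_tags separates LD blocks like an all-pairs oracle scan", {
  hp <- two_block_panel()
  cfg <- ld_config(r2_min = 0.8, window_kb = 250)
  ts <- find_tags(hp, "1:1000", candidate_sites = 2:4, config = cfg)
  expect_equal(sort(ts$tags$site), 2L)
  oracle <- oracle_find_tags(hp, 1, 2:4, cfg)
  expect_equal(ts$tags$site, oracle$site)
  expect_equal(ts$tags$r2, oracle$r2)
})

test_that("tag sets never shrink as r2_min decreases or window_kb increases", {
  withr::with_seed(99, {
    for (i in 1:10) {
      hp <- random_small_panel(n_hap = 10, n_site = 6, spacing = 120000)
      cands <- 2:6
      grid <- expand.grid(r2 = c(0.9, 0.5, 0.2), win = c(150, 300, 600))
      sets <- lapply(seq_len(nrow(grid)), function(k) {
        find_tags(hp, list(chrom = "1", pos = hp$sites$pos[1]), cands,
                  ld_config(grid$r2[k], grid$win[k]))$tags$site
      })
      for (k in seq_len(nrow(grid))) {
        for (k2 in seq_len(nrow(grid))) {
          if (grid$r2[k2] <= grid$r2[k] && grid$win[k2] >= grid$win[k]) {
            expect_true(all(sets[[k]] %in% sets[[k2]]))
          }
        }
      }
    }
  })
})

test_that("ld_tag_coverage flags direct, tagged, uncovered and unassessable variants", {
  hp <- two_block_panel()
  panel <- tibble::tibble(
    gene = "G",
    rsid = c("rs100", "rs200", "rs300"),
    chrom = "1",
    pos = c(1000, 3000, 99999) # in block A, block B, and absent
  )
  # manifest: variant 1 itself, plus site 2 (block A proxy); nothing in block B
  manifest <- tibble::tibble(chrom = "1", pos = c(1000, 2000))
  expect_warning(
    cov <- ld_tag_coverage(panel, manifest, hp),
    class = "admecov_unassessable_warning")
  expect_equal(cov$status, c("direct", "uncovered", "unassessable"))
  expect_equal(cov$covered, c(TRUE, FALSE, NA))

  # proxy for block B put on the manifest -> variant 2 becomes tagged
  manifest2 <- tibble::tibble(chrom = "1", pos = c(1000, 2000, 4000))
  cov2 <- suppressWarnings(ld_tag_coverage(panel[1:2, ], manifest2, hp))
  expect_equal(cov2$status, c("direct", "tagged"))
  expect_equal(cov2$best_r2[2], 1)
  expect_equal(cov2$best_tag_pos[2], 4000)
})

test_that("population modes aggregate per-population tag status as declared", {
  # population A: variant in perfect LD with the proxy; population B: none
  make_pop <- function(linked, seed) {
    withr::with_seed(seed, {
      v <- stats::rbinom(60, 1, 0.5)
      proxy <- if (linked) v else stats::rbinom(60, 1, 0.5)
      while (!linked && oracle_r2(v, proxy) >= 0.5) {
        proxy <- stats::rbinom(60, 1, 0.5)
      }
      hap_panel(cbind(v, proxy),
                tibble::tibble(chrom = "1", pos = c(1000, 2000)))
    })
  }
  pops <- list(A = make_pop(TRUE, 1), B = make_pop(FALSE, 2))
  panel <- tibble::tibble(gene = "G", rsid = "rs100", chrom = "1", pos = 1000)
  manifest <- tibble::tibble(chrom = "1", pos = 2000)

  any_cov <- ld_tag_coverage(panel, manifest, pops,
                             ld_config(pop_mode = "per_population_any"))
  all_cov <- ld_tag_coverage(panel, manifest, pops,
                             ld_config(pop_mode = "per_population_all"))
  expect_true(any_cov$covered)
  expect_false(all_cov$covered)
})

test_that("merging panels pools haplotypes over shared sites", {
  a <- hap_panel(cbind(c(0, 1), c(1, 0)),
                 tibble::tibble(chrom = "1", pos = c(10, 20)))
  b <- hap_panel(cbind(c(1, 1), c(0, 0), c(1, 0)),
                 tibble::tibble(chrom = "1", pos = c(10, 20, 30)))
  expect_warning(m <- merge_hap_panels(list(a, b)),
                 class = "admecov_merge_warning")
  expect_equal(n_haplotypes(m), 4)
  expect_equal(m$sites$pos, c(10, 20))
  expect_equal(m$alleles[, 1], c(0L, 1L, 1L, 1L))
})
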