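test_that("physical coverage counts exact (chrom,pos) matches", {
  panel <- adme_panel()
  mat <- read_coverage_matrix(fixture_matrix_path(), panel)
  # manifest holding exactly the 18 published Axiom-direct positions
  axiom_direct <- panel[mat$cells[, "Axiom"], c("chrom", "pos")]
  res <- physical_coverage(panel, as_platform_manifest(axiom_direct, "Axiom"))
  expect_equal(res$covered_n, 18)
  expect_equal(glance(res)$percent, 52.94)

  full <- physical_coverage(panel, as_platform_manifest(
    panel[, c("chrom", "pos")], "all"))
  expect_equal(glance(full)$percent, 100)

  none <- physical_coverage(panel, as_platform_manifest(
    tibble::tibble(chrom = character(), pos = numeric()), "empty"))
  expect_equal(none$covered_n, 0)
  expect_equal(glance(none)$percent, 0)
})

test_that("rsID fallback matching is opt-in", {
  panel <- adme_panel()
  manifest <- tibble::tibble(chrom = "1", pos = 1, rsid = "rs776746")
  expect_equal(physical_coverage(panel, manifest)$covered_n, 0)
  expect_equal(
    physical_coverage(panel, manifest, rsid_fallback = TRUE)$covered_n, 1)
})

test_that("coverage percent is invariant under panel reordering", {
  panel <- adme_panel()
  manifest <- as_platform_manifest(panel[c(3, 9, 20), c("chrom", "pos")], "m")
  shuffled <- panel[withr::with_seed(3, sample.int(34)), ]
  expect_equal(physical_coverage(panel, manifest)$percent,
               physical_coverage(shuffled, manifest)$percent)
})

test_that("LD-adjusted coverage never falls below physical coverage", {
  for (seed in c(2, 3)) {
    study <- simulate_coverage_study(c(5, 3, 2), genes = c(G1 = 10),
                                     n_samples = 120, seed = seed)
    phys <- physical_coverage(study$panel, study$manifest)
    ld <- ld_adjusted_coverage(study$panel, study$manifest, study$haplotypes)
    expect_gte(ld$percent, phys$percent)
    expect_true(all(ld$per_variant$covered >= phys$per_variant$covered,
                    na.rm = TRUE))
    # direct implies LD-covered (self-tag)
    expect_true(all(ld$per_variant$covered[phys$per_variant$covered]))
  }
})

test_that("LD coverage equals physical when the manifest already holds all variants", {
  study <- simulate_coverage_study(c(6, 0, 0), genes = c(G1 = 6),
                                   n_samples = 80, seed = 4)
  phys <- physical_coverage(study$panel, study$manifest)
  ld <- ld_adjusted_coverage(study$panel, study$manifest, study$haplotypes)
  expect_equal(phys$percent, 100)
  expect_equal(ld$percent, 100)
  expect_equal(ld$per_variant$covered, phys$per_variant$covered)
})

test_that("LD coverage collapses to physical when sites are independent", {
  # no-LD panel: every site its own block
  cfg <- sim_config(n_samples = 400, n_sites = 12,
                    block_sizes = rep(1L, 12), within_block_r = 1,
                    seed = 8)
  hp <- simulate_haplotypes(cfg)$haplotypes
  panel <- tibble::tibble(gene = "G", rsid = sprintf("rs%d", 1:6),
                          chrom = hp$sites$chrom[1:6],
                          pos = hp$sites$pos[1:6])
  manifest <- tibble::tibble(chrom = hp$sites$chrom[c(1, 2, 7, 8)],
                             pos = hp$sites$pos[c(1, 2, 7, 8)])
  phys <- physical_coverage(panel, manifest)
  ld <- ld_adjusted_coverage(panel, manifest, hp)
  expect_equal(ld$per_variant$covered, phys$per_variant$covered)
})

test_that("matrix building, summary and round-trip agree with the results", {
  panel <- adme_panel()
  m1 <- as_platform_manifest(panel[1:8, c("chrom", "pos")], "P1")
  m2 <- as_platform_manifest(panel[5:34, c("chrom", "pos")], "P2")
  r1 <- physical_coverage(panel, m1)
  r2 <- physical_coverage(panel, m2)
  mat <- build_matrix(panel, list(r1, r2))
  expect_equal(dim(mat$cells), c(34, 2))
  summ <- summarize_matrix(mat)
  expect_equal(summ$covered_n, c(r1$covered_n, r2$covered_n))
  expect_equal(summ$percent, c(glance(r1)$percent, glance(r2)$percent))
  expect_equal(colSums(mat$cells), setNames(c(8, 30), mat$columns$label))

  expect_error(build_matrix(panel, list()), class = "admecov_invalid")
  expect_error(build_matrix(panel[1:10, ], list(r1)),
               class = "admecov_alignment_error")
})

test_that("uncovered variants are the all-false rows in panel order", {
  panel <- adme_panel()
  mat <- read_coverage_matrix(fixture_matrix_path(), panel)
  unc <- uncovered_variants(mat)
  expect_equal(unc$rsid, c("rs72549352", "rs72549357"))

  all_true <- physical_coverage(panel, as_platform_manifest(
    panel[, c("chrom", "pos")], "all"))
  expect_equal(nrow(uncovered_variants(build_matrix(panel, list(all_true)))), 0)

  none <- physical_coverage(panel, as_platform_manifest(
    tibble::tibble(chrom = "1", pos = 1), "none"))
  expect_equal(nrow(uncovered_variants(build_matrix(panel, list(none)))), 34)
})

test_that("tidy/glance/autoplot views of matrices and results are consistent", {
  panel <- adme_panel()
  mat <- read_coverage_matrix(fixture_matrix_path(), panel)
  long <- tidy(mat)
  expect_equal(nrow(long), 34 * 10)
  expect_equal(sum(long$covered), sum(mat$cells))
  expect_s3_class(autoplot(mat), "ggplot")
  expect_s3_class(plot_coverage_summary(summarize_matrix(mat)), "ggplot")

  res <- physical_coverage(panel, as_platform_manifest(
    panel[1:8, c("chrom", "pos")], "P"))
  expect_equal(nrow(tidy(res)), 34)
  expect_equal(glance(res)$covered_n, sum(tidy(res)$covered))
})

test_that("a single flipped matrix bit moves a column summary by one variant", {
  panel <- adme_panel()
  mat <- read_coverage_matrix(fixture_matrix_path(), panel)
  flipped <- mat
  flipped$cells["rs776746", "Axiom"] <- FALSE
  s0 <- summarize_matrix(mat)
  s1 <- summarize_matrix(flipped)
  delta <- s0$percent[s0$platform == "Axiom" & s0$mode == "direct"] -
    s1$percent[s1$platform == "Axiom" & s1$mode == "direct"]
  expect_equal(delta, 52.94 - 50)
})
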