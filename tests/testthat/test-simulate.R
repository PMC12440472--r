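test_that("simulated haplotype panels are reproducible and respect the MAF range", {
  cfg <- sim_config(n_samples = 200, n_sites = 10,
                    block_sizes = c(4, 3, 3), within_block_r = 1,
                    maf_range = c(0.2, 0.4), seed = 13)
  sim1 <- simulate_haplotypes(cfg)
  sim2 <- simulate_haplotypes(cfg)
  expect_identical(sim1$haplotypes$alleles, sim2$haplotypes$alleles)
  expect_identical(sim1$truth$block_assignment, sim2$truth$block_assignment)
  expect_equal(sim1$truth$block_assignment$block, rep(1:3, c(4, 3, 3)))

  # realised frequencies near the founder range (binomial noise at 400 haps)
  freq <- allele_frequency(sim1$haplotypes)
  maf <- pmin(freq, 1 - freq)
  expect_true(all(maf > 0.2 - 0.1 & maf < 0.4 + 0.1))
  expect_equal(sim1$haplotypes$sites$pos, 1e6 + (0:9) * 1000)
})

test_that("within_block_r = 1 gives perfect within-block LD, blocks stay independent", {
  cfg <- sim_config(n_samples = 500, n_sites = 6, block_sizes = c(3, 3),
                    within_block_r = 1, seed = 17)
  hp <- simulate_haplotypes(cfg)$haplotypes
  for (pair in list(c(1, 2), c(2, 3), c(4, 6))) {
    expect_equal(pairwise_r2(hp, pair[1], pair[2])$r2, 1)
  }
  # cross-block r2 small, averaged over seeds
  cross <- vapply(1:10, function(s) {
    hp <- simulate_haplotypes(sim_config(n_samples = 500, n_sites = 4,
                                         block_sizes = c(2, 2),
                                         within_block_r = 1,
                                         seed = s))$haplotypes
    pairwise_r2(hp, 1, 3)$r2
  }, 0)
  expect_lt(mean(cross), 0.05)
})

test_that("intermediate within_block_r yields correlations near the target", {
  r2s <- vapply(1:12, function(s) {
    hp <- simulate_haplotypes(sim_config(n_samples = 800, n_sites = 2,
                                         block_sizes = 2,
                                         within_block_r = 0.7,
                                         maf_range = c(0.3, 0.5),
                                         seed = 100 + s))$haplotypes
    pairwise_r2(hp, 1, 2)$r2
  }, 0)
  # target pairwise correlation 0.7 -> expected r2 about 0.49
  expect_equal(mean(r2s), 0.49, tolerance = 0.12)
})

test_that("degenerate simulation configs are rejected", {
  expect_error(sim_config(n_samples = 10, n_sites = 1))
  expect_error(sim_config(n_samples = 10, n_sites = 4, block_sizes = c(2, 1)))
  expect_error(sim_config(n_samples = 10, n_sites = 4,
                          block_sizes = c(2, 2), within_block_r = 1.5))
  expect_error(sim_config(n_samples = 10, n_sites = 4,
                          block_sizes = c(2, 2), maf_range = c(0, 0.5)))
})

test_that("simulated manifests realise the designed direct/taggable/untagged roles", {
  study <- simulate_coverage_study(c(18, 12, 4), n_samples = 250, seed = 23)
  truth <- study$truth
  expect_length(truth$designed_direct, 18)
  expect_length(truth$designed_taggable, 12)
  expect_length(truth$designed_untagged, 4)
  expect_equal(nrow(truth$proxy_map), 12)
  expect_true(all(truth$proxy_map$r2 >= 0.8))

  phys <- physical_coverage(study$panel, study$manifest)
  expect_setequal(study$panel$rsid[phys$per_variant$covered],
                  truth$designed_direct)
  ld <- ld_adjusted_coverage(study$panel, study$manifest, study$haplotypes)
  expect_setequal(study$panel$rsid[ld$per_variant$covered],
                  c(truth$designed_direct, truth$designed_taggable))
  expect_setequal(study$panel$rsid[!ld$per_variant$covered],
                  truth$designed_untagged)
})

test_that("extreme truth specs give all-or-nothing coverage", {
  all_direct <- simulate_coverage_study(c(6, 0, 0), genes = c(G = 6),
                                        n_samples = 60, seed = 31)
  expect_equal(physical_coverage(all_direct$panel, all_direct$manifest)$percent,
               100)
  none <- simulate_coverage_study(c(0, 0, 6), genes = c(G = 6),
                                  n_samples = 60, seed = 32)
  expect_equal(nrow(none$manifest), 0)
  phys <- physical_coverage(none$panel, none$manifest)
  ld <- ld_adjusted_coverage(none$panel, none$manifest, none$haplotypes)
  expect_equal(phys$covered_n, 0)
  expect_equal(ld$covered_n, 0)
})

test_that("infeasible manifest specs fail loudly", {
  cfg <- sim_config(n_samples = 50, n_sites = 2, block_sizes = c(1, 1),
                    within_block_r = 1, seed = 41, site_spacing_bp = 10)
  hp <- simulate_haplotypes(cfg)$haplotypes
  panel <- tibble::tibble(gene = "G", rsid = c("rs1", "rs2"),
                          chrom = hp$sites$chrom, pos = hp$sites$pos)
  # both sites are panel positions: no proxy site exists at all
  expect_error(simulate_manifest(panel, hp, c(0, 1, 1), seed = 1),
               class = "admecov_sim_error")
  # panel variant not present in the haplotype panel
  bad_panel <- tibble::tibble(gene = "G", rsid = "rs9", chrom = "1", pos = 42)
  expect_error(simulate_manifest(bad_panel, hp, c(1, 0, 0)),
               class = "admecov_invalid")
})

test_that("probe simulation hits requested fractions within one base", {
  regions <- tibble::tibble(gene = "G", region_id = sprintf("r%d", 1:5),
                            chrom = "1",
                            start = (0:4) * 1000, end = (0:4) * 1000 + 201)
  fr <- c(1, 0.95, 0.5, 0.05, 0)
  probes <- simulate_probes(regions, fr, seed = 6)
  got <- region_base_coverage(regions, probes)$base_fraction
  expect_true(all(abs(got - fr) <= 1 / 201))
  expect_identical(probes, simulate_probes(regions, fr, seed = 6))
  expect_error(simulate_probes(regions, c(1, 1, 1, 1, 1.2), seed = 1))
})
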