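---
title: "Assessing platform coverage of an ADME variant panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing platform coverage of an ADME variant panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admecov)
```

## The problem

Whether a pharmacogenomic association study can see a drug-response
variant at all is decided upstream of any statistics: the variant must
either sit on the genotyping array's manifest, be in strong linkage
disequilibrium (LD) with a manifest SNP, or — for sequencing studies — lie
inside a region the enrichment design actually captures. `admecov`
quantifies all three for a target panel of pharmacogene variants. The
packaged target list is the 34-variant ADME core panel in CYP2C8, CYP2D6,
CYP3A4 and CYP3A5 (Hg19 coordinates), genes central to the metabolism of
many drugs including the aminoquinolines.

## Coverage statistics

**Physical coverage.** A panel variant is directly covered by a platform
when its exact `(chromosome, position)` is interrogated. The statistic is
the intersection percentage `covered × 100 / panel size`. Matching is by
position; matching by rsID is available as an explicit fallback
(`rsid_fallback = TRUE`) for manifests annotated on a different build, but
is off by default because positions are the primary key of both panel and
manifests.

**LD-adjusted coverage.** An uncovered variant still counts as captured
when some manifest SNP within a window tags it. From phased haplotypes,
with $p_A$, $p_B$ the alternate-allele frequencies at two sites and
$p_{AB}$ the frequency of haplotypes carrying both,

$$D = p_{AB} - p_A p_B, \qquad
r^2 = \frac{D^2}{p_A(1-p_A)\,p_B(1-p_B)},$$

and $D' = |D|/D_{\max}$ with the usual frequency-dependent bound. Because
the input is phased, these are plain haplotype counts — no EM or composite
estimator is involved, and unphased input is rejected rather than phased.
A directly assayed polymorphic variant tags itself at $r^2 = 1$, so
LD-adjusted coverage can never fall below physical coverage; this
implication is asserted by the test suite and holds row-by-row in the
packaged matrix.

**Enrichment coverage.** Per target region, the fraction of bases inside
the *union* of the probe intervals (a base under three overlapping probes
counts once), classified high coverage when the fraction is at least the
threshold — inclusive, matching the "≥ 90%" convention of published
summary tables — and aggregated per gene and overall as the share of
high regions.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `r2_min` | 0.8 | minimum r² for a manifest SNP to count as a tag; the conventional pharmacogenomics cut-off for a usable proxy |
| `window_kb` | 250 | tag-search half-window around the target, in kb; the documented default of the standard tagging tool this engine mirrors |
| `pop_mode` | `"pooled"` | how population panels combine: pool haplotypes, or require a tag in ≥ 1 (`per_population_any`) or all (`per_population_all`) populations |
| `high_threshold` | 0.90 | inclusive base-fraction cut-off for a high-coverage region |
| `flank_bp` | 100 | half-width of the per-variant target regions built by `target_regions()` (region length 2·flank + 1) |

The published analysis this package generalises lists three continental
populations but does not state how they were aggregated; pooling into one
haplotype panel matches a single run of the tagging tool over a merged
fileset and is therefore the default, with both per-population modes
provided. Likewise the published region tables imply one region per panel
variant without giving extents, so regions are caller-supplied, with the
±100 bp per-variant builder as a convenience default.

## The synthetic-data generator

`simulate_haplotypes()` induces LD with a copy-with-flip block model:
each block has a latent founder column drawn Bernoulli with MAF uniform on
`maf_range` (default 0.1–0.5, the common-variant regime where array
tagging operates), and every site in the block is an independent copy of
the founder with per-haplotype flips at rate $\varepsilon$. For two such
copies of a Bernoulli($p$) founder with $a = 1 - 2\varepsilon$ and mean
$m = \varepsilon + pa$,

$$\mathrm{corr} = \frac{p(1-p)\,a^2}{m(1-m)},$$

which decreases monotonically from 1 at $\varepsilon = 0$ to 0 at
$\varepsilon = 1/2$; `within_block_r` is the target correlation and the
flip rate is solved numerically from this expression per founder MAF
(exactness is only guaranteed at $\varepsilon = 0$, i.e.
`within_block_r = 1`, where sites are literal copies and every
within-block pair has $r^2 = 1$). Cross-block sites are independent, so
realised cross-block $r^2$ is $O(1/n_{\mathrm{hap}})$.

`simulate_manifest()` turns a `c(n_direct, n_taggable, n_untagged)` design
into a manifest: direct variants appear at their own positions, taggable
variants get an in-window proxy whose *realised* r² clears the threshold,
and the construction verifies that designed-untagged variants are not
accidentally tagged (at small sample sizes a chance cross-block
correlation would make the design infeasible, which is reported as an error
rather than silently absorbed). `simulate_probes()` tiles each region to a
requested base fraction within one base. All randomness flows from a
single seed via `withr::with_seed`; identical configurations are
bit-identical.

What this emulates — and what it does not: the generator reproduces the
features the coverage machinery is sensitive to (block LD with
controllable r², allele-frequency ranges, manifest composition, probe
union geometry) but not coalescent genealogies, recombination-rate
variation, population divergence, or the paralogous-region artifacts that
complicate real CYP2D6 assays. Green tests on simulated data therefore
validate the computation, not the biology of any particular array.

## Numerical choices

* **r² from integer counts.** `pairwise_r2()` evaluates
  $r^2 = (n\,n_{AB} - n_A n_B)^2 / (n_A(n-n_A)\,n_B(n-n_B))$ on integer
  haplotype counts, a single correctly-rounded division. This makes the
  result bit-identical under swapping the sites and under 0↔1 relabelling,
  and keeps threshold comparisons stable when the true r² is exactly the
  cut-off (e.g. 0.5 on small panels). A one-ulp overshoot at perfect LD is
  clamped to 1.
* **Monomorphic sites.** LD at a monomorphic site is undefined; it is an
  error (`pairwise_r2`, `find_tags`), never a silent 0. In the coverage
  pipeline a monomorphic target falls back to direct presence with a
  warning, and monomorphic candidates are excluded.
* **Unassessable vs uncovered.** A variant absent from every haplotype
  panel gets `covered = NA` and status `"unassessable"`, distinct from an
  assessed-but-uncovered variant; under `per_population_all`, a variant
  absent from some populations is not covered (it cannot be tagged in
  every panel).
* **Tag ordering.** Tags sort by r² descending, then position ascending —
  deterministic output for byte-identical reports.
* **Rounding.** Internally coverage is kept as integer counts; percentages
  round half-up to two decimals only at presentation (`23.53` from
  8/34, `88.24` from 30/34). Half-up is used because bankers' rounding
  would print 8/34 as 23.52. One consequence: 33/34 prints as 97.06,
  where the source tables print 97.05 (a truncation); the package reports
  the rounded value.
* **Coordinates.** Panels and manifests are 1-based (as printed in array
  annotation), intervals are BED 0-based half-open; a variant at 1-based
  position $p$ lies in $[s, e)$ iff $s \le p - 1 < e$. Chromosome labels
  are normalised by stripping a leading `chr`; strand is ignored
  throughout.

## Known limitations

* The packaged matrix is the published one; recomputing it from real
  1000 Genomes haplotypes and vendor manifests requires downloads outside
  the package's scope. The published text names rs72549353 among the
  platform-uncovered variants while the matrix's all-zero rows are
  rs72549352 and rs72549357; the fixture reproduces the matrix verbatim
  and the package reports the count (2), which both agree on.
* Only biallelic SNPs are modelled; multi-allelic LD, star-allele calling
  and CYP2D6 structural variation are out of scope.
* VCF sites with any missing genotype are skipped, not imputed, and
  unphased records are skipped, not phased.

## Problem sizes

The test suite exercises the LD engine against a brute-force oracle on
1000 random panels of ≤ 12 haplotypes × ≤ 6 sites, and the end-to-end
recovery of an 18/12/4 design over a 20-seed suite at 250 diploid samples
per panel — sizes at which designed cross-block independence is
numerically safe (chance cross-block r² ≥ 0.8 is negligible at 500
haplotypes) while the whole suite runs in well under a minute.

## Session pipeline at a glance

```r
panel <- adme_panel()
study <- simulate_coverage_study(c(18, 12, 4), n_samples = 250, seed = 1)
phys  <- physical_coverage(study$panel, study$manifest)
ld    <- ld_adjusted_coverage(study$panel, study$manifest, study$haplotypes)
mat   <- build_matrix(study$panel, list(phys, ld))
summarize_matrix(mat)
uncovered_variants(mat)
regions <- target_regions(panel)
enrichment_coverage(regions, simulate_probes(regions, rep(0.95, 34), seed = 2))
```
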