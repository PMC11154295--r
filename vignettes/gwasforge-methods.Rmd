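---
title: "Simulating GWAS datasets with gwasforge: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating GWAS datasets with gwasforge: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gwasforge simulates complete genome-wide association study (GWAS) datasets —
genotypes, quantitative or binary traits, and per-variant association summary
statistics — in which the causal architecture is known by construction. Its
distinctive feature is that causal variants can be *anchored to named
biological pathways*: a gene-set file plus a nearest-gene annotation of the
simulated variants lets the user demand that k of the K causal variants fall
in genes of a chosen set. Datasets with that property are what benchmarking
of gene-set enrichment tools for GWAS requires: the enriched pathway is known
ground truth. This vignette describes each model in the pipeline, its
assumptions, and the design decisions that were genuinely open.

## 1. Genotypes: haplotype-mosaic resampling

A phased reference panel (VCF with `GT` like `0|1`) is expanded to an
arbitrary sample size by mosaic resampling. Each simulated haplotype starts
as a copy of a uniformly chosen panel haplotype; between consecutive
variants it switches to a fresh uniformly chosen template with probability
`switch_rate` (default 0.002 per variant interval), and the template is
always redrawn at chromosome boundaries. Two independent mosaic haplotypes
are summed into a 0/1/2 dosage per individual.

Properties of this sampler:

* Expected allele frequency at every variant equals the panel frequency.
* Local LD is preserved on the scale of `1/switch_rate` variants (500 at the
  default) and decays monotonically as `switch_rate` grows; at
  `switch_rate = 0` each simulated haplotype is a verbatim panel haplotype.
* The process is seeded and bit-reproducible.

The constant per-interval switch probability is deliberately simpler than a
recombination-map-aware or conditional-coalescent model: the generator is
treated as a black box that produces random permutations of reference
haplotypes, which preserves what downstream stages actually consume (allele
frequencies and local LD) while remaining fully specifiable. The price is
that switch density is uniform in variant index, not in genetic distance, so
simulated recombination hotspots do not exist. A consequence worth knowing:
resampling N = 10,000 individuals from 200 panel haplotypes *inherits
chance LD of the panel* — two variants uncorrelated in the population but
weakly correlated in a small panel stay correlated in the expanded sample.
This is a property of any panel-resampling simulator and is visible in the
evaluation below as occasional spurious associations near true loci.

Panel filtering before resampling: the variant MAF filter is *inclusive*
(`maf >= min_maf` retained), mirroring the common reading of a `--maf`
cutoff, and is distinct from the causal-candidate window (below), which is
*exclusive* on both ends. Sample keep-lists subset the panel before MAF is
recomputed.

## 2. Causal-variant selection

Variants are annotated with their nearest gene (zero distance inside a gene
interval, otherwise base pairs to the nearer boundary; strand ignored,
matching the default behaviour of interval-closest tools). Equidistant genes
are resolved deterministically — smaller start coordinate, then
lexicographic gene id — because the reference tooling leaves the tie rule
unspecified and reproducibility demands *some* fixed rule; this is an
artifact decision, not a modelling claim.

Candidate causal variants are those with sample MAF strictly inside
(0.05, 0.5) by default. From the target gene set, only genes with at least
one mapped candidate are *eligible* (n' of them); the sampler draws
min(k, n') genes uniformly without replacement and one candidate variant
uniformly per gene. If k exceeds n', assignment continues in round-robin
cycles over a fresh uniform permutation of the set's genes, so per-gene
causal counts never differ by more than one ("uniform coverage"). The
remaining K − k variants are drawn uniformly from candidates whose nearest
gene is *not* in the set. No MAF weighting is applied at any step, because
none is part of the design being emulated. Explicit variant-id lists bypass
all of this and are simply intersected with the genotype variants.

## 3. Phenotypes: the variance-partition model

Effect sizes are `beta_j = s_j * x_j` with `x_j ~ N(m_beta, sd_beta^2)` and
`s_j` a uniform random sign (on by default, toggleable). Sign randomization
is used because only the mean and spread of effect magnitude are part of the
parameterization; all-positive effects would couple the trait to allele
frequency systematically.

The trait for N individuals with causal dosage matrix G is built from

* `G_s = standardize(G) %*% beta`, rescaled to unit sample variance;
* optionally, when `hs2 < 1`, a background polygenic score over B background
  variants with i.i.d. `N(0, 1/B)` effects, mixed as
  `sqrt(hs2) * G_s + sqrt(1 - hs2) * G_bg` and re-standardized;
* noise `eps ~ N(0, 1)`, *orthogonalized against the genetic component* and
  standardized;
* `y = sqrt(h2) * genetic + sqrt(1 - h2) * eps`.

Two choices matter here. First, every component is scaled by its *empirical*
(sample) standard deviation, not its expected one, so the realized variance
partition equals the requested one on every dataset rather than on average.
Second, the noise is residualized against the genetic score before scaling;
without this, the sampling covariance between a random noise vector and the
genetic score (order `1/sqrt(N)`) would perturb the realized partition by
far more than floating-point error. With both choices,
`var(genetic part) / var(y) == h2` holds to machine precision, which is the
contract the package's evaluation machinery relies on.

The multi-trait sharing parameters (`theta`, `p_indep`, `phi`, `alpha`) are
accepted and validated but must hold their inert single-trait values (0, 1,
1, 0); anything else is rejected loudly. Silently approximating a
multi-trait model we do not implement would be worse than refusing.

Binary traits are produced by liability thresholding: the `prevalence * N`
individuals with the largest trait values become cases (PLINK-style 1/2
coding). The upstream design did not document its binary mechanism, so this
standard construction is our documented choice; `prevalence` is an explicit
parameter with no default hidden in the pipeline.

## 4. Association testing

Quantitative traits: per-variant simple linear regression of trait on
dosage; Wald t with N − 2 degrees of freedom, two-sided p from the t
distribution (exact for small toy datasets, indistinguishable from normal at
GWAS N). Monomorphic variants keep their row with `beta = 0`, `se = NA`,
`p = 1` so summary rows stay aligned with the genotype matrix. Binary
traits: allelic 1-df chi-squared on the 2x2 allele-count table, odds ratio
with the Haldane–Anscombe 0.5 correction when a cell is empty. No
covariates, logistic models, or mixed models — matching the scope of the
single-SNP `assoc`-style scan the pipeline emulates.

The genomic inflation factor reported on Q-Q plots is the median observed
chi-squared over the null median (~0.4549).

## 5. LD utilities

LD is the squared Pearson correlation of dosage columns (genotypic r²),
always computed from the simulated genotypes themselves, never from an
external reference. Clumping is the standard greedy algorithm: index
variants taken in ascending p below `p1`, members assigned once each if
below `p2`, within `kb` kilobases on the same chromosome, and at `r² >= r2`
with the index. Defaults are pinned to the widely published clumping
defaults (`p1 = 1e-4`, `p2 = 1e-2`, `r2 = 0.5`, `kb = 250`); the
causal-recovery evaluation overrides `p1` to 5e-8 so that "a clump" means
"a genome-wide-significant locus". Ties in p are broken by chromosome and
position. LD pruning is the sliding-window scheme: within each window of
`window` variants, while any retained pair exceeds `r2_max`, the
smaller-MAF member of the worst pair is removed (ties: later position), then
the window slides by `step`.

## 6. Evaluation

Causal-locus recovery is scored as:

* **precision** — fraction of clumps that contain (as index or member) at
  least one causal variant;
* **recall** — fraction of the K causal variants appearing in any clump;
* **F1** — their harmonic mean, zero when both are zero.

The prose this scheme descends from is ambiguous about which proportion is
which; clump-level purity as precision and causal coverage as recall is the
only reading consistent with using F1 as the summary, and "contains" counts
both index and member roles (index-only variants of both metrics are also
reported for comparison). For enrichment benchmarking, per-simulation result
tables (simulation id, set name, p) are aggregated into TPR (target set
significant in causal-design simulations) and FPR (any set significant in
null-design simulations), with a Wilson score interval on each rate; the
multiple-testing procedure across the sets tested within one simulation
defaults to Bonferroni and is exposed (`none`, `bonferroni`, `BH`) because
the upstream description does not fix it.

## 7. The synthetic fixture generator

The fixture module replaces the external inputs a real run would use (a
reference cohort's phased VCF, a genome annotation, a pathway database) so
the full pipeline runs offline. Its defaults are the package's study
conditions: 100 diploid samples (200 haplotypes) over ~20,000 sites in 400
LD blocks on 2 chromosomes. Each block carries **two founder haplotypes**
with a block-specific mixing weight drawn from U(0.15, 0.5); 45% of sites
segregate between the founders (the common arm of the frequency spectrum,
MAF ≈ the mixing weight), the rest form a rare arm with per-site carrier
frequencies in U(0.005, 0.045), and every common allele is flipped with
probability 0.003 per haplotype (mutational noise). Sites within a block are
0.2–1.5 kb apart; blocks are separated by 30 kb.

What this emulates: strong within-block LD, negligible between-block LD, a
frequency spectrum with both rare and common arms, and candidate pools that
are never empty (roughly half of all variants fall in the (0.05, 0.5)
causal window). What it deliberately does not emulate: graded LD decay
within blocks (two founders make common variants in a block near-perfectly
correlated), recombination maps, demography, and population structure. Tests
passing on these fixtures therefore demonstrate the *mechanics* of the
pipeline — selection, variance partitioning, testing, clumping, scoring —
not robustness to the messier LD of real cohorts, where partial tagging
(r² between 0.1 and 0.5) makes locus definitions fuzzier and recovery
metrics somewhat worse. Gene annotations are tiled so every gene interval
contains at least one variant (genes cover ~70% of their variant chunk,
leaving intergenic gaps), and the gene-set file always includes three
calibrated sets of 17, 69 and 199 genes — small/medium/large pathway sizes
typical of curated pathway databases — alongside randomly sized sets.

## 8. Numerical and reproducibility choices

* All randomness flows through explicit seeds; sub-seeds for stages and
  replicates are derived by multiplicative hashing modulo 2^31 − 1
  (`derive_seeds`), so any stage can be reproduced in isolation and derived
  seeds are valid 32-bit R seeds.
* Q-Q expected quantiles use `i / (M + 1)` uniform order statistics.
* PCA standardizes dosage columns by their sample standard deviation
  (monomorphic columns dropped) rather than by expected binomial variance;
  with the first four components reported.
* p-values are clamped into `(0, 1]` at the smallest positive double to keep
  the stated invariant under extreme signals.
* Chromosome labels are opaque strings ordered by first appearance within a
  panel; merged per-chromosome matrices use a numeric-aware canonical label
  sort so that merging is invariant to input order.

## 9. Problem sizes used in validation

The package's own validation (test suite plus `scripts/acceptance.R`) runs
the full pipeline at N = 10,000 individuals on the default fixture panel
(200 haplotypes, ~19,500 polymorphic sites), with 20 replicates per
configuration: K = 10 (k = 5) at the default parameter set
(m_beta = 0.05, sd_beta = 0.001, h2 = 0.1, hs2 = 1), and K = 20 (k = 10) at
h2 = 0.2, i.e. h2/K = 0.01 per variant and m_beta/sd_beta = 50. Unit tests
use smaller panels (30–100 diploids, 300–2,000 sites) chosen so every
brute-force oracle (all-pairs nearest gene, normal-equations OLS, replayed
greedy clumping, direct eigendecomposition) runs in seconds.

## 10. Known limitations

* One trait per run; no covariates, kinship, or gene–environment terms.
* The background polygenic score (`hs2 < 1`) is the minimal faithful
  construction (i.i.d. normal effects over supplied background variants) and
  is not exercised by the default settings.
* LD-based steps are quadratic in window size and meant for desk-scale
  simulations, not biobank-scale data.
* The binary-trait path tests association on the dichotomized trait only;
  no case-control ascertainment or disease-model genotype simulation.
* Causal variants are drawn without regard to mutual LD, so two causal
  variants can land in the same LD block; with random effect signs their
  marginal association signals can then partially cancel, and such variants
  occasionally stay below genome-wide significance even at large N. This is
  a property of marginal single-SNP testing, not of the simulator, and it
  is the main source of imperfect recall in the validation runs.
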