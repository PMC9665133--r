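---
title: "Long-range pCHi-C interactions: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Long-range pCHi-C interactions: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lriscape)
```

`lriscape` analyses significant promoter Capture Hi-C (pCHi-C)
interaction calls across a differentiation time course — preadipocytes
(PAd), day-1 differentiating cells (Diff) and adipocytes (Adip) in the
motivating system — with a focus on long-range interactions (LRIs,
1–2 Mb), which mark epigenetically repressed domains. This vignette
explains the statistical procedures, the tunable parameters, and the
choices made where the design was genuinely open. All coordinates in the
package are 0-based half-open; all point-in-interval assignments use the
fragment (or feature) midpoint, `floor((start + end) / 2)`.

## Interaction classes and filters

The unit of analysis is a bait-fragment / other-end-fragment pair with a
caller score and supporting read count. `filter_significant()` applies,
in a fixed and audited order: score ≥ 5 (the conventional significance
threshold of CHiCAGO-style callers), intra-chromosomal only, optional
exclusion regions (outlier loci such as histone-gene clusters; supplied
as BED, empty by default because no universal coordinates exist), and
midpoint distance < 2 Mb. Distance is midpoint-to-midpoint: it is
symmetric in the two fragments and robust to fragment length, and no
alternative operational definition is standard. The class boundary
places exactly 1 Mb in the LRI class, and exactly 2 Mb in the excluded
class.

**Replicate concordance** deduplicates each replicate to distinct
unordered fragment-id pairs (identity by id, not coordinates: callers
operate on a fixed restriction map, and coordinate-fuzzy matching would
inflate concordance), assigns each pair to a 50-kb distance bin, and
reports |A ∩ B| / |A ∪ B| per bin. The union denominator is the
strictest reading of "proportion seen in both replicates"; a
`denominator = "mean"` flag offers 2|A ∩ B| / (|A| + |B|). Bins whose
union holds fewer than 10 pairs are reported `NA` — too few interactions
to estimate a proportion. **Sharing** across time points counts each
distinct pair once and tallies how many time points contain it.
**Read support** is summarized by type-7 (linear interpolation)
quartiles per class.

## TAD annotation and chromatin state

TADs are a fixed genome partition supplied as BED. A fragment is
"within" a TAD when its midpoint falls inside it; a TAD with at least
one LRI end is an LRI TAD at that time point, a TAD with interaction
ends but no LRI ends is non-LRI, and interaction-free TADs are excluded
from all comparisons. The category of a TAD names the time points
contributing LRI ends ("all", "Diff only", "Diff and Adip", ...).

chromHMM states are grouped into promoter, active, enhancer and
quiescent (the shipped map covers the Roadmap 25-state model and is
user-overridable; unknown states fall into "other"). Fragment state
assignment takes the group with the highest coverage fraction, with a
deterministic tie-break order (quiescent > promoter > enhancer >
active > other) so results never depend on input order. Per-TAD group
coverage is overlap length divided by TAD length. Arms are compared by
the two-sided Wilcoxon rank-sum test in its normal approximation with
tie correction and no continuity correction (`stats::wilcox.test`,
`exact = FALSE, correct = FALSE`); identical constant arms return p = 1
by convention. At very small arm sizes the approximation can run
slightly above its nominal level — visible in the package's own null
calibration, where an LRI arm of ~7 TADs rejects at ~6–8% instead of
5%.

The marker-gene test assigns each marker gene to a TAD by midpoint
(genes outside every TAD are dropped and counted), builds the cell-type
× category contingency table, drops categories whose expected count
under independence falls below 5 in any row, and applies Pearson's
chi-square without continuity correction — cells are large after the
expected-count rule.

## A/B compartments from binned accessibility

Reads are binned by midpoint into 100-kb bins (blacklisted reads
dropped), converted to bins-per-million mapped reads (BPM), and
log2-transformed with a pseudocount of 1 BPM (zero-count bins would
otherwise be undefined; 1 BPM is the natural unit-scale choice). The
FRiP quality metric is removed by per-bin ordinary least squares of
log2 BPM on FRiP across samples, keeping residual + bin mean; a
constant-FRiP design degrades gracefully to a no-op, and fewer than
three samples skip the correction with a warning. Whether the original
procedure corrected per bin or globally is not documented anywhere we
know of; per-bin OLS is the strictest reading and a flag-free no-op
when FRiP carries no signal. Zero-count bins are kept (pseudocount)
rather than dropped.

Per chromosome, the bins' Spearman correlation matrix is computed
across samples (zero-variance bins excluded), and its leading
eigenvector extracted by power iteration from the normalized all-ones
vector (tolerance 1e-10, at most 10,000 iterations). For a symmetric
matrix this equals the NIPALS first component while being trivially
deterministic; an eigenvalue tie (e.g. the identity matrix) is flagged
as degenerate. Because the eigenvector's sign is arbitrary, it is
oriented using the fact that B compartments co-vary more strongly than
A compartments: each bin's connectivity is the sum of its correlations
with all other bins on the chromosome, and the eigenvector is negated
if positively correlated with connectivity, making A compartments the
positive, less-connected side. A centered moving average of width 3
(truncated at chromosome ends — no invented data) smooths the vector,
and bins are labelled by sign; exact zeros are excluded. Orientation is
sign-invariant: negating the input eigenvector cannot change the final
labels.

## Enrichment tests

Feature / LRI-TAD co-occurrence counts features whose midpoint lies in
an LRI TAD. The permutation null shuffles which TADs carry the LRI
label — a uniform subset of the *interaction-containing* TADs, of the
observed size, per permutation (10,000 by default) — and the p-value
uses the add-one rule (1 + #{null ≥ observed}) / (1 + N), which can
never return zero. Shuffles are genome-wide; per-chromosome
stratification was considered and not adopted since the synthetic
genome is homogeneous across chromosomes. The hypergeometric
counterpart treats eligible TADs as the population, LRI TADs as
successes and features as draws; it is exact only under one-feature-
per-TAD sampling and is reported alongside the permutation p.

## Expression stratification

External RNA-seq time points are matched to the pCHi-C time points by
Spearman correlation over the top 5000 genes of each reference column
(lowered with a warning when fewer genes are shared). Genes are
classified by the distance classes of the interactions baited at their
promoter fragment: SRI-only, LRI-only, both (excluded from two-class
comparisons), or neither; each distinct gene is tested once. The
expressed-fraction comparison uses Pearson's chi-square on the 2×2
expressed × class table with "expressed" meaning value > 0 in the
matched time point (configurable; the external study's own threshold is
not restated anywhere). Expression-level comparisons use Welch's
unequal-variance t-test on log2(x + 1) — a robust default where only "a
t-test" is conventional — with Bonferroni adjustment over the time
points tested (Benjamini–Hochberg available). The bystander test runs
the same machinery on SRI-only genes, stratified by whether their TAD
is an LRI TAD at the matching time point.

## Interaction-restricted long-range cis-eQTL

Genes expressed (> 0) in more than 90% of individuals and SNPs passing
info ≥ 0.8, MAF ≥ 5% (from mean dosage, folded) and HWE p ≥ 1e-5
(1-d.o.f. chi-square on rounded dosages — the classical hard-call test)
enter the analysis. Candidate pairs use the minimum distance from the
SNP to either gene end: short below 1 Mb, long from 1 Mb up to 2 Mb.
A long pair is tested only when interaction-supported: the SNP position
lies inside the other-end fragment (half-open) of an LRI whose bait is
the gene's promoter fragment. The association model is ordinary least
squares of log2(expression + 1) on dosage, covariates and an intercept
— exactly the additive linear model standard eQTL software fits — with
the two-sided p from the t distribution at residual degrees of freedom.
Multiple testing uses Bonferroni over the number of independent
signals: SNPs are greedily pruned in ascending p-value order, accepting
a SNP only when its LD R² with every accepted SNP is below 0.2, and
every long-range p is multiplied by the accepted count (globally, the
default; a per-gene option exists). Long-range SNPs are finally
cross-checked against the short-range analysis at BH FDR < 0.05.

## The synthetic study

`synthetic_config()` defines a miniature study whose defaults are the
package's test conditions; they are chosen once and every recovery
experiment runs under them.

- **Genome**: 4 chromosomes × 15 Mb; restriction fragments of mean 4 kb
  and TADs of mean 800 kb partition each chromosome exactly; 200 genes
  per chromosome sit on distinct bait fragments away from chromosome
  ends.
- **Repressed domains**: 25% of TADs, drawn as contiguous runs of three
  (~2.4 Mb) so that 1–2 Mb pairs can have *both* ends inside repressed
  chromatin, and pruned to TADs actually reachable by such pairs.
- **Interactions**: 5,000 significant calls per replicate and time
  point. The distance distribution is a piecewise mixture: the class
  probabilities are the configured per-time-point rates (LRI 1.1% →
  2.6% → 3.5%, matching the observed rise; 2% beyond 2 Mb so the
  retention filter is exercised) and *within* each class distance
  follows a d^-1 power law. A pure power law cannot express a 1–2%
  LRI share — a d^-1 tail truncated at 2.5 Mb puts over 10% of draws
  beyond 1 Mb — so the mixture keeps the decay shape while making the
  class rates identifiable. 90% of LRIs come from a persistent pool of
  planted repressed-TAD pairs (at most two anchor promoters per TAD
  carry them; the TAD's remaining genes are bystanders), so planted
  LRIs recur across time points (≈ half the LRIs appear in ≥ 2 time
  points) and, at the terminal time point, cover every repressed TAD.
  The remaining LRIs concentrate at three persistent "hot" loci,
  mimicking interaction-dense outlier regions such as histone-gene
  clusters. Free-draw class ranges are buffered by 25 kb so snapping a
  position to its fragment midpoint cannot cross a class boundary.
  Read support is shifted Poisson (means 11 SRI / 5.5 LRI, medians 12
  and 6); 10% sub-threshold decoy rows exercise the score filter; the
  second replicate thins the first at per-class retention (0.75 SRI,
  0.55 LRI, 0.10 beyond 2 Mb), reproducing concordance that decays
  with distance.
- **Chromatin states**: segments of mean 5 kb tile each TAD; the
  quiescent fraction is Beta(8, 2) (mean 0.8) inside repressed TADs
  and Beta(2, 6) (mean 0.25) elsewhere.
- **Expression**: log2 baseline N(5, 1) per gene plus a random-walk
  stage trajectory (step SD 0.7) shared between the query and an
  external-style reference course (0d/1d/3d/7d/14d; the query tracks
  1d/3d/14d), observation noise SD 0.5, dropout 5%. Genes in repressed
  TADs and planted-LRI bait genes are multiplied by 0.5 (one log2
  unit) with dropout 0.4. A per-individual matrix (n = 300) serves the
  eQTL analysis.
- **Accessibility**: alternating 2.5-Mb A/B blocks (compartments are
  multi-megabase). Per bin and sample, counts are Poisson with log
  intensity base + loading × factor + noise: means 200 (A) and 60 (B)
  reads per 100-kb bin, loadings −0.4 (A) and +0.9 (B) on a shared
  per-sample factor standardized to unit realized spread, and noise SD
  0.45 (A) versus 0.2 (B) — open chromatin carries more
  sample-specific variability, so B bins are the more strongly
  co-varying ones, which is precisely the asymmetry the orientation
  rule needs. Twelve samples are emitted — the study's full replicate
  set pooled across the course — because per-bin FRiP regression on
  four samples leaves two residual degrees of freedom, at which
  bin–bin rank correlations are pinned near ±1 and compartment
  structure is unidentifiable at this genome size; the real study's
  genome-scale bin count compensates for what the miniature genome
  cannot.
- **Genotypes**: background SNPs every 25 kb plus two planted SNPs
  inside each planted-LRI other end (one, at the midpoint, for the
  causal fragment). Within 100-kb LD blocks individuals' haplotypes
  copy one of two founders (block-level mixing probability, per-SNP
  flip rate 3%), giving high within-block and near-zero across-block
  R², and Hardy–Weinberg-consistent dosages. One planted SNP–gene pair
  (MAF 0.3, effect 0.8 log2-SD per dosage unit) is wired through a
  planted LRI.

Every generator is a pure function of (config, seed); the full default
study builds in about two seconds.

**What passing tests do and do not show.** The generator plants clean,
block-structured effects: repression keyed to whole TADs, a single
global accessibility factor, rectangular LD blocks, one causal variant.
Real data add partial effects, batch structure, copy-number and
mappability artifacts, overlapping annotations and cell-type mixtures,
none of which are emulated. Recovery of the planted truth therefore
demonstrates the correctness of the statistical machinery and the
wiring between modules — not expected performance on real libraries.

## Numerical and degenerate-input conventions

Quantiles are type 7; power iteration declares degeneracy at a relative
eigenvalue gap below 1e-6; moving averages truncate at boundaries;
identical constant samples give p = 1 in the rank-sum comparison;
zero-variance dosages after covariate projection are an error, not a
silent NA; empty filter results warn rather than error; permutation
helpers save and restore the caller's RNG state so seeded calls never
perturb the surrounding stream. The problem sizes used by the shipped
tests and the acceptance script (100-instance oracle sweeps, 500
permutation-calibration runs, 20 eQTL seeds, 100 null-calibration
seeds) were chosen so the whole suite completes in minutes on one CPU
while leaving the binomial acceptance bands narrow enough to detect
miscalibration.

## Known limitations

- Interaction identity is fragment-id based; analyses across different
  restriction maps are out of scope.
- The hypergeometric enrichment model requires fewer features than
  eligible TADs; with denser feature sets only the permutation test is
  meaningful.
- The Wilcoxon normal approximation is slightly anticonservative for
  arms under ~10 TADs; at those sizes an exact test would be
  preferable.
- The eQTL module consumes covariates (expression factors, genetic
  PCs); estimating them is out of scope, as are imputation, phasing and
  kinship control.
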