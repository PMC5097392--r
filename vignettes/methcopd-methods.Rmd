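---
title: "Methods: differential methylation and comethylation networks in whole blood"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation and comethylation networks in whole blood}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

methcopd implements a complete case-control analysis for Illumina
27K-style whole-blood methylation arrays, of the kind used to study
COPD-associated differential methylation: quality control, beta/M
transforms, reference-based cell-type deconvolution, per-CpG linear
modelling with empirical-Bayes moderation and Benjamini-Hochberg FDR,
a qualitative two-cohort test-statistic-difference screen, signed
weighted comethylation network analysis, and hypergeometric gene-set
enrichment. A synthetic-data generator with full ground truth makes
every stage testable without access to any real cohort. This vignette
explains the models, the defaults, and the choices made where the
design was genuinely open.

## Measurement model and transforms

Each probe yields methylated and unmethylated fluorescence
intensities. The methylation fraction is summarised as

\[
\beta = \frac{\mathrm{meth}}{\mathrm{meth} + \mathrm{unmeth} + 100},
\]

the standard offset-100 formula: the offset regularises low-intensity
probes and keeps \(\beta < 1\). Association testing uses the M-value

\[
M = \log_2 \frac{\mathrm{meth} + 1}{\mathrm{unmeth} + 1},
\]

which is unbounded, closer to homoscedastic, and the natural scale for
linear modelling. The M-value offset is not standardised anywhere; we
use 1 — the smallest perturbation that guarantees finiteness — and
expose it as a parameter (`m_values(x, offset = )`). For large
intensities \(M \to \mathrm{logit}_2(\beta)\), a relation the test
suite checks.

Effect sizes are reported as delta-beta in percentage points,
\(100\,(\bar\beta_{\text{cases}} - \bar\beta_{\text{controls}})\),
signed: positive values mean relative hypermethylation in cases. The
sign convention matters because COPD-associated CpGs in whole blood
are predominantly hypomethylated in cases, and the generator plants
effects that way by default.

## Quality control

`run_qc()` applies three stages in a fixed order, each with strict
(`>`) threshold comparisons:

1. **Annotation probe filters** — probes with a SNP within 5 bp of
   the interrogated CpG, probes over repeat regions, and probes on
   X/Y. Each removal gets one primary reason with precedence
   SNP > repeat > sex so the ledger is deterministic.
2. **Subject-level filters** — samples with more than 1% of sites at
   detection \(p > 0.05\) (evaluated on annotation-surviving probes),
   then samples with any missing model covariate. Missing covariates
   are represented explicitly and only ever handled by removal, never
   imputation. Technical replicate duplicates are also removed here,
   after their concordance (Pearson correlation of beta across probes,
   and the fraction of probes with \(|\Delta\beta| \le 0.10\)) has
   been recorded; `technical_replicate` is the ledger reason. Two
   metrics are reported because "concordance" has no single standard
   definition; neither gates the pipeline.
3. **Signal probe filters** — probes with beadcount < 3 in more than
   5% of samples or detection \(p > 0.05\) in more than 1% of
   samples, evaluated after failed samples are gone so that dying
   samples do not drive probe loss.

The sample-level detection rule is phrased ambiguously in common usage
("having 1% of sites"); we interpret it as *strictly more than* 1%,
parallel to the probe rule, and expose every threshold in
`qc_thresholds()`. The stage ledger conserves counts (before − removed
= after) and `run_qc()` is idempotent; both properties are tested.

## Cell-type deconvolution

Whole blood is a mixture of leukocyte populations with distinct
methylomes; COPD and smoking both shift blood composition, so
composition is a classic confounder of whole-blood EWAS. We estimate
per-sample proportions of NK, CD8+ T, CD4+ T, B cells, monocytes and
granulocytes by projection onto reference methylomes
(Houseman-style): for each sample, on cell-type-discriminating probes,

\[
\hat w = \arg\min_{w \ge 0,\; \Sigma w \le 1} \lVert y - X w \rVert^2 ,
\]

where \(X\) holds the reference beta profiles. The constraints are
enforced exactly by a Lawson-Hanson nonnegative least-squares solve on
an augmented system with a slack variable and a heavily weighted
sum-to-one row (weight \(10^4 \max|X|\)); exact mixtures are recovered
to machine precision, and the constraint residual is far below the
\(10^{-8}\) tolerance the container invariant allows. A reference
condition-number guard rejects collinear references.

Discriminating probes are chosen per cell type by one-vs-rest mean
beta difference (top 50 per type by default), with a between-type
F-statistic used for ranking when the reference carries replicate
columns.

Regression covariates are derived in one of two modes, because the
phrase "principal component-based covariates" is ambiguous between PCs
of proportions and the proportions themselves: `"proportions"`
(default) drops the last cell type — proportions are compositional,
so one column is redundant; granulocytes, the largest fraction, are
dropped — and centres the rest, while `"principal_components"`
returns the leading PCs of the centred proportion matrix with a
deterministic sign convention (first nonzero loading positive). Both
modes span nearly the same column space; the default is the more
interpretable one.

## Per-CpG differential methylation

For each probe, M-values are regressed on case status, age, gender,
pack-years, batch (fixed-effect treatment coding, reference batch
first alphabetically), and the cell covariates. The published analyses
this mirrors describe the model inconsistently ("logistic mixed
model" in one place, "linear mixed models" with limma as the engine
in another); a linear model of M on case plus covariates with batch
as a fixed effect is the formulation consistent with per-CpG
t-statistics and the limma workflow, and is what we implement. The
fits are computed by a single QR decomposition shared across probes,
so a 20k-probe EWAS takes well under a second.

With `moderation = TRUE` (default), residual variances are shrunk by
empirical Bayes exactly as in the moderated t framework: the prior
\((d_0, s_0^2)\) is estimated by method of moments on \(\log s_g^2\)
(using digamma/trigamma moments of the log chi-square, with a Newton
trigamma inverse), each posterior variance is
\(\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)\), and the moderated
t has \(d_0 + d\) degrees of freedom. The test suite verifies
agreement with limma to \(10^{-6}\) and with textbook OLS to
\(10^{-10}\) when moderation is off. Constant probes are reported with
\(t = 0, p = 1\) unmoderated, or rescued through \(s_0^2\) when
moderation is on.

Multiple testing uses Benjamini-Hochberg step-up adjustment
(`bh_adjust()`, delegating to `stats::p.adjust`), with an `m_total`
argument that adjusts a printed top table as if its p-values were the
smallest among the genome-wide test count — this is what lets the
bundled twelve-CpG published table reproduce its printed FDR column
from only its printed p-values with `m_total = 19302`. Significance
is reported at FDR < 5% with a second tier at < 10%, strict
comparisons.

`genomic_inflation()` summarises test-statistic inflation as
\(\lambda = \mathrm{median}(t^2) / F^{-1}_{1,d}(0.5)\); under the null
\(t^2 \sim F(1, d)\), and the reference median tends to the
chi-square value 0.4549. Using the F quantile (rather than
transforming each t to a chi-square through its p-value) makes
\(\lambda\) exactly scale-equivariant, which is the diagnostic
behaviour one wants.

## Cross-cohort screen

To ask which associations are specific to one cohort, both cohorts
are run through byte-identical QC, deconvolution and EWAS settings
(a settings hash is recorded), and the per-probe difference of
t-statistics \(t_A - t_B\) is formed, retaining sign. Probes strictly
below the lower 2.5-percentile cutoff of this difference distribution
are flagged. Two cutoff variants are provided because the published
analysis observed normality but did not say which it used: the
empirical quantile (default, linear interpolation) and a normal fit
\(\hat\mu + \hat\sigma\,\Phi^{-1}(0.025)\). At the published fit
parameters (mean −0.316, sd 1.515) the normal cutoff is −3.285. The
screen is qualitative and hypothesis-generating: no per-probe p-value
is attached to a flag, and the output says so.

## Comethylation network analysis

A signed weighted network is built from probe-probe Pearson
correlations of M-values:

\[
A_{ij} = \left(\frac{1 + \mathrm{cor}(i, j)}{2}\right)^{\beta},
\qquad \beta = 12 ,
\]

so anticorrelated probes get adjacency near 0 and cannot share a
module. Power 12 is the conventional signed-network default at which
approximate scale-free topology is reached; `soft_threshold_scan()`
reports the signed scale-free fit \(R^2\) and mean connectivity across
candidate powers for the user to confirm.

Module dissimilarity defaults to \(1 - \mathrm{TOM}\) with

\[
\mathrm{TOM}_{ij} =
\frac{\sum_{u \ne i,j} A_{iu} A_{uj} + A_{ij}}
     {\min(k_i, k_j) + 1 - A_{ij}},
\]

(raw \(1 - A\) is available via `use_tom = FALSE`). Modules come from
average-linkage hierarchical clustering with a documented hybrid cut:
a static cut at 0.90 of the merge-height range, then recursive
splitting of each cluster at its subtree root whenever both children
reach the minimum module size (30) and the root height exceeds the
children's by a relative gap above 0.05. Clusters below the minimum
size are unassigned ("grey"), and modules are labelled by decreasing
size through the conventional colour list. The static-cut fraction
was set by planted-block recovery: at 0.90 the three-block reference
design is recovered with adjusted Rand index 1.0, whereas cuts near
the top of the dendrogram let average-linkage chaining glue background
probes onto genuine modules. The cut is not a port of any particular
tree-cut implementation; correctness is defined by planted-structure
recovery, which the acceptance suite measures across seeds.

Each module is summarised by its eigengene — the first right singular
vector of the probe-standardised module block, unit norm, sign-aligned
to correlate positively with the module's mean profile so module-trait
correlation signs are reproducible. Module-trait association is the
Pearson correlation of eigengene with trait with the usual
\(t = r\sqrt{(n-2)/(1-r^2)}\) p-value; gene significance (GS) is the
signed point-biserial correlation of a probe with case status (its
square maps monotonically to the two-sample t statistic, an identity
the tests verify numerically); module membership (kME) is the
correlation of a probe with an eigengene. Trait-associated modules are
re-checked by logistic regression of case status on the eigengene
plus age, gender and pack-years, with explicit detection of (quasi-)
separation — which genuinely occurs when a planted effect module's
eigengene nearly equals the case indicator — reported as an error
(or a flagged row in the pipeline table) rather than a meaningless
Wald test.

For enrichment, modules are limited to probes with kME strictly above
0.85 (the stringent driver-probe convention), mapped to their nearest
genes, deduplicated, and tested by one-sided hypergeometric
over-representation against user-supplied GMT collections. The
background universe defaults to the unique nearest genes of all
post-QC probes — an explicit, defensible default given that hosted
pathway databases define theirs opaquely. BH correction is applied
across sets (the alternative reading, across genes, has no standard
formulation), using the same `bh_adjust()`.

## Nearest-gene annotation

Probes use 1-based coordinates; gene intervals are BED half-open
\([start, end)\). Distance to an interval is 0 inside, otherwise the
gap to the nearer boundary; assignment is whole-interval distance
(TSS-distance is a plausible alternative the source material does not
disambiguate; whole-interval is the convention chosen, and it is
flagged as such). Ties break alphabetically; assignment never crosses
chromosomes; probes on gene-free chromosomes get `NA`.

## The synthetic generator

`generate_cohort()` produces a full study with known truth. Defaults
are the study conditions the pipeline targets:

- **Design**: 93 cases / 269 smoking controls (comparison cohort
  678 / 427), cases older (61.4 ± 7.7 vs 48.9 ± 6.4 years), similar
  pack-years (42 vs 39, floor 20), gender mix 54% / 72% male.
- **Cell composition**: Dirichlet draws per arm around realistic
  whole-blood fractions (granulocytes ≈ 60%); cases shift toward
  granulocytosis with relative lymphopenia, so composition
  confounding is on by default and the deconvolution adjustment is
  consequential. Per-probe per-cell-type reference dispersion is 0.07
  on the beta scale.
- **Planted effects**: 100 DMPs with |mean beta difference| uniform
  on [0.05, 0.12], hypomethylated in cases — the effect-size range a
  27K COPD EWAS reports — planted on the beta scale (where percent
  methylation lives) and clipped to [0.01, 0.99].
- **Comethylation blocks**: latent-factor structure added on the M
  scale (where the model operates) with loadings U(0.75, 0.95)
  calibrated to a within-block correlation of 0.7.
- **Noise and nuisance**: measurement noise sd 0.35 on M, two batches
  with per-probe shifts of sd 0.1, lognormal total intensity (median
  2000) inverted so the offset-100 beta formula recovers the intended
  beta within noise.
- **QC artifacts**: 5% SNP-flagged, 3% repeat, 4% sex-chromosome
  probes; 1% planted low-beadcount and 1% detection-failing probes;
  one detection-failing sample; three incomplete-covariate samples;
  two technical replicate pairs (one male, one female). Artifact
  samples are appended beyond the nominal arm sizes so the post-QC
  cohort is exactly the design size.

What the generator does **not** emulate: probe type chemistry and
dye bias, genotype-driven mQTL structure, spatially correlated batch
effects, and the full complexity of real 27K beta distributions (the
baseline is a two-component Beta mixture). Passing tests therefore
demonstrate statistical correctness of the methods under a controlled
generative model, not performance on any real cohort.

## Problem sizes and numerical choices

The test and acceptance suites run at deliberately scaled sizes chosen
to make every Monte-Carlo check stable yet quick: 5000 probes for
calibration and power runs (20 seeds), 3000 for the confounding
contrast, 10,000 for the cross-cohort flag-rate check, and the
750-probe three-block design (60/50/40 among 600 background, 200
samples, 20 seeds) for module recovery. Tolerances follow the
structure of each quantity: machine-precision agreement for algebraic
oracles (TOM, BH, hypergeometric, SVD), \(10^{-6}\) for the limma
cross-check, Monte-Carlo bands elsewhere. Degenerate inputs have
defined behaviour throughout: constant probes are dropped from
networks and reported `NA` in GS, zero-variance difference
distributions and constant traits are errors, empty case or control
groups are errors, and all-grey assignments are returned (with a
warning) when nothing reaches the minimum module size.

## Limitations

The pipeline ingests tabular intensities, not IDAT binaries;
between-array normalisation (BMIQ, functional normalisation) is out
of scope, as are DMR-level analysis, module merging by eigengene
similarity, consensus networks, and reference-free deconvolution.
Batch enters as a fixed effect; a random-effect formulation would need
a mixed-model engine and is not what per-CpG t-statistics from the
standard workflow correspond to. The cross-cohort screen is
deliberately qualitative — differences in ascertainment, batch and
population structure between real cohorts cannot be separated from
biology by this design, and the output labels itself accordingly.
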