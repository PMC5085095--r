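---
title: "Family-based methylation heritability: models, simulator, and design choices"
author: "famMeth"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Family-based methylation heritability: models, simulator, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The scientific problem

DNA methylation at a CpG site varies between people, and part of that
variation runs in families. Given beta scores (methylation fractions in
[0, 1]) measured on members of extended pedigrees, famMeth asks, per CpG:

1. How much of the variance is attributable to family structure
   (broad-sense heritability, H²)?
2. For highly heritable CpGs, is the signal driven by a nearby SNP
   (cis-meQTL), a distant or cross-chromosome SNP (trans-meQTL), or no
   common variant at all (genotype-independent CpG, GIC)?
3. Do relative-pair correlations behave as a genetic model predicts
   (parent–offspring ≈ sibling > grandparent ≈ avuncular > cousin >
   spouse ≈ 0)?
4. Could GIC heritability be a rare variant private to one family
   (the beta-score extremes screen)?

# The mixed model and H²

Per CpG the model is

$$ y = X\beta + g + \varepsilon,\qquad
   g \sim N(0,\ \sigma^2_g A),\qquad
   \varepsilon \sim N(0,\ \sigma^2_e I), $$

where `y` holds the beta scores, `X` the fixed covariates (intercept, age,
sex, and methylation principal components as cell-composition/technical
surrogates), and `A` the expected relatedness matrix from the pedigree.
Broad-sense heritability is the variance-component ratio

$$ H^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_e}. $$

**Scaling of A.** We default to the numerator-relationship convention
`A = 2Φ` (unit diagonal for non-inbred individuals), so that a fully
familial trait gives `H² = 1` and the ratio is directly interpretable. The
kinship convention `Φ` (diagonal ½) is available through
`kinshipMatrix(..., convention = "kinship")`; it rescales `σ²_g` but not
the ratio's interpretation once the diagonal is accounted for.

**Estimation.** We profile the restricted likelihood over the single ratio
`h = σ²_g/(σ²_g + σ²_e) ∈ [0, 1]`. After one eigendecomposition `A = UDU'`
per pedigree, rotating `y` and `X` by `U'` makes the covariance diagonal,
`σ²(hD + (1-h)I)`, so each likelihood evaluation is O(np²) and the same
decomposition serves every complete-case CpG of a genome-wide scan. The
scalar optimization uses `optimize()` with tolerance 1e-8; both boundary
values (0 and 1) are evaluated explicitly and a boundary optimum is
returned flagged, not as an error. REML is the default (ML behind a flag):
REML is the standard estimator for variance components, and the package's
correctness surface is parameter recovery, which the test suite checks
against a brute-force grid search of the same restricted likelihood and an
independent, unrotated matrix-formula implementation of it.

**Residuals.** The meQTL stage regresses residuals on genotype. We use
*marginal* residuals `y − Xβ̂` rather than BLUP-subtracted ones: the
genetic signal must remain in the residuals for a causal SNP to be
discoverable, which is the only reading under which a residual-on-dosage
scan can find cis-meQTLs at all.

**Missing data.** Per CpG, missing outcomes are dropped together with the
matching rows of `X` and the kinship submatrix; eigendecompositions for
recurring missingness patterns are cached. With `A ∝ I` (degenerate, e.g.
all-founder "pedigrees") the ratio is not identifiable; the fit warns and
flags rather than failing.

# The expanding-window meQTL scan

For each CpG with `H² > 0.4` (strict), residuals are regressed on
minor-allele dosage SNP by SNP (simple linear regression, two-sided t test
on the slope, pairwise deletion of missing dosages; SNPs with fewer than
10 informative samples are skipped, zero-variance dosages get p = 1,
flagged). Windows are symmetric ±5 kb, ±20 kb, ±100 kb, ±1 Mb, ±3 Mb
around the CpG, then the whole chromosome, then the genome; the scan stops
at the first stage whose minimum p-value is below α = 1e-7 (the same α at
every stage — a deliberate reproduction of the published procedure, which
does not adjust for stage size). The best SNP of that stage (smallest p,
ties by distance then position) decides the class: same chromosome and
≤ 1 Mb (inclusive) = cis, otherwise trans; no significant stage = GIC.
Coordinates are 1-based; the window edge is inclusive.

Because per-SNP p-values do not depend on which window they are tested in,
the implementation computes the scan once per CpG and then walks the
stages — algorithmically identical to testing stage by stage, and
invariant to SNP input order.

# Familial correlations

For pairs of a given relationship type the package evaluates the weighted
correlation

$$ r = \frac{\sum_i w_i (x_i-\bar x)(y_i-\bar y)}
  {\sqrt{\sum_i w_i (x_i-\bar x)^2 \sum_i w_i (y_i-\bar y)^2}}, $$

with weighted means under the same weights. Uniform weights reduce it to
Pearson's correlation exactly, which is the package default. The
minimum-variance weighting used by the classic FCORR implementation is not
printed in the accessible literature; as an alternative we provide
`weights = "family-size"` (1 / number of same-type pairs in the family),
which downweights large sibships. Neither option claims to reproduce
FCORR's exact scheme.

As printed, the formula is order-dependent. Symmetric types (sibling,
cousin, spousal) are therefore double-entered — each pair contributes
(a, b) and (b, a) — making the estimate order-invariant; asymmetric types
put the elder member first (parent, grandparent, aunt/uncle). One
correlation is computed per CpG per type, matching the per-CpG density
summaries used in family studies. Under a purely additive model the
expected per-type mean is relatedness × H², which the acceptance tests
verify at H² = 0.8.

**Extremes screen.** For each CpG the k = 10 largest and smallest observed
betas are taken (ties broken by sample id for determinism); a CpG is
flagged when more than 3 of either extreme come from a single family — the
signature of a private rare-variant effect.

# Quality control

The filter order is fixed so counts are deterministic: detection-p mask
(p > 0.01 → missing) → sample filter (> 1.5% missing removed, strict) →
probe filters in the order non-autosomal, > 10% missing, SD ≤ 0.02 (SD
computed on observed entries after masking), probe-SNP flag, multimapping
flag. Flags are consumed from the annotation (as the array manufacturer
provides them), not recomputed. SNPs are kept when call rate ≥ 95%,
MAF > 0.01, and the within-family MAF exceeds 0.01 in at least 10% of
families.

The Infinium I/II chemistry correction fits one least-squares quadratic
from type-II to type-I betas over all per-pair per-sample values of
differing-chemistry probe pairs within 50 bp (at least 30 pairs required),
then applies it to every type-II probe, clipped to [0, 1]. Type I is the
reference because pairing anchors on proximity and type-I chemistry is
conventionally less biased mid-range. Pairs are not additionally filtered
on observed correlation before fitting; at 50 bp they are expected to be
nearly perfectly correlated anyway, and the round-trip test shows ≥ 80%
RMS reduction on a planted squaring distortion. A fitted polynomial that
is non-monotone on [0, 1] triggers a recorded warning (inverting a convex
distortion with a quadratic can do this near the boundary) but is still
applied. Empirical-Bayes batch normalization is deliberately out of scope:
it is an established external method, and the simulator can emit
batch-free data; the batch labels are still assigned (12 samples per
array) for any external hook.

Methylation PCs are column-centered SVD scores (`prcomp`) of the
mean-imputed beta matrix, sign-fixed so the largest-magnitude loading of
each component is positive; the first four serve as covariates.

# The synthetic cohort generator

The generator exists so that every downstream stage is testable with known
truth and no data access. Its defaults emulate the study cohort shape: 163
families, sizes 2–35, up to three generations, founders marrying in from
outside (so spousal pairs are genetically unrelated — required for the
spouse-correlation null checks). Each family grows from a founding couple
by a depth-guaranteeing chain plus randomized extra children and
marriages; the paper does not state the distribution of family depth, so
depth is a parameter, and a family whose sampled size cannot support the
requested depth (a depth-g chain needs 2g−1 members) grows to the deepest
feasible depth instead.

Genotypes are gene-dropped: founders Hardy–Weinberg at per-SNP MAFs drawn
from `maf_range`, offspring receiving one allele per parent with
probability dosage/2, SNPs uniform on two synthetic 50-Mb chromosomes (two
chromosomes are the minimum that exercises every window stage including
"chromosome" and "genome", at desk scale).

Per CpG the latent signal is

* baseline (uniform in [0.25, 0.75]) — mid-range, so the affine
  latent-to-beta placement with clamping keeps planted variance fractions
  intact on the observed scale (clamping touches < 1% of entries at the
  default latent SD of 0.08, which also comfortably clears the 0.02
  probe-SD filter);
* fixed effects: age (uniform within 15-year generation bands, 25 years
  apart), sex, and a standard-normal cell-composition-like sample gradient
  shared across CpGs (what the methylation PCs recover);
* additive genetic effect ~ N(0, h²s²A), drawn per family from the
  Cholesky factor of the relatedness block;
* shared-household effect (variance c²s²): each person belongs to exactly
  one nuclear household — parents with their own children when they have
  any, otherwise their parents' household — so parent–offspring, sibling
  and spousal pairs share environment while the model's single random
  effect cannot distinguish it from genetics (the confounding the spousal
  correlations are meant to expose, reproduced on purpose);
* a planted meQTL effect, additive in the causal dosage and scaled to a
  chosen fraction of s² (cis CpGs are placed within `cis_distance` of
  their SNP, default 2 kb; trans CpGs on the other chromosome);
* an independent residual completing the unit variance budget
  (h² + c² + meQTL fraction ≤ 1, enforced).

Array artifacts are injected afterwards: a configurable fraction of
entries get failing detection p-values (> 0.01); a configurable number of
probe pairs are rewritten as Infinium I/II pairs within 50 bp measuring
near-identical signal, after which a known quadratic distortion is applied
to all type-II probes; samples are batched in groups of 12.

What the simulator does *not* emulate — and therefore what passing tests
do not establish about real data: linkage disequilibrium beyond family
co-segregation, X-chromosome inheritance, genuine cell-mixture
deconvolution (the gradient is a one-dimensional proxy), probe cross-
hybridization, or non-Gaussian beta distributions near the boundaries.
Parameter recovery here shows the estimator is correct under its own
model, not that the model is correct for arrays.

# Problem sizes and numerical choices

The test and acceptance workloads are sized for a desk machine: the
parameter-recovery fixture uses 163 families with sizes 2–10 (≈ 975
individuals — the cohort's observed mean family size rather than the full
2–35 range, which would triple the cohort), 200 CpGs per heritability
level; the meQTL recovery panel uses 300 CpGs (70% cis / 10% trans / 20%
none), 4,000 SNPs and ≈ 700 genotyped samples; the REML-vs-grid check uses
50 datasets of 50 samples at a 1e-4 grid. Recovery in those runs lands
within |mean(ĥ²) − truth| ≤ 0.05 per level, ≥ 90% per-class meQTL
agreement, and ≤ 5e-4 agreement with the grid oracle.

Other numerical conventions: the kinship recursion uses the tabular
method (parents before children); PSD of A is asserted with tolerance
−1e-10 on the smallest eigenvalue; heritability fits drop constant
covariate columns after missing-data row deletion; association ties are
broken smallest-p, then distance, then position; Monte Carlo Fisher
p-values use fixed-margin resampling with the +1 correction
(p = (1 + #{at least as extreme})/(1 + B)) and "at least as extreme"
means conditional table probability not exceeding the observed one, which
converges to the exact enumeration p. BED input is converted to 1-based
inclusive coordinates; the 25-kb region flank is inclusive at the
boundary. Whether published 25-kb overlaps anchored on CpG positions or
gene bodies is ambiguous; both anchors work here via the input you supply,
and neither is claimed as the published choice.

# Known limitations

* One random effect only: shared environment inflates H² by construction
  (verified by a dedicated test); the package reports, and the familial
  correlation module exposes, the spousal correlations used to argue about
  it — it does not attempt an ACE decomposition.
* Expected (pedigree) relatedness only; no marker-based realized kinship.
* The fixed α = 1e-7 at every window stage carries the published
  procedure's multiple-testing asymmetry; loosening α can only move a CpG
  to an earlier stage (a tested invariant), it cannot change that
  asymmetry.
* Half-relationships are excluded from the six named pair types; pairs
  holding several relationships carry each label independently.
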