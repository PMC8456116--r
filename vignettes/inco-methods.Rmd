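---
title: "Joint SNV-CNV region testing and co-localization: models and design choices"
author: "incoloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint SNV-CNV region testing and co-localization: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single nucleotide variants (SNVs) and copy-number variation (CNV) segments
are usually analyzed on separate tracks and only merged at the end, by
taking the union or intersection of the per-platform hit lists. That
parallel scheme cannot see a *concurrent* effect — a trait driven by the
joint presence of a sequence variant and a copy-number change in the same
genomic region — and it inherits the multiplicity and sparsity problems of
single-marker analysis, especially for rare variants.

`incoloc` implements an integrative alternative. For each gene (and later
each sub-gene window) it assembles the combined marker matrix

$$
G \;=\; \bigl[\, \underbrace{g_{ir_11}}_{n \times q_1}\;\big|\;
\underbrace{g_{ir_22}}_{n \times q_2} \,\bigr],
$$

where the SNV block is additively coded (0/1/2 copies of the minor allele)
and the CNV block is dichotomized (1 = gain or loss, 0 = unchanged), and
tests the whole unit jointly under a generalized linear model
$g(E[Y_i]) = G_i\beta + Z_i\alpha$ with non-genetic covariates $Z_i$. The
two platforms enter one score test on equal footing: the collective effect
is tested, not the interaction term.

The pipeline has two stages:

1. **Gene-level screen.** Every gene's combined matrix is tested; genes
   with (optionally multiplicity-adjusted) p-values below `gene_alpha`
   become candidates.
2. **Moving-window co-localization.** Candidate genes are tiled with
   windows (default 0.5 kb, step = width) and each window's combined
   matrix is re-tested, alongside SNV-only and CNV-only versions for the
   skyline comparison. Windows with combined p below `window_alpha` are
   the co-localized regions.

Screening only ever affects *which* windows are examined, never the value
of any statistic; a one-stage mode (`one_stage = TRUE`) scans every gene
directly and is the method of choice when compute cost is no concern.

## The region test

The unit test is an optimal weighted-kernel score test (the SKAT-O
family), written from first principles in this package. With weighted
score vector $S_w = W G^\top (y - \hat\mu)$ and
$R_\rho = (1-\rho) I + \rho \mathbf{1}\mathbf{1}^\top$,

$$
Q_\rho \;=\; S_w^\top R_\rho S_w,
$$

so $\rho = 0$ is the variance-component (SKAT) statistic and $\rho = 1$
the squared weighted burden score. Under the null, $Q_\rho$ is distributed
as a positive mixture of 1-df chi-squares whose weights are the
eigenvalues of $R_\rho^{1/2} W G^\top P_0 G W R_\rho^{1/2}$, with $P_0$
the usual GLM projection $V - VX(X^\top VX)^{-1}X^\top V$. The omnibus
test minimizes the per-$\rho$ p-value over a grid and evaluates the
minimum's null distribution by one-dimensional integration over the
shared burden direction.

Numerical choices, all of which are visible in results (`backend` field):

* **Mixture tails** are computed by numerical inversion of the
  characteristic function. User-facing calls
  (`pvalue_quadform()`) use an adaptive error-bounded integral (absolute
  tolerance `1e-9`); when the adaptive scheme fails (slowly decaying
  oscillatory integrands at very few eigenvalues) a fixed-grid inversion
  with an integrated-by-parts tail correction takes over; only if both
  fail does a 4-moment (Liu-type) approximation report
  `moment-approx`.
* **The omnibus integral** maps the $\chi^2_1$ mixing variable to (0, 1)
  by its probability transform and uses 64-point Gauss–Legendre
  quadrature on the exact conditional mixture tail. The batch inversion
  shares the amplitude and phase grids across all quadrature nodes, so
  the exact path is cheap enough to be the default everywhere.
* **Weights.** SNV columns get the Beta(1, 25)-density-of-MAF weight
  (computed from the analysis sample, after re-orienting each marker to
  its data-minor allele); CNV columns have no allele frequency, so they
  carry a flat weight of 1. Both are configurable in `test_config()`.
  Note two practical consequences: in a unit mixing common SNVs
  (near-zero Beta weight) with CNV columns, the CNV block dominates by
  construction — the intended rare-variant emphasis, not a bug; and the
  null spectrum of a large unit is dominated by its most rare (hence most
  heavily weighted) markers, so power against a *common* causal variant
  varies strongly with how many rare background markers the unit carries.
  Window-level testing bounds that spectrum, which is one more reason the
  co-localization stage is the informative one.
* **$\rho$ grid** default \{0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1\};
  ties in the minimum are broken toward smaller $\rho$ (more
  variance-component-like). Inside the omnibus integral $\rho$ is capped
  at 0.999 so the $1/(1-\rho)$ scaling stays finite.
* **Degenerate units.** A unit whose columns are all constant in the
  sample returns p = 1 with a warning; monomorphic columns inside a
  polymorphic unit simply contribute zero and keep window coordinates
  stable.

Known limitations: no small-sample (kurtosis) adjustment of the binary
null is applied — with the simulation sample sizes (n ≥ 100 total) the
test is near-nominal but visibly inflated at 50 cases/50 controls,
mirroring the original study's small-sample behavior. The asymptotic null
also ignores the exact case/control split that a permutation null
conditions on, an $O(1/n)$ difference that the test suite accounts for
with a small fixed allowance when comparing against permutation oracles.

## Data model and QC

Coordinates are 1-based closed intervals internally; BED input is
converted from 0-based half-open on read. SNVs map to a unit when their
position falls inside it (closed on both ends, optional `flank_bp`); CNV
segments map by any ≥ 1 bp overlap (`min_overlap_frac` tightens this). A
segment longer than a window therefore legitimately appears in every
window it overlaps, which induces correlated window p-values — expected,
and worth remembering when reading skylines.

QC follows standard practice: markers are dropped when missingness
exceeds 5% or the exact Hardy–Weinberg test (conditional on allele
counts, probability-ordered two-sided) falls below 1e-6; thresholds are
arguments. Remaining missing genotypes are mean-imputed per marker (the
SKAT convention; zero-fill available). Minor-allele orientation is always
recomputed from the data rather than trusted from REF/ALT.

## The synthetic study pool

The simulation harness emulates a biobank-derived marker pool of 21 genes
with fixed per-gene SNV and CNV segment counts (q1 from 2 to 24, q2 from
1 to 10). The real pool it stands in for is access-restricted, so the
generator makes explicit, deliberately simple distributional choices:

* **Gene span 2,000 bp per gene** — four 0.5-kb windows per gene. Real
  genes are longer and their array markers sparser; this compact span
  keeps the full 21-gene × 1,000-replicate study tractable on one CPU
  while preserving what matters for the method: several markers per
  window and multiple windows per gene. Consequences of this choice are
  flagged below.
* **MAF spectrum** uniform on (0.01, 0.5): a rare-variant tail without a
  separate rare/common mixture knob.
* **CNV segments 1–2 kb long** (clipped to the gene), carrier
  probability 0.05: CNVs are kb-scale structural events, so background
  segments typically span several windows.
* **Dependence** is off by default (independent markers). An optional
  latent-Gaussian threshold model adds LD blocks for SNVs
  (`ld = list(block_size, r)`) and, via `cnv_r`, a shared per-gene factor
  for CNV carrier status — overlapping segment calls in real data largely
  share carriers, so independent Bernoulli status is the optimistic
  extreme, not the realistic default, for the *comparator* analyses (see
  below).
* **Causal placement.** The causal SNV–CNV pair sits inside the first
  window of the first gene (the causal segment is exactly that window);
  a second pair for two-region settings occupies the last window.
  Causal frequencies default to MAF 0.05 / carrier 0.05 and are exposed
  as parameters, swept in the operating-characteristic tests.

Disease status follows the logistic model
$\mathrm{logit}(p_i) = \beta_0 + \beta_1\,\mathrm{SNV}_{1i} +
\beta_2\,\mathrm{CN}_{1i} + \beta_3\,\mathrm{SNV}_{1i}\mathrm{CN}_{1i}$
(plus a $\gamma$-term region in Part B), with the *generative* SNV coding
dominant (carrier indicator) while the *analysis* matrices keep the
additive 0/1/2 coding — the mismatch is intentional and mirrors the study
design. The intercept is interpreted on the probability scale:
$\beta_0 = \mathrm{logit}(0.01)$ so baseline prevalence is 1%; a literal
reading ($\beta_0 = 0.01$, implying prevalence ≈ 0.5) is preserved behind
`beta0_literal = TRUE` for auditing. Cases and controls are accrued by
resampling pool individuals with replacement until each group is full,
with an explicit draw budget and diagnostics.

## Metrics and the two window-scan modes

`evaluate_methods()` reports per method × setting: gene-level and
region-level false-positive rates, true-positive rates (causal units) and
true-negative rates (non-causal units), averaged over replicates, with
binomial standard errors. Window denominators count every non-empty
window of every gene.

The region-level *null* rate deserves care. In the two-stage procedure
(`window_scan = "screened"`) windows of unscreened genes are never
flagged, so the all-null region rate is roughly the gene rate times the
conditional probability that a window follows its (falsely) significant
gene — a strongly geometry-dependent quantity. The *standalone* size of
the window-level test (`window_scan = "all"`: stage 2 applied to every
gene) is the geometry-robust operating characteristic, tracks the
gene-level rate's sample-size pattern, and is what the acceptance script
reports for the all-null settings; the two-stage mode is used for power
and specificity under signal, where screening is part of the procedure
being evaluated.

What passing the bundled simulation checks does *not* show about real
data: the compact gene span makes windows denser in markers than
array-genotyped biobank genes, which (a) raises the union-rule baselines'
window-level noise floor far above its real-data level, and (b) makes
window tests behave more like gene tests. Comparisons that hinge on
sparse window occupancy — notably the region-level *power* ranking of the
integrative test against the union baseline — do not transfer from this
geometry and are reported for what they are in the test suite.
Comparator absolute rates also depend strongly on inter-marker
dependence: the ordering checks therefore run on the
strongly-dependent pool variant (`ld = list(block_size = 30, r = 0.98,
cnv_r = 0.98)`), while the integrative test's own calibration is
dependence-robust and is checked on the independent pool.

## Traditional baselines

The union–union (TUU) and intersection–union (TIU) analyses test every
marker separately (GLM score test per column), select genes by "any
marker significant" (union) or "a significant SNV *and* a significant CNV
segment" (intersection), and in stage 2 flag any window containing a
stage-1-significant marker — a union rule on both platforms by
construction. Per-marker α defaults to 0.05 with no multiplicity
correction at either stage; stage-2 reuses stage-1 p-values without
re-fitting. Genes lacking one platform can never pass the intersection
rule.

## Defaults worth knowing

| parameter | default | where |
|---|---|---|
| `gene_alpha` | 0.05, correction `"none"` (simulation); `"benjamini-hochberg"` recommended for real data | `screen_policy()` |
| `window_alpha` | 0.05 (simulation); 1e-4 is the conventional reporting threshold for real-data skylines | `screen_policy()` |
| `window_size_bp` / `step_bp` | 500 / = width (tiling); overlapping windows via smaller step | `screen_policy()` |
| `beta_weights`, `cnv_weight` | (1, 25), 1 | `test_config()` |
| `max_missing_rate`, `hwe_alpha` | 0.05, 1e-6 | `qc_snv()` |
| replicates | 1,000 in the acceptance script; 120–500 in the test suite, with 3-SE tolerances widened accordingly | simulator |

Every run writes a manifest (package version, seed, policy, input
digests — no timestamps), so identical configurations produce
byte-identical outputs.
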