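---
title: "Methods: effect sizes and conservation analysis of the APP promoter PRE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: effect sizes and conservation analysis of the APP promoter PRE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apppre)
```

## Scope

The proximal regulatory element (PRE) is the 30-nt segment at -76/-47 of
the APP gene promoter (transcription start site = +1, no position 0). It
confers cell-type-specific promoter activity and carries overlapping
literal binding sites for PuF (nm23/NDPK), SP1, AP2 and other factors.
`apppre` implements the quantitative workflow around this element:

1. **Effect sizes** for mutant-panel EMSA densitometry and reporter
   ELISA: per-film standardization, one-way ANOVA with a shared error
   mean square, bias-corrected Hedges *g*, the assay-level
   root-mean-square standardized effect (Psi), and Dunnett's multiple
   *t* against wildtype.
2. **Correlation meta-analysis** of paired effect sizes across assays,
   with bootstrap inference and bootstrap-distribution overlap.
3. **Cross-species conservation** of an aligned promoter region:
   taxonomic working weights, per-column information content in bits,
   100-nt window tracks, weighted homology and sequence-logo matrices.
4. A **root-to-tip molecular-clock outlier test** on a rooted phylogeny.
5. **Literal TF-site scanning** of PRE variants against the bundled
   site catalog, and southwestern band-size matching.
6. **Seeded generators** producing inputs with the statistical structure
   each stage assumes.

Computing the multiple sequence alignment, the distance matrix and the
fitted tree themselves is out of scope: those are consumed as aligned
FASTA and newick inputs produced upstream.

## Effect-size model

Raw EMSA band densities live on an arbitrary per-film scale. Within each
film every signal is z-scored, $(x - \bar x_f)/s_f$, removing film
offset and exposure scale; the control (wildtype) standardized value of
the film is then subtracted so that wildtype sits at exactly 0
(`standardize_by_film()`). Reporter ELISA signals are strictly positive;
they are divided by the cotransfection covariate and scaled so the
control mean is exactly 1 (`normalize_ratio()`).

A balanced one-way ANOVA pools the within-group mean square `ms_error`,
which is the shared denominator for every effect size of the assay. The
pairwise standardized difference uses the small-sample gamma correction

$$g_j = \frac{m_j - m_c}{\sqrt{MS_{error}}}\cdot J(n),\qquad
J(n) = \frac{\Gamma\!\big(\tfrac{2n-2}{2}\big)}
{\Gamma\!\big(\tfrac{2n-3}{2}\big)\sqrt{\tfrac{2n-2}{2}}},$$

with $J(3) = 0.797885$ for triplicates. The assay-level effect is the
bias-corrected root-mean-square standardized effect

$$\Psi = J(n)\,\sqrt{\frac{\sum_j (m_j - GM)^2}{(k-1)\,MS_{error}}},$$

which is 0 exactly when all group means are equal and is scaled
comparably to a pairwise $g$. This specific form (spread about the grand
mean over $k-1$, under the same $J(n)$ correction as $g$) was chosen
because it is the only candidate that reproduces all recomputable
published assay-level values from their own columns' means; an F-based
estimator does not, so printed F statistics are deliberately not a
reproduction target. `ms_error_from_g()` is a reproduction utility only:
given one variant's printed (mean, g) pair it inverts the $g$ formula to
recover the column's error mean square; the pipeline itself always
computes `ms_error` from raw replicates.

**Anchoring.** The control's standardized value is subtracted *per
film*. This makes the control group exactly 0 with zero variance, and
the pooled `ms_error` of the anchored table absorbs the control noise
into every other group (each anchored value is a difference of two
z-scores). A consequence worth knowing: the Dunnett stage run on
anchored values is mildly conservative — the anchored-table `ms_error`
counts the control noise a second time — so its family-wise error on
null simulations sits near 0.02-0.03 rather than 0.05. The alternative
(subtracting the control's grand mean only) leaves the control SE
nonzero but makes the stage anticonservative (about 0.08 measured);
per-film anchoring was kept as the stricter reading of the procedure.

**Normality gate.** For ratio assays, residuals of the one-way layout
are tested with Anderson-Darling; if $p < 0.05$ a Box-Cox power
transformation is applied with $\lambda$ maximized on the grid $[-3, 3]$
in steps of 0.01 (via the profile likelihood in `MASS::boxcox`),
$\lambda = 0$ meaning the log. Downstream ANOVA/Dunnett run on the
transformed scale; reported means are back-transformed. Subtractive
(signed) data are never power-transformed.

**Dunnett critical value.** For $k - 1$ comparisons against a shared
control with equal $n$, the comparison statistics are equicorrelated
with $\rho = 1/2$. The two-sided equicoordinate critical value solves

$$\int_0^\infty\!\!\int_{-\infty}^{\infty}
\phi(z)\left[\Phi(z + c\sqrt2 s) - \Phi(z - c\sqrt2 s)\right]^{k-1}
f_S(s)\,dz\,ds = 1-\alpha,$$

with $S = \sqrt{\chi^2_{df}/df}$, computed by nested quadrature and root
finding to absolute tolerance $10^{-4}$ (`dunnett_critical()`). At
$k = 2$ it collapses to the two-sided Student quantile (2.776 at
df = 4), and at $(k=8, n=3, df=16, \alpha=0.05)$ it agrees with a
$10^6$-draw Monte-Carlo multivariate-*t* oracle within 0.01 (both
asserted in the test suite). Values are cached per $(k, df, \alpha)$.

## Correlation meta-analysis

Per-variant $(g_{EMSA}, g_{ELISA})$ pairs — the control contributing
$(0,0)$ — are correlated by the product-moment coefficient. Including
the control pair is the default because it reproduces the published
coefficients; it is configurable. Significance is the bootstrap
sign-crossing fraction: pairs are resampled with replacement $B$ times
(default $10^5$), and $p$ is the fraction of bootstrap coefficients on
the opposite side of zero from the observed one (exact zeros count
half; degenerate zero-variance resamples are skipped and counted). Two
bootstrap distributions are compared by percent overlap of
relative-frequency histograms on 50 equal-width bins spanning the
pooled range — the bin count is a reporting choice recorded in the
output, as the published analyses do not state one.

## Conservation analysis

**Working weights.** Integer base weights (bundled for the 35-species
panel, from 12 for cow down to 1 for opossum) are converted to working
weights $w = 2^{1/\text{base weight}}$ and max-normalized within the
analysis scope so the largest is exactly 1. The printed form of the
conversion equation is typographically ambiguous; the reading
$2^{1/bw}$ was chosen because it yields the described *mild*
down-weighting of over-represented clades (human 0.53 vs opossum 1.0 at
mammal scope) rather than the orders-of-magnitude suppression the
alternatives ($2^{1-bw}$, $(1/2)^{bw}$) would give.

**Information content.** Per column, weighted base frequencies are
formed over non-gap residues (weights renormalized to non-gap rows) and
$R_i = 2 + \sum_b p_b\log_2 p_b$ bits: 2 = fully conserved, 0 =
uniform. No small-sample correction is applied — the maximum is exactly
2 bits by construction. Columns with fewer than two non-gap residues
are flagged undefined and excluded. The SD of $R_i$ is a weighted
bootstrap over species rows (B = 1000, seeded).

**Window track.** Per-column $R_i$ is averaged in a sliding 100-nt
window (roughly the internucleosomal spacing); columns gapped across
all primate rows (e.g. the marsupial insertion inside the PRE) are
skipped, so clade-specific insertions do not dilute the track. The CI
is a *t*-interval over the per-column values inside the window, with an
optional Bonferroni factor for simultaneous clade-level contrasts.
Window centers are reported in promoter coordinates of the reference.

**Homology and logos.** Weighted homology is the weight-averaged
per-column identity to the reference (gap = mismatch; the reference
participates and matches itself), averaged over the region with its SE
over columns. Logo letter heights are $p_b R_i$, summing to $R_i$ per
column. Gaps counting as mismatches is what lets a marsupial insertion
depress mammal-scope homology while information content (computed over
non-gap mass) stays defined.

Reproducing the published clade-level summary numbers requires the
original 35-sequence GenBank download and an external alignment, which
is deliberately out of scope; the suite instead asserts the properties
that do not depend on that input — duplication/weight-halving
invariance, the 100% self-homology identity, the $2\cdot$length bound
on region totals, and conserved-block recovery on synthetic alignments.

## Molecular-clock outlier test

The unrooted tree is rooted on the single edge separating two named
clades (marsupials vs eutherians in the motivating analysis), at the
edge midpoint by default (the published procedure does not state the
placement; the fraction is configurable, and all tip-to-tip path
lengths are preserved regardless). Root-to-tip distances are compared
to their mean $\pm\,t_{1-\alpha/(2m),\,N-1}\cdot SD$, Bonferroni-adjusted
for $m$ comparisons ($m$ = number of tips by default). Tips above the
band are "faster", below it "slower". Because each distance enters its
own mean and SD, the deviations are internally studentized and the band
is conservative — under a pure noisy clock the family-wise flag rate is
below $\alpha$, not equal to it. The test is nevertheless sharp enough
that a single five-fold terminal-branch acceleration on a 35-tip clock
tree is flagged essentially always.

## Site scanning

Catalog sites are literal strings; lowercase letters are 3' context
that extends beyond the 30-nt core into the plasmid sequence
(`pre_plasmid_context()`). Matching is case-insensitive exact substring
search on the forward strand (reverse complement behind a flag, since
the catalog lists forward-strand strings). Variant-vs-wildtype site
diffs are plain set algebra on (factor, site) pairs. Southwestern bands
match a factor when any cataloged molecular weight falls inside the
closed interval band $\pm 10\%$ of the band size.

Two readings of the mutant oligomer table are possible because the
printed variant labels contain a duplicate; the bundled
`pre_mutant_oligos()` keeps the printed labels and assigns the second
duplicate to the missing variant, because under that reading every
published single-string site deletion (PuF, Pax4a, R, GATA2) is
confirmed by the scanner. The published deletion lists are themselves
not exhaustive relative to literal scanning, so tests assert the subset
direction only. The effect-size tables are read positionally
(PRE, M1..M7), which is the order their own statistics require.

## Synthetic generators

All generators are pure functions of their seed.

* `gen_densitometry()`: signal $=$ offset$_f$ + scale$_f\cdot(\mu_j +
  \varepsilon)$ with $\mu_j = \delta_j\sigma$; defaults 8 variants
  (wildtype + M1..M7), 3 films with one lane per variant each
  (triplicate across films, matching the assay design), film offset SD
  0.5, film scale SD 0.1, residual SD 1. Note that film standardization
  plus anchoring attenuates a configured $\delta$ by roughly
  $1/\sqrt2$ (and by the film-SD inflation when effects are large); the
  recovery test pins the pipeline to an independently coded simulation
  oracle rather than to $\delta$ itself.
* `gen_reporter()`: lognormal multiplicative noise around true ratios,
  times an independent uniform positive covariate that normalization
  must divide out.
* `gen_alignment()`: evolves a random ancestor down a fixed nested
  five-clade topology (9 primates, 9 glires, 9 laurasiatherians, 5
  atlantogenatans, 3 marsupials — the sampling structure of the
  35-species panel) by uniform-replacement substitution, default 0.06
  substitutions/site per unit branch; a conserved block (default the
  PRE span) substitutes at a configurable multiplier, and an optional
  marsupial-specific insertion creates primate-gap columns. Base
  weights are set to clade sizes, giving the same
  small-clade-up-weighting shape as the curated panel.
* `gen_tree()`: ultrametric coalescent tree scaled to depth 0.5
  substitutions/site, with optional per-tip terminal-branch rate
  multipliers.

What the generators deliberately do **not** emulate: context-dependent
substitution, indel processes beyond the single configurable insertion,
heteroscedastic densitometry saturation, and between-film correlation.
Green tests on synthetic data therefore demonstrate correctness of the
statistical machinery under its stated model, not robustness to every
feature of real gels or real promoter evolution.

## Numerical choices and problem sizes

* Dunnett quadrature: `integrate` at relative tolerance $10^{-8}$
  (inner) / $10^{-7}$ (outer), root to $10^{-5}$; cached.
* Box-Cox grid $[-3, 3]$ step 0.01; $|\lambda| < 10^{-12}$ treated as
  log.
* Bootstrap sizes: correlation $B = 10^5$ (default; configurable),
  column-SD $B = 1000$, region totals $B = 200$.
* Simulation sizes used by the test suite: 2000 null replicates for the
  family-wise error measurement, 200 replicates for clock-outlier and
  correlation detection rates, 100 runs for window-peak localization,
  $10^6$ draws for the Monte-Carlo Dunnett oracle. These sizes hold the
  Monte-Carlo error comfortably below each assertion's tolerance.
* Degenerate inputs are hard errors, never silent NaNs: zero film SD,
  missing control in a film, zero `ms_error`, $n = 1$, nonpositive
  ratio data, columns with fewer than two residues, position 0 in
  promoter coordinates, non-monophyletic rooting splits.

## Known limitations

* The asymmetric $\pm a/b$ uncertainties printed alongside published
  $g$ values match no single standard formula and are not reproduced;
  the symmetric delta-method SE $\sqrt{2/n + g^2/(2\,df)}$ is reported
  instead.
* Published F statistics are not reproducible from printed means
  (transformation ambiguity) and are not targets.
* One published reporter column (PC12 ELISA) is internally inconsistent
  under the shared-`ms_error` identity — likely analyzed on a
  transformed scale — and is excluded from reproduction assertions.
* The per-film anchoring choice makes the null family-wise error of the
  full densitometry pipeline land near 0.02-0.03 (see above); this is a
  property of the published normalization design, not of the Dunnett
  implementation, which is calibrated under its own model.
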