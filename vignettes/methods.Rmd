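---
title: "Methods: two-phase DMR calling with promoter-border classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-phase DMR calling with promoter-border classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methborder)
```

# Scope and data model

`methborder` starts at CpG count tables — it performs no alignment or
methylation calling.  A sample is a sorted table of
`(chrom, pos, meth, unmeth)` rows, where `pos` is the 0-based position of
the plus-strand C of the CpG.  All coordinates inside the package are
0-based half-open; the Bismark coverage dialect (1-based inclusive) is
converted at the reader boundary, which is the only place an off-by-one can
exist.  Strand-split caller output can be folded onto the plus-strand C with
`merge_strands()`, which strictly validates that minus-strand records sit at
`pos + 1` of a mate and refuses colliding non-mate positions.

The default coverage floor is 5 reads per CpG per sample, applied per
sample before testing; it is the conventional display and analysis floor
for WGBS-class data and is exposed as `min_cov` everywhere.

# Phase 1: per-CpG binomial GLM tests

At one CpG, the two-group contrast is the binomial GLM with logit link

$$\mathrm{logit}(\pi_{ij}) = \beta_0 + \beta_1\,[i = A],$$

tested by likelihood ratio.  Because the only covariate is a two-level
factor, the maximum-likelihood fits are the group-pooled fractions
$\hat\pi_g = M_g / C_g$ under the alternative and the overall pooled
fraction under the null, so the deviance difference is computed in closed
form and vectorised over all sites:

$$G = 2\left[\ell(M_A, C_A, \hat\pi_A) + \ell(M_B, C_B, \hat\pi_B)
      - \ell(M_A{+}M_B,\, C_A{+}C_B,\, \hat\pi_0)\right],
  \qquad p = P(\chi^2_1 \ge G / \hat\phi).$$

The unit tests verify equality of this closed form with
`glm(cbind(meth, unmeth) ~ group, family = binomial)` deviances.

**Boundary fits.**  Groups that are entirely methylated or unmethylated put
$\hat\pi_g$ on the boundary; the log-likelihood remains finite under the
$0\log 0 = 0$ convention, which the implementation applies literally.  No
pseudo-counts enter the statistic.  The reported effect size `delta` does
use Haldane–Anscombe 0.5 pseudo-counts
($\tilde\pi_g = (M_g + 0.5)/(C_g + 1)$), purely to shrink boundary
estimates; `pi_a`/`pi_b` are reported raw.

**Overdispersion.**  Biological variation between replicate cultures makes
counts extra-binomial.  With `dispersion_mode = "auto"` (default) and at
least two replicates per group, the LRT statistic is scaled by
$\hat\phi$ = pooled within-group Pearson $X^2/\mathrm{df}$ of single-rate
site fits, averaged over the two groups and floored at 1.  The floor keeps
an under-dispersed estimate from inflating significance; the design (e.g.
3 vs 6 samples) is exactly the replicated case this is meant for.  With
single-sample groups the scale is 1 (pure binomial) — the test is then
well calibrated only under binomial sampling, and its p-values should be
read as descriptive.

**Filters.**  A sample contributes to a site only with coverage
`>= min_cov` there; a site is tested only when both groups keep
`>= min_samples_per_group` contributing samples (default 1).  Filtered
sites are recorded with reasons in the result's `skipped` attribute and in
the pipeline run log.

# Phase 2: Uniform-Product DMR aggregation

Candidate regions are maximal runs of phase-1-significant
(`p < alpha_site`), same-direction sites in which consecutive significant
members lie within `max_gap` bp; runs with `>= min_sites` significant
members survive.  Defaults `alpha_site = 0.01`, `max_gap = 500` bp,
`min_sites = 3` are conventional for WGBS DMR callers; all are exposed.

Each candidate is scored by the product of its member p-values referred to
the exact null of a product of $k$ independent Uniform(0,1) variables,

$$F(x, k) = x \sum_{j=0}^{k-1} \frac{(-\ln x)^j}{j!}
          = P\!\left(\chi^2_{2k} \ge -2\ln x\right),$$

Fisher's method in its product form.  `uniform_product_cdf()` accumulates
the series in log space (log-sum-exp over terms
$\ln x + j\ln(-\ln x) - \ln j!$) and accepts the log-product directly
(`log_x = TRUE`), so products far below double underflow are handled; the
members' p-values are floored at the smallest positive double before
taking logs.  At log-products below roughly $-745$ the CDF value itself is
smaller than the smallest representable double and underflows to exactly 0,
which BH adjustment treats correctly.  Note that $F(x, k)$ is
*non-decreasing* in $k$ at fixed $x$ — more uniform factors make the
product stochastically smaller.  The test suite checks the series against
the chi-square form to $10^{-12}$ for $k \le 50$ and against Monte Carlo
($10^6$ products per $k$) to $2\times10^{-3}$.

**Which p-values enter the product** is genuinely open.  Combining only the
significant members (`combine_scope = "significant_only"`) is the stricter
reading of a two-phase procedure, but conditioning the product on phase-1
selection makes the uniform null anti-conservative.  The default
`"all_in_span"` therefore combines every tested CpG inside the candidate
span, including interior non-significant sites, which tempers the selection
bias; both modes are implemented and logged.  A second caveat is
independence: neighbouring CpGs are spatially correlated, so $k$ effective
independent p-values are fewer than $k$ sites.  The `effective_k` factor
(default 1 = off) deflates both the member count and the log-product, a
crude Good-style correction left off by default because the right factor is
data-dependent.

BH adjustment runs across candidate regions genome-wide (the region is the
phase-2 inferential unit, and adjusting across all CpGs would double-count
phase 1); regions with `q < q_threshold` (default 0.05) are reported, named
`DMR_0001_hyper` etc., where `hyper` means group A more methylated.

# LMR detection

The LMR contract is "significantly lower methylation than the rest of the
same genome".  The implementation is the simplest auditable procedure
satisfying it: the sample background is the coverage-weighted pooled
fraction $\sum m / \sum c$ (weighted, not site-averaged, to match
pooled-count testing); windows of `window_cpgs = 10` consecutive covered
CpGs slide in steps of one; windows with pooled fraction below
`max_meth_frac = 0.5` of background are flagged; overlapping flagged
windows merge; the merged region's one-sided binomial tail
$P(X \le m)$ at the background rate is computed on its pooled counts, with
BH across merged regions.  Whether published LMR tracks derive from an
HMM-style or threshold-style segmentation is not recoverable from count
data alone; this windowed formulation is a deliberate, parameter-exposed
stand-in for the contract, not a reproduction of any specific published
segmentation.

# Regional comparison and TSS-relative classification

`compare_region()` pools `(meth, unmeth)` over covered CpGs and samples per
side and tests the 2×2 table.  The default branch is Fisher's exact test,
implemented as enumeration of the hypergeometric support with the standard
relative tolerance for "as extreme" ties (probabilities
$\le p_\mathrm{obs}(1 + 10^{-7})$); the suite verifies it against both
`stats::fisher.test()` and an independent `choose()`-based enumeration over
every table with total $\le 50$.  Above 10,000 pooled reads the continuity-
corrected chi-square takes over (the exact enumeration gains nothing
there).  Pooling across samples ignores between-sample variance — adequate
for single-sample-per-side comparisons, and the `method = "glm"` mode
(binomial LRT on per-sample regional totals) is provided when replicates
should count as the unit.

TSS-relative offsets are signed with upstream negative on either strand
(`pos - tss` on plus, `tss - pos` on minus).  Classification of a DMR
against a promoter interval is by occupied base range, so it is invariant
to the half-open encoding: intersecting the promoter gives
`promoter_overlapping`; otherwise the nearest-edge distance within
`border_window = 5000` bp assigns `upstream_border`/`downstream_border`
by TSS-relative side, else `distal`.  The 5-kb default spans the farthest
promoter-border DMRs seen in practice (≈ −5.6 kb) while keeping `distal`
meaningful.

# The simulator: what it emulates, and what it does not

`build_layout()` + `simulate_cohort()` generate the test bed.  The default
layout is one 100-kb chromosome with a TSS at 50 kb, a promoter-core island
at TSS-relative −700..+600 bp, and two planted group-A-hypermethylated DMRs
at −2600..−1500 and +2600..+4600 — an unmethylated core flanked on both
sides, the promoter-border architecture.  CpG positions are laid out
deterministically at 10-bp spacing inside islands and 100-bp outside
(density contrast, reproducible independent of the noise RNG).  Defaults:
3 vs 6 samples, mean coverage 30 (Poisson), background methylation 0.85,
island/core 0.05, DMR levels 0.90 (A) vs 0.15 (B), chosen to mirror the
magnitude of real promoter-border contrasts (~91% vs ~67% and stronger).

Counts are beta-binomial: coverage $c \sim$ Poisson, the site-level rate
$p \sim \mathrm{Beta}$ with mean $\pi$ and dispersion
$\rho = 1/(a + b + 1)$, then $m \sim \mathrm{Binomial}(c, p)$; $\rho = 0$
short-circuits to exact binomial.  The default $\rho = 0.05$ represents
mild replicate-to-replicate biological variation, so the GLM's
quasi-scaling is exercised under its intended misspecification; $\rho = 0$
is used wherever a test needs the exact binomial null.  One master seed
derives per-sample streams (sample $i$ always gets stream $i$), making
cohorts byte-reproducible.

The simulator does **not** model read-level artefacts (conversion errors,
mapping bias, PCR duplicates), distance-decaying spatial correlation of
methylation beyond the piecewise-constant layout, CpG-density biology
(islands are declared, not emergent), or copy-number/coverage waves.
Passing tests therefore demonstrate the statistical machinery under its
stated noise model and under beta-binomial misspecification — not
robustness to every artefact of real libraries.

# Problem sizes and determinism

The shipped tests run the null calibration on 5,000 CpGs (3 vs 6 samples,
coverage 30), DMR recovery on 10 planted DMRs of 10–30 CpGs (coverage 20),
the border fixture on ~1,100 CpGs with 20 replicate simulations for the LMR
check, $4\times10^6$ Monte-Carlo products for the Uniform-Product CDF, and
the exhaustive 2×2 enumeration over all ~316,000 tables with total
$\le 50$ — sizes chosen so the full suite completes in well under a minute
while keeping Monte-Carlo tolerances honest.  The pipeline itself contains
no randomness: given samples and parameters, reruns are byte-identical
(the run log carries no timestamps), and every number in the outputs can be
regenerated by calling the module functions with the logged parameters.

# Known limitations

- Two groups only; no covariates, paired designs, or smoothing across
  sites.
- The Uniform-Product null ignores residual inter-site correlation beyond
  the `effective_k` knob; on strongly autocorrelated methylomes region
  q-values are optimistic.
- Quasi-binomial scaling is a single genome-wide scale, not a per-site
  shrinkage dispersion as in beta-binomial likelihood methods.
- LMR detection is threshold-based windowing, with the shortest detectable
  LMR set by `window_cpgs`.
- `compare_region`'s pooled default treats reads, not samples, as the unit
  (use `method = "glm"` when replicates matter).
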