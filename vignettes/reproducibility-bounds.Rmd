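---
title: "Bounding the reproducibility of discovered biomarker sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounding the reproducibility of discovered biomarker sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reproscore)
```

## The problem and the model

Univariate biomarker discovery — test every feature for a two-class
difference, correct for multiple comparisons, keep what passes — is the
workhorse of differential-expression and GWAS-style analyses, and it is
notoriously unstable: two cohorts of the same design frequently yield
gene lists with little overlap. `reproscore` quantifies that instability
*prospectively*, from a single dataset.

The data model is an $n \times r$ matrix $x_{ij}$ of feature values with
a binary outcome $\ell^{(j)} \in \{+,-\}$ per subject. Feature values
are either all continuous or all genotype counts in $\{0,1,2\}$ (raw
two-letter genotypes are converted to minor-allele counts first). We
assume each feature's values within each class are i.i.d. draws from a
fixed marginal $p_{i,c}(v)$; nothing is assumed about dependence
*between* features. A discovery operator
$\mathrm{BD}_{t,\alpha,\chi}(D)$ returns the features whose two-sided
pooled-variance t-test, corrected by $\chi \in \{\mathrm{BH},
\mathrm{Bonferroni}, \mathrm{none}\}$ across the family of tested
features, falls strictly below $\alpha$ (default $0.05$, BH).

The reproducibility score $\mathrm{RS}(D, \mathrm{BD})$ is the expected
Jaccard overlap $J(A,B) = |A \cap B| / |A \cup B|$ (defined as 0 when
both sets are empty) between the biomarker sets discovered on two
independent *comparable* datasets — same per-class counts — from the
distribution behind $D$. Two resampling estimators bracket it:

* **oRS** duplicates every subject, partitions the doubled multiset per
  class into two full-size halves uniformly at random over the copy
  slots, discovers on both halves, and averages $J$ over $k$
  repetitions. On average half the distinct subjects appear in both
  halves (exactly $n_c/(2n_c-1)$ of a class of $n_c$), so the two
  discovery runs are positively coupled.
* **uRS** does the same with two *disjoint* outcome-balanced half-size
  subsets: per class, $\lfloor n_c/2 \rfloor$ subjects drawn without
  replacement into each side, one leftover per odd class sitting out
  that repetition (a fresh draw each time, so no subject is permanently
  excluded). Halving the sample degrades the stability of discovery, so
  the average Jaccard underestimates the full-size score.
* **bRS** replaces the doubling partition by two independent
  class-stratified full-size bootstrap resamples. Bootstrap pairs share
  more subjects than doubled pairs, so bRS is expected to sit above oRS
  — a looser overbound, which is why the doubling construction is the
  preferred one.

Because uRS's halves are genuinely disjoint same-distribution cohorts,
`rs_hat_half()` reuses it as the truth estimate of the reproducibility
of half-size subsets: that is the quantity the bounds can be validated
against on real data, and `subset_curve()` generalises it to any size
$s \le n/2$ (per-class counts allocated proportionally by largest
remainder; sizes that cannot give two disjoint subsets with at least two
subjects per class are skipped with a warning). On synthetic data the
generating distribution is known, so `rs_star_monte_carlo()` computes
the true score $\mathrm{RS}^*$ directly by simulating fully independent
dataset pairs.

## Parameters that matter

* `alpha` (default 0.05) and `mcc` (default BH): the declaration
  threshold is strict (`p_adj < alpha`). `alpha = 1` is allowed as the
  degenerate declare-everything operator — useful as a thought
  experiment, since it is trivially reproducible (score 1) while being
  scientifically vacuous; the package warns. (Strictness is visible
  only on the measure-zero event `p_adj == alpha`; a zero-variance
  feature with equal means has exactly $p = 1$ and is never declared.)
* `k` (default 50 for the bound estimators, 20 per subset-curve point):
  the number of split repetitions. The reported `sd` is the sample
  standard deviation over the $k$ per-iteration Jaccard values
  (denominator $k-1$), so mean ± sd summarises the estimator's spread,
  not the standard error of its mean.
* `test`: `"t"` is the canonical pooled-variance statistic with
  $df = n_+ + n_- - 2$; `"welch"` is offered as a non-canonical
  alternative for heteroscedastic data.
* `positive`: which outcome label counts as the positive class; default
  the lexicographically larger label. The test being two-sided, every
  result is invariant to this choice (tested).

## Numerical and degenerate-input choices

* Zero pooled variance: the continuity limit of the t formula is taken
  — equal means give $t = 0, p = 1$; unequal means give $t = \pm\infty,
  p = 0$. Constant-in-both-classes features are therefore handled
  without special-casing, and a feature constant at different levels is
  (correctly) always declared.
* Features with fewer than two finite values in a class cannot enter
  the t formula; they are excluded from testing *and* from the
  correction family, whose size is the number of features actually
  tested.
* Missing values are rejected at construction by default;
  `missing = "drop_features"` discards affected features with a
  message.
* Genotype encoding: the minor allele is the one with the lower total
  count in the column; an exact 50/50 tie takes the lexicographically
  later symbol, and a monomorphic column encodes to all zeros. Encoding
  is idempotent on already-numeric input.
* Survival dichotomization: the median is computed once over *all*
  input times (computing it post-removal would be circular); subjects
  with time at or above the median are labeled long-survival, observed
  events below it short-survival, and subjects censored before the
  median are removed as uninformative.
* RNG discipline: repetition $i$ of a run rooted at `seed` uses the
  child seed $((\mathrm{seed} - 1 + 1000003\,i) \bmod 2147483629) + 1$.
  Re-running with the same seed reproduces per-iteration values
  bit-for-bit, and enlarging $k$ extends a run without reshuffling
  earlier repetitions. Child seeds are recorded in reports so any
  single iteration can be replayed.

## What the synthetic generator emulates

`synthetic_spec()` instantiates the i.i.d. marginal model directly: in
continuous mode every feature is Gaussian with class-independent
standard deviation `sigma`, and the `n_true` planted features have
their positive-class mean shifted by `delta * sigma`; in genotype mode
features are $\mathrm{Binomial}(2, \mathrm{maf})$ minor-allele counts
with the planted features' frequency shifted between classes. Gaussian
equal-variance classes are the canonical choice because they are
exactly the regime the pooled t-test assumes; a unit-variance scaled
Student-t option (`dist = "t"`) and an equicorrelated-block option
(`rho`, `block_size`) are provided for robustness experiments and
default off.

What this does *not* emulate: real expression data's heavy-tailed,
heteroscedastic, batch-affected, strongly correlated structure, or
linkage disequilibrium between SNPs. Passing tests on synthetic data
therefore validate the estimators' *mechanics* (their constructions,
determinism, calibration, and mutual ordering in the regimes discussed
below), not the field performance of t-test discovery on any particular
platform.

Default study conditions used by the validation suite, chosen once as
desk-scale versions of a typical two-class design: balanced cohorts of
60–400 subjects, $r = 100$–200 features with 10–20% planted, effects
$\delta \in [0, 3]$ spanning null to saturating signal, $k = 50$
(bounds) and $k = 20$ (curves).

## When the bounds hold — and when they provably do not

The two bound heuristics rest on a premise: *more shared subjects and
larger samples both make the two discovered sets more alike*. That
premise holds when discovery is statistically strained — the regime
real studies occupy — and the package's property tests confirm the
ordering $\mathrm{uRS} \le \mathrm{RS}^* $ and $\mathrm{uRS} \le
\mathrm{oRS}$ there.

In *saturated* regimes (large $\delta \sqrt{n}$, where even half-size
cohorts recover the planted set essentially perfectly) the ordering
inverts, for a quantifiable reason: a doubled or bootstrapped half
contains duplicated subjects, and duplication deflates the
within-group variance estimate relative to its nominal degrees of
freedom. The per-feature type-I error of the t-test inside oRS/bRS
halves is therefore inflated (roughly, the null t acquires variance
$\approx 1.5$ instead of 1 under the doubling construction), each half
picks up a few extra false positives, and — because a subject doubled
in one half is *absent* from the other — those false positives tend not
to be shared. Meanwhile disjoint half-size subsets at saturating power
discover nearly clean sets. The result is $\mathrm{oRS} <
\mathrm{uRS} \approx \mathrm{RS}^*$ precisely when discovery is easy,
and the acceptance protocol's full effect grid makes this visible. The
same mechanism explains why exact recovery of a planted set under BH is
not a near-certain event even at huge effects: BH controls the false
discovery *rate*, not the family-wise error, so with 40 null features
the probability that at least one sneaks under the post-discovery
threshold is tens of percent per dataset. Users should read oRS as an
optimistic estimate that is trustworthy in the strained regimes where
reproducibility is actually in doubt, and read uRS — which is free of
duplication artefacts — as the conservative, always-defensible number.

## Known limitations

* Single binary outcome only; no multi-class or continuous outcomes,
  and no mixed continuous+categorical matrices.
* Discovery is strictly univariate: the framework scores the *set*
  returned by per-feature testing and does not consider learned feature
  combinations, fold-change ranking, or cross-size set comparisons.
* The score is a property of (dataset, operator) jointly: changing
  `alpha`, the correction, or the test changes the reproducibility
  being estimated.
* Estimator output at tiny class counts is legitimate but coarse: with
  one subject per class the doubling partition is forced and oRS is
  degenerate; disjoint halving requires at least four subjects per
  class.
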