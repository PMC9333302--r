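# reproscore

How believable is a list of biomarkers? When a study reports that a set
of genes (or SNPs, proteins, ...) separates cases from controls, the
practical question is whether an *independent cohort of the same design*
would yield substantially the same set. `reproscore` attaches a
falsifiable, resampling-based estimate of that set-level reproducibility
to any biomarker set discovered from a two-class labeled data matrix —
without needing a second cohort.

## The framework

A **biomarker discovery operator** `BD_{test, p, chi}(D)` maps a labeled
dataset `D` (n subjects x r features, each subject labeled + or −) to
the subset of features whose per-feature two-sample test, corrected by
the multiple-comparison method `chi`, falls below the threshold `p`. The
canonical operator is `BD_{t, 0.05, BH}`: a two-sided pooled-variance
two-sample t-test,

    t = (X̄₊ − X̄₋) / (s_p · sqrt(1/n₊ + 1/n₋)),
    s_p² = [(n₊−1)s₊² + (n₋−1)s₋²] / (n₊ + n₋ − 2),

with Benjamini–Hochberg correction at α = 0.05.

The **reproducibility score** `RS(D, BD)` is the expected Jaccard
overlap

    J(A, B) = |A ∩ B| / |A ∪ B|     (0 when both sets are empty)

between `BD(D₁)` and `BD(D₂)` for two *comparable* datasets (same
per-class counts) drawn from the distribution that generated `D`. With
only one dataset in hand, `RS` cannot be computed — but it can be
bracketed by resampling:

* **oRS** (overbound): duplicate every subject, randomly partition the
  doubled multiset into two outcome-balanced full-size halves, run
  discovery on both, record the Jaccard score; average over k
  repetitions. The halves share about half their subjects, which makes
  agreement easier than for independent cohorts.
* **uRS** (underbound): the same protocol on two *disjoint*
  outcome-balanced half-size subsets. Halving the sample makes
  discovery less stable than at full size, so agreement is harder.
* **bRS** (bootstrap variant): two class-stratified full-size bootstrap
  resamples per repetition; shares even more subjects than oRS, so it
  is a looser overbound.

`uRS(D)` is also a direct estimate of the true reproducibility of
half-size subsets of `D` (`rs_hat_half()`), which is what makes the
bounds testable on real data; `subset_curve()` traces reproducibility
as a function of subset size; and on synthetic data with known
generating distributions, `rs_star_monte_carlo()` computes the true
score by simulation. A synthetic two-class generator with planted
differential features (`synthetic_spec()` / `generate_dataset()`)
supports all of this, in continuous (expression-like) and genotype
({0,1,2} minor-allele count) modes.

## Worked example

```r
library(reproscore)

spec <- synthetic_spec(n_plus = 50, n_minus = 50, r = 200,
                       n_true = 20, delta = 1)   # 20 planted features, 1-sigma shift
D <- generate_dataset(spec, seed = 42)

discover(D)
#> <discovery_result> BD_{t, 0.05, BH}: 18 / 200 tested features declared biomarkers

jaccard(discover(D)$biomarkers, true_biomarkers(spec))
#> [1] 0.9

reproducibility_report(D, methods = c("oRS", "uRS", "bRS"),
                       k = 50, seed = 1)
#> <rs_report> 100 subjects (50+ / 50-) x 200 continuous features
#>   BD_{t, 0.05, BH}: 18 biomarkers on the full dataset
#>   oRS    0.658 +/- 0.060  (k = 50)
#>   uRS    0.426 +/- 0.095  (k = 50)
#>   bRS    0.514 +/- 0.080  (k = 50)
#>   seed 1
```

Read it as: the 18-feature set found on the full data would overlap a
replication set with a Jaccard score somewhere between roughly 0.43
(pessimistic: what half-size cohorts achieve) and 0.66 (optimistic:
overlapping full-size resamples) — informative, but far from perfectly
reproducible. Results objects have `tidy()` / `glance()` methods, and
subset-size curves have an `autoplot()`.

The same workflow runs from a shell on any delimited file with an
outcome column:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "reproscore.R", package = "reproscore"))')" \
  --input data.csv --outcome-col outcome --methods oRS,uRS --k 50 \
  --seed 1 --output report.json
```

The JSON report (schema in `inst/schema/`) records per-iteration values
and per-repetition child seeds, so any run is exactly regenerable from
(input, configuration, seed).

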