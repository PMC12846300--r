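---
title: "Methods: permutation CDF statistics and RF concordance for small serum cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation CDF statistics and RF concordance for small serum cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serumsig)
```

## The problem

Label-free LC–MS/MS of depleted serum yields a peptide-by-sample
intensity matrix in which a substantial fraction of entries is missing,
mostly because low-abundance peptides fall below the detection limit
(missing **not** at random). In a discovery cohort of six cancer and six
control sera there is no room for asymptotics: mean-based statistics are
distorted by left-censoring, and after imputation the per-sample
intensity distributions can turn bimodal, invalidating t-test normality.
`serumsig` therefore combines left-censored imputation with conservative
coverage filtering and a nonparametric, permutation-calibrated
significance statistic, cross-checked by a machine-learning ranking.

## Imputation model and its assumptions

For each sample (column) with observed mean $\mu$ and SD $\sigma$ on the
log2 scale, every missing entry is replaced by

$$X_{\text{imputed}} = \mu - d\,\sigma + w\,\sigma\,\varepsilon,
\qquad \varepsilon \sim N(0,1),$$

with downshift $d = 1.8$ and width $w = 0.3$ by default — a narrow
distribution centred well below the bulk of observed intensities. The
assumption is precisely the MNAR mechanism: what is missing was too low
to detect. Two numerical choices matter:

* each sample is imputed independently, preserving its own distribution;
* the random draws consume a single RNG stream in column-major order
  (missing cells in row order within each sample), making results
  byte-reproducible for a fixed seed and insensitive to how other columns
  are filled.

A column with fewer than two observed values has no defined $\sigma$;
the function refuses it rather than guessing. Observed cells are never
touched (asserted bit-exactly in the tests). When the missing fraction is
large, the imputed population becomes visible as a second low-intensity
mode; `intensity_histograms()` emits the observed/imputed histogram data
that make this visible, and the coverage filter below is the remedy.

## Coverage filtering and its accounting

`filter_min_samples()` keeps a peptide only if it has at least
`min_samples` **observed** values in the control group *and* in the
cancer group. Imputed values never count toward coverage — the missing
mask survives imputation for exactly this purpose — and the filter runs
*after* imputation so that the removal accounting can split removed
entries into observed and imputed parts. Because the filtered matrix is
complete, removed values = removed peptides × samples, an identity the
`filter_report` constructor enforces. The report exposes two distinct
observed-value ratios for the retained set (fraction of retained entries
that are observed; fraction of all observed entries retained) because the
two are easily conflated when summarizing a filtering step.

Duplicate rows of the same peptide sequence (verbatim string, including
flanking-dot notation like `K.AETGDKVYVHLK.N`) are then collapsed by
arithmetic mean on the log2 scale, metadata taken from the first
occurrence. Collapsing is idempotent, and on a complete matrix the whole
impute→filter→collapse chain reduces to filter→collapse (a property
test).

## The permutation CDF statistic

For one peptide with intensities $x_1,\dots,x_n$ and labels
$y_j \in \{0,1\}$ (1 = cancer), sort samples by ascending intensity and
let

$$\mathrm{CDF}_{\text{real}}(j) =
  \frac{\sum_{k \le j} y_{(k)}}{\sum_{k=1}^n y_k}.$$

Under no association, shuffling the labels over the fixed intensity
ordering generates the null. With $B$ shuffles (default 1000), the
statistic is

$$S = \max_{j} \frac{\lvert \mathrm{CDF}_{\text{real}}(j) -
  \mu_{\text{surr}}(j)\rvert}{\sigma_{\text{surr}}(j)},$$

the maximum deviation in null-SD units. Bands: $S \ge 3$ high,
$2 \le S < 3$ moderate, $1 \le S < 2$ low, $S < 1$ non-significant.

Numerical choices, each deliberate:

* **Ties** in intensity are broken by original sample order (stable
  sort); monotone-transform invariance is exact on tie-free data, which
  continuous intensities are with probability one.
* **Vacuous positions**: at $j = n$ every CDF equals 1, so numerator and
  null SD both vanish; positions with $\sigma_{\text{surr}} <$
  `sigma_floor` (default 1e-12) are skipped. This removes the 0/0 without
  touching informative positions.
* $\sigma_{\text{surr}}$ uses the $n-1$ denominator across surrogates.
* **Shuffling samples with replacement** among orderings, so the real
  labeling may reappear among surrogates — plain label shuffling, no
  exclusion. `exact_mode` instead enumerates all
  $\binom{n}{n_1}$ distinct assignments once (924 for a 6/6 cohort) and
  is the oracle the sampled mode is tested against (agreement within
  0.15 at $B = 20{,}000$ on $n = 12$ fixtures).
* **One surrogate set per table**: the null depends only on the label
  multiset, never on a peptide's values, so `cdf_significance()` shares
  the surrogate moments across all peptides. This is statistically
  identical to per-peptide shuffling and makes a table run reproducible
  from one seed.

No analytic p-value is attached to S and no multiple-testing correction
is applied: the banding *is* the inference, and the attainable maximum of
S grows with $n$ (about 2.9–3.3 is the practical ceiling at $n = 12$), so
bands should be read as cohort-specific evidence grades, not universal
probabilities.

## Random-Forest concordance

`loocv_rf()` runs leave-one-out cross-validation: for each of the $N$
samples a forest (default 100 trees, $\sqrt p$ features per split,
unlimited depth, bootstrap on) is trained on the remaining $N-1$ and the
held-out cancer probability recorded. Pooled probabilities feed the ROC
(threshold sweep + trapezoid; provably equal to the pairwise rank
statistic with ties counted half, and property-tested against an $O(n^2)$
oracle) and the per-patient TP/TN/FP/FN assignment (probability ≥ 0.5 is
a cancer call, boundary inclusive). Per-feature Mean-Decrease-Gini is
averaged over folds; `rank_concordance()` summarizes top-$k$ overlap and
Spearman correlation with the S ranking. The forest is a concordance
check on peptide relevance, not the primary inference — no tuning, no
alternative learners.

A caution learned from the separable-case tests: with very few samples
and many pure-noise features, forests can reach node purity through noise
splits before ever consulting an informative feature, leaving held-out
votes near 0.5 even when a perfectly separating peptide exists. The
qualitative "wide-margin separable" behavior (all folds correct) is
exercised at small feature counts where split sampling reliably finds the
separator.

## Protein-level evidence

`aggregate_proteins()` counts, per protein, peptides with $S$ strictly
above the threshold (default 2, matching the reading of "exceeding" as
strict), total detected peptides, their ratio (exact, rendered to at most
three decimals so printed values reproduce from the counts), and the
maximum S. *Strong evidence* requires at least two significant peptides
and at least two detected peptides. Peptides mapping to multiple proteins
raise an error rather than double-count — the supported mapping is
one-to-one. `cross_validate_maldi()` flags proteins independently
identified in the gel-based MALDI-TOF/TOF arm, comparing UniProt
`accession|entry` strings verbatim.

## 2D-DIGE screening

`screen_spots()` applies the conjunction: presence in ≥ `min_presence`
of `n_gels` gels (defaults 24/33), t-test $p < 0.05$, and a fold-change
clause. DeCyder average ratios are signed linear fold changes with no
values in $(-1,1)$, so the default clause $|r| \ge 2$ is a true two-fold
change; a `log2` mode thresholds $|\log_2 |r||$ instead for users who
prefer that formula. The two conventions genuinely disagree (e.g. a spot
at $-2.52$ passes the linear two-fold rule but has $|\log_2|$ only
≈ 1.33), which is why both are provided and the choice is explicit.
`spot_t_test()` is the pooled-variance Student form by default (Welch
optional), with the degenerate both-constant case mapped to $p = 1$ when
means agree. The dual-parameter prioritization places its confidence
threshold at the inclusive lower-third order statistic
`sort(score)[ceiling(n/3)]` of the chosen identification score; published
thresholds of this kind are generally not recoverable from a handful of
scores under any standard quantile definition, so the rule is fixed,
simple and documented rather than fitted.

## What the synthetic generator does and does not emulate

`generate_cohort()` draws per-peptide baseline means from
$N(\texttt{base\_mean\_log2} = 20,\ \texttt{base\_sd\_log2} = 2)$, adds
within-peptide noise $N(0,\ \texttt{noise\_sd\_log2} = 1)$ (the spread
field of the cohort description was split in two because a single SD
cannot control both between-peptide dispersion and replicate noise),
shifts a `frac_differential` = 10% subset by `effect_size_log2` = 2 in
the cancer class, duplicates a configurable number of rows with
independently redrawn intensities, and censors each entry with
probability $\mathrm{logit}^{-1}(s\,(m - x))$, midpoint $m = 17.5$ and
steepness $s = 1$. The midpoint was set by numerically integrating the
dropout curve against the marginal intensity distribution so the expected
missing fraction is ≈ 0.19, the scale of real depleted-serum data;
realized fractions land within a point or two of that across seeds.

The generator emulates: dimensions (286 peptides × 6+6 samples), MNAR
direction (missing entries have lower latent intensity than observed
ones — the uncensored matrix is returned so tests can assert this),
duplicate rows, and a truth flag per peptide for recovery tests. It does
**not** emulate peptide–peptide correlation within proteins, heteroscedastic
noise, batch effects, retention-time structure, or identification error.
Passing recovery tests therefore demonstrate that the pipeline detects
location-shift signal under MNAR censoring at realistic dimensions — not
that it is robust to every artifact of real spectra.

## Problem sizes and determinism

Default analyses use $B = 1000$ surrogates and 100 trees per fold;
property tests run at $B$ = 300–20,000 and cohorts of 25–306 rows, sizes
at which the full suite completes in seconds on one core. Every stochastic
stage takes an explicit seed; `run_pipeline()` derives per-stage seeds
from a master seed and the stage name (so inserting a stage never
perturbs another's stream) and writes a manifest with parameters, seeds,
stage counts and output checksums — two runs with the same configuration
are byte-identical.

## Known limitations

* The S statistic's scale depends on $n$; bands are not comparable
  across cohort sizes.
* The coverage filter assumes the two groups are meaningfully sized
  (thresholds 2–4 against groups of 6); it refuses thresholds above a
  group size rather than degrading.
* LOOCV with $n = 12$ has high variance; AUC values from it should be
  read as qualitative support, which is exactly how the concordance
  analysis uses them.
* Multi-protein peptides are rejected, not apportioned; protein
  inference (parsimony grouping) is out of scope.
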