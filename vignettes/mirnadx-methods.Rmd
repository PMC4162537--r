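---
title: "mirnadx: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirnadx: models, calibration, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirnadx)
```

This vignette is the package's own account of its science: the
measurement models it assumes, what the synthetic-data generator does
and does not emulate, the numerical conventions, and the places where
the design was genuinely open and a choice had to be made. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The analysis problem

A hepatic small-RNA profiling study of the kind this package targets
measures each specimen twice: total RNA is sequenced (counts per mature
miRNA, ~2.2 million reads per sample of which roughly 57% are
assigned), and — for a subset of specimens — hybridized to a
microarray whose background-corrected probe signals are averaged per
mature miRNA. Three questions follow, and the package implements one
module per question:

1. **Do the platforms agree?** Pearson correlation of log expression,
   per sample and — more importantly for biology — per sample *pair*
   (differences of log expression), restricted to miRNAs with strictly
   positive values on both platforms.
2. **Does the NGS profile diagnose the tumor?** Unsupervised PCA-based
   outlier selection of `M` miRNAs, PCA embedding of samples on those
   miRNAs, Fisher LDA on `M′` scores, leave-one-out cross-validation.
3. **Which individual miRNAs differ, and which novel candidates are
   real?** Exact Wilcoxon rank-sum tests; the >80%-probability /
   ≥4-samples retention rule for discovery-tool candidates.

## 2. Normalization conventions

* **Log base 10, pseudocount 0.** The log base is not dictated by the
  method (correlations are base-invariant); base 10 is used because the
  data's dynamic range is naturally described in decades (close to
  five). With pseudocount 0, non-positive values have no logarithm and
  become missing, and the correlation routines drop them pairwise while
  reporting how many values were used. A positive pseudocount is
  supported (`log_config(10, 1)`) and is the default *inside the
  classification pipeline*, where PCA needs a complete matrix.
* **Per-sample z-scoring** uses the n−1 (sample variance) denominator
  and errors loudly on constant columns. It is idempotent and invariant
  to per-sample affine rescaling; both properties are tested.
* **Order of operations.** Whether z-scoring is applied to raw or
  log-scale values is a genuine open point in this family of analyses;
  ranks are unaffected within a sample either way. The pipeline default
  is log10(count + 1) then z-score — the log first keeps the dominant
  miRNA (which can absorb a double-digit share of all reads) from
  dictating every column's scale — and both orders are available
  through the public functions.
* **Positive common subset.** "Non-negative in both platforms" admits
  zeros, but a zero has no log; the default rule keeps strictly
  positive values in both matrices (`rule = "positive"`), with the
  literal non-negative variant available for use together with a
  pseudocount.

## 3. The synthetic world

The generator (`generator_config()` and `simulate_*`) is a stated
world, not a fitted model. Its purpose is to let every downstream stage
be exercised, at realistic scale and noise, without any external data.
Structure and anchors:

| parameter | default | anchor |
|---|---|---|
| `n_tumor` / `n_control` | 14 / 6 | the emulated study design (confusion tables have the same shape) |
| `n_array_tumor` | 11 | only part of the tumors were arrayed |
| `mean_library_size` × `mapped_fraction` | 2.2e6 × 0.57 | reads per sample and assigned fraction |
| baseline log abundance | Exponential(mean 1.8), natural log | right-skewed heavy tail; ~4.5–5 decades of dynamic range |
| `sample_effect_sd` | 0.6 | biological specimen variation; see calibration below |
| `nb_dispersion` | 0.2 | typical NB overdispersion for bulk counts |
| `n_diff`, `log2_fold_changes` | 11 effects, 1.5–2.5, mixed sign | planted diagnostic signal |
| `probe_affinity_sd` / `array_noise_sd` | 3.0 / 0.5 | calibrated to the ≈0.6 cross-platform regime |
| `replicate_noise_sd` | 0.05 | technical jitter; replicate r > 0.97 |

Three modelling decisions deserve explanation:

* **The abundance distribution is right-skewed on the log scale**
  (exponential), not symmetric. This is what hepatic small-RNA
  libraries look like — a handful of dominant miRNAs over a dense bulk
  of rare ones — and it matters for the method: per-sample z-scores of
  a *symmetric* abundance distribution make the rarest miRNAs exactly
  as outlying as the most abundant, and the PCA-distance selection then
  fills up with uninformative low-count rows. With the skewed baseline
  the profile outliers are the dominant miRNAs, which is the regime in
  which this selection rule is useful at all.
* **The planted differential miRNAs are the most abundant ones**, and
  the default effect vector puts the negative fold changes on the most
  abundant of them. This mirrors the liver: the dominant hepatic
  miRNAs (the miR-122-5p / miR-21-5p class) are precisely the known
  HCC-relevant ones, and the most abundant of all is down-regulated in
  tumors. It is also the world in which an outlier-based selection can
  recover a planted signal — a generator that scattered its effects
  over rare miRNAs would be testing a different method.
* **Microarray error has two components.** A per-probe *affinity
  offset*, constant across samples (sd 3.0 natural log — probe
  affinities genuinely span orders of magnitude), plus per-measurement
  noise (sd 0.5). The decomposition is what makes the single-sample and
  differential cross-platform correlations sit near the *same* value
  (≈0.6): affinity offsets depress the former but cancel exactly from
  per-miRNA differences between samples.

**Calibration.** `array_noise_sd`, `probe_affinity_sd`,
`replicate_noise_sd` and `sample_effect_sd` are defined as calibrated
parameters. Three stated regimes pin them jointly: (i) mean per-sample
cross-platform log correlation ≈ 0.61; (ii) mean differential
correlation in the same band (measured 0.58); (iii) two-sided rank-test
power ≥ 0.9 for a planted |log2FC| = 2 at 14 vs 6. Larger biological
variation raises (ii) but destroys (iii); the defaults
(`sample_effect_sd = 0.6`, `array_noise_sd = 0.5`,
`probe_affinity_sd = 3.0`) satisfy all three, and the acceptance suite
re-measures them on every run. Technical replicates are Poisson
re-draws around the observed counts with small log-normal jitter — no
biological redraw, because replicates share the specimen — and their
log correlations come out at 0.97–0.995, bounded below by shot noise on
low-count miRNAs rather than by the jitter parameter.

**What a green test does not establish.** The generator has no
sequence content, no mapping ambiguity, no GC or length bias, no batch
structure, no correlated miRNA families, and its unmapped reads exist
only as a budget scaling. Passing the planted-recovery criterion shows
the pipeline machinery recovers a strong, abundance-coupled signal of
the stated size; it does not reproduce any real study's miRNA list,
AUC, or printed correlations, which require the original deposited
data.

## 4. Numerical and statistical conventions

* **Wilcoxon rank-sum.** Statistic = rank sum of the first group with
  midranks. Exact p by full enumeration of all `C(n, n1)` assignments
  for combined n ≤ 14 without ties (so every 7-vs-7 or smaller design
  is exact); beyond that, normal approximation with tie correction and
  0.5 continuity correction. Two-sided p = min(1, 2·min(tails)). The
  suite checks the exact path against an independent distribution-based
  oracle for *every* attainable statistic at every n₁, n₂ ≤ 7, and the
  approximate path against the reference implementation under heavy
  ties.
* **Fisher exact, one-sided.** Full enumeration of the (1,1)-cell
  support from binomial coefficients; the tail is taken on the side of
  the observed association (relative to the cell's conditional
  expectation). A zero margin fixes the table and returns p = 1 — this
  arises in practice when a degenerate classifier predicts one class
  for every sample. The printed worked example `[[12,0],[2,6]]` gives
  91/125970 ≈ 7.224 × 10⁻⁴.
* **AUC** is the Mann–Whitney rank form (ties count ½), so it equals
  the probability a random tumor outscores a random control.
* **PCA.** Base-`svd` on the column-centered matrix; deterministic
  sign convention (each axis's dominant loading is positive).
  Rank-deficient input is allowed — surplus axes carry zero scores —
  matching the behaviour of standard PCA implementations.
* **Outlier selection** breaks distance ties by lexicographic miRNA
  id, making the selection a pure function of the coordinate values.
* **LDA.** Pooled within-class covariance with ridge fallback
  (λ = 1e-6 · trace/dim) if singular; identical class means degrade to
  a majority-class rule with a warning; a singleton training class
  contributes zero covariance weight, which keeps leave-one-out folds
  of minimal (2 vs 2) designs fittable.
* **Priors.** The discriminant cut-point uses *training class
  frequencies* by default (`prior = "proportional"`), the convention of
  standard LDA implementations and the sensible default for an
  imbalanced 14-vs-6 diagnostic design; `prior = "equal"` is one flag
  away. This is a deliberate deviation from an equal-priors default:
  with near-zero class separation an equal-prior rule classifies at
  coin-flip rates, whereas the proportional prior anchors degenerate
  predictions to the majority class — the behaviour every permutation
  null expects of a sane classifier.
* **Feature selection and cross-validation.** The PCA embedding and
  distance rule never see labels, so the selection is computed once on
  all samples; there is no label leakage to the held-out sample. The
  sample embedding and the discriminant *are* refit in every fold, and
  the held-out sample is projected into the fold's score space.

## 5. The permutation-null criterion, left red

One acceptance test is intentionally failing. It demands that mean
LOOCV accuracy under label permutation be *centered on the
majority-class rate* (0.70 for 14 vs 6) within 3 standard errors over
50 permutations. Measured: 0.680, sd 0.040, i.e. ~2 points below, just
outside the ±0.017 band. The shortfall is a real and well-understood
property of leave-one-out cross-validation, not leakage: removing a
sample shifts its own class's training mean *away* from it, biasing the
fold against the held-out sample; and the proportional prior anchors
only ~90% of degenerate predictions to the majority class. The
leakage-relevant direction — permuted accuracy must not *exceed* the
majority benchmark — passes with wide margin. We report the criterion
as specified rather than weakening it; with equal priors the same
criterion would sit near 0.5 and fail far more severely.

## 6. Known limitations

* The classifier assumes a complete (no-missing) expression matrix;
  zeros are handled by the pipeline's pseudocount, not by imputation.
* Candidate identity for the novel-miRNA filter is exact coordinate
  equality; overlap-based merging of near-identical loci is out of
  scope.
* The Agilent reader accepts a simplified single-table dialect, not
  full multi-section feature-extraction exports.
* The whole pipeline is two-class; multi-class LDA is not implemented.
* Whether the probability bar of the candidate filter must hold in
  *each* counted sample or merely once is ambiguous in the field's
  usage; the default is the stricter per-sample reading, with
  `mode = "any"` for the laxer one.
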