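---
title: "Methods: developmental analysis and synthesis of mouse USV repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: developmental analysis and synthesis of mouse USV repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usvrep)
```

# Scope and data model

Mouse pups emit ultrasonic isolation vocalizations when separated from
the nest; adults vocalize in social encounters. Both produce discrete
*syllables* — silence-delimited frequency-time contours — organised into
*bouts*. `usvrep` analyses annotated syllable tables (it performs no
audio detection): one row per syllable with onset/offset times,
per-element dominant-frequency measurements at the start (+2 ms),
center and end (−2 ms), a reversal count, a spectral-purity label
(tonal / harmonic / nonlinear), an optional fundamental frequency for
harmonic stacks, and a broadband-noise flag.

A syllable has 1–3 *elements*: step-separated components with no silent
gap between them. The reversal count (directional frequency changes
greater than 6 kHz) is an annotated input, not recomputed: the
three-point tracks carried by the table cannot resolve two reversals,
exactly as in manual spectrogram annotation.

# Classification

Eleven syllable types are recognised: complex, 1-frequency-step,
2-frequency-step, up-FM, down-FM, flat, short, chevron, reverse
chevron, low-frequency harmonic (LFH) and noisy. Harmonic content and
nonlinearities are per-syllable attributes, not types.

The published type definitions are criteria, not an algorithm: several
can hold simultaneously (a 4 ms syllable with a 30 kHz step is both
"short" and "stepped"). `classify_syllable()` therefore applies a fixed
precedence ladder — LFH (fundamental < 5 kHz), noisy, short (≤ 5 ms),
2-step, 1-step (steps ≥ 10 kHz between element centers), complex
(≥ 2 reversals), chevron, reverse chevron, up-FM, down-FM (≥ 6 kHz
criteria), then flat as the residual — so that classification is a
total, deterministic partition. Structural rules precede shape rules
because they reference discrete annotation structure rather than
thresholded contour geometry. Two consequences worth knowing:

* a syllable that is simultaneously short and stepped is labelled
  *short* (the duration rule defines its own type);
* multi-element records whose steps are all below 10 kHz are treated as
  one concatenated track and classified by the shape rules;
  sub-threshold steps are treated as annotation noise.

All thresholds are inclusive as printed: modulation of exactly 6 kHz
satisfies the FM/chevron rules, duration of exactly 5 ms is short, a
step of exactly 10 kHz qualifies.

One derived quantity needs a convention: the table's per-syllable
`dominant_khz` is the center frequency of the *first* element for
stepped syllables (and of the only element otherwise). The element
blocks carry no durations, so "the longest element" is not computable
from the interchange format; the first element is the stable choice and
matches how stepped syllables are described (the syllable "starts at"
its leading component).

# Bout segmentation

Inter-syllable intervals are silent gaps — next onset minus current
offset — formed within an animal/session, never across. Intervals below
a 5000 ms analysis window are summarised (sample SD, n − 1), and the
bout criterion is `mean + 2 SD`; with the pooled all-age statistics
(mean 337.8 ms, SD 616.0 ms) this gives the standard 1569.8 ms
threshold. Comparison is strict (`gap < threshold` keeps a bout
together), a single global threshold is used for all ages, and runs
shorter than 3 syllables are returned as *discards*: excluded from bout
statistics but retained for repertoire-level censuses, which is why
syllable totals can exceed bout-syllable totals.

# Repertoire statistics

* **Zipf slope** — OLS slope of log count on log rank (natural logs;
  base-invariant). Zero-count types are excluded, rank ties break
  alphabetically. Exact `1/rank` counts give −1 and uniform counts give
  0 to machine precision; these are analytic anchors in the tests.
* **Proportion test** — `stats::chisq.test` goodness-of-fit against the
  uniform model over observed types (the maximum-entropy "random
  model"; the source analysis does not specify another null).
* **Pair table / independence** — overlapping consecutive pairs within
  bouts of *more than three* syllables, never across bout boundaries.
  The independence statistic compares observed pairs with the product
  of first- and second-position marginals; zero-marginal rows/columns
  are dropped with a warning and df is `(r−1)(s−1)` over the retained
  table. The df actually analysed is reported rather than asserted
  against any historical value, which is not derivable without the
  original retained-type count.
* **Switching probability** — 1 minus (repetitions / total pairs).
* **Censuses** — fractions of syllables with dominant frequency above
  100 kHz (the approximate upper limit of adult mouse hearing) and with
  *all* energy above 100 kHz; purity fractions per age. Fractions are
  kept at full precision and rounded only for presentation.
* **Descriptive statistics** — mean, sample SD, median,
  normal-approximation 95% CI, and Fisher excess kurtosis by the
  sample-moment estimator `m4/m2² − 3` (normal → 0; `{0,0,1,1}` → −2
  exactly). Groups with fewer than 4 observations or zero variance
  report kurtosis as `NA`, never a fabricated number.

# Sequence entropy

Orders are defined by context length plus one: `H0 = log2(c)` over the
`c` observed types, `H1` is the Shannon entropy of type frequencies,
and `Hm` (m ≥ 2) is the plug-in conditional entropy of a syllable given
its `m − 1` predecessors, in bits. n-grams are harvested strictly
inside bouts; bouts shorter than the context are skipped for that
order. Estimates are maximum-likelihood with the `0·log 0 = 0`
convention and no bias correction. The fourth order extends the same
conditional form to three-symbol contexts.

The drop test between orders is
`T = 2 · N · ln 2 · (H_lower − H_higher)`, compared against chi-squared
with df accumulated over the spanned levels: `c − 1` for the 0→1 level
and `c^{j−1}(c−1)²` for level j ≥ 1 (the classical df ladder; the df
table's rows are indexed by the *lower* order of each comparison, which
the non-adjacent rule `df(H1→H3) = (c−1)² + c(c−1)²` confirms).

Two numerical choices make the framework exact rather than
approximate. First, inside a drop test, *both* entropies are computed
from the same n-gram table by marginalising onto suffix contexts: the
entropies then share one joint sample, monotonicity is exact, the
adjacent-order T equals the G statistic (`2 Σ O ln(O/E)`) of the
corresponding conditional-independence test identically, and a
non-adjacent T is the sum of the adjacent Ts it spans — matching the
additive df rule. (The standalone `H1` of a report is still the
all-token unigram entropy; both are reported.) Second, `N` is the
number of harvested n-grams — the sequence positions that actually
enter the table — which coincides with the token count at order 0 and
is what the G identity requires.

For comparisons between repertoires (ages), the classical formulation
admits more than one reading, so both are implemented and labelled as
interpretations: a scaled difference of the two drop statistics
(default), and a pooled likelihood-ratio heterogeneity test
(`(T_a + T_b) − T_pooled`) under `method = "pooled"`. T grows with the
type inventory, so a warning is issued when the two inventories differ
by more than a configurable margin.

# The virtual vocal organ

`fit_profile()` estimates, per age: the bout-initial type distribution
(first-in-bout counts), overall type probabilities, and transition
tables conditioning on the previous 1, 2 and 3 syllables (from bouts
with more than 3 syllables). Terminology caution: the literature
sometimes numbers models by table dimension, calling the
two-syllable-context rule a "third-order" model. This package defines
order = conditioning-context length, so the greedy most-probable-bout
construction (first syllable from the initial distribution, second from
the previous one, each later syllable from the previous *two*) uses
order-2 contexts.

`generate_sequence()` draws pseudo-randomly at order 1–3 with back-off:
an unseen context falls back to the next-shorter context and finally to
the type probabilities. Back-off keeps generation total even though the
fitted tables come from finite data. Ties in the greedy construction
break alphabetically. Generation is bit-reproducible from
`(profile, order, length, seed)`.

`synthesize_bout()` renders sequences as audio: phase-continuous FM
synthesis along a piecewise-linear frequency track, raised-cosine
onset/offset ramps, harmonics as additive partials, syllables separated
by the profile's mean inter-syllable interval (defaulting to the age's
median interval — the robust printed location for right-skewed
intervals). Frequency steps are abrupt, phase-continuous jumps with no
silent gap. The default sample rate is 500 kHz / 16-bit mono, mirroring
the recording chain the annotations describe; 250 kHz halves file
sizes. Templates are parametric, not recorded exemplars; per-age
parameters anchor on reported typical values (adult flat near 76 kHz
for 19 ms, adult chevron near 83 kHz for about 40 ms, pup 2-step
syllables stepping roughly −31/+32 kHz, the adult 2-step reversed and
smaller) and otherwise use representative values within reported
ranges. Deterministic chaos and subharmonics are *not* synthesised;
nonlinear purity is only ever an annotation attribute. Output never
clips: waveforms are scaled to 90% of full scale.

# The synthetic-repertoire generator

`generate_dataset()` exists so every pipeline stage is testable without
recordings. Its defaults are the study conditions; they are not tuning
knobs.

* **Sample sizes** per age are the reported counts (p5 3145, p7 4329,
  p9 6306, p11 4560, p13 3082, adult 6963).
* **Type proportions** follow a rank-frequency power law over the age's
  type ranking (rankings taken from the reported most-common types per
  age; the proportions themselves are published only as a figure, so
  the packaged values are flagged interpolations). For p5 and p13 the
  H0−H1 entropy drop is itself a reported value (1.24 and 0.48 bits),
  and a reported χ²(8) for that comparison implies a 9-type inventory;
  since no exact power law attains the reported slope and the reported
  drop simultaneously, the proportion exponent is tempered (solved by
  `uniroot`) so the profile reproduces the reported drop exactly, while
  the reported slope (−1.97 at p5) remains the packaged rank-frequency
  exponent used in Zipf-recovery experiments. This tension between two
  printed summaries of the same distribution is a documented limitation.
* **Sequencing** uses `calibrate_transitions()`: a diagonal loading of
  the product-form kernel, `P(i→j) = (1−a) p_j + a·1[i=j]`, which keeps
  the stationary distribution at `p` exactly and solves `a` in closed
  form from the target switch probability (reported 0.43 at p5 rising
  to 0.63 at p13; intermediate ages interpolated). Infeasible targets
  (a too-dominant type) raise an error naming the attainable bound.
* **Bout-initial syllables** are flat-weighted (reported 0.46 in
  adults; pup values within the reported 0.32–0.64 range, chosen so
  flat is the modal initial type at every age, as reported; the p5
  value is 0.50 for that reason).
* **Bout lengths** are 3 + negative binomial with the age's reported or
  interpolated mean (24 at p5 down to 11 in adults).
* **Timing** uses log-normal within-bout gaps at the age's reported
  median (capped at 1550 ms, i.e. strictly below the 1569.8 ms
  criterion) and between-bout gaps of threshold + log-normal
  (median 700 ms), so segmentation recovers the generated bouts
  exactly by construction. The two dispersion constants (sdlog 1.05
  within, 0.8 between) were calibrated once, by design-time simulation,
  against the reported pooled interval mean 337.8 / SD 616.0 and then
  frozen.
* **Frequencies** come from a two-component Gaussian mixture per age
  (low mode near 70 kHz, high mode near 100–105 kHz, reflecting the
  described bimodality), with the high-mode weight solved analytically
  from the age's >100 kHz fraction (reported 30.1% at p5, 13.8% at
  p11, 0.6% in adults as a single 78 ± 8.7 kHz mode; other ages
  interpolated). Fixed mode locations are a simplification: in real
  data the modes themselves drift with age.
* **Purity** fractions anchor on the reported values (nonlinear 0.3% at
  p5 → 23.5% at p13; adult harmonic 1.7% / nonlinear 1.6%); pup
  harmonic fractions are interpolated.
* **Element structure** is constructed to invert the classifier: the
  generated annotation re-classifies to the generating type with 100%
  agreement, which the tests assert. Step magnitudes are floored at
  14 kHz and element-center jitter at ±1.5 kHz so the 10 kHz rule
  cannot be crossed by jitter.

What passing tests on these data do **not** show: the generator has no
litter or individual-animal structure, no amplitude information, no
drift of mixture modes within an age, no deterministic-chaos spectra,
and its distributional families (log-normal durations/intervals,
Gaussian mixtures) are artifact choices — real distributions are only
known through histogram shape. Recovery results on synthetic data
validate the *estimators*, not biological conclusions.

# Problem sizes and determinism

All randomness flows through explicit integer seeds; datasets,
sequences and audio are byte-reproducible. The packaged analyses run at
the reported per-age sample sizes (about 28,000 syllables across the
six ages) in seconds; property tests that need asymptotics (transition
recovery at n = 50,000, Markov entropy-rate convergence) state their n
explicitly and use fixed seeds. Known numerical edge cases: degenerate
(single-type) sequences yield zero-width tables, which the entropy code
handles through the `0·log 0` convention and which drop tests report as
T = 0; constant samples report kurtosis as absent; uniform count
vectors make the Zipf fit's r² undefined (reported `NA`).

# Known limitations

LFH syllables are classifiable but excluded from the packaged age
profiles (they sit at the recording chain's low-frequency cutoff and
were not analysed developmentally). The adult "no energy exclusively
above 100 kHz" census is reproduced only approximately (a far tail of
the adult frequency mode can exceed it). Historical chi-squared
magnitudes tied to the original dataset (e.g. the two-syllable model's
10511) are not reproduction targets; only their direction and the
documented identities are.
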