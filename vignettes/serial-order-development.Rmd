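---
title: "Quantifying the development of serial order in child speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the development of serial order in child speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(articudev)
library(dplyr)
```

## The measurement problem

Longitudinal speech corpora record what a child said, month by month, as
phonemic transcriptions. The question this package addresses is *how the
serial ordering of consonants develops*: when do children move beyond
repeating the same consonantal gesture (/papa/, /tata/) to variegated
sequences, and does variegation within one articulatory organ (tongue apex
vs. tongue dorsum) develop differently from variegation across organs
(lips vs. tongue)?

The unit of analysis is the CVC stretch. Every three-symbol window of an
utterance with consonant–vowel–consonant shape, restricted to the eight
stop and nasal consonants that dominate early speech
([p] [b] [m]; [t] [d] [n]; [k] [g]), is classified by the places of
articulation of its two consonants into nine ordered categories (LL, LC,
LD, CL, CC, CD, DL, DC, DD). Windows overlap — C₁VC₂VC₃ contributes both
C₁VC₂ and C₂VC₃ — and extraction deliberately ignores syllable positions:
boundaries and diacritics are stripped first, so cross-boundary sequences
within an utterance count. Vowel identity never enters the measures; only
the CC relationship carries the combinatorial structure of interest.

From monthly category counts the package computes five measures per month:

| measure | definition | range |
|---|---|---|
| repetition | (LL + CC + DD) / total | [0, 1] |
| fronting | (a − b)/(a + b), a = LC + LD + CD, b = CL + DL + DC | [−1, 1] |
| intra-organ | (CD + DC) / total | [0, 1] |
| inter-organ (LC) | (LC + CL) / total | [0, 1] |
| inter-organ (LD) | (LD + DL) / total | [0, 1] |

A month whose defining denominator is zero carries no information about
preference, so it is *absent* from the series, never imputed as zero. The
`min_tokens` argument of `compute_indices()` can additionally drop months
supported by very few relevant tokens; its default of 1 keeps every
month with data, matching an analysis that uses all available tokens.

## The developmental-curve model

Monthly index values are noisy, and the quantities of scientific interest
— when a developmental change starts, how long it takes — live on a smooth
underlying trajectory. The package fits that trajectory with Bayesian
kernel regression.

With observed months $x_1,\dots,x_N$ and values $t_1,\dots,t_N$, one
radial basis function $k(x, x_i) = \exp(-(x - x_i)^2 / 2\sigma^2)$ is
centred at every training month, so the design matrix is the Gram matrix
$\Phi = K$. The weights get a zero-mean Gaussian prior with precision
$\alpha$; observations get Gaussian noise with precision $\beta$. The
posterior over weights is Gaussian with

$$S = (\alpha I + \beta \Phi^\top \Phi)^{-1}, \qquad
  m = \beta\, S\, \Phi^\top t,$$

and the hyperparameters are re-estimated by the evidence-approximation
fixed point: with $\lambda_i$ the eigenvalues of $\beta \Phi^\top \Phi$,

$$\gamma = \sum_i \frac{\lambda_i}{\alpha + \lambda_i}, \qquad
  \alpha \leftarrow \frac{\gamma}{m^\top m}, \qquad
  \beta \leftarrow \frac{N - \gamma}{\lVert t - \Phi m \rVert^2},$$

iterated until both precisions change by less than a relative `tol`
(default 1e-6) or `max_iter` (default 1000) is reached. At a fixed
$(\alpha, \beta)$ the posterior mean coincides with kernel ridge
regression with penalty $\alpha/\beta$ — the test suite verifies this
equivalence against a direct matrix solve. The updates are implemented in
the eigenbasis of $K$ (one symmetric eigendecomposition per fit; every
subsequent iteration is $O(N)$), which is what makes leave-one-out
bandwidth selection affordable.

Design choices that were genuinely open, and how they were resolved:

- **Evidence updates as the estimator.** The iterative
  mean/variance/hyperparameter scheme is instantiated as the standard
  evidence (marginal-likelihood) approximation for Bayesian linear
  regression in a kernel basis. This is an interpretation of a
  procedure that is usually described at pseudo-code level; it is the
  textbook form of "set random hyperparameters, compute the posterior,
  update, iterate".
- **Initialization.** $(\alpha_0, \beta_0)$ are independent draws from a
  broad log-normal (meanlog 0, sdlog 2), controlled by `seed`. On
  well-conditioned data the fixed point is initialization-independent
  (checked to 1e-4 relative agreement across seeds), so the randomness is
  a safeguard against degenerate starts, not a source of variance in
  results.
- **Bandwidth selection.** $\sigma$ is chosen from 20 log-spaced values
  between 0.5 and 30 months by leave-one-out cross-validation, with
  hyperparameters re-estimated inside every fold. Folds are warm-started
  from the full-data fixed point rather than from fresh random draws:
  the optimum does not depend on the start, and warm starts make
  selection deterministic and roughly ten times faster. The grid spans
  sub-month wiggle tracking up to near-linear trends over a 7–60 month
  range.
- **Non-convergence** within `max_iter` yields a warning and a curve
  flagged `converged = FALSE`, not an error: heavily noise-dominated
  series (the fronting index is the recurring example) can cycle slowly,
  and the partial fit is still the best available smoother for them.
- **No extrapolation.** The predictive mean is evaluated on a dense grid
  (step 0.1 months, matching the sub-month resolution at which onsets are
  conventionally reported) spanning exactly the observed month range.
  Features that would fall outside it are reported as missing, not
  extrapolated.

Goodness of fit is the ordinary coefficient of determination $R^2$ at the
training months, on the raw (unnormalized) scale; it is undefined for a
constant series.

## Onsets, offsets, durations, intersections

Fitted curves are divided by their maximum over the grid. The *onset of
developmental change* is the first month at which the normalized curve
exceeds 1/3; the *offset* the first month it exceeds 2/3; the *duration of
developmental change* their difference. Crossings are refined by linear
interpolation between grid points (error at most one grid step for
Lipschitz curves). Intersections between two normalized curves — used to
date when inter-organ articulation overtakes intra-organ articulation —
are the first sign change of their difference from negative to
nonnegative. Peak months take the first grid month attaining the maximum.

Two degenerate situations need a policy:

- **First-crossing semantics.** A curve may dip back below a threshold
  after exceeding it (fluctuating fronting indices do). The earliest
  exceedance is used, and `stays_above_onset` / `stays_above_offset`
  report whether the curve in fact stayed above, so the analyst can see
  when the summary is fragile.
- **Curves starting above threshold.** A measure already past its
  developmental change at the left edge of the observed range (the
  repetition ratio, which starts near its maximum, is the standing
  example) gets a degenerate crossing at the first grid month and
  duration 0. This is applied uniformly — including to constant
  trajectories, whose normalized curve is identically 1. `NA` is reserved
  for thresholds that are genuinely never exceeded within the range.

The thresholds are constants of the analysis; both are exposed as
arguments for sensitivity checks and default to 1/3 and 2/3.

## The synthetic-corpus generator

Real longitudinal corpora are large, partly proprietary, and slow to
obtain; the generator provides corpora with exactly the statistical
structure the analysis assumes, plus closed-form ground truth, so the
whole pipeline can be validated by parameter recovery.

Each of the nine categories follows a four-parameter logistic weight
function of age, $w(t) = \mathrm{floor} + (\mathrm{ceiling} -
\mathrm{floor})\,\sigma(\mathrm{slope}\,(t - \mathrm{midpoint}))$;
probabilities are the weights normalized to the simplex. The backing
categories CL and DL mirror their fronting partners LC and LD scaled by an
asymmetry factor $\rho(t) \le 1$ that rises to 1, so the fronting
preference is transient by construction. The `trajectory_paperlike()`
preset encodes, as a one-time choice: repetition mass ≈ 0.95 before 12
months decaying after ~18 (midpoint 20, slope −0.35); symmetric
intra-organ categories rising slowly from midpoint 17 (slope 0.25, floor
0.01, ceiling 0.10); inter-organ fronting categories rising steeply at
midpoints 19–20 (slope 0.6); $\rho$ from 0.3 toward 1 around 19 months
(slope 0.45, effectively 1 by ~24 months). Tokens are realized as concrete
CVCV strings (uniform consonant of the required place, uniform vowel), so
extraction is exercised end to end. Durations follow an inverted U: total
CVCV duration 400 ms at the edges rising to 600 ms at 18 months (Gaussian
bump, width 8 months) with unit-mean multiplicative log-normal noise per
phoneme (CV 0.15) — values in the range reported for early child speech,
peaking where the developmental literature places the slowdown.

`true_features()` computes the exact months at which each max-normalized
analytic trajectory crosses the thresholds (fine scan plus root-finding to
1e-9; verified against the closed-form logistic inverse where one exists),
and `true_intersections()` the exact overtaking months. The logistic
family was chosen precisely because these ground truths are available
essentially in closed form.

What the generator does *not* emulate — and what recovery results
therefore do not establish about real corpora: lexical structure and
vocabulary growth (tokens are i.i.d. given the month), session-level
burstiness and irregular recording schedules (token counts are constant
per month), transcription error and inter-transcriber disagreement,
child-to-child heterogeneity in trajectory shape (children differ only by
sampling noise), and any acoustic detail beyond the duration summary.

## Parameter recovery and its limits

`recovery_experiment()` runs simulate → extract → count → index → fit →
features over many seeds and compares against the analytic truth. At the
default study design — 3 children, months 7–60, 50 tokens per child-month,
20 seeds, bandwidth by LOOCV — the repetition, intra-organ and both
inter-organ measures recover onset and offset months with median absolute
error well under 2 months, and the qualitative signature (intra-organ
onset earlier than inter-organ onsets; inter-organ durations shorter) is
reproduced in essentially every seed. These sizes keep the full recovery
run in the low minutes on one core and are the problem sizes used
throughout the test suite.

The *fronting index* is the documented exception. Its relevant token
count (a + b) is only ~5–10 per month before 15 months at this sampling
intensity, giving monthly index values a standard error near 0.3 while the
true transient peaks around 0.16. Leave-one-out correctly judges such a
series noise-dominated and selects the widest kernel; the flattened fit
max-normalizes into a band that sits above both thresholds from the start
of the range, so the detected onset collapses to the left edge, several
months from the truth. This is a property of applying max-normalization
plus fixed thresholds to a weak, signed, non-monotone signal, not of the
implementation: the same procedure on the ratio measures (nonnegative,
rising from near zero) is well behaved. Onset/offset summaries for the
fronting index should therefore not be trusted at these token counts —
report its peak month and raw trajectory instead.

## Known limitations

- Month binning is a floor to integer months; corpora with very uneven
  within-month sampling may prefer finer bins, which the regression (it
  accepts arbitrary real-valued months) but not the counting step
  currently supports.
- The CHAT reader consumes the phonological tier only; utterances without
  one are skipped rather than guessed at, so corpora transcribed purely
  orthographically need external grapheme-to-phoneme conversion first.
- Whether CVC windows should cross word boundaries is corpus-dependent;
  the package strips word boundaries (treating them like syllable
  boundaries), which slightly inflates counts relative to a word-internal
  analysis.
- Uncertainty on feature months is not propagated: onsets and offsets are
  point summaries of the posterior mean curve.
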