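---
title: "Modelling dyadic affect dynamics from SPAFF streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dyadic affect dynamics from SPAFF streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spaffdyn)
```

`spaffdyn` analyses two-person interactions — a therapist and a client over
a course of psychotherapy is the motivating case — that have been coded
second by second with the Specific Affect Coding System (SPAFF). This
vignette explains the model each stage implements, the parameters that
matter and their defaults, the design choices made where the design was
genuinely open, and what the synthetic-data tests do and do not establish
about real sessions.

## From codes to scores

SPAFF assigns each second one of 20 mutually exclusive codes: Neutral,
seven conventionally positive codes and twelve negative ones. Analyses
weight each code with a signed score and sum consecutive 6-second windows,
so 900 coded seconds become 150 window scores — the time series unit for
everything downstream.

Two conventions deserve comment:

* **Weights.** The historical weight values used in the marital-interaction
  literature are not part of the public coding manuals, so
  `default_weight_table()` ships an explicit, configurable default
  (strong positives +4, mild positives +2, Neutral +0.1, mild negatives
  −1, hostile negatives −2..−4 with Contempt at −4). It follows that
  literature's ordering of code severity and is a package default, not a
  recovered ground truth; `read_weight_config()` loads alternatives, and
  `validate_weight_table()` enforces coverage and sign conventions.
* **Tense Humor.** Although coding manuals list Tense Humor among the
  positive codes, the session tables this package reproduces count it with
  the negative totals and the negative-affect meta-state (a tense joke
  carries tension). `spaff_codes()` follows the tables' arithmetic.

Windows are half-open `[6k, 6k+6)` on 0-based time and a trailing partial
window is dropped, since real sessions are not exact multiples of the
window length. Session summaries (`summarize_session()`) compute exact
second counts; percentages are always recomputed from seconds and the
session's total coded seconds, never from re-rounded intermediates. For
the packaged study tables the session length is not reported, so it is
taken as the row sum of the per-code seconds — the choice that reproduces
the printed percentages.

## Comparing affect use across sessions

With only six sessions, per-code usage is compared across sessions with a
one-sample Kolmogorov–Smirnov statistic on the per-session *percentages*
(session lengths differ, from 1800 to 2705 coded seconds, so seconds and
percentages are not interchangeable). `ks_D()` computes the sup-distance
between the empirical CDF and a reference distribution fitted to the
sample, handling ties through the left limit of the empirical CDF —
important here because many codes are absent (0%) in most sessions, and a
pile of zeros against an exponential reference contributes its full jump.

The source tables do not state which reference distribution was used, so
the package makes the caller choose and ships, with the fixtures, the
choice under which each table's printed statistics actually reproduce:
fitted normal (sample mean, n−1 SD) for the therapist's per-code scans and
the client's meta-states; fitted exponential (rate 1/mean) for the
client's per-code scans and the therapist's meta-states. One printed
value (the therapist's Positive Affect meta-state, 0.486) does not
reproduce under any reference/variable combination tried and is recorded
in the fixtures as a known discrepancy rather than asserted.

Two p-value conventions are available in `ks_pvalue()`:

* `exact_kolmogorov` — the classical exact null `P(D_n ≥ D)` for a fully
  specified continuous reference, via the Marsaglia–Tsang–Wang matrix
  method. It ignores that the reference parameters were estimated, and at
  n = 6 it is conservative: D values near 0.4–0.5 are not significant
  under it.
* `monte_carlo` — a seeded parametric bootstrap (fit, simulate, refit,
  recompute D), i.e. a Lilliefors-type estimated-parameters null, under
  which the same D values can be significant. Both families are closed
  under the transformations their estimators absorb, so simulation from
  the standard member suffices.

This ambiguity — which null makes a small-sample D "significant" — is
inherent to the reported analysis; the package exposes both rather than
guessing.

## The dyadic model

Each actor's window score is modelled by a coupled pair of difference
equations. For the therapist (and symmetrically for the client):

$$T_{t+1} = r_T\,T_t + a_T + I_T(C_t) + R_T(C_t)$$

* `r` (*inertia*) multiplies one's own previous score: the tendency to
  remain in the current emotional state. `|r| < 1` gives stable dynamics.
* `a` (*initial state*) is the constant uninfluenced disposition.
* `UnSS = a/(1−r)` is the *uninfluenced steady state*, the score the actor
  settles at absent partner influence.
* `I(·)` is the partner's *influence function*: piecewise linear with a
  dead zone between a lower threshold `nth` and an upper threshold `pth`
  and linear response beyond each ("trilinear"; dropping a threshold gives
  "bilinear", dropping both the null function). It is continuous by
  construction: each branch is anchored at its threshold.
* `R(·)` is the *repair* term: a constant lift `sr` that switches on when
  the partner's score falls to or below `kr`, damping negative spirals.

Although such models are often written in derivative notation, estimation
and iteration here are discrete with one 6-second window per time step:
the published parameters (inertia as a multiplier, `UnSS = a/(1−r)`) are
only consistent with the discrete map, and the identity is verified on all
twelve published parameter rows to 5×10⁻⁶.

**Estimation** proceeds in three least-squares stages per actor
(`fit_dyad()`):

1. `estimate_uninfluenced()` regresses `x[t+1]` on `x[t]` (OLS, `lm()`)
   over windows where the partner is *neutral*. Neutrality is a band
   `|partner score| ≤ ε` with ε = 0.25 by default: window scores are
   continuous, and exact zeros would be rare. Note that under the default
   weight table a window of pure Neutral scores 0.6, so callers working
   from real code streams should widen the band (ε = 0.6) if pure-Neutral
   windows should count; the default band is deliberately tight so that
   windows mixing mild positives and negatives to a small sum do not
   masquerade as neutral. At least 3 uninfluenced transitions are
   required.
2. `estimate_influence()` works on the residuals at non-neutral windows.
   Candidate thresholds are scanned over the distinct observed partner
   scores (a threshold between two observed scores is not identifiable, so
   observed scores are the natural candidate set); slopes are no-intercept
   least squares within each regime; every form is scored by SSE, a regime
   needs at least 3 supporting points to be eligible — which is exactly how
   sessions that never visit one regime come out bilinear — and SSE ties
   break toward fewer regimes, then smaller-magnitude thresholds.
3. `estimate_repair()` scans thresholds over negative partner scores on
   the influence-adjusted residuals; the strength is the mean residual
   lift below the threshold, the threshold maximises the explained sum of
   squares, and the term is inactive when no candidate has 3 supporting
   points with positive lift.

Because stages 2 and 3 are sequential, a strong repair signal can be
partially absorbed by the negative influence slope; tests therefore
validate repair recovery conditional on the influence term, and the
recovery study below uses influence-only ground truth.

The update is simultaneous: both actors respond to the partner's *previous*
window. No turn structure is assumed for a therapy dyad; an alternating
update is available behind a flag in `step_dyad()` for sensitivity
analysis.

## Phase portraits

`build_portrait()` iterates the fitted map 10 steps (the published
procedure's horizon) from every point of a lattice of starting
coordinates, default `[−12, 12]²` at step 1 — wide enough to contain any
window score reachable under the default weights (|weight| ≤ 4 × 6
seconds) — with client score on x and therapist score on y. The session's
own projected trajectory starts from the mean of each actor's first 10% of
windows (`session_start_point()`).

Critical points are found analytically, not by search: the influence and
repair thresholds of the two actors partition the plane into rectangles on
which the map is affine, the 2×2 fixed-point system is solved in each
rectangle, and solutions are kept when they lie in their own rectangle
(boundary solutions are admitted with tolerance 10⁻⁸ and deduplicated at
10⁻⁶). Stability follows the discrete-map convention: an attractor has
all Jacobian eigenvalue moduli below 1, a saddle exactly one above.
Quadrant labels (`classify_quadrant()`) read the signs of the fixed point,
with axis points labelled "boundary"; the therapist-positive /
client-negative quadrant is the conventional "working" regime, and
mutually negative attractors flag strained sessions.

One caveat matters when portraying the *published* parameter tables: they
report thresholds but not influence slopes, so `fixture_dyad()` takes
slopes from configuration (default 0.5 per regime) or drops influence
entirely. Portraits from printed parameters are therefore qualitative —
quadrant structure, not coordinates — and the package's quantitative
claims about them are limited to the uninfluenced fixed point, e.g. that
session 3's uninfluenced attractor lies in the mutually negative quadrant:

```{r session3}
critical_points(fixture_dyad(3, influence = "null"))
```

## Synthetic data and what the tests show

Raw session streams are not publicly deposited, so every stage is
validated against generators with known ground truth:

* `generate_stream()` — a sticky first-order Markov chain over codes
  (repeat the previous second with probability `persistence`, else draw
  from the stationary propensities). It reproduces the Neutral-dominated,
  bursty texture of coded sessions, not any psychologically meaningful
  sequencing.
* `generate_dyad_series()` — forward simulation of the coupled map from
  the steady-state pair plus a Gaussian perturbation, with independent
  `N(0, noise_sd)` window noise. Additive Gaussian noise is the simplest
  perturbation consistent with least-squares estimation; real residuals
  are likely heavier-tailed and state-dependent.
* `stream_for_series()` — inverts windowing by composing each window score
  from code weights (choosing, among valid compositions, the most neutral
  one), so stream-level and series-level pipelines can be cross-checked
  exactly.

The parameter-recovery study in the test suite runs 100 seeded dyads of
150 windows at noise SD 0.5 — the series length of a 15-minute coded
segment and a noise level of roughly half a mild code's window weight —
with true inertias 0.4/0.5, initial states −0.2/+0.15 and trilinear
influence (thresholds ±0.8, slopes 0.4), and requires median absolute
errors below 0.1 for `(a, r)` and below one score unit for thresholds.
The true steady states are placed near zero deliberately: the uninfluenced
regression only sees windows where the partner passes through the neutral
band, so a dyad parked far from zero (e.g. a client steady state of −3
with noise SD 0.5) leaves that estimator without data — a genuine
identifiability limit of the estimation scheme, not an implementation
artefact, and worth remembering when fitting real sessions dominated by
strong negative affect.

All generators are bit-reproducible under a fixed seed (`withr::with_seed`,
so the global RNG state is untouched).

## Numerical choices and known limitations

* KS D is computed from the sorted-sample formula with left limits; tests
  check it against a 10⁶-point grid sup and against
  `stats::ks.test` on tie-free samples (tolerance 10⁻⁶).
* The exact KS null uses factorial scaling directly, which is accurate at
  the small n (≤ 15) this package targets.
* Analytic critical points are cross-checked against an independent
  multi-start numerical fixed-point search (agreement to 10⁻³).
* Iteration guards divergence with an overflow bound (default 10⁶) and
  flags truncated trajectories rather than erroring mid-portrait.
* Three cells of the published aggregate rows are inconsistent with their
  own constituent code rows, and a handful of printed percentages are
  inconsistent with their seconds; fixtures keep the printed values
  verbatim and the tests assert the seconds-derived arithmetic, with the
  discrepant cells listed explicitly.
* One reported statistic (client Tension, 0.430) sits on a third-decimal
  rounding boundary because the session-6 row-sum length (2705 s)
  slightly reshapes the exact percentages; the recomputed value is 0.4306.
* Influence slopes for the published sessions are unknown (see above), so
  published-parameter portraits are qualitative only.
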