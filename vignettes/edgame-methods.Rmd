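---
title: "Methods: simulating and analysing a scoring-based ED logistics game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing a scoring-based ED logistics game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgame)
```

## What the package models

`edgame` is a headless re-implementation of a serious game about patient-flow
logistics in a pediatric emergency department (ED), together with the
learning-analytics chain used to study such games.  The original game is
played by six people — five module nurses and one triage nurse — around a
deck of 90 unique patient cards over 12 rounds representing a 6-hour shift.
Patients arrive at triage each round; the triage role refers them out or
admits them to one of five care modules (one of which, the *red module*, is
reserved for urgent patients — the only priority level the rules act on).
Each patient card carries an ordered plan of activities, each needing a
stated number of doctors and nurses for a stated number of rounds.

Play is scored with a token mechanic built on four logistical indicators:

| indicator | red module | normal module | triage |
|---|---|---|---|
| production throughput (PT) | +16 per discharge | +4 per discharge | quarter of the receiving module's reward; −1 per 2 rejections |
| activity execution (AE) | −4/−8/−12/−16 at +25/50/75/100% delay | −1/−2/−3/−4 | n/a |
| resource management (RM) | −4 | −1 | −1 |
| production resilience (PR) | −4 | −1 | n/a |

The red module carries four times the stakes of a normal module on every
indicator, which the constructor asserts structurally.

Human players are replaced by *bot policies* — deliberately simple
stochastic heuristics (`policy_set()`).  They exist to exercise the
mechanics and generate telemetry, not to play well; no learning, no
negotiation.

## Interpretation choices in the scoring rules

The rule card leaves several details open.  The package resolves them as
follows, each behind a configurable knob:

* **Triage quarter-share.**  A normal discharge earns the module +4, so
  triage earns exactly +1.  If a custom rules table makes the share
  fractional, it rounds half away from zero, so triage is never
  short-changed by banker's rounding.
* **Delay buckets.**  The activity-execution penalty uses the largest
  threshold not exceeding the realised delay fraction
  `(actual − planned)/planned`.  Delays under 25% cost nothing; delays past
  100% cap at the last bucket (the card lists no higher tier).  Early
  completion earns nothing and is rejected as a validation error — the
  mechanic penalises delay only.
* **Rejection penalty** accumulates over the session with a floor rule
  (−1 per completed pair of referrals), rather than resetting per round.
* **RM granularity** is once per under-staffed activity per round.
* **PR timing**: evaluated on *free* (unallocated) doctors at round end;
  a module whose doctors are all consumed by the round's work has no slack
  for a surge and is penalised.  Triage is exempt.

`apply_scoring()` is a pure, idempotent function of the event log.  It
recomputes every delta from the rules: PT and AE from their causal events
(`discharge`, `activity_complete`), the rejection penalty from
`triage_refer_out` counts, and RM/PR from occurrence records that the
engine logs when it observes the staffing condition (those conditions are
state snapshots that exist nowhere else in the log).  Deltas stored on
telemetry are never trusted.  An independent single-pass scorer in the test
suite re-derives all totals on 1000 random logs.

## The synthetic world

Neither the 90 real cards nor the source ED's flow statistics are
published, so the generator defines a *parametric* case mix
(`case_mix()`), with every choice config-exposed rather than hard-coded:

* activities per patient: `1 + Binomial(3, 0.5)` — most patients need one
  to three steps, emulating a low-acuity-heavy pediatric mix;
* planned duration per activity: 1, 2, 3 rounds with weights 0.5/0.3/0.2;
* staffing per activity: a doctor with probability 0.6, nurses 0/1/2 with
  weights 0.2/0.6/0.2, with a floor of one staff member;
* urgent fraction: 0.15 i.i.d. Bernoulli — a declared assumption, not a
  published fact;
* arrivals: truncated Poisson, default mean 3 per round over 12 rounds
  (≈36 patients per session), sampled from the deck without replacement.

These defaults are the package's stated world.  What a green test
establishes is that the *mechanics and analytics* behave correctly in that
world — not that the world matches Karolinska's case mix, which the tests
make no claim about.

**Staff-pool calibration.**  Module staff pools are unstated in the source
material.  The mechanic was explicitly designed around the Losada 6:1
ratio of positive to negative feedback, so the default pools were set by a
one-time calibration of that design point: with 4 doctors and 4 nurses per
module the median overall positive:negative delta-count ratio across
seeded default sessions is ≈5.6 (leaner 3/3 pools starve activities and
drive the ratio to ≈1.8; richer 5/5 pools over-shoot to ≈10).  The
acceptance suite re-measures this over 500 fresh sessions and requires the
median in [4, 8].  The calibration was performed once, before the band was
tested, and is not revisited.

**Module capacity** defaults to 4 patients: stretcher negotiation between
human players is replaced by a fixed cap for the bots.

## Engine determinism

Rounds execute a fixed sub-phase order: arrivals → triage decisions →
staff allocation → activity ticks → completions/discharges → round-end
scoring.  The source material describes rounds but not intra-round
ordering; fixing it makes scoring see a consistent snapshot and a seed
fully determine the log.  All randomness flows from one master seed
through named substreams (`substream_seed()`), so adding one consumer of
randomness never perturbs another.  Identical inputs give byte-identical
JSON-Lines logs, asserted by hash in the tests.

The red-module rule is enforced by the engine, not the policy: a policy
that prefers another module for an urgent patient is overridden and a
`rule_enforcement` event is logged.  Three event types extend the core
telemetry vocabulary for auditability: `round_start` (round markers),
`triage_wait` (capacity-blocked patients are retried, never dropped), and
`rule_enforcement`.

## Behavior coding

Telemetry is transcribed per player role into the participatory behavior
codes used in game-based learning research: MR (managing resources —
staff allocations), EP (editing profiles), IC (inviting cooperation), FT
(finishing tasks — confirmed decision results).  Triage admit/refer
decisions are coded FT, an interpretation (the published coding guideline
does not enumerate triage events) that the coding map makes overridable.
A scoring announcement enters the stream as RA ("receiving update")
followed by its indicator code, modelling the point system informing the
player as the start of a behavior chain.  The stimulus stream is
interleaved with behaviors by default; `include_stimuli = FALSE` gives a
behavior-only stream.  Time-on-task is proxied by active rounds ×
minutes-per-round, since a board game has no keystroke timestamps.

## Lag sequential analysis

Lag-1 transitions are counted within each player's sequence only (never
across players) and pooled into one matrix per condition, matching the
single per-condition transition graphs of the genre.  Each cell gets the
Allison–Liker adjusted residual

$$Z_{ij} = \frac{O_{ij} - E_{ij}}{\sqrt{E_{ij}\,(1 - r_i/N)\,(1 - c_j/N)}},
\qquad E_{ij} = \frac{r_i\,c_j}{N},$$

the standard in the education-technology LSA literature (the source names
the method but prints no formula; this choice is pinned in tests against
direct evaluation).  Cells with zero variance are undefined and never
become edges.  Edges default to the one-sided rule $Z > 1.96$ — published
transition graphs display excitatory transitions — with a `two_sided`
switch.  No multiple-comparison correction is applied by default (none is
described in the genre); the threshold is a plain argument.  A simulation
test checks the ~5% false-positive cell rate under an i.i.d. null.

## Engagement regression and parameter recovery

Performance (a role's session token total) is regressed on the four
behavior counts by OLS with intercept, reporting R², the block ΔR² (equal
to R² under single-block entry over intercept-only — the published tables
report exactly that identity, so no stepwise selection is modelled),
per-predictor B, SE, standardized β = B·SD(x)/SD(y), p, and the overall F
with df (k, n−k−1).  Time-on-task is computed but excluded from the
default model, matching the four-predictor reference schema.

Because the participant-level data behind the published fit are
unavailable, validation is by *parameter recovery*: counts are simulated
as rounded lognormals over an equicorrelated Gaussian latent, and the
outcome is a linear function of the standardized counts plus Gaussian
noise scaled so the population R² equals `t(β) R β` (R the realised count
correlation).  With independent predictors the reference coefficients
(0.42, 0.08, 0.18, 0.53) can only explain ≈0.50 of the variance; reaching
the reference R² ≈ 0.8 requires positively correlated counts — players who
do more of one thing do more of everything — and `solve_latent_rho()`
solves the required latent correlation (≈0.33) on a fixed calibration
draw.  At n = 2000 the fitted standardized βs recover the generating ones
within ±0.05; under all-zero βs each coefficient's t-test rejects at ≈5%.

A note on the reference F statistics: values near 2700 are analytically
impossible for n = 36 with R² ≈ 0.8 (the implied F is ≈30).  The package
does not reproduce them; it asserts df consistency instead.

## Questionnaire scoring

Dimension scores are arithmetic means of item scores on a 0–4 anchor
scale ("not at all" … "extremely"); the source calls this a 6-point scale
while printing five anchors, so the bounds are configurable and default
to 0..4.  The bundled item→dimension map is a clearly-marked synthetic
template (`geq_map_synthetic.json`); the real instrument's assignment
must be supplied by the user.  Dimension comparisons default to a paired
Wilcoxon signed-rank (the data are ordinal; the source does not name its
test), implemented as an exact sign-flip permutation for n ≤ 14 — valid
under tied ranks, where the classical exact tables are unavailable — and
a tie-corrected normal approximation above.  All-zero differences are a
reported degenerate branch (p = 1), not an error.

## Numerical and degenerate-input conventions

* Delay-bucket lookup adds 1e-12 before `findInterval` so delays that are
  exact threshold fractions in real arithmetic never fall under them
  through floating-point rounding.
* Sequences shorter than lag + 1 contribute zero transitions, with a
  warning naming how many.
* A constant predictor column is flagged (β undefined) but not silently
  dropped; a singular design names the collinear column.
* In small recovery replicates the sample signal variance can exceed 1;
  the noise floor clamps at zero rather than failing the replicate.
* Scoring rules serialisation converts named vectors to JSON objects so
  role names survive a round trip.

## Known limitations

Bot policies are stationary heuristics: they do not reproduce the
collaborative adaptation human groups show in later rounds, so analytics
over bot telemetry exercise the *pipeline*, not human behavioral
hypotheses.  The deck generator makes no claim of clinical realism (SBAR
notes are flavour text).  Empirical z-scores, GEQ means, and regression
coefficients of the original study are structure/recovery references
only — the raw data are unpublished and desk-scale reproduction is out of
scope by design.
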