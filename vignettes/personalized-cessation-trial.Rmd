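---
title: "Personalized text-message cessation support: model, engine and trial simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized text-message cessation support: model, engine and trial simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(textquit)
```

## The behavioural model

The intervention this package implements pairs two behaviour-change
theories. The *transtheoretical model* (TTM) supplies the stage logic:
before a smoker's quit day their messages are keyed to the strength of
their quitting intention (weak intention calls for consciousness raising,
dramatic relief and environmental re-evaluation; strong intention for
stimulus control, self-liberation and reinforcement management), and after
the quit day to their relapse status (relapsed smokers get re-evaluation
content; smokers maintaining abstinence get no TTM content at all).
*Protection motivation theory* (PMT) supplies the motivational targeting:
seven constructs — perceived severity, perceived vulnerability, intrinsic
and extrinsic rewards of smoking, self-efficacy of quitting, response
efficacy, and response cost of quitting — each measured by three 7-point
Likert items, 21 items in all, scored as per-construct item means.

Because the seven constructs overlap, they are merged into three
intervention target groups:

* **SS** — raise severity and susceptibility: `mean(severity, vulnerability)`;
* **RR** — reduce the rewards of smoking and the cost of quitting:
  `mean(8 − intrinsic, 8 − extrinsic, 8 − response_cost)`;
* **EE** — raise self-efficacy and response efficacy:
  `mean(self_efficacy, response_efficacy)`.

The rewards and response-cost constructs are *reflected* (`8 − x`) before
averaging. This is a deliberate design choice: those constructs are
maladaptive (a high score means low protection), and reflection makes
"lower merged score = weaker protection" hold uniformly, so the deployed
rule — target the component with the lower score, the one that needs to be
strengthened — is well defined across oppositely oriented constructs.
Comparing raw construct scores instead would systematically conflate "high
rewards" (bad) with "high severity" (good). Exact ties are broken by a
fixed priority order (SS, then RR, then EE by default); ties have measure
zero for continuous scores but occur for scale-point profiles, and a fixed
order keeps targeting deterministic. Whether response cost should
contribute to RR or EE is genuinely ambiguous in the merge description;
we group it with RR (it is reflected either way), matching the "decreased
response cost and rewards" reading.

Quitting intention is a single 5-point item (1 = not at all likely,
5 = very likely, to try quitting within 6 months). The published programme
states the scale but not the cut point; `classify_intention()` defaults to
*strong* at a score of 4 or more and the threshold is configurable.
Smoking status is the conjunction of a self-report of not smoking since the
last assessment and, where biochemical verification is requested, an
expired carbon monoxide reading strictly below 6 ppm; the strict inequality
follows the verification criterion literally, and a positive self-report
always dominates a clean CO reading.

## The message bank and the 91-day engine

The bank is three-layered: programme phase (registration day 0, pre-quit
days 1–7, quit day 8, withdrawal management days 9–18, early quitting days
19–36, late quitting days 37–90), TTM stage class, and PMT target group.
The atomic motivational pools carry the 13 labels P-W, P-S, P-SS, P-RR,
P-EE, E-R, E-SS, E-RR, E-EE, L-R, L-SS, L-RR, L-EE; the deployed programme
describes its core bank as 14 sub-groups of 200 messages, but only 13
atomic pools are operationally enumerable from the phase table — we treat
the withdrawal-management rotation as the likely fourteenth and generate
fixtures over the 13 enumerable labels, each non-empty, summing to exactly
200 motivational messages, plus roughly 200 contact messages and the fixed
registration/quit-day/withdrawal content. Placeholder fixture texts embed
their own label and index (for example `[E-RR #7]`) so every logged
selection is auditable. The real trial's Chinese-language texts are out of
scope; the engine is content-agnostic.

Per-day selection: registration and quit day emit their fixed message;
withdrawal days emit one withdrawal-management message; pre-quit days emit
two messages, one from the intention pool and one from the current PMT
pool; early/late quitting days emit the relapse pool plus the PMT pool for
relapsed participants. Maintained-abstinence rows carry no TTM pool, which
leaves a one-message day against the stated two-messages-per-day cadence;
we reconcile this by filling the second slot with a contact message
(configurable down to one message per day). Within a pool, selection is
rotation without repetition: the rotation order is shuffled once at pool
entry and re-shuffled at exhaustion, and these shuffles are the engine's
only use of randomness, so a delivery log is byte-for-byte reproducible
from (seed, banks, assessment stream). Within a day the stage-class
message precedes the PMT message — an arbitrary but fixed ordering.

In-app evaluations run on days 0, 19, 36, 45, 60 and 75. Day 0 classifies
intention; later evaluations classify relapse status; every evaluation
re-selects the PMT target group from the fresh profile. In-app evaluations
carry no CO meter, so status there relies on self-report alone
(`verify_co = FALSE` by default in `apply_evaluation()`); the follow-up
visits at months 1, 3 and 6 are CO-verified. Control participants receive
a fixed 91-message bank laid out one message per day over days 0–90,
identical for every participant, with no evaluations.

## Trial design and analysis

Sample-size planning uses the unpooled-variance normal approximation
`n = ⌈(z₁₋α/₂ + z₁₋β)² (p₁q₁ + p₂q₂) / (p₁ − p₂)²⌉`; at 4% versus 10%,
two-sided α = 0.05, power 0.80 this yields 280 per group (the
pooled-variance variant would give 283, so the unpooled form is the one
consistent with the published plan). Attrition inflation multiplies by
(1 + rate) — 280 × 2 × 1.2 = 672 — rather than dividing by (1 − rate),
again matching the published arithmetic (÷0.8 would give 700).

Randomization is 1:1, simple (fair coin) within two nicotine-dependence
strata (low versus moderate/high). The deployed system also "balanced
demographics" by an unstated algorithm; we provide Pocock–Simon
minimization (assign each arrival to the arm minimizing summed absolute
covariate imbalance, coin-flip on ties) as an optional method, off by
default since no method is named.

The primary outcome is Russell-standard 6-month continuous abstinence:
self-reported abstinence since the quit day at every one of the three
follow-up visits, each verified by CO < 6 ppm, with any missed visit —
including loss to follow-up — counted as smoking, and every randomized
participant analysed in their assigned arm (intention to treat). Effect
estimation is the raw 2×2 odds ratio with the Woolf log-normal interval
`exp(ln OR ± z √(1/a + 1/b + 1/c + 1/d))`; zero cells are an explicit
opt-in to the Haldane–Anscombe +0.5 correction rather than a silent
default. Reporting follows the conventional rounding: percentages to one
decimal, OR and CI to two. The arm comparison uses the Pearson chi-square
(Yates correction optional). The package deliberately does not reimplement
GEE: longitudinal analyses of real data belong in dedicated tools, and
`export_long_format()` writes the per-visit construct scores in the long
format those tools expect. The package's own `fit_logistic_irls()` is a
plain maximum-likelihood logistic fitter under working independence, used
as the parameter-recovery oracle for simulated data.

## The synthetic cohort and what it does (not) emulate

`generate_cohort()` draws categorical attributes (sex, age band,
education, residence, smoking pattern, income, dependence) from configured
proportions and baseline construct scores from normal distributions
truncated to [1, 7]. Defaults encode a realistic Chinese community smoker
cohort: 99% male, 82% daily smokers, 64% low dependence, severity near the
scale ceiling (mean 6.17) and rewards well below the midpoint. One
numerical subtlety: truncation pulls the realized mean of a near-ceiling
construct several tenths below its parent mean, so the generator solves
for the parent mean (by `uniroot` on the truncated-normal mean) such that
the *realized* mean equals the configured one; realized SDs are then
slightly below the configured values, which we accept. The education
proportions are entered as 0.155/0.234/0.611 — printed baseline tables
round to one decimal percent and sum to 99.9%, so the largest category
absorbs the rounding slack to satisfy the sum-to-one contract. The
intention distribution over 1–5 is not published; the default
(0.10, 0.15, 0.25, 0.30, 0.20) places about half the cohort at strong
intention, a plausible mix for volunteers who signed up to a cessation
programme.

`simulate_trial()` evolves each participant through the protocol:

* **Score dynamics** are first order: at each update time,
  `score ← clip(score + targeted δ + N(0, σ), 1, 7)`. Intervention
  participants receive the protective shift `δ` on the constructs of their
  currently targeted group (sign-aligned, so rewards move down and
  self-efficacy moves up); both arms receive the mean-zero noise. No
  autoregressive decay is modelled — the simplest dynamics consistent with
  the small drifts real score tables show. The target group is re-selected
  at each in-app evaluation; it is also computed (latently) for control
  participants so that arm-contrasted trajectory estimates of δ have a
  clean comparator under identical clipping.
* **Behaviour** is logistic in the mean-centred construct scores through a
  single protective coefficient vector β whose signs follow the abstinence
  associations reported for this population: strongly positive
  self-efficacy (log-odds 0.75), negative intrinsic rewards (−0.21) and
  response cost (−0.17), small free values elsewhere. The quit attempt on
  day 8 succeeds with probability `plogis(α_q + βᵀ(x − c))`; at each later
  status check an abstinent participant relapses with probability
  `plogis(α_r − βᵀ(x − c))`, and a lapsed one may re-quit (with a logit
  penalty), which is what lets the engine exercise relapsed→maintained
  messaging transitions. Continuous abstinence for the outcome is broken
  permanently by any lapse.
* **Measurement**: expired CO is truncated-normal at mean 3 ppm (SD 1.5)
  when abstinent and mean 15 ppm (SD 5) when smoking, giving a small
  (≈2% per visit) false-relapse rate at the strict 6 ppm cut.
  Self-reports are truthful. Dropout is missing-completely-at-random and
  absorbing at 1.5% per visit, matching per-visit follow-up counts that
  decline by roughly 1–2% in community mHealth trials of this design.
* **Calibration**: α_q defaults to logit(0.70); α_r = 0.15 and δ = 0.45
  were fixed once by a coarse grid search so that, at the default cohort
  size of 722, measured continuous abstinence averages ≈3% in the control
  arm and ≈7% in the intervention arm — the regime the design arithmetic
  anticipates. These are generator conditions, not fitted quantities.

What the simulator does **not** emulate: within-person correlation of
repeated scores beyond the shared random walk (the noise SD of 0.25 per
update is a free parameter); secular drift in the control arm (real
cohorts often drift downward in rewards scores without intervention);
covariate-structured dropout; untruthful self-report; seasonal or social
contagion effects; and any dependence of behaviour on the *content* of
messages — the intervention effect enters only through δ. Passing
end-to-end tests therefore demonstrates that the machinery (scoring,
targeting, scheduling, adjudication, estimation) is internally consistent
and recovers known parameters, not that the behavioural model is an
accurate portrait of real smokers.

## Numerical and testing choices

Degenerate inputs are rejected rather than patched: missing Likert items
are never imputed (the in-app capture is all-or-nothing), empty message
pools raise configuration errors naming the pool, and a control bank must
hold exactly 91 messages. The IRLS fitter bounds weights away from zero,
declares convergence at `max |Δβ| < 1e-8`, and reports quasi-separation as
a non-convergence error naming the runaway column. δ recovery uses the
arm contrast of per-participant mean signed targeted changes with a
two-sample t interval; clipping attenuates the estimate toward zero for
high-baseline constructs, so recovery tests assert sign and null coverage
rather than unbiasedness.

Test problem sizes are chosen to keep the suite quick while leaving
comfortable statistical margins: 10⁴ profiles for the targeting oracle,
10⁴ tables for Woolf coverage (tolerance ±1.5 points around 95%), 5000
participants for coefficient recovery (each protective β within 3
standard errors), and 200 replicate trials at n = 722 for the directional
end-to-end check (the simulated odds-ratio distribution must bracket the
anticipated effect and the intervention arm must win in at least 95% of
replicates).
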