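---
title: "Methods: the remote hypertension management rule engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the remote hypertension management rule engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htnrms)
```

## The program model

`htnrms` encodes the decision logic of a remote hypertension management
program: patients with uncontrolled office BP are screened in, receive a
connected home BP cuff, transmit scheduled readings, and a pharmacist
titrates guideline-preferred antihypertensives — dihydropyridine calcium
channel blockers (CCB), ARB/ACE inhibitors (one shared RAAS slot),
thiazide-type diuretics (TD), then mineralocorticoid receptor
antagonists (MRA) or beta blockers (BB) — against weekly home-BP
averages, with laboratory safety gates around every lab-sensitive
prescription.

The engine is deliberately a *pure rule system*: every decision function
is deterministic in its declared inputs (there is no hidden clock — the
decision date is always an argument), and every numeric constant
resolves through a configuration registry. This makes each clinical rule
independently testable by boundary search and makes the whole engine
fuzzable.

### Goals and aggregation

The weekly home average is the unit of decision. Each channel (SBP, DBP)
is averaged separately after a single-pass exclusion of values more than
3 sample SDs from that week's channel mean. Choices worth noting:

* **Per-channel exclusion.** An aberrant systolic transmission removes
  only that systolic value; its paired diastolic survives. The exclusion
  rule speaks of outlying *values*, not readings, and device artifacts
  typically corrupt one channel.
* **Single pass, week-local SD.** The filter runs once and uses the
  week's own sample SD (n − 1). Iterated trimming and long-run SDs are
  deliberate non-features: with 12–28 readings a second pass can cascade
  on near-constant series, and a week-local scale adapts to each
  patient's variability. A constant series has SD 0 and never excludes.
* **Sufficiency before classification.** 28 readings over ≥ 7 distinct
  days grade *optimal*, 12 over ≥ 3 days *minimal*; anything less is
  *insufficient* and refuses goal classification rather than classifying
  on thin data. Heart rate is averaged without exclusion; it feeds only
  the beta-blocker safety rule, where a biased-low mean would be the
  conservative direction.

Goals are 130/80 mmHg, relaxed to 135/85 for frail patients (assistive
device use or non-mechanical falls within 12 months). A weekly mean at
or above either channel's goal is *above goal*.

### The titration state machine

`next_action()` returns exactly one step per weekly report, in a fixed
priority order: (0) at goal → hold, maintenance pending labs; (1) safety
floor (weekly mean SBP < 105 or DBP < 50) or heart rate < 55 bpm on a
beta blocker → physician conversation; (2) titration lockout — at least
1 week on the current dose, 6 weeks for an MRA (the MRA spacing is also
enforced against the MRA's own last change when other agents moved in
between); (3) a 2-month lifestyle-only trial for medication-naive
patients in the stage-1 band with 10-year ASCVD risk < 10%;
(4–5) maximize-before-add along the pathway sequence; (6) the
HCTZ-to-chlorthalidone switch; (7) secondary-cause screen and fourth
line; (8) specialist referral.

Design decisions where the protocol text left room:

* **Childbearing potential outranks RAAS-first.** The RAAS-first rule is
  defined over patients *not* of childbearing potential, so a young
  diabetic woman without contraception follows CCB → labetalol. The
  engine never escalates a RAAS agent or MRA for such a patient even if
  one is already on board.
* **Maximize-before-add is global.** Before opening a new class the
  engine escalates *any* tolerated, escalatable ladder already on board,
  including agents outside the current pathway's sequence (e.g. a
  beta blocker inherited from pandemic-mode prescribing). Ladders that
  cannot be escalated — documented intolerance, lab-blocked MRA, lab
  classes in no-labs pandemic mode — do not block an add.
* **Lifestyle-first band.** The trial is offered when the weekly mean is
  above goal but below 140/90 on *both* channels. A disjunctive reading
  (either channel in its stage-1 band) would divert a 150/85 patient to
  lifestyle-only, contradicting the escalation rule, so the band is
  read conjunctively as "stage 1, not stage 2".
* **Chlorthalidone as conditional up-titration.** On maximum-dose HCTZ
  the switch to chlorthalidone is offered only when every above-goal
  channel sits < 10 mmHg from its goal; otherwise the thiazide slot
  counts as maximized and the engine proceeds to the secondary-cause
  screen. When both channels are above goal, both distances must be
  inside the margin (the conservative reading of "systolic or
  diastolic").
* **RAAS slot policy.** New starts get the program-default potent ARB
  (irbesartan); losartan and non-lisinopril ACE inhibitors are switched
  to it; lisinopril titrates in place. An intolerance recorded on any
  RAAS agent closes the slot rather than re-challenging within class.
* **Fourth line.** After a negative secondary-cause screen the MRA is
  preferred when potassium permits (eplerenone for males, spironolactone
  otherwise), at the conservative starting dose when K lies in
  (4.5, 5.2); the beta-blocker fallback is labetalol, or metoprolol with
  reactive airway disease, and requires heart rate ≥ 55.
* **Repeat-before-down-titrate.** The post-titration lab rule offers
  "repeat labs or down-titrate" without sequencing; the engine takes the
  two-step reading — repeat first, down-titrate on a confirmed repeat.
* **Strict-vs-inclusive comparisons** follow the protocol text verbatim
  in each rule, even where inconsistent between rules (the program-level
  warning uses a K rise *>* 15%, the repeat-labs trigger *≥* 15%).

### Alerts

The daily scanner re-evaluates a trailing 7-day window. A calendar day
qualifies for a threshold if *any* reading that day crosses it, so a
single 200 mmHg reading raises its own alert and feeds the ≥ 190 and
≥ 180 day counts. Two readings over threshold on one day are one day.
Events deduplicate by (type, window end), so a persistent episode does
not re-alert for the same trigger set within one report.

## Configuration

Everything numeric lives in `inst/extdata/default_config.yaml` under
`thresholds:` (goals, alert limits, lab bounds in mmol/L and
ml/min/1.73 m², lockouts in weeks, cuff weight limits in lb, age bands)
and `dosing_table:` (per-agent mg ladders, standard starting step,
`requires_labs`). The conservative start — used for frail patients and
constrained pandemic-mode prescribing — is one step below the standard
start, floored at the lowest step; the protocol names the strategy but
not the doses. The irbesartan (75/150/300 mg), HCTZ→chlorthalidone
(12.5/25 → 25 mg) and spironolactone (12.5/25/50 mg) ladders are the
protocol's own; the remaining agents carry conventional outpatient
ladders as editable site defaults.

`load_config()` validates structure (strictly increasing steps,
`requires_labs` true exactly for ARB/ACEI/TD/MRA, frail goals strictly
above standard) and round-trips through `write_config()`.

## The simulator

`generate_cohort()`, `simulate_week()` and `run_program()` exist so the
full closed loop — aggregate, classify, gate, recommend, apply — can be
exercised end to end. The response model is editorial (no dose-response
model is part of the protocol) and intentionally the simplest thing the
titration logic can be inverted against:

* latent true BP per patient, drawn from N(150, 12²)/N(92, 8²) mmHg by
  default — an uncontrolled referral population;
* each dose step of each on-board agent subtracts a fixed class effect
  (defaults 4–5 mmHg SBP per step; DBP half of that), scaled by a
  patient-level lognormal sensitivity (sdlog 0.35) for heterogeneous
  response; chlorthalidone continues the HCTZ ladder with a step offset
  of 2 so the thiazide sequence is monotone;
* home readings add N(0, 6²) mmHg measurement noise; office readings add
  a white-coat offset (mean 10, SD 6 mmHg) — within-person home-BP
  variability and white-coat effects of this size are typical of
  home-monitoring cohorts;
* adherence thins the 28-slot schedule at 0.9 per slot;
* follow-up labs shift linearly per dose step (K +0.08 per RAAS step,
  +0.15 per MRA step, −0.12 per TD step; Na −0.7 per TD step; creatinine
  +3% per RAAS/MRA step) with small Gaussian noise.

One random substream per patient (master seed + patient index, weekly
draws keyed on the week number) makes the entire log bit-reproducible
and insensitive to cohort edits elsewhere.

What the simulator does **not** emulate: pharmacokinetics, adverse
events beyond lab shifts, diurnal BP patterns, autocorrelated noise,
non-adherence clustering, or drop-out. Passing tests therefore
demonstrate the *engine's* correctness against a known ground truth, not
clinical effectiveness on real data; the program's clinical outcomes are
a property of real cohorts and are out of scope here.

A useful consequence of the linear model: with noise, sensitivity
spread and white-coat offset all at zero, the number of medication
changes the engine makes before a patient reaches maintenance equals the
closed-form number of dose steps needed to bring both channels under
goal — the parameter-recovery check in the acceptance suite (run at
4 patients × ≤ 30 weeks; the fuzz suite runs 10,000 engine invocations
and the full test suite completes in well under a minute on one CPU).

## Degenerate inputs and numerical details

* Dates are ISO-8601; timestamps are interpreted in UTC so "calendar
  day" is unambiguous and reproducible across machines.
* Weeks since a dose change are computed as exact day differences / 7
  and compared inclusively ("at least 1 week" admits exactly 7 days).
* An empty reading week yields an *insufficient* summary with undefined
  means — flagged, never an exception; an empty office history simply
  fails inclusion.
* A missing UACR is treated as below the 30 mg/g pathway threshold with
  a logged warning; missing labs suppress the rules that need them
  (never the blocks: a lab-requiring class with no panel at all is
  blocked outright).
* Tied office-visit dates are broken by record order with a warning.
* Postural-drop and goal comparisons are inclusive at their printed
  boundaries (a drop of exactly 20/10 flags; a weekly mean of exactly
  130/80 is above goal), matching standard definitions.

## Limitations

The engine encodes one program's protocol; site deployment requires
reviewing every default in the configuration against local policy. The
simulator's lifestyle-trial handling reassesses after the 2-month window
at weekly cadence rather than modeling behavioral change. Combination-
pill consolidation checks component stability, not dose-pair
availability, against the configured product map. None of this code is a
medical device; it is a reference implementation for testing and
research.
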