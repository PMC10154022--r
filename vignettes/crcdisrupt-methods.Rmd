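---
title: "Methods: simulating disruptions to colorectal cancer screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating disruptions to colorectal cancer screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcdisrupt)
```

## The question the package answers

Screening for colorectal cancer (CRC) works by interrupting the
adenoma–carcinoma sequence: most CRC arises from adenomatous polyps that
grow slowly, a few of which transform into preclinical cancer that later
surfaces clinically. Removing adenomas at colonoscopy prevents cancers;
detecting preclinical cancer earlier improves survival. When screening is
disrupted — delayed, switched to a less sensitive modality, or abandoned
— part of that benefit is forfeited. `crcdisrupt` measures the forfeited
part, in life-years, for cohorts defined by age and pre-pandemic
screening behaviour, under an explicit menu of disruption scenarios.

The estimand for a scenario is a contrast between three runs of the same
simulated people: life-years under no screening (LYNS), under the
undisrupted screening plan (LYND), and under the disrupted plan (LY), all
accrued from the beginning of 2020 over remaining lifetimes and scaled
per 1000 persons. The package reports LYL = LYND − LY,
LYG = LYND − LYNS, %LYLost = 100·LYL/LYG, lifetime CRC cases and deaths
per 1000, and life-days lost per person. Because all three arms replay
identical natural histories (common random numbers), the identities hold
exactly, and Monte-Carlo standard errors come from paired per-person
differences, which are far tighter than independent-arm errors.

## Natural-history model

Each person carries:

* **Other-cause mortality:** a death age sampled from a cohort life table
  (discrete year plus uniform within-year offset). The bundled table is
  Gompertz–Makeham, hazard $a + b e^{c\,\mathrm{age}}$ with
  $a = 5\times10^{-4}$, $b = 3\times10^{-5}$, $c = 0.09$, capped at age
  100 — a synthetic but realistic stand-in for US all-cause mortality
  that avoids any external data dependency.
* **Frailty:** a mean-1 multiplicative risk on adenoma onset (gamma or
  lognormal, variance configurable per preset). Risk heterogeneity
  matters because screening benefit concentrates in high-risk people.
* **Adenoma onset:** a non-homogeneous Poisson process with a
  piecewise-constant baseline age hazard (zero before 20, rising with
  age) scaled by the frailty.
* **Growth:** per-lesion exponential diameter growth from 1 mm at a
  lognormal rate, mapped through the 6 mm and 10 mm thresholds into the
  size classes 1–5 mm, 6–9 mm, ≥10 mm. Size class is therefore monotone
  in age, which is what the size-class-specific test sensitivities need.
* **Transformation:** size-class-dependent annual probabilities of
  adenoma → preclinical cancer, converted to hazards and inverted at an
  Exp(1) draw.
* **Sojourn and survival:** preclinical-to-clinical time from a
  preset-specific distribution; survival after diagnosis is lognormal,
  evaluated at a per-lesion quantile draw with a larger meanlog for
  screen-detected cancers, so screen detection stochastically dominates
  clinical detection by construction rather than by sampling accident.

Only the adenoma pathway is modelled (no serrated lesions), and nothing
after CRC diagnosis is simulated beyond the survival draw.

### The two presets

Published comparative analyses of this kind rest on independently
calibrated microsimulation models whose parameters are not printed in the
papers. This package instead ships two explicit, documented presets and
reports every outcome as the min–max range across them:

| | preset-A | preset-B |
|---|---|---|
| frailty | gamma, var 1.2 | lognormal, var 1.8 |
| growth rate meanlog | −2.16 | −2.30 |
| transformation (S/M/L, per yr) | 2e-4 / 1.5e-3 / 0.015 | 1e-4 / 2e-3 / 0.018 |
| sojourn | lognormal, mean ≈ 3.5 y | exponential, mean 5 y |
| FIT positivity | per-person | per-lesion |

Both were parameterized once, at design time, to land lifetime unscreened
clinical CRC incidence in a plausible 4–7% band (they measure 6.3% and
5.9%) and to differ enough that cross-preset ranges are non-degenerate.
They are **not** calibrated to SEER or to any registry: absolute
life-year levels are illustrative, and the meaningful outputs are
contrasts, identities and ranges. All parameters live in YAML files under
`inst/extdata/` and are validated on load.

## Test characteristics

Colonoscopy applies an independent Bernoulli per prevalent within-reach
lesion with size-class sensitivity (high: 0.75/0.85/0.95, low:
0.55/0.70/0.90; preclinical cancer 0.95 in both), removes every detected
adenoma in that scenario's replay, and converts a detected preclinical
cancer into a screen-detected diagnosis that ends screening. Colonoscopy
specificity (0.86) is carried in the profile but deliberately unused:
false-positive colonoscopies matter for burden and cost outcomes, which
are out of scope. The within-reach flag defaults to probability 1 and is
configurable per preset.

FIT supports both positivity conventions found in practice: *per-person*
(positive with the sensitivity of the most advanced prevalent lesion,
0.05/0.15/0.22 by size and 0.74 for preclinical cancer; 1 − 0.97 if
lesion-free) and *per-lesion* (each lesion triggers its own draw at
0.00/0.114/0.159, preclinical 0.62565 early / 0.886 late, OR'd with an
independent other-cause-bleeding draw at 1 − 0.97). The early/late split
for the per-lesion preclinical sensitivities is taken at the lesion's
sojourn midpoint; that split is an interpretive choice, not an assertion
about the source convention. A positive FIT triggers a diagnostic
colonoscopy at the same age. Per-lesion FIT draws are independent across
exams (no persistent bleeding trait), the simplest defensible model.
FIT, being a stool test, ignores the within-reach flag. A per-lesion
small-adenoma sensitivity of 0 is honoured literally: small adenomas can
never trigger a per-lesion FIT.

Exam randomness is drawn per (person, exam index, lesion slot), so the
high- and low-sensitivity profiles consume identical uniforms and the
lesions detected under the low profile are always a subset of those
detected under the high profile — the cleanest way to make
sensitivity-scenario contrasts noise-free.

## Surveillance state machine

After any colonoscopy that detects adenomas the person leaves routine
screening for colonoscopic surveillance. The interval to the next exam is
a function of the findings categories of the two most recent
colonoscopies (normal; 1–2 small; 3–4 small; 5–10 small or any ≥10 mm;
\>10 adenomas), using the shortest guideline interval wherever the
guideline offers a range. The no-prior row uses the same five categories;
one published rendering of that row prints "10 adenomas" where the other
blocks print "5–10", which the package treats as the same category. Two
boundary rules complete the machine:

* a normal **first** (screening or diagnostic) colonoscopy does not start
  surveillance; the person resumes their original modality 10 years
  later (or the routine interval if it exceeds 10);
* surveillance stops after age 85 **unless** the most recent exam found
  adenomas. The canonical worked example: 1–2 small adenomas at a
  surveillance exam at 83 schedules the next exam at 90 (interval 7);
  a normal exam at 83 after a normal prior exam would propose 93, which
  is dropped.

Once on surveillance a person stays colonoscopy-based until the stopping
rule ends it; the package resolves the (underspecified) question of
whether a FIT user ever returns to FIT after entering surveillance in
favour of the surveillance rules taking precedence. Negative FITs never
touch the surveillance state.

## Cohorts, calendar and scenarios

Eight cohorts are indexed by age in April 2020 (50, 60, 70) and
pre-pandemic behaviour: never screened (U50, U60, U70), colonoscopy at 50
(C60) or 50 and 60 (C70), annual FIT since 50 (F60, F70), and biennial
FIT at 50–56 (f60). Calendar time is anchored so a person's age equals
the cohort age exactly at pandemic onset (calendar 2020.25); life-years
accrue from 2020.0, i.e. from age −0.25 relative to the anchor. The
0.25-year offset is common to all arms and cancels exactly in LYL and
LYG. "Biennial" FIT is read as every-two-years testing.

Scenario labels follow `"[cohort] | [disruption]"`. Disruptions:

* **Short delays** (`C3m`/`C9m`/`C18m`, `F3m`/…): the first exam due at
  or after pandemic onset shifts by 3, 9 or 18 months and the shift
  carries forward, preserving pairwise gaps — even past the nominal
  stopping age, matching the carry-forward convention (a colonoscopy due
  at 60 under an 18-month delay happens at 61.5, the next at 71.5).
* **Long-term delays** (`C@65`, `C@75`): post-pandemic colonoscopies are
  replaced by explicit exams at 65 and 75 (75 alone for 70-year-olds),
  deliberately overriding the stop age.
* **Switching** (`F[d]m` for C60/C70): all post-pandemic exams become
  annual FIT to age 75, shifted by the stated delay; the switch is
  permanent, as a boundary case.
* **Discontinuation** (`U`): no exams at or after pandemic onset —
  including surveillance of previously detected adenomas, making it the
  upper bound on disruption harm.

Surveillance exams that fall due inside a delay window are postponed to
the window's end and subsequent intervals run from the actual exam date;
the routine backbone carries the full shift. Diagnostic colonoscopies
happen at their FIT's (possibly shifted) age. Cohort membership
conditions on being alive and CRC-free at pandemic onset under the
no-disruption history; since all screened arms share the pre-pandemic
exam prefix draw-for-draw, the inclusion set is arm-invariant, and the
no-screening arm is evaluated on the same people.

## Randomness and reproducibility

Every draw is a pure function of (root seed, person id, stream id,
counter) through a keyed SplitMix64 hash; distribution sampling applies
R's quantile functions to those uniforms. Streams separate mortality,
frailty, lesion count, per-lesion blocks of 8, and per-exam blocks of 64
(slot 0 person-level, slot *j* for lesion *j*). Consequences, all tested:
bit-identical populations for a given seed; the first *k* persons of an
*n*-person run equal the *k*-person run; person *i*'s natural history is
invariant to the consuming scenario; and engine output is identical
between the compiled C++ replay and the pure-R reference replay, which
exists precisely to cross-validate the compiled core.

## Numerical and design choices

* Exams occur at exact scheduled continuous ages, no within-year jitter —
  determinism and comparability outweigh realism here.
* Ties: a cancer surfacing clinically exactly at an exam age is resolved
  clinically after the exam misses it; age comparisons use 1e-9-year
  guards. Lesion counts are capped at 60 per person (the Poisson tail
  beyond this is negligible at the bundled parameters).
* Life-years are undiscounted; the published magnitudes this design
  mirrors imply undiscounted accounting. Discounting would be a
  post-processing hook, not a simulation change.
* Internal accounting is full precision; only report rendering rounds
  (integers for life-year columns, nearest integer for percent).
* Percent lost is undefined (NA) when LYG ≤ 0.
* The dot-plot data filter (≥2 life-days lost per person) and descending
  sort mirror the reporting convention of the comparative analyses this
  package emulates.

## Problem sizes

Bundled defaults are chosen for desk-scale work: unit tests run cohorts
of 10³–10⁴ persons; the property-level checks (accounting conservation,
delay-severity dominance, sensitivity-scenario contrasts) use 10⁵
persons per preset, where paired Monte-Carlo standard errors on LYL are
a few life-years per 1000 — small enough to resolve the dominance
ladder. Published analyses of this kind use 10⁷ persons; nothing in the
engine precludes that scale (it replays roughly 10⁶ persons·scenarios
per second per core), but the shipped tests do not need it.

## What the synthetic data does and does not show

The generator emulates: heterogeneous adenoma risk rising with age,
size-structured lesion progression, sojourn-time dynamics, modality- and
size-dependent detection, guideline surveillance, and realistic
old-age mortality. It does not emulate: registry-calibrated incidence by
age/stage/site, serrated-pathway cancers, stage-specific treatment and
survival, adherence behaviour beyond the scenario definitions,
correlation between disruption exposure and CRC risk, or COVID-19
mortality itself. Green tests therefore certify the *mechanics* —
accounting identities, state-machine fidelity, operating
characteristics, monotone dose-response of harm in disruption severity —
and the *qualitative* conclusions (short delays cheap, discontinuation
expensive), not absolute life-year magnitudes for any real population.

## Known limitations

* Two presets bound structural uncertainty only coarsely; real
  cross-model ranges come from independently calibrated models.
* Surveillance, once entered, never returns a person to FIT; guidelines
  are ambiguous here and the alternative reading would slightly raise
  FIT-arm benefit.
* Per-person FIT positivity ignores multiplicity of lesions by design
  (that is what the convention means); the per-lesion preset exists to
  bracket this.
* The early/late preclinical FIT sensitivity split at the sojourn
  midpoint is an interpretation; no published definition was available
  to pin it down.
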