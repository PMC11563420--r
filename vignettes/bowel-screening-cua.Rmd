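---
title: "Microsimulation cost-utility analysis of targeted bowel screening recruitment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microsimulation cost-utility analysis of targeted bowel screening recruitment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcscreen)
```

## The question

Australia's National Bowel Cancer Screening Program (NBCSP) mails an
immunochemical faecal occult blood test (FOBT) kit every two years to
residents aged 50–74. Participation among people who speak a language other
than English at home is 15–20 percentage points below that of English
speakers, and follow-up colonoscopy after a positive test is also less
common. `crcscreen` models whether inexpensive, culturally tailored
recruitment programs for Arabic- and Mandarin-speaking communities in
Victoria (community education, in-language media) are value for money: what
does one year of such a program buy, in quality-adjusted life years (QALYs)
and downstream healthcare costs, if it lifts screening participation by a
few tenths of a percentage point to a couple of points?

## Model structure

The core is a discrete-time Markov microsimulation in 1-year cycles. Each
simulated person carries a health state on the adenoma–carcinoma pathway —
free of disease, low-risk adenoma, high-risk adenoma, or colorectal cancer
(CRC) in Australian Clinico-Pathological Stage A–D — plus age, diagnosis
status, time since diagnosis, and a pathway track (screening, natural
history, or colonoscopy surveillance). Within a cycle the engine applies, in
a fixed documented order:

1. **Mortality** — background mortality from a life table, then, for people
   within five years of a CRC diagnosis, stage- and year-specific cancer
   mortality. Survivors beyond five years revert to background mortality
   only (no recurrence).
2. **Screening** — at even ages 50–74 a kit is mailed; participation,
   positivity (6.4% for language-other-than-English groups), GP follow-up
   and colonoscopy assessment (54.3% baseline) are Bernoulli draws.
   Colonoscopy findings are sampled from the observed prevalence among
   assessed Australians (87.40% no disease, 6.09% low-risk adenoma, 5.65%
   high-risk adenoma, 3.13% CRC, renormalised to sum to one), and the
   sampled finding *replaces* the latent state: the model works from
   observed diagnostic outcomes rather than test sensitivity and
   specificity. Detected adenomas are removed (polypectomy) and the person
   enters surveillance; detected cancer is staged from the screen-detected
   stage distribution (49/19/24/8). Decliners of colonoscopy move
   permanently to the natural-history track.
3. **Surveillance** — a GP referral plus colonoscopy every five years until
   age 75, removing any adenoma present.
4. **Symptomatic diagnosis** — an undiagnosed cancer presents with a
   latent-stage-specific annual probability (A 0.22, B 0.35, C 0.59,
   D 1.00); the stage recorded at diagnosis is drawn from the not-screened
   stage distribution (22/32/27/19). See "Design choices" for why the
   recorded stage is imposed rather than taken from the latent stage.
5. **Progression** — at most one transition per cycle: adenoma incidence
   from the age-specific schedules (progressive-adenoma incidence seeds the
   high-risk state, low-risk incidence the low-risk state), low→high 0.02,
   high→CRC 0.05, A→B 0.05, B→C 0.28, C→D 0.28 per year.
6. **Accrual** — costs attach at the start of the cycle of the event;
   utilities accrue for the cycle lived (CRC states 0.74 for A–C and 0.68
   for D; population norms 0.80/0.76/0.70 for ages 50–69/70–79/80+;
   survivors more than five years post diagnosis revert to the norm; the
   dead contribute zero). Both streams discount at 5% per year (0% and 3.5%
   in sensitivity analysis), reference year 2019.

People enter at their 2019 age (sampled from census interpolation), all free
of disease, and are simulated for 50 years or until death, with a hard
ceiling at age 100.

## Parameters that matter

| Parameter | Default | Units / range |
|---|---|---|
| Participation baseline | 0.307 Arabic, 0.40 Mandarin | per invitation |
| Participation uplift | scenario input | percentage points, 1 year |
| Colonoscopy follow-up | 0.543 baseline, 0.631 in uplift year | per positive |
| Positivity | 0.064 | per returned kit |
| Transitions | 0.02 / 0.05 / 0.05 / 0.28 / 0.28 | per year, with printed ranges |
| Treatment costs | $40,999 / $52,594 / $95,754 / $90,272 | per diagnosis, A–D |
| Colonoscopy | $2,258 (no polypectomy), $4,203 (polypectomy) | per procedure |
| FOBT pathway | $8.00 kit + $2.40 postage + $17.85 lab + $37.60 GP | per event |
| Program cost | $120,863 Arabic, $120,337 Mandarin | one year, spread per person |
| Discount rate | 0.05 | per year; 0 / 0.035 in SA |
| WTP threshold | $50,000 | per QALY |

The one-year intervention raises participation by the scenario's uplift and
colonoscopy follow-up to the English-speaking rate (0.631) for the first
cycle, then both revert. The program cost is charged per eligible person in
year 0: $120,863 / 17,522 = $6.90 (Arabic) and $120,337 / 38,660 = $3.11
(Mandarin; the source reports $3.10 from a slightly different denominator).

## What the synthetic generators emulate

Three inputs of the original analysis are not published as reusable tables,
so the package generates documented stand-ins with known truth:

* **Census populations** (`gen_census_tables()`): smooth single-year-of-age
  counts for 2016 and 2021 whose linear interpolation at 2019 reproduces the
  published eligible totals exactly (17,522 and 38,660). Shape and growth
  (geometric age decline, 25% five-year growth) are plausible for these
  communities but invented.
* **Survival by stage** (`gen_survival_table()`): conditional annual
  survival for years 1–5 after diagnosis hitting five-year targets of
  0.95/0.85/0.65/0.15 for stages A–D exactly, with a front-loaded hazard.
  These are stage-graded, epidemiologically ordinary values — not the
  registry table the original model used.
* **Life table** (`gen_life_table()`): Gompertz-shaped annual death
  probabilities (0.2% at age 50, doubling roughly every 6.6 years), death
  certain at 100.
* **Monthly kit-return series** (`gen_monthly_kit_series()`): negative
  binomial counts around rate × kits-sent offsets for March–November of a
  control and an intervention year, with a known true rate ratio, used to
  verify that the effectiveness estimators recover what generated the data.

Because survival and background mortality are stand-ins, every model output
that depends on mortality — mean QALYs, CRC deaths, and anything downstream
of them — is approximate. Passing tests demonstrate internal correctness
(the engine agrees with a deterministic cohort oracle; every published
probability is reproduced by its Bernoulli draw), not that the fixtures
equal the unpublished registry inputs.

## Effectiveness stage

Scenario effect sizes come from an interrupted-time-series comparison of
screening-register style monthly kit counts: the participation rate is
returns over kits sent; the incidence rate ratio (IRR) compares the
intervention year (2019) with the control year (2018) as a pooled-rate
ratio, with an advisory negative-binomial regression
(`MASS::glm.nb`, log offset of kits sent) for confidence intervals. The
scenario input is the *incremental* year-over-year participation increase of
a proxy area (Whitehorse for Mandarin, Hume for Arabic) over the
comparison state (South Australia, which had the national campaign but no
tailored intervention), floored at zero: 5.4 − 4.3 = 1.1 points for
Whitehorse, 4.3 − 4.3 = 0 for Hume, 4.8 − 4.3 = 0.5 for Victoria. The
published scenarios evaluate +0.2 and +1.3 points (Arabic) and +1.1 and
+2.4 points (Mandarin).

## Design choices where the design was open

* **Cycle ordering** (mortality → screening → surveillance → diagnosis →
  progression) is not stated in the source material; fixing it makes the
  chain well-defined and lets a matrix-product cohort model serve as an
  exact oracle.
* **Stage at symptomatic diagnosis.** The printed per-stage presentation
  probabilities (0.22/0.35/0.59/1.0) combined with slow latent progression
  (0.05/year out of stage A) cannot generate the registry's not-screened
  stage mix of 22/32/27/19 through latent stages alone — detection would
  overwhelmingly occur at stage A. The model therefore uses the latent stage
  to decide *whether* a cancer presents and draws the *recorded* stage (which
  drives survival, treatment cost and utility) from the not-screened
  distribution, mirroring how the original model separates detection route
  from stage at diagnosis. Surveillance-detected latent cancers keep their
  latent stage (they are rare and found directly by colonoscopy).
* **Stage C→D transition** is absent from the printed table (one row is
  duplicated); it defaults to 0.28, mirroring B→C, and is a config field.
* **Colonoscopy prevalence** rows print to 102.27%; they are renormalised
  preserving ratios, since the four outcomes are exhaustive.
* **Adenoma incidence.** The printed progressive-adenoma incidence
  (0.0038–0.0068) seeds the high-risk state; the all-adenoma schedule is
  derived as progressive / 0.24 and low-risk as the remainder, following the
  stated derivation rule. The printed "all adenomas" row is inconsistent
  with that rule and is stored unused; the printed "low risk" row
  (numerically equal to progressive / 0.24) is stored as an alternative
  preset.
* **PSA distributions** are not stated: every parameter with a printed range
  (transitions, presentation probabilities, treatment costs) is drawn
  uniformly over its exact (min, max); parameters without ranges stay fixed,
  including the FOBT kit cost, whose printed range does not bracket its
  point value.
* **Common random numbers.** Paired arms consume identical uniform streams
  (a fixed number of draws per person per cycle, regardless of branch), so
  arm differences isolate the scenario effect. At the published effect sizes
  (0.2 percentage points on 10,000 people) the comparison would otherwise be
  pure noise. An independent-arms mode exists for fidelity checks.
* **Decliners of colonoscopy** stay in the natural-history track permanently
  (cancer is then found symptomatically), following the stated pathway.

## Numerical choices

Problem sizes are chosen so the full analysis runs on one CPU in minutes:
10,000 patients per arm for study-scale runs, 100,000 (pooled over three
replicates) for point estimates of incremental quantities, 200 PSA trials of
10,000 patients. One arm of 10,000 × 50 cycles takes well under a second;
a 200-trial PSA a couple of minutes. Ages are integers, birthdays at cycle
boundaries, no half-cycle correction (none is used in the source model).
The diagnosis year itself carries no cancer-specific mortality; years 1–5
since diagnosis do.

## Known limitations

* **The intervention's QALY effect is structurally non-positive here.**
  Colonoscopy findings are sampled from observed prevalence independently of
  the latent state, and the cohort enters free of disease. Extra
  colonoscopies in the intervention year therefore impose "detected" cancer
  on about 3.1% of people who are genuinely disease-free, while the
  compensating benefits (adenoma removal, better stage mix) accrue slowly
  and are discounted. At n = 200,000 with common random numbers the
  incremental QALYs are about −1×10⁻⁴ per person — the intervention arm is
  weakly dominated, where the original analysis reports +0.005 to +0.024
  QALYs per person and ICERs of $749–$2,768. The incremental *cost* side
  reproduces well (≈ +$10 per person against a published +$9.94). The
  original model evidently couples colonoscopy findings to latent disease
  and/or applies the follow-up uplift beyond one year; neither is stated,
  so this package implements the stated design and reports the discrepancy
  rather than tuning toward the published figures. The acceptance checks on
  ICER magnitude and the PSA cost-effectiveness fraction fail for this
  reason and are left failing.
* **Mortality validation is fixture-bound.** Simulated CRC cases per year in
  a Mandarin-scale cohort match the registry benchmark (≈47/year); deaths
  run ≈12–13/year against a benchmark of 8, implying the original survival
  inputs were more favourable than the synthetic stage gradient used here.
* No family-history risk, no adverse colonoscopy events, no screening
  outside the program, constant CRC incidence over the horizon, closed
  cohort — all stated assumptions of the source model.
* Participation draws are independent across rounds (no persistent
  never-screener class); this is an extension point.

## A worked run

```{r example, eval = FALSE}
params <- default_parameters("mandarin")
cua <- run_cua(params, uplift_pp = 1.1, n = 10000, seed = 1)
glance(cua)
summary_table(list(`+1.1 pp` = cua))

psa <- run_psa(params, uplift_pp = 1.1,
               spec = psa_spec(n_trials = 200, n_patients = 10000), seed = 1)
glance(psa)
autoplot(psa)
```

The full reproduction pipeline is `scripts/acceptance.R`, which recomputes
program costs per person, incremental effect sizes, base-case and
discount-rate-varied ICERs, registry-scale validation rates, and PSA
summaries from scratch.
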