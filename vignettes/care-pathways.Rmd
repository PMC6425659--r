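---
title: "Care pathways after mental-health ambulance calls: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Care pathways after mental-health ambulance calls: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(carepath)
```

## The analysis model

`carepath` analyses linked person-level records of unscheduled care:
ambulance calls, emergency-department (ED) attendances, hospital
admissions (acute and psychiatric wards) and death registrations, joined
by a person identifier. The analysis proceeds in five stages.

### 1. Cohort selection

An ambulance call is a *mental-health call* when its final AMPDS dispatch
code is on a ten-entry inclusion list (`ampds_inclusion_list()`): nine
full five-character codes covering psychiatric emergencies, hanging and
jumper falls, plus the chapter-level entry `"23"` (intentional
poisoning), which matches any code starting with `23` under the default
prefix mode. The *index cohort* holds one episode per person: the
earliest mental-health call of the index calendar year, restricted to
persons who were resident in scope and at least 16 years old (attained
age in completed years at the call). Exclusions are tallied by reason
(`unknown_age`, `under_16`, `non_resident`).

### 2. Pathway construction

All of a person's timed contacts — ambulance calls (`S`), ED attendances
(`E`), acute admissions (`A`), psychiatric admissions (`M`) — are sorted
and chained into *care pathways*: a contact continues the current pathway
when it starts no more than 24 hours after the previous contact's end
(its start when the end is missing); exactly 24 hours still links.
Each pathway is encoded as its letter string, truncated at 11 characters.
Pathways are duplicated once per mental-health call they contain, each
row anchored at that call, and classified from the anchored suffix:

| suffix      | class    |
|-------------|----------|
| `S`         | `S`      |
| `SE`        | `SE`     |
| `SEA`       | `SEA`    |
| `SEM`, `SM` | `SEM_SM` |
| anything else | `OTHER` |

```{r pathways}
t0 <- as.POSIXct("2011-02-01 21:00", tz = "UTC")
contacts <- data.frame(
  contact_id = c("S1", "E1", "E2"), person_id = "P1",
  service_class = c("S", "E", "E"),
  start_datetime = c(t0, t0 + 45 * 60, t0 + 21 * 3600),
  end_datetime = c(t0 + 40 * 60, t0 + 4 * 3600, t0 + 23 * 3600))
attr(link_contacts(contacts)[[1]], "code_string")
classify_pathway("SEE")
```

### 3. Follow-up

The cohort converts to person-period format: one row per person counting
later ambulance calls within 365 days of the index timestamp (all-cause
by default, since repeat calls by these people are not necessarily
mental-health coded), binned as 0/1/2/3/4/5–9/10–14/15+. Mortality within
one year splits at the one-calendar-day boundary: a death dated no later
than the index date plus one day counts as *within one day*; later deaths
up to 365 days count as *one day to one year*, with causes categorized as
suicide, mental/behavioural or other.

### 4. Statistics

Two 2×2 analyses follow the self-discharge theme: alcohol involvement
against ED self-discharge (over ED-ending pathway rows) and index
self-discharge against any repeat call (over persons whose index pathway
reached an ED). Both use the uncorrected Pearson χ² (`chi_squared_2x2()`;
Yates' correction available behind a flag) and the relative risk with a
log-normal 95% CI. ED length of stay compares self-discharged against
completed attendances with the Wilcoxon rank-sum z using mid-ranks and
the tie-corrected variance; medians and IQRs use type-7 quantiles.

### 5. Reporting

Three tables — reasons for call, repeat-attendance bins, and pathway
class by outcomes — render with half-up rounding at the printed
precision (`round_half_up(42.5)` is 43) and optional disclosure control:
counts strictly between zero and the suppression threshold render as
`< N`; totals are never suppressed and stored data are never altered.
Internal totals must reconcile with the cohort size or the build fails.

## The synthetic-data generator

Real linked health records cannot be distributed, so `generate_bundle()`
simulates a bundle whose analysed distributions match published national
values. Each person receives one index mental-health call in the index
year plus a repeat-call count drawn from the calibrated bin distribution;
every call spawns a pathway from the class mixture, materialized with
intra-pathway gaps under 24 hours (so chaining holds by construction)
while distinct calls sit at least 48 hours apart (so pathways never chain
accidentally).

Design choices worth knowing when you change the configuration:

* **Self-discharge is a marginal probability.** The configured
  `selfdischarge_prob` (0.17) is the proportion among ED-ending rows.
  Because alcohol multiplies the risk by `rr_alcohol_on_selfdischarge`
  (1.49), the generator derives the unexposed baseline as
  `p / (1 - a + a * RR)` with `a = alcohol_prob`, so both the marginal
  and the risk ratio are recovered by the analysis.
* **Repeat calling depends on self-discharge** the same way: the
  probability of any repeat call is scaled so the marginal bin
  distribution holds while self-dischargers repeat at
  `rr_selfdischarge_on_repeat` (1.25) times the baseline rate.
* **`OTHER` pathways** are one ambulance call followed by 2–10 letters
  over `{E, A, M}` (rejecting the named classes), so each generated
  pathway contains exactly one call and the repeat-bin distribution stays
  exact under per-call duplication.
* **Deaths within one day** force zero repeat calls; the survivors' bin-0
  probability is renormalized so the marginal distribution over all
  persons still matches. Those index pathways are compressed to span
  under 24 hours so every contact starts by the death date; late deaths
  are dated after the person's last contact.
* **ED length of stay** is log-normal (σ = 0.6) re-parameterized by the
  target median (150.7 min completed, 100.5 min self-discharge); IQRs are
  therefore approximate.

The same seed always yields a field-identical bundle, and
`run_pipeline()` output directories are byte-identical across runs.

```{r recovery}
b <- generate_bundle(simulation_config(n_persons = 2000L), seed = 7L)
s <- summarize_bundle(b)
round(s$pathway_mixture, 3)
round(c(selfdischarge = s$selfdischarge_prop,
        rr_alcohol = s$rr_alcohol_on_selfdischarge,
        rr_repeat = s$rr_selfdischarge_on_repeat), 3)
```

## Problem sizes and limitations

The pipeline is vectorized: generating and analysing 20000 persons
(~60000 ambulance calls, ~130000 contacts) takes a few seconds. Known
limitations: the rank-sum p-value uses the normal approximation, which
deviates from the exact permutation distribution for very small samples
(the tie-corrected variance is exact; agreement within 0.10 in p needs
both samples ≥ 5); IQRs of simulated lengths of stay are approximate; and
the generator's calls-per-person ratio is governed by the repeat-bin
distribution plus `repeat_nonmh_prob`, not calibrated separately.
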