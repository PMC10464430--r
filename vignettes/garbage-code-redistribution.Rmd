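---
title: "Redistributing ill-defined causes of death: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Redistributing ill-defined causes of death: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcredist)
library(data.table)
```

## The problem

Official mortality statistics tabulate a single underlying cause of death
(UC) per death certificate. A substantial fraction of UCs — in ageing
Western European populations roughly a third — are *ill-defined deaths*
(IDDs, "garbage codes"): codes too unspecific (R99, "ill-defined and
unknown cause of mortality") or causally implausible (I46, cardiac
arrest; I50.9, unspecified heart failure) to support burden-of-disease
accounting. Ignoring them understates exactly the causes that dominate
old-age mortality. `gcredist` implements a four-step probabilistic
redistribution of IDDs onto a GBD-style cause hierarchy that exploits
the *multiple causes of death* (MCOD) listed on the certificate, and
quantifies the resulting fatal burden as deaths and Standard Expected
Years of Life Lost (SEYLL) with Monte-Carlo uncertainty intervals.

## The redistribution model

Each UC is first mapped to a four-level cause hierarchy (level 1
clusters: non-communicable; communicable, maternal, neonatal and
nutritional; injuries → level 2 groups → level 3 causes → level 4
subcauses) by longest-prefix match on the dotless ICD-10 code, a
4-character entry shadowing its 3-character parent. Before mapping,
UC/MCOD *combination rules* recode drug-related deaths: poisoning codes
(X41, X44, X61, X64, Y11) combined with T43.6 on the certificate, or
(X42, X62, Y12) combined with T40, become drug-use disorder F19.
Records missing age or sex, and stillbirths (P95), are excluded and
counted.

IDDs then pass through four steps, in order; within a year, the output
of each step feeds the target distributions of the next:

1. **ICD-based redistribution.** IDDs whose code constrains the
   plausible true causes (e.g. C55, malignant neoplasm of uterus part
   unspecified) are redistributed pro rata to the occurrence of their
   predefined target codes (C53, C54) as UCs. Codes that are
   ill-defined only at level 4 (J18.9, I64) carry targets inside their
   own level-3 cause, so they are fully recovered at level 3 by the
   same mechanism rather than a special case.
2. **Package redistribution.** Intrinsically uninformative codes (N19
   and friends; I50.x heart failure) are grouped into *packages*; the
   target distribution is the UC mix of window deaths that mention a
   package code anywhere in their MCOD chain (any role) and whose
   current UC is specific or already redistributed.
3. **Internal redistribution.** Remaining IDDs are assigned uniformly
   at random to one of the distinct specific level-4 causes mentioned
   on their own certificate.
4. **All-cause redistribution.** Whatever remains — including deaths
   deferred from steps 1–3 for lack of support — is redistributed over
   all specific causes observed in the window. No death exits
   unassigned; the step at which each death was actually resolved is
   recorded.

Target distributions are built from the deaths of a rolling
`window_years = 5` reference window ending in the report year, so the
first reportable year is `min(year) + 4`. They are stratified by age
group (0–4, 5–14, 15–44, 45–64, 65–84, 85+; closed-open bounds) and
sex, fall back to a sex-only distribution when the stratum's support is
below `sparse_stratum_min`, and are empty (deferring to step 4) when
even that fails. Level-3 causes with fewer than `rare_cause_min = 5`
window occurrences (less than one per year) are excluded as targets —
rare causes have specific diagnoses and are rarely miscertified — and
sex-restricted causes (prostate, cervix, uterus, breast in the demo
map) are never offered to the other sex.

The whole process is repeated `n_iterations` times (default 100); each
iteration is a complete four-step run yielding a fully imputed dataset.
Summary statistics report the mean and the 2.5th/97.5th percentiles of
the per-iteration values (the 95% uncertainty interval, UI). A
`fractional` mode replaces sampling by exact fractional assignment of
each death over its target distribution; with one iteration it gives a
deterministic completed dataset whose counts the sample-mode means
converge to.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `window_years` | 5 | rolling target window (years) |
| `n_iterations` | 100 | probabilistic iterations |
| `rare_cause_min` | 5 | minimum level-3 window count for a target |
| `sparse_stratum_min` | 20 | stratum support below which sex-only is used |
| `master_seed` | 1 | RNG seed; child seed *i* is `master_seed + (i-1)·1000003` |
| `mode` | sample | `sample` or `fractional` |
| `update` | group | refresh targets per redistribution group or per step |

`sparse_stratum_min = 20` is a judgement call in common small-cell
practice; it is deliberately conservative and configurable. Group
processing order inside steps 1 and 2 is lexicographic (entry prefix,
package id): the order is not scientifically identified, so determinism
is prioritized. Whether targets refresh after every *group* or only
after every *step* is equally defensible; the per-group reading is the
default and `update = "step"` provides the alternative. Step-3
sampling is uniform over the *distinct* causes mentioned, not weighted
by the number of mentions.

## SEYLL and rates

SEYLL weights each death by the residual life expectancy at its age
from an aspirational reference life table, completed by anchoring
residual expectancy to 0 at age 122 (the highest observed human
lifespan) and interpolated linearly between knots:

```{r}
lt <- synthetic_life_table()
seyll_at_age(lt, c(70, 95, 108.5, 122))
```

Ages are completed years; a configurable `age_offset` (e.g. 0.5)
evaluates the table mid-interval instead — the choice is not
identified by the method and defaults to 0. The bundled life table is
*synthetic* (aspirational structure, life expectancy 88.9 at birth,
5-year knots to age 95); real analyses should supply their reference
table via `read_life_table()`. Deaths and SEYLL are reported as counts,
crude rates per 100,000, and age-standardized rates on five-year age
groups against the bundled 2013 European Standard Population (or any
user standard); population denominators are a user input.

## What the synthetic generator emulates

`generate_synthetic_deaths()` produces microdata with known ground
truth: old-skewed ages (Normal(79, 12) bulk plus a small young
component), a 51% female share, three regions, and a true level-4
cause drawn from age-group/sex-specific prevalence weights in which
cardiovascular disease, dementia and pneumonia dominate old age and
injuries young age. With probability `idd_fraction` the UC is garbled
into an ill-defined code drawn from a cause-specific garble
distribution; the true cause's ICD code stays on the certificate as a
contributory code with probability `p_mcod_truth`, and Poisson noise
adds further contributory codes.

Two generator design choices matter for interpretation:

* **Contributory codes are disease-linked.** Ill-defined MCOD mentions
  are drawn from the death's *own* garble distribution (heart failure
  is mentioned on cardiac deaths, N19 on kidney deaths), and specific
  comorbidity mentions follow the death's age/sex stratum mix. This is
  the mechanism package redistribution exploits in real certificates;
  with cause-independent mentions the MCOD chain would carry no signal
  and steps 2–3 would degenerate to all-cause behaviour.
* **The unassigned-garbage share is uniform across causes.** Every
  major cause family has its own garbage route (I50.9 for heart
  disease, I64 for stroke, J18.9 for pneumonia, C80 for cancers, Y34
  for injuries, J98 for chronic respiratory disease, K72 for
  cirrhosis, N19 for kidney/diabetes, F03 for dementia, C55 for
  uterine cancers), and the residual share garbled to wholly
  uninformative codes (R99, R96, R54, I46) is the same for all of
  them. Proportional redistribution is unbiased when IDD incidence is
  cause-independent; making the *class* of garbage cause-independent
  puts steps 3–4 in that regime, so recovery error measures the
  method, not an arbitrary generator asymmetry. Causes without a
  linked garbage code (Parkinson's disease, alcohol use, diarrhoeal
  disease) garble entirely to R-codes and carry a small residual bias.

The generator does **not** emulate temporal trends in garbling,
certifier- or region-specific coding styles, correlated comorbidity
structure beyond the stratum mix, or coding-revision artefacts.
Passing recovery tests therefore shows the algorithm is correct and
well-calibrated *under its own assumptions*, not that redistributed
national statistics are unbiased.

## Uncertainty intervals and their coverage

The UIs quantify the Monte-Carlo uncertainty of the probabilistic
redistribution *conditional on the observed data* — the only
uncertainty the method propagates. Against ground truth they are
anti-conservative: the truth also deviates from the conditional mean
through garbling and MCOD-retention sampling noise, and through small
systematic components introduced by the sex-only fallback in sparse
strata. In the package's validation suite the per-cause recovery error
stays within a few percent for all major causes, while the nominal 95%
intervals cover the true counts far less often than 95% — users should
read the UIs as redistribution-stochasticity bands, not as confidence
intervals for the unknown true cause-specific mortality.

## Numerical and degenerate-input choices

* Probabilities are renormalized counts; a target distribution sums to
  1 within 1e-12 or is empty.
* Deaths deferred by an empty distribution resolve at step 4;
  `resolution_step` records where each death was actually resolved.
* Step 4 falls back stratum → sex-only → both sexes pooled; it errors
  only when the window contains no specific deaths at all.
* Ages above 122 are clamped to 122 with a warning (the life table's
  terminal age); negative or missing ages are excluded.
* UC codes without any map entry are treated as unassigned IDDs with a
  warning, not errors.
* Within a group and stratum, deaths are processed in record order;
  all orderings are deterministic so a master seed fixes the ensemble
  byte-for-byte.

## Validation problem sizes

The test suite exercises the pipeline at the scales the package is
designed to run at comfortably on one core: conservation and safety
scans on 20,000 generated deaths, sampling-distribution checks on
10,000 draws, fractional/sample agreement on 5,000 deaths with 200
iterations, and ground-truth recovery on twenty independent
generations of 50,000 deaths with 20 iterations each (about a quarter
of a minute per generation-and-run). Larger national extracts simply
scale linearly in deaths and iterations.

## Known limitations

* The demo cause map is a compact teaching map (27 specific level-3
  causes); it covers the classic garbage codes but is not a national
  map, which users must supply.
* Region is an opaque stratifier: target distributions are never
  stratified by region, matching the reference method.
* MCOD roles (immediate/intermediate/associated) are retained on read
  but treated identically by steps 2–3.
* No regression-based or fixed-proportion redistribution is provided;
  those are different methods with different assumptions.
* ICD-9/ICD-11 and death-certificate text parsing are out of scope;
  input is ICD-10-coded microdata.
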