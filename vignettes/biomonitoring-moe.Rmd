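---
title: "Margin-of-exposure risk assessment from urinary biomarker data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Margin-of-exposure risk assessment from urinary biomarker data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biomoe)
library(dplyr)
```

## The problem

Chlorpyrifos is an organophosphate insecticide whose EU health-based
guidance values were repeatedly tightened over the last decade (ADI
0.01 mg/kg bw/day from 2006, 0.001 from the 2014 reassessment entering
legislation in 2016) until, with its genotoxicity potential unresolved, no
reference value could be set at all and the substance was banned in 2020.
When no acceptable daily intake exists, risk has to be characterised
retrospectively as a **margin of exposure** (MoE) between a toxicological
**point of departure** (PoD) and the measured exposure. Exposure here is
measured in urine through 3,5,6-trichloro-2-pyridinol (TCPy), the
metabolite chlorpyrifos shares with chlorpyrifos-methyl.

`biomoe` implements the full chain as reusable, tested components:

1. **Reverse dosimetry** — convert an animal PoD (mg/kg bw/day) into the
   equivalent urinary TCPy concentration, the *biomonitoring PoD*
   (HBM-PoD).
2. **Forward dosimetry from food monitoring** — convert dietary risk
   reported as *% of ADI* per diet into predicted urinary TCPy.
3. **Ingestion of aggregated biomonitoring percentiles** with validation,
   missing-value policy and creatinine-adjustment correction.
4. **Risk engine** — margins of exposure, a four-colour classification, and
   cross-study summaries.
5. **Uncertainty propagation** of the excretion-fraction range.
6. **Synthetic data** — lognormal biomarker populations and %-of-ADI diet
   tables so every stage is testable without external downloads.

## The model

### Reverse dosimetry

For an endpoint-specific PoD, the equivalent urinary concentration is

$$\mathrm{HBM\text{-}PoD} \;=\;
  \frac{\mathrm{PoD} \times R_{mol} \times F_{ue}}{V_{urine}}$$

with $R_{mol} = \mathrm{MW(TCPy)}/\mathrm{MW(chlorpyrifos)} = 0.566$ the
molar mass ratio, $F_{ue} = 0.7$ the molar urinary excretion fraction
(central estimate from human volunteer studies; plausible range
0.5–0.93), and $V_{urine}$ the body-weight-adjusted daily urinary output:
0.02 L/kg bw/day for adults and 0.03 for children under the harmonised
guidance-value convention. A third output convention, 0.024 L/kg bw/day, is
used by the food-monitoring forward model; the two conventions are kept as
separate named constants and never interchanged silently.

```{r}
derive_hbm_pods(chlorpyrifos_pods())
```

Because the children and adult values differ only by the urinary output,
their ratio is exactly $0.02/0.03 = 2/3$ for every endpoint — one of the
package's property tests.

### Margins of exposure and colours

For a measured (or predicted) urinary concentration $E$ (µg/L),

$$\mathrm{MoE} = \frac{\mathrm{HBM\text{-}PoD}}{E}.$$

Margins are computed at three exposure tiers of each study — the median
(average population), the 95th percentile (highly exposed group) and the
upper bound of the 95% CI of the 95th percentile (most exposed
individuals) — and classified into four colours built from standard
uncertainty-factor reasoning:

| category | RED below | ORANGE below | YELLOW below | rationale |
|---|---|---|---|---|
| overall (LOAEL) | 300 | 1000 | 10 000 | 100 × interspecies/intraspecies, ×3 LOAEL→NOAEL, extendable ×10 |
| short-term AChE | 100 | 300 | 3 000 | 100 ×, plus ×3 subacute→subchronic |
| generic NOAEL | 100 | — | 1 000 | 100 × baseline |
| carcinogenicity | 10 000 | — | 100 000 | unresolved genotoxicity |

GREEN is operationalised as a further factor of 10 above the most severe
applicable concern cutoff (the ORANGE cutoff where one exists, otherwise
the RED cutoff); this is stated explicitly because the underlying rule
("an additional margin of at least 10") is prose, not a table. ORANGE
exists only for the overall and short-term AChE categories; the others skip
from RED to YELLOW. Boundaries are strict: a margin exactly at a cutoff
belongs to the safer class, so an MoE of exactly 100 on a NOAEL is YELLOW,
not RED.

### Reporting conventions

Derived HBM-PoDs are reported at 2 decimals (mg/L) and margins as nearest
integers, both rounded half-to-even; full precision propagates internally
and classification always uses unrounded margins. Reported margins use the
*reported* (2-decimal) HBM-PoD values as their basis — the convention that
reproduces published tables ($3.96\,\mathrm{mg/L} \times 1000 / 6.52 = 607$
for the highest children's median) — with `basis = "full"` available
everywhere for full-precision work.

## A full run

```{r}
res <- run_pipeline()      # packaged aligned-study percentile summaries
res$ranges %>% filter(endpoint == "overall")
res$rollup %>% head(6)
```

The validation stage retains records with missing percentiles (the
"n.r." convention used when too many samples fall below the detection
limit) but flags them unusable per tier, and rejects ordering violations
(P50 > P95) to an issue log without ever altering clean values.

Known input inconsistencies are *documented, not replicated*: a few
published range bounds cannot be recovered from the published percentile
inputs (e.g. a children's carcinogenicity lower bound printed as 47 180
where the highest children's median implies 20 256, and a children's
overall upper bound printed as 6462 where the lowest median implies 6492).
The package always computes from its inputs; the tests assert the computed
values and record the discrepancy.

Studies that publish only margins (not concentrations) are handled through
`endpoint_rescale()`: at fixed exposure the margin is proportional to the
HBM-PoD, so one published margin determines all others, e.g.
`endpoint_rescale(2970, "overall", "carcinogenicity")` = 99 050. Fallback
statistics (geometric mean standing in for the median, 75th percentile for
the 95th, maximum for the upper CI) are disclosed per tier in the packaged
study table rather than silently substituted.

## Food-monitoring forward model

Annual EU monitoring reports express each diet's highest calculated
chronic exposure as % of the ADI. The forward model recovers the external
dose as $\%ADI/100 \times ADI$, converts to molar units, sums the TCPy
contributions of chlorpyrifos and chlorpyrifos-methyl, and applies
$F_{ue} = 0.7$ and the 0.024 L/kg bw/day output. The default ADI table
assigns chlorpyrifos 0.01 mg/kg bw/day for report years 2012–2015 and
0.001 from 2016, and keeps 0.01 for chlorpyrifos-methyl throughout; it is
fully overridable because the reports do not state which ADI underlies each
year's percentages. The chlorpyrifos-methyl molar ratio (0.615 =
198.43/322.53 from standard molecular weights) is likewise configuration,
not hard-coding.

Per-year box-whisker summaries use linear-interpolation quantiles
(`type = 7`); the underlying per-diet inputs of the published yearly figure
are not printed anywhere, so no quantile convention could be validated
against it — the choice is documented and configurable. The yearly figure
itself is consequently not a reproduction target; what *is* exactly
assertable is its mechanism: at fixed %ADI, the tenfold ADI reduction in
2016 drops every predicted concentration exactly tenfold.

## Uncertainty propagation

The dominant stated parameter range is the excretion fraction
(0.5–0.93 around 0.7). `moe_bounds()` recomputes the whole chain at the
range endpoints — the margin is increasing in $F_{ue}$, so the interval
always brackets the central estimate. `moe_mc()` samples $F_{ue}$ from a
triangular distribution (chosen because only a low/central/high triple is
stated; the family is configurable through `rtriangular()` replacements)
and summarises the margin distribution by P5/P50/P95. A seed is mandatory
and reruns are bit-identical. Exposure-side variability is deliberately
excluded by default: the percentile tiers already encode it.

## What the synthetic generator emulates — and what it does not

`simulate_population()` draws individual concentrations from a lognormal
distribution parameterised by median and $\sigma_{\log}$, matching the
multiplicative framing in which biomarker variability is reported:
$P95/P50 = \exp(1.645\,\sigma_{\log})$, so observed ratios of ~4 and ~10
correspond to $\sigma_{\log} \approx 0.84$ and $1.40$. Optional
detection-limit censoring reproduces the not-reported convention: records
whose censored fraction exceeds 60% (configurable) withhold their
percentiles. `aggregate_to_record()` aggregates to the ingestion schema,
with the upper CI of P95 from a seeded percentile bootstrap (default 1000
resamples; the two-sided 95% interval attains 90–98% empirical coverage at
n = 200 in the test suite, run over 500 seeded replicates of 400 resamples
each — sizes chosen to make the coverage experiment a routine part of the
suite). `simulate_diet_table()` draws per-diet %ADI values uniformly within
era-specific ranges, with the era break at 2016.

The generator does **not** emulate country-specific covariate structure,
dietary questionnaires, creatinine physiology, correlations between
pesticides within a diet, or non-dietary exposure routes. Passing tests
therefore demonstrate correctness of the computational chain and the
statistical calibration of the aggregation machinery — not that any real
population follows a clean lognormal.

## Numerical and design choices

* **Units.** µg/L is the canonical concentration unit internally; mg/L
  appears only where derived PoD tables are formatted (the published
  convention).
* **Rounding.** Half-to-even (base `round()`), 2 decimals for mg/L values,
  integers for margins; never inside a computation.
* **Quantiles.** Linear interpolation (`type = 7`) throughout, checked
  against an independent sort-based oracle in the tests.
* **Degenerate inputs.** Empty dose lists predict 0; zero exposure, empty
  record sets, unknown population or category labels and non-positive
  parameters are rejected with explicit messages; a degenerate triangular
  spec collapses the Monte-Carlo to the point estimate.
* **Creatinine correction.** `ug/L = a + b × ug/g` with user-supplied
  coefficients only; the correlation used for the one published
  creatinine-adjusted dataset is not public, so the package refuses to
  invent it and warns when the identity default is used.
* **Problem sizes.** The statistical tests run at n = 10^5 for parameter
  recovery (tolerances 2% on the median, 5% on the P95/P50 ratio) and
  500 × 400 bootstrap replicates for coverage, which keeps the whole suite
  under half a minute while leaving Monte-Carlo error well inside the
  asserted bands.

## Limitations

Single-biomarker, single-pair scope (no cumulative multi-pesticide
assessment beyond the TCPy-sharing pair); no PBPK modelling or
benchmark-dose derivation; aggregated percentiles in, aggregated margins
out — no individual-level inference; and the colour scheme encodes one
specific uncertainty-factor reasoning, which is why every cutoff is
overridable in the YAML configuration.
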