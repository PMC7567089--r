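---
title: "Isotope-tracer flux analysis for sponge holobionts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope-tracer flux analysis for sponge holobionts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spongeflux)
library(dplyr)
```

## The scientific problem

Deep-sea sponge holobionts — the animal host plus its microbial symbiont
community — feed on both dissolved organic matter (DOM) and particulate
food such as bacterioplankton. Pulse-chase experiments with
^13^C/^15^N-enriched food sources quantify how much of each source a
sponge assimilates into biomass versus respires to dissolved inorganic
carbon (DIC), and compound-specific isotope analysis of phospholipid-derived
fatty acids (PLFAs) partitions the assimilated carbon between host cells
and bacterial symbionts, because some membrane fatty acids are diagnostic
of bacteria (iso/anteiso, mid-methyl branched and cyclopropyl acids) while
very-long-chain acids are diagnostic of the sponge host.

`spongeflux` implements the complete analysis chain for such experiments:
isotope bookkeeping, bulk flux accounting, PLFA quantification and
biomarker partitioning, permutational statistics, and a forward simulator
with known ground truth that lets every stage be validated without access
to raw field data.

## Isotope bookkeeping

All conversions run through three representations of the same measurement:
delta notation $\delta = (R_{sample}/R_{ref} - 1)\times 1000$ (per mil,
against VPDB for carbon, $R_{ref} = 0.01118$, and atmospheric N~2~ for
nitrogen, $R_{ref} = 0.00368$), the isotope ratio $R$, and the atom
fraction $F = R/(1+R)$. Tracer content is expressed as atom fraction
excess over the pre-feeding background, $E = F_{sample} - F_{background}$.

Two atom-fraction modes are provided. The default, `mode = "exact"`, uses
$F = R/(1+R)$. `mode = "approx"` uses the isotope ratio itself as the atom
fraction, $F \approx (\delta/1000 + 1) R_{ref}$ — a small-$R$
approximation that is widespread in spreadsheet-era workflows and differs
from the exact form by exactly the factor $(1 + R_{sample})$, about 1.1 %
for carbon at natural abundance. Because excess values propagate linearly
into every rate, a single `mode` switch flips the whole pipeline for
sensitivity analysis. Negative excess values (noisy near-background
samples) are preserved and flagged in QC output, never clamped.

## Bulk assimilation and respiration

Assimilation multiplies the tissue excess by the tissue element pool
(total organic C or N, µmol) and normalises by biomass (mmol of the same
element) and by the cumulative substrate-exposure time in days:

$$\text{rate} = \frac{E \cdot \text{pool}}{\text{biomass}/1000 \cdot
\text{duration}} \quad
[\mu\text{mol tracer } \text{mmol}^{-1}\, \text{d}^{-1}]$$

For whole-tissue measurements pool and biomass are the same quantity and
the rate reduces to $1000\,E/\text{duration}$; rates are therefore
expressed per tracer atom. No division by the food-source atom fraction is
applied by default (rates quantify tracer, not food, carbon).

Respiration is inferred from the rise of $F$ in the DIC pool of the
closed incubation chamber over each feeding pulse:
$(F_{t_{end}} - F_{t_0}) \cdot \text{DIC} \cdot V$ µmol tracer per pulse,
summed over pulses and normalised like assimilation. Duplicate water
samples are averaged; the $t_{end}$ DIC concentration is used for the
pool (a `"mean"` option averages both ends); sponge-free control chambers
can be subtracted (`control_correct = TRUE`, off by default since the
simulated controls carry no drift). Multi-pulse schedules (3 × 8 h or
2 × 24 h in the presets) accumulate tracer mass; the time denominator is
the cumulative exposure (1 or 2 days) because tissue is measured only once
at the end, so per-pulse tissue attribution is not attempted.

The assimilation-to-respiration efficiency is
$100 \cdot A/(A+R)$ per specimen, and species values are means of
individual efficiencies, not ratios of mean rates — with strongly varying
individuals the two differ substantially, and the per-individual mean is
the quantity the ecology cares about.

## PLFA quantification and biomarker partitioning

Concentrations come from chromatogram peak areas relative to the C19:0
internal standard,

$$C_{PLFA} = \frac{A_{PLFA}/A_{19:0}\cdot C_{19:0}}{g_s \cdot f}
\cdot \frac{n}{n+1},$$

with $g_s$ the extracted sample mass (mg), $f$ the DCM fraction recovered
and $n$ the carbon number; $n/(n+1)$ removes the methyl carbon added
during derivatization. The measured methyl-ester delta is corrected by the
corresponding mass balance
$\delta_{PLFA} = ((n+1)\delta_{FAME} - \delta_{methanol})/n$. (The two
published forms of this correction line are typographically garbled in
parts of the literature; the package implements the standard mass-balance
form, whose fixed point at $\delta_{FAME}=\delta_{methanol}$ and $1/n$
shrinkage are asserted in the tests.)

Fatty acids are parsed from CX:YωZ nomenclature with i-/ai-/Me-/Cy-
prefixes and classified table-first, rules-second: an explicit
classification table always wins; otherwise Cy/Me prefixes and short
iso/anteiso acids (chain ≤ 19) are bacteria-specific, chain ≥ 22
(demospongic and other very-long-chain acids, including branched ones
such as i-C25:1ω7 and the hexactinellid marker C30:3ω7) are
sponge-specific, and the rest are unspecific. The rule set reproduces
every assignment named in the source literature for these species; users
can override any of it with a two-column table.

Per-PLFA tracer incorporation compares the corrected delta with a
species- and fatty-acid-specific background pooled from unlabelled
specimens (concentration-weighted), falling back to a species-wide mean
and finally to a configurable natural-abundance default (−25 ‰) with a QC
warning. The excess times the whole-specimen PLFA carbon pool
(concentration × dry mass, µg C converted at 12.011 g mol^−1^), normalised
by biomass and duration, gives rates in the same units as the bulk
pipeline. Fatty acids labelled above a detection threshold (default
$E > 10^{-5}$ atom fraction excess — an operational choice, reported with
results) that are absent from the food-source profile are flagged as de
novo synthesised.

## Permutational statistics

Species and food-source comparisons use PERMANOVA on Euclidean distances
with type III (partial) sums of squares: the Gower-centred matrix
$G = -\tfrac12 C D^2 C$ is partitioned by hat-matrix traces,
$SS_{term} = \mathrm{tr}(H_{full}G) - \mathrm{tr}(H_{reduced}G)$, so each
term is tested conditional on all others; for a univariate response the
pseudo-F equals the classical ANOVA F to machine precision, and by the
Gower identity the raw-response and distance-matrix routes coincide
(both are implemented and cross-checked). Significance uses unrestricted
permutation of raw observations with the $(b+1)/(m+1)$ estimator; when
the number of distinct relabelings is below the requested permutations
(tiny designs) every distinct assignment is enumerated exactly and the
count is reported. "Unique permutations" counts distinct relabelings —
for a single factor the multinomial coefficient divided by the
permutations of equal-sized groups (two groups of 3 give
$\binom{6}{3}/2 = 10$). A parametric Monte Carlo p-value from the
$F(df_{term}, df_{res})$ (pairwise: $t(df_{res})$) reference distribution
is reported alongside as the standard asymptotic stand-in for tiny
designs; it approximates, rather than reproduces, the Monte Carlo draw of
the commercial PRIMER implementation. Pairwise statistics are
$t = \sqrt{F}$ of the two-level sub-design. Welch's t (Satterthwaite df)
wraps `stats::t.test()`.

A note on discreteness: with two groups of 3–4 individuals a permutation
test cannot produce p-values below 1/10–1/35, which is why the Monte
Carlo p-value is the operative quantity at these sample sizes, and why
the type-I calibration reported in the tests uses the three-group design
(3 × 4, empirical rejection within [0.03, 0.07] at α = 0.05 for both
p-value types).

## The forward simulator

`simulate_experiment()` generates the complete input bundle for any of six
presets (three species × two food sources) with the incubation designs,
doses (80 µmol C L^−1^ DOM; 12–16 µmol C L^−1^ bacterial carbon), label
atom fractions (0.99/0.80 for diatom DOM ^13^C/^15^N, 0.97/0.97 for
cyanobacterial DOM, 0.95 for bacteria) and group sizes of the emulated
study, plus sponge-free controls and unlabelled background individuals.

Per specimen the simulator draws a total processing rate $T$ (lognormal,
preset mean and CV) and an efficiency $e$ (logit-normal) linked by a
Gaussian copula, then sets $A = eT$, $R = (1-e)T$. The copula correlation
is calibrated by quadrature so that the mean respiration $E[T(1-e)]$ also
matches its preset value where the three species-level moments (total,
efficiency, respiration) are jointly attainable; where they are not —
small-n field means need not be mutually consistent, and for three of the
six conditions they are not — the preset honours total and efficiency and
lets respiration emerge. This reconciliation is the reason the simulator
parameterises $(T, e)$ rather than $(A, R)$ directly. Nitrogen
assimilation derives from a lognormal per-specimen assimilation C:N
(DOM, mean 1.2) or is drawn directly (bacteria, the per-species means);
between-individual variation is lognormal throughout, a modelling
convention in the absence of information about the true variance
structure.

Forward observables invert the analysis equations exactly: tissue deltas
from $E = A \cdot \text{duration}/1000$ over the species background
(−20 to −21 ‰ for ^13^C, +7 to +8 ‰ for ^15^N), per-pulse DIC deltas from
the respired tracer over a 2100 µmol L^−1^ DIC pool in a 2 L chamber, and
per-PLFA deltas from a preset allocation of the total PLFA incorporation
rate across source-derived and de-novo fatty acids. Species PLFA profiles
encode realistic compositions whose class totals are 62.7 / 16.4 %
(bacteria/sponge-specific, HMA demosponge), 8.6 / 68.7 % (encrusting LMA
demosponge) and 17.7 / 58.0 % (hexactinellid). Measurement noise is
Gaussian in delta space (SD 0.2 ‰ at background, plus 0.5 % of the
enrichment above background; 0.05 ‰ for DIC) with a 5 % CV on peak areas;
`sim_noise(0, 0)` switches everything off, and then the pipeline recovers
every truth to better than 10^−9^ relative — asserted in the tests.

Mass balance is enforced: a configuration whose mean tracer demand per
pulse exceeds the label fed is rejected with an error, and stochastic
per-specimen draws are rejection-sampled into the feasible region
(violation probability is below 1 % per draw, so the induced truncation
of the rate distributions is negligible). Biomass presets (dry weights
3 / 0.8 / 1.5 g; 25 / 25 / 10 % organic carbon; tissue C:N 5–6) were
chosen once as field-realistic values that keep enrichments well above
measurement noise and demands well inside the label budget.

What the simulator does *not* emulate: chamber hydrodynamics and oxygen
dynamics, isotope dilution and recycling of respired tracer, DI^15^N
release, cell shedding, chromatographic co-elution, and drift in the
IRMS. Passing recovery tests therefore demonstrates that the estimators
invert the stated forward model without bias at realistic noise — not
that field data are free of these additional processes.

## Numerical choices and degenerate inputs

* Roots and quadrature in the preset calibration use 48–60-node
  Gauss–Hermite rules and `uniroot` at 10^−10^–10^−12^ tolerance.
* A response with zero total variance gives pseudo-F = 0 and p = 1 rather
  than 0/0; terms aliased in non-crossed designs are reported as NA with
  a warning; ties in enumerated permutation statistics count as ≥ the
  observed value (with a small relative tolerance).
* Efficiency with zero assimilation and respiration, and C:N with a zero
  nitrogen rate, return NA markers with QC warnings.
* All-zero PLFA peak areas yield NA percentages with a warning; the
  C19:0 internal-standard peak is excluded from profiles and recorded in
  an `"excluded"` attribute, as is every specimen dropped from the bulk
  pipeline — input rows always equal analysed rows plus excluded rows
  with reasons (asserted by the pipeline and its tests).

## Problem sizes

The validation suite and the acceptance script use 200 replicate
simulated experiments at the study group sizes (n = 3–4 per species and
source, ~19 specimens per replicate including backgrounds), 200 × n = 11
profile-only simulations for the composition summary, 300–1000 simulated
null datasets for the statistical calibration, and 99–499 permutations
inside the replicated tests (9999 remains the analysis default). These
sizes put Monte Carlo error comfortably inside the stated tolerances
(e.g. SE of the recovered mean total rate ≈ 3.5 % of truth at 200 × 3
specimens).

## Known limitations

* The Monte Carlo p-value is a parametric approximation; for the tiny
  designs it serves, permutation p-values are necessarily coarse.
* Type III partitioning with `contr.sum` matches the usual PERMANOVA+
  convention for crossed designs but, as always with partial SS, depends
  on the coding for severely unbalanced designs.
* Backgrounds pooled from 2–3 unlabelled individuals carry sampling error
  that propagates into per-PLFA excess; the simulator reproduces this,
  the tests quantify it only in aggregate.
* The de novo flag is membership-based (canonical name in/not in the
  source profile); isomers that differ only in unstated double-bond
  position are treated as distinct compounds.
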