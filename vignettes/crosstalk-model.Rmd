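---
title: "Modelling DSB formation from BER/MMR crosstalk on alkylated plasmids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling DSB formation from BER/MMR crosstalk on alkylated plasmids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alkrepair)
```

## The model

`alkrepair` models a circular duplex plasmid of `L` base pairs, i.e. `2L`
strand-nucleotides, dosed with a methylating agent. Three ingredients:

1. **Lesion placement.** Each strand-nucleotide independently carries an
   adduct with probability `d / (f7mG + f3mA)`, where `d` is the *N-alkyl*
   density per strand-nucleotide (the quantity the alkaline-cleavage assay
   measures) and the class fractions come from the agent's spectrum. This
   is a Bernoulli/Poisson field: no clustering, no sequence-context bias
   beyond base identity in the optional sequence-aware mode. Dose in mM
   maps linearly to density; the default calibration anchors 1 mM to one
   N-alkyl adduct per 500 strand-nucleotides.

2. **Snapshot repair.** Rather than simulating excision/resynthesis
   kinetics in time, one observation is sampled per molecule in which each
   potential event is "open" with a stated probability. The experimental
   read-outs this mirrors are end-point gels: what matters for a DSB is the
   *joint* openness of two lesion-processing events, and that concurrency
   is compressed into the product of openness probabilities. Every N-alkyl
   adduct carries an open BER nick with probability `p_nick_open` and
   contributes completed-BER patch synthesis regardless; every O⁶mG:C
   engages MMR with probability `p_engage_base`, excising a `track_length`
   track on a uniformly chosen strand that is an open gap with probability
   `p_mmr_gap_open` and contributes its length in synthesis.

3. **DSB call and topology.** One DSB per open MMR gap whose circular
   interval contains an open BER nick on the opposite strand (a single
   gap–nick encounter severs the molecule once, so nick multiplicity does
   not add breaks). Topology is `linear` with ≥1 DSB, `oc` with any open
   nick or gap, else `ccc`.

The analytic twin (`analytic_dsb_fraction()`) gives the expected DSB count
per molecule in closed form; the Monte Carlo and the closed form are held
to agree within Monte Carlo error across random parameter sets in the test
suite.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `density_per_mM` | 1/500 | per strand-nt per mM | single-strength reaction yields one N-alkyl per 500 nt; double-strength, one per 250 nt |
| spectrum (MNU) | 0.725 / 0.10 / 0.085 / 0.09 | fractions | midpoints of the reported 7mG 70–75%, 3mA 8–12%, O⁶mG 8–9% ranges; N:O ≈ 9.7 |
| spectrum (MMS) | 0.82 / 0.105 / 0.003 / 0.072 | fractions | same N-alkyl proportions, O⁶mG at its <0.3% upper bound |
| `p_engage_base` | 0.30 | probability | fraction of O⁶mG:C sites processed by MMR, inferred from the mGC/mGT UDS comparison |
| `stimulation_factor` | 2.9 | fold | UDS increment ratio with/without N-alkyl co-damage |
| `track_length` | 500 | nt | per-engaged-site MMR patch from the UDS arithmetic (270 nt / 1.7 sites / 0.30) |
| `p_mmr_gap_open` | 0.75 | probability | fraction of molecules with ≥1 nick/gap at the 1 h end point |
| `p_nick_open` | calibrated ≈ 0.0145 | probability | inverted from the 6% linear fraction anchor (11.3 kb plasmid, 1/250 density); BER nicks are transient, so this is small |
| `ber_long_patch_fraction`, `ber_long_patch_mean` | 0.4, 5 | –, nt | mixture of 1 nt short patches and 2–8 nt long patches giving ≈2.6 nt per adduct |

ENU is run with the MNU spectrum (the two behave alike in repair-synthesis
assays); this is overridable. Long patches are drawn as
`2 + Binomial(6, (mean − 2)/6)`, which has support 2–8 nt and exactly the
configured mean.

### Stimulation: engagement, and what triggers it

The 2.9-fold stimulation could act on engagement probability or on the
number of excision tracks per site; the data cannot distinguish these, and
engagement probability was chosen. Two further choices:

* The default `p_engage_base = 0.30` was measured on constructs that
  *already carried* N-alkyl co-damage, so by default no stimulation
  multiplier is applied (`apply_stimulation = FALSE`) — applying it would
  double-count. The multiplier pathway exists for the reconstitution
  scenario (single O⁶mG ± MMS), where the unstimulated base (≈ 0.30/2.9)
  is boosted 2.9-fold in the presence of co-damage.
* The trigger is the presence of an N-alkyl *adduct* (a site that BER
  processes at some point during the incubation) within the ±500 nt
  window, not an *open* nick at the snapshot. With the calibrated,
  deliberately small `p_nick_open` an open nick is almost never inside the
  window, and a snapshot-open trigger could never produce the observed
  ~3-fold effect; nicks are transient, but over the incubation every
  N-alkyl site is visited.

## What the generator emulates, and what it does not

The synthetic-data module reproduces: Poisson lesion statistics at
dose-proportional density on both strands; agent class fractions; base
compatibility (7mG/O⁶mG at G, 3mA at A) when a sequence is supplied; the
saturating alkaline-cleavage read-out; and the snapshot repair state.

It does **not** emulate: alkylation chemistry (SN1/SN2 kinetics,
depurination), minor adducts and their direct-reversal repair, MGMT
demethylation, time-resolved Exo1 processivity, re-ligation/end-joining of
broken molecules (DSB calls are steady-state), or replication-dependent
futile MMR cycling at O⁶mG:T. Consequently a green test establishes the
internal consistency of the two-hit model and its calculators — not that
extract biochemistry contains no additional pathways.

A known tension is inherited from the data rather than resolved: the ~75%
open-circular fraction (4.3 kb plasmid, 1 h) and the ~6% linear fraction
(11.3 kb, double dose) imply different nick-openness scales. The package
keeps `p_nick_open` (calibrated small, drives DSBs) and `p_mmr_gap_open`
(0.75, drives the oc signal) as independent knobs and claims no single
consistent set.

### Which "linear fraction" obeys the quadratic law

The gel read-out is `linear/(linear + oc)`, and `sweep_doses()` reports it
as `linear_fraction`. In the experiments ccc is negligible at the doses
plotted, so this equals the fraction of molecules broken. In the
*calibrated model world*, however, ~18% of molecules are still ccc at
1 mM, which deflates the gel-convention ratio at low dose and would drive
its log–log slope toward 1 as dose → 0 (the denominator itself becomes
linear in dose). The quadratic two-hit statement is about `P(linear)`, so
the acceptance measurements (fold change and log–log slope) use the
fraction of molecules linear (`linear_of_total_pct`); both columns are
reported, and the choice was made on this analysis, before measurement.

## Numerical choices

* Coordinates 0-based; intervals half-open `[start, start + len)`; all
  circular arithmetic modulo `L`.
* `calibrate_nick_availability()` inverts the monotone closed form by
  bisection to 1e-6 relative tolerance and refuses unreachable targets,
  reporting the attainable maximum.
* Median→density inversion defaults to the conventional `1/median`
  identification so calibrations match the published numbers; the exact
  geometric relation `ln 2 / median` is provided (`mode = "geometric"`)
  because random cleavage gives geometric fragment lengths whose median is
  `ln 2` times the mean spacing. Whether the published "median" was an
  intensity-weighted centroid (which tracks the mean) is not stated; both
  conventions are exposed and no intent is guessed.
* The genome calculators keep the source's mixed genome sizes — 6×10⁹ nt
  for lesion density, 3×10⁹ bp for DSB scaling — because harmonising them
  silently would change headline numbers; pass equal values for a
  consistent mode. Exact values are returned; `paper_round()` applies the
  2-significant-figure print convention.
* The stock pBR322 entry uses the catalogue length 4.3 kb (4300 bp), which
  is what the expected-count arithmetic (~17 N-alkyl, ~1.7 O⁶mG) is based
  on; analyses tied to the exact 4363 bp sequence pass that length
  explicitly.
* `batch_simulate()`'s default vectorized path draws per-molecule event
  counts and positions only for geometric events; it is distributionally
  identical to composing `place_lesions()` + `simulate_repair()` (the
  `"molecule"` method), up to neglecting position collisions among a
  molecule's handful of open events, and the two paths are compared
  statistically in the tests. The single dose the exact MNU+ reaction
  corresponds to is not published; 1 mM is inferred from the 2 mM
  double-strength statement and kept configurable.
* All randomness flows through R's global RNG from a single seed per call;
  seeded runs are byte-reproducible.

## Limitations

The model is a deliberately minimal two-hit geometry. Its DSB yield at the
anchor is calibrated, not predicted; what the package tests is the
*scaling* (quadratic dose law, fold change, closed-form/simulator
agreement) and the deterministic arithmetic built on printed inputs.
Extrapolations to genomes assume plasmid-like chromatin-free repair and
equal reactivity of MNU and temozolomide, and report steady-state break
counts that ignore re-ligation.
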