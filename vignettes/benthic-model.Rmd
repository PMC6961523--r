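---
title: "A layered benthic biogeochemistry model for muddy and sandy shelf sediments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A layered benthic biogeochemistry model for muddy and sandy shelf sediments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(shelfbenthos)
```

## The scientific problem

Shelf-sea sediments receive a pulse of phytodetritus after the spring
bloom, process it through a benthic food web, and return nutrients to the
water column. Two sediment types bracket the transport regimes: muddy beds,
where solute exchange is molecular diffusion enhanced by bio-irrigation,
and permeable sands, where bottom currents interacting with seabed ripples
pump pore water through the upper bed. `shelfbenthos` is a desk-scale,
fully mass-ledgered implementation of a layered benthic model spanning both
regimes, with four ready-made scenario configurations: a muddy site with a
standard (`A`) and a re-parameterised (`A1`) constant set, and a sandy site
with the ripple-pumping modification switched on (`G`) and off (`G0`).

## Bed structure and oxygen

The bed (default 0.25 m deep, depth positive downward) carries three
dynamically bounded layers: oxic down to the oxygen penetration depth
`D1`, a transition layer with nitrate but no free oxygen down to `D2`, and
an anoxic layer below. `D1` uses a quasi-steady balance between downward
diffusion and a zero-order volumetric consumption `R`:
`D1 = sqrt(2 K C_w / R)`, with `C_w` the bottom-water oxygen
concentration. The volumetric demand is taken as `TOU/D1` and closed with
one fixed-point update per daily step, under-relaxed by 0.5 to avoid
oscillation; `D1` is floored at 1 mm and capped at the bed depth (the cap
is itself informative: the standard muddy configuration caps `D2` at the
full 25 cm in winter, the re-parameterised one does not). `D2` repeats the
construction below `D1` with the transition-layer nitrate concentration
and the denitrification demand.

In permeable sands the advective enhancement is confined to a flushed
surface stratum: ripple-driven pore-water flow penetrates to a depth
comparable to the ripple height `h`, so when `D1 > h` oxygen crosses the
top stratum with the enhanced diffusivity and the remainder with the
background value. Solving the same zero-order balance across the two
strata gives a quadratic for `D1`
(`oxygen_penetration_layered()`) that reduces *exactly* to the single-layer
form when the enhancement is zero — so switching the modification off is
bit-identical to setting permeability to zero, which the test suite
asserts. Without this confinement a molecular background
(`K0 = 1e-9 m^2 s^-1`) plus a typical advective term (`~2.7e-8 m^2 s^-1`
at 0.1 Pa bed stress) would oxygenate the entire modelled bed, which is
neither observed nor intended: the enhancement is meant to deepen the oxic
layer of sands by a few centimetres, not erase the anoxic zone.

## The pore-water exchange chain

Bed stress from M2+S2 tidal currents is converted to an advective
diffusivity by the chain

* `U = (u*/kappa) ln(z_r/z0)` with `u* = sqrt(tau_b/rho)`, `z0 = h/7`,
  `z_r = 0.1 m` (the standard logarithmic profile; a printed variant that
  multiplies by `kappa` is kept behind `log_law_form = "literal"` for
  sensitivity work only),
* `dP = a1 rho U^2 (h/L)` — the pressure difference across a ripple,
* `w0 = k dP / (rho nu L)` — the Darcy velocity through the bed,
* `K_adv = a2 w0 min(h, D1)` — velocity scale times length scale,
* `K = (K0 + K_adv) I_bio` — bio-irrigation multiplies both terms.

`a2 = 4` is treated as a given calibration constant. Every link has a
hand-computed oracle in the tests (e.g. `tau_b = 0.101 Pa` gives
`U = 0.0768 m s^-1`, `dP = 0.894 Pa`, `w0 = 2.21e-7 m s^-1`,
`K_adv = 2.66e-8 m^2 s^-1`), and a composition property (`K_adv`
proportional to `tau_b` at fixed length scale) is verified over a stress
grid. The kinematic viscosity default is `1e-6 m^2 s^-1`.

## Organic matter

Incoming detritus is split by fixed ratios into labile dissolved organic
matter (10% by default), semi-labile and refractory particulate pools; the
standard particulate split is 9:1 semi-labile:refractory, the
re-parameterised run uses 1:1 together with a fivefold faster bacterial
conversion of refractory to semi-labile material
(2e-6 to 1e-5 m^2 (g C)^-1 day^-1). Pools are depth-integrated stocks per
element (C, N, P, Si) with diagnostic exponential profiles
`c(z) = (S/zp) exp(-z/zp)`; the penetration depths respond to a
bioturbation index through a saturating map, keeping semi-labile material
in roughly the top 3–4 cm. Refractory POM also leaks into an inert buried
pool at `5e-5 day^-1`, chosen so a 21-year run accumulates a few
g C m^-2 (the buried pool only ever grows). Direct microbial grazing on
refractory POM is throttled by an accessibility fraction (1.5% of the
stock is treated as edible as-is) — without it the "refractory" pool is
consumed like fresh detritus and ceases to be refractory in any meaningful
sense.

## Food web

Five functional groups — aerobic and anaerobic bacteria, meiofauna,
deposit feeders, suspension feeders — feed along preference-weighted
Holling type-II responses with Q10 temperature scaling, stepped daily by
forward Euler with per-flux limiting (no resource loses more than 80% of
its stock per step; suspension feeders can intercept at most 40% of the
settling flux, since they only filter the water that passes them).
Structural choices worth knowing:

* **Bacteria respire their unassimilated uptake** (growth efficiency 30%)
  rather than egesting it. This is what ties total oxygen uptake to POM
  availability — the mechanism by which the re-parameterised muddy run
  sustains late-winter oxygen demand.
* **Background mortality is linear and temperature-independent** (the
  0.001/0.004 and 0.001/0.002 day^-1 values are the documented scenario
  constants); fauna additionally carry a weak quadratic closure mortality
  standing in for predation by unresolved higher trophic levels. Without a
  closure the web is structurally fragile: whichever macrofaunal group
  gets ahead monopolises the semi-labile pool and starves the rest.
* **Deposit feeders' preference for meiofauna is 0.2** of their preference
  for POM, not the 0.5 used for the other less-preferred diet links; at
  0.5 meiofauna are grazed to extinction under the standard constants.
* **A trace bacterial inoculum** (0.01 g C m^-2, funded from semi-labile
  POM so mass is conserved) keeps bacterial collapse from being absorbing.
  The muddy standard run relies on this: anaerobic bacteria genuinely
  collapse each winter when the bed runs out of degradable POM, and
  regrow from the inoculum after the bloom.

Rate constants are calibration values, set so that the spun-up standard
muddy run lands in observed orders of magnitude (aerobic bacteria
~0.1 g C m^-2, meiofauna ~0.2, deposit feeders ~1.3, suspension feeders
~0.4) and reproduces the qualitative seasonal patterns: aerobic bacteria
peak within two weeks of the detritus pulse, anaerobic bacteria peak in
autumn, deposit feeders peak in winter. Only the four documented scenario
constants are treated as fixed; `scenario_provenance()` tags which
parameters are documented constants and which are calibration.

## Nutrients

Bed nutrients are total (dissolved plus adsorbed) contents per layer, with
instantaneous dissolved/adsorbed equilibrium by fixed partition
coefficients (ammonium 0.7–0.8 dissolved; phosphate 0.2 oxic / 0.6 anoxic
— stronger adsorption when oxygenated; nitrate and silicate fully
dissolved). Nitrification is first order in dissolved oxic ammonium
(0.5 day^-1); denitrification is bimolecular in anaerobic bacterial
biomass and deep nitrate (0.02 m^2 (g C)^-1 day^-1), with the removed
nitrogen routed to a surface-return accumulator so the whole-system
nitrogen ledger closes. Silicate dissolves from particulate Si at
0.005 day^-1, distributed over layers by the POM profile. The top layer
relaxes toward equilibrium with the overlying water on a 1-day timescale;
adjacent layers equilibrate their dissolved concentrations diffusively on
a `L^2/2K` timescale. When the layer boundaries move, contents are
re-apportioned carrying the donor layer's mean concentration.

The interplay of these pieces produces the model's signature winter
behaviour: when the standard muddy run exhausts degradable POM in late
winter, anaerobic bacteria collapse, denitrification stops, and nitrate
produced by ongoing nitrification accumulates in the bed — the winter
bed-nitrate maximum. The re-parameterised run keeps anaerobic bacteria
(and denitrification) alive through winter on the larger refractory pool
and roughly halves that maximum.

## Synthetic forcing: what it emulates and what it does not

`generate_forcing()` produces a deterministic, annually periodic daily
series: a Gaussian spring detritus pulse (peak day 120 plus a 7-day
settling lag, s.d. 10 days, truncated at ±4 s.d.), a smaller autumn pulse
(20%), and a small year-round settling floor (2% weight). The floor is
deliberately near zero: the standard muddy configuration is *defined* by
its bed running out of degradable material in late winter, and a generous
winter drizzle of fresh detritus would abolish the regime the scenario
comparisons probe. The annual integral is normalised to the configured
input (20 g C m^-2 yr^-1 by default) exactly; N, P and Si follow Redfield
(C:N:P = 106:16:1) with a diatom-like Si:C of 15:106. Bottom temperature
is a sinusoid peaking near the end of stratification (day 300, mean 11°C,
amplitude 2.5°C); bottom-water oxygen draws down 10% over the stratified
season; winter nutrient concentrations (8 mmol m^-3 nitrate, etc.) are
plausible temperate-shelf values, not site measurements. Tidal bed stress
uses M2 = 0.10 and S2 = 0.035 m s^-1 current amplitudes, giving a mean
stress near 0.1 Pa and a spring–neap beat of 14.77 days; the daily value
is the mean over 48 sub-samples, and one year of stress is tiled so the
forcing is exactly annually periodic (the raw beat is not commensurate
with the year).

A green scenario test therefore establishes that the *model* reproduces
the documented qualitative patterns under a clean, repeating climatology —
not that it matches any particular year of observations. Real forcing has
meteorological noise, interannual bloom-timing shifts and storm-driven
stress events, none of which are emulated; observation fixtures for the
comparison harness instead add bias-corrected lognormal replicate scatter
(matching the orders-of-magnitude spread of real replicate grab samples)
around model output, and are labelled synthetic.

## Numerical choices

Daily forward-Euler stepping with per-flux limiting everywhere; a
step-size error is raised if limiting cannot keep biomass non-negative.
Elemental ledgers (C, N, P, Si — bed pools + biota + accumulated
respiration, exchange and denitrification returns minus cumulative input)
are checked every step against 1e-8 relative and abort the run on breach;
in practice they close to ~1e-13 over 21 years. The box model uses an
exponential integrator (exact per step for `l = lambda*Q`), so its
acceptance oracle is the analytic solution at 1e-10. Diffusivities are
m^2 s^-1 internally and converted once (86400 s/day) at the stepping
boundary. Carbon is g C; nutrients mmol; 12.011 g C mol^-1.

## Design choices on genuinely open points

* The equilibrium content for benthic–pelagic exchange is the content at
  which the top layer's dissolved concentration equals the bottom-water
  concentration (`C_eq = c_bw * porosity * D1 / partition`); sources and
  sinks act separately in the same step rather than being folded into the
  equilibrium.
* The re-parameterised split change applies to the particulate fractions
  only; the dissolved fraction is held at 10%.
* Suspension feeders' egestion goes to the semi-labile pool (their
  "sub-surface excretion" is not spatially resolved; penetration depths
  carry the vertical information here).
* Bio-irrigation multiplies both the background and the advective term, as
  the effective-diffusivity formula states literally.
* Configuration files are JSON — one structured-text dialect, parsed with
  `jsonlite`, with unknown keys rejected by name.

## Known limitations

* Anammox is absent (as in ERSEM-family benthic models), so at sites where anammox
  dominates fixed-nitrogen removal the nitrate/ammonium comparisons are
  structurally biased.
* The sandy-site oxygen penetration depth is somewhat too deep (~7–9 cm
  late-winter against ~5 cm typical observations) and the deep oxic layer
  pushes anaerobic processes to the inoculum floor at that site; observed
  denitrification at sandy sites is indeed very low, but the model gets
  there more abruptly than nature does.
* The nitrate penetration depth contrast between the standard and
  re-parameterised muddy runs is directionally right (bed-deep vs
  shallower) but the re-parameterised value remains deeper than the few
  centimetres the full model reaches.
* Biomass magnitudes are calibrated, not emergent: treat absolute levels
  as order-of-magnitude.
* No advective entrainment of particulate matter into permeable beds, no
  wave- or density-driven pore-water exchange, no multi-G diagenesis, no
  iron/manganese/sulfur cascade.
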