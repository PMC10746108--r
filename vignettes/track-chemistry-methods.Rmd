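---
title: "Monte Carlo track chemistry of the Fricke dosimeter under carbon ions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo track chemistry of the Fricke dosimeter under carbon ions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`frickeirt` simulates the radiolysis of the air-saturated ferrous sulfate
(Fricke) dosimeter — 1 mM FeSO₄ in 0.4 M H₂SO₄, ~2.5 × 10⁻⁴ M O₂ — and of
Fricke solutions containing the aminothiol radioprotector cystamine (RSSR,
10⁻⁶–1 M), irradiated by carbon ions of 6–500 MeV per nucleon
(LET ≈ 248–9.3 keV/µm). The observable is the ferric-ion yield G(Fe³⁺) in
molecules per 100 eV, resolved in time from 1 ps to 200 s and decomposed by
producing reaction. This vignette is the package's own account of the
models, their assumptions, the parameters that matter, and what the tests
do and do not establish.

## The three-stage pipeline

1. **Track generation** (`generate_track()`): a parametric model of the
   1-ps nonhomogeneous species distribution along a short ion-track
   segment. This stage *replaces* an event-by-event physical transport
   code; it is the central approximation of the package.
2. **Intratrack chemistry** (`run_track_stage()`): the independent reaction
   times (IRT) method. Each reactive pair draws a first-passage time to
   contact from the free Brownian-pair law
   W(t) = (R/r₀)·erfc((r₀ − R)/(2√(D t))), never reacting with probability
   1 − R/r₀; each trace particle additionally draws exponential
   pseudo-first-order scavenging times against the bulk solutes (H⁺, O₂,
   Fe²⁺, RSSR). The globally earliest valid event executes; products enter
   the competition where they are born. The stage ends at the handoff time
   (default 1 µs: track expansion is essentially complete by ~0.2 µs at low
   LET; the extra margin covers dense high-LET columns).
3. **Homogeneous continuation** (`propagate_bulk_stage()`): after the track
   has dissipated, every surviving trace species sits in a large excess of
   bulk solutes, so its fate is a linear pseudo-first-order cascade solved
   analytically with a matrix exponential (a stiff ODE integration
   cross-checks it in the test suite). The readout G(Fe³⁺)(200 s) and the
   per-reaction extents ΔG come from this stage plus the intratrack event
   log; the extents sum to the total exactly, by construction.

## The reaction scheme

The default network (36 + 2 reactions among 26 species) has three parts:

* the ferrous oxidation set — •OH, HO₂•, H₂O₂ and (marginally) H• against
  Fe²⁺, reactions 6–9 with their established 25 °C rate constants
  (k₆ = 3.4 × 10⁸, k₇ = 7.9 × 10⁵, k₈ = 52, k₉ = 1.3 × 10⁷ M⁻¹ s⁻¹);
* the cystamine set, reactions 10–21 (e⁻_aq, H• and •OH capture by RSSR and
  the downstream RS•/RSOO•/R•/ROO•/RSSR•⁺ chemistry), plus thiyl
  dimerization RS• + RS• → RSSR (reaction 22, k = 1.5 × 10⁹ M⁻¹ s⁻¹, a
  literature value). The dimerization channel is the one member of the full
  cystamine scheme beyond the core set that the model cannot do without:
  with every captured radical chain ending in exactly one Fe³⁺, G(Fe³⁺) at
  1 M cystamine would be bounded near 5.5 regardless of track structure,
  whereas the disulfide radical-radical chemistry caps the high-
  concentration plateau near the observed 4.4 (9.3 keV/µm);
* a compiled Elliot/Buxton-style pure-water intratrack set (W1–W17) and the
  triplet-oxygen channels used by the double-ionization model (W18–W22).

Acid–base handling at pH 0.46 is pre-resolved: superoxide appears only as
HO₂• (pKa 4.8, protonation treated as instantaneous), the peroxide anion
only as H₂O₂, and OH⁻ is an inert sink. The hydrated electron's conversion
to H• by the 0.4 M proton background is an explicit pseudo-first-order
channel (not an instantaneous conversion), so that capture by concentrated
cystamine can compete for e⁻_aq — the mechanism behind the electron-channel
protection at high RSSR.

Every reaction must balance elements and charge, allowing implicit H₂O and
H⁺ exactly where the chemistry writes them; the validator solves for the
implicit counts and rejects anything else. Cystamine-family species carry
the two protonated amino groups (RSSR is +2 below pH 8), which matters only
through the ionic-strength corrections.

### Ionic strength

Rate constants between ions are corrected by the 25 °C
Brønsted–Bjerrum/Davies form 10^(1.02·zA·zB·√I/(1+√I)), the hydrated
electron self-recombination excepted. The effective ionic strength uses a
fixed speciation: first H₂SO₄ dissociation complete (H⁺ 0.4 M, HSO₄⁻
0.4 M), FeSO₄ dissociated, cystamine as its dihydrochloride
(RSSR²⁺ + 2 Cl⁻), giving I = 0.404 + 3·[RSSR] mol/L. Two caveats are
deliberate: the Davies form is extrapolated far beyond its validity at
I ≈ 3.4 (1 M cystamine), and for multiply charged pairs it can push an
effective encounter radius to unphysical sizes — encounter radii are
therefore capped at 1 nm, the physical contact scale. Sulfate
radical chemistry is omitted: the acid is a proton/ionic-strength
background, consistent with radiolytic products being trace relative to
0.4 M.

### Two stages, one scheme

Reactions carry a `bulk_stage` flag. Trace–trace channels (all radical–
radical reactions, including RSSR•⁺ disproportionation and thiyl
dimerization) act only inside the track, where local concentrations are
high; in the homogeneous stage the single-track, low-dose-rate limit makes
them negligible. H• + Fe²⁺ (reaction 9) is also confined to the track
stage: its influence is minimal at 1 mM Fe²⁺, and excluding it from the
continuation preserves the exact Fricke stoichiometric identity
G(Fe³⁺) = 3[g(H•) + g(HO₂•)] + g(•OH) + 2 g(H₂O₂), which the test suite
verifies to 10⁻⁹ relative error.

## The track model and its calibration

Energy deposition events form a Poisson process along the segment axis with
mean energy 90 eV per event; each event spawns Poisson numbers of
charge-balanced dissociation patterns — ionization {e⁻_aq, •OH, H₃O⁺},
radical excitation {H•, •OH}, molecular channel {H₂, H₂O₂} — with 1-ps
pattern yields 4.9, 0.62 and 0.12 per 100 eV. Heavy species are displaced
from the event centre by an isotropic Gaussian of σ = 0.9 nm; electrons by
2.7σ ≈ 2.4 nm (thermalization). A fraction 0.65 of events is carried
off-axis by its δ ray into a penumbra of Gaussian radius 70 nm at
34.5 keV/µm, scaling as (34.5/LET)^0.1. The segment is axially periodic
(minimum-image distances), so per-100-eV yields carry no end artifacts —
this replaces explicit guard regions. Double ionization, when enabled,
converts a pair of single-ionization slots into {2 e⁻_aq, 2 H₃O⁺, O(³P)}
(the slot pair's energy pays for the double event). The O(³P) fragment is
displaced from the event core at twice the spur scale — the Coulomb
explosion of the doubly charged water ejects its fragments — rather than
inheriting the parent position. The conversion is the last random draw of
generation, so MI-on/off runs with the same seed share every other
particle — exact common-random-number pairing.

The geometry (event energy, the two Gaussian scales, the penumbra fraction,
radius and exponent) was calibrated **once** against (i) the accepted
⁶⁰Co-equivalent escape yields in 0.4 M acid — g(H•) = 3.70, g(•OH) = 2.90,
g(H₂O₂) = 0.80, stoichiometric G = 15.5 — evaluated at 0.3 keV/µm where
spurs are isolated, and (ii) the cystamine-free 200-s yields over the
carbon-ion LET series (13.3 / 11.2 / 7.2 at 9.3 / 34.5 / 248 keV/µm). The
frozen defaults reproduce the anchor within ~3 % per g-value and the series
within ~8 %. All cystamine-containing and double-ionization predictions are
out of sample: no parameter was adjusted against them.
`calibrate_track_model()` exposes the same objective for re-calibration
under a modified scheme.

Why a penumbra at all? A single radial scale cannot reconcile three facts:
isolated spurs must recombine ~30 % of their radicals (the ⁶⁰Co anchor),
the dense 248 keV/µm column must still let ~45 % of the oxidizing
equivalents escape, and at 1 M cystamine the ~25–60 ps capture times must
intercept most of the *remaining* radicals before they recombine. A
core/penumbra split decouples these: intra-event geminate recombination is
penumbra-independent (it sets the anchor and the fast phase that the 1 M
competition probes), while the off-axis fraction controls how much of a
high-LET column's energy escapes the collective recombination.

## Tunable parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `mean_energy_per_event` | 90 | eV | spur size / spacing at fixed LET |
| `spur_radius_sigma` | 0.9 | nm | heavy-species cluster scale |
| `electron_sigma_factor` | 2.7 | — | e⁻_aq thermalization scale (×σ) |
| `penumbra_fraction` | 0.65 | — | δ-ray (off-axis) energy share |
| `penumbra_radius` | 70 | nm | penumbra width at 34.5 keV/µm |
| `penumbra_let_exp` | 0.1 | — | penumbra-width vs LET exponent |
| `mi_probability` | 0 (0.25 when enabled) | — | per-slot double-ionization conversion |
| `t_handoff` | 10⁻⁶ | s | IRT → homogeneous transition |
| `cutoff_nm` | 120 | nm | pair-sampling neighbour cutoff |

The handoff and cutoff are numerical, not physical, knobs: pairs beyond the
cutoff have ultimate reaction probabilities R/r₀ ≲ 0.5 %, and with most
radical lifetimes far below 1 µs the truncation error is negligible (the
cutoff actually used is recorded in each event log's metadata). The
double-ionization share is a *configured* parameter. `mi_probability` is a
per-ionization-slot conversion probability and each double ionization
consumes two slots, so the default 0.25 corresponds to a double share of
p/(2-p) = 14 % of ionization events — the scale inferred from heavy-ion
double-ionization cross sections near the Bragg peak, and the value at
which the paired comparison reproduces the documented few-percent yield
reduction at millimolar cystamine. The comparison is meaningful for any
small value.

## Numerical choices

* Inverse-transform sampling of W(t) via erfc⁻¹ (from the normal quantile);
  contact at birth (r₀ ≤ R) reacts at the birth time.
* Partially diffusion-controlled channels use the Collins–Kimball
  effective-radius mapping R = k/(4πD_mut) in per-molecule units; a purely
  activation-limited treatment is not separated out.
* No Coulomb (Onsager) correction to first-passage times: at I ≳ 0.4 M the
  screening length (~0.3 nm) is below the encounter radii; the net ionic
  effect is carried by the rate-constant correction.
* Pair separations are taken at birth positions without refreshing the
  partner's diffused position on re-sampling — the standard IRT
  simplification; its bias is absorbed by the one-time geometry
  calibration.
* Equal sampled times execute in queue order (deterministic); simultaneous
  independent events commute, and conflicting ones are resolved by the
  aliveness check.
* Product placement: single product at the pair midpoint, two products at
  the consumed reactants' positions, extras at the midpoint; scavenging
  products at the particle's position.
* The homogeneous generator is checked for trapped recurrent classes
  (a cycle whose members decay only into the cycle raises an error), and
  the 200-s readout is the exact final grid point.
* Replicate seeds derive linearly from the base seed; identical
  configuration and seed give bit-identical results (tested), satisfying
  the replay contract without a counter-based RNG.

## Study sizes

Default runs use segments sized to ~6000 reactive species (the 1.5–30 µm
protocol window); reported experiments use 4000-particle segments with 10
replicates at 9.3 and 34.5 keV/µm and 5 shorter (0.3 µm) segments at
248 keV/µm, matching the reduced-statistics protocol for the densest
tracks. Monte Carlo standard errors at these sizes are ~0.1–0.3 G-units.

## What the synthetic tracks do and do not emulate

The generator reproduces the gross architecture that drives the LET
dependence — Magee-type spur strings at low LET collapsing into a dense
column with a δ-ray penumbra at high LET, with charge-balanced 1-ps
inventories. It does not transport secondary electrons explicitly, has no
cross-section-level energy-loss spectrum (a single mean event energy), no
Bragg-peak depth evolution, and no nuclear fragmentation. Passing tests
therefore establish that the *chemistry engine* converts a calibrated 1-ps
geometry into correct yields, not that the geometry itself is predictive
outside the calibrated 0.3–248 keV/µm carbon-ion window.

## Known limitations

* G(Fe³⁺) at 1 M cystamine and 248 keV/µm runs ~20 % above the reference
  value (3.8 vs 3.1): with only the core cystamine set plus thiyl
  dimerization, the dense-core annihilation of captured-radical chains is
  incomplete. The missing ingredients are the remaining disulfide
  radical–radical channels (e.g. RSOO•/ROO• cross-terminations), which are
  deliberately not defaulted; they can be supplied through `load_scheme()`.
* At 1 M the MI-on arm sits ~0.1 G-units *above* the MI-off arm rather
  than converging exactly: under near-complete pairwise RSSR•⁺
  disproportionation, removing an •OH (hence an RSSR•⁺) frees its
  disproportionation partner to oxidize Fe²⁺ — a marginal-value effect of
  the pairing, not a property of the dilute regime.
* Davies-type corrections at I > 1 are an extrapolation; results at 1 M
  cystamine inherit that uncertainty.
* Everything is at 25 °C; no temperature dependence, no dose-rate
  (multi-track) effects, no direct energy deposition in solutes.

## Reproducing the study conditions

```{r}
library(frickeirt)

# one kinetics run with channel decomposition (500 MeV/u, 1 mM cystamine)
kin <- run_kinetics_experiment(energy_per_nucleon = 500,
                               cystamine_conc = 1e-3,
                               replicates = 10, seed = 1)
autoplot(kin)

# the 200-s concentration scan across the LET series
scan <- run_concentration_scan(energy_per_nucleon = c(500, 300, 70, 6),
                               conc = 10^seq(-6, 0), replicates = 5, seed = 1)
autoplot(scan)

# the double-ionization comparison at 248 keV/um
mi <- run_mi_comparison(conc = c(1e-6, 1e-3, 1), replicates = 5, seed = 1)
tidy(mi)
```
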