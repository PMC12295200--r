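---
title: "Methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the modelling choices behind `frickesim`, the
conventions that a user of the numerical results should know, and the known
limits of the model's fidelity. Code chunks are illustrative and not
evaluated at build time (several take minutes).

## Overview of the pipeline

A simulated history is one track realisation followed end to end:

1. a synthetic spatial distribution of radiolysis species at 1 ps
   (`sample_spur_ensemble` for low LET, `sample_cylindrical_track` above
   2 keV/µm);
2. the nonhomogeneous (intra-track) stage by the independent reaction
   times (IRT) method (`run_irt`), from 1 ps to a hand-off time of
   1 µs × *f*, where *f* is the viscosity factor;
3. deterministic pseudo-first-order bulk kinetics of the escaped species
   (`evolve_bulk`) to 200 s.

Histories are averaged by `run_scenario`; the quantity of interest is the
ferric yield G(Fe³⁺) at 100 s in molecules/100 eV.

## Chemistry stage

### Speciation and ionic strength

Sulfuric acid speciation uses the second dissociation constant
(pK~a2~ = 1.99) solved self-consistently; at 0.4 M H₂SO₄ the medium is
approximately 0.41 M H₃O⁺, 0.39 M HSO₄⁻ and 0.01 M SO₄²⁻, with ionic
strength ≈ 0.42 M. Rate constants between charged reactants get a
Debye–Brønsted correction
log₁₀(k/k₀) = 1.02 z₁z₂ √I / (1 + √I); the hydrated-electron
self-recombination is exempt (its measured constant already reflects a
high-ionic-strength medium).

### Rate-constant partition and viscosity scaling

Every reaction's observed constant is split by the Noyes relation
1/k~obs~ = 1/k~act~ + 1/k~diff~ with k~diff~ = 4πR~eff~D~rel~N~A~.
Reactions flagged fully diffusion-controlled get k~act~ = ∞ and an
effective radius solved from k~obs~; partially controlled reactions use a
fixed contact radius and a finite k~act~ solved from the partition.

**Design decision — what viscosity scales.** `apply_viscosity(system, f)`
divides every diffusion coefficient by *f*, recomputes k~diff~ with the
*fixed* reaction radii, and recombines with the *unchanged* k~act~. The
activation component is treated as a property of the encounter pair, not
of transport, so it does not scale with the medium viscosity. This is the
standard Noyes/Stokes–Einstein reading, and it is applied uniformly. Its
main observable consequence is discussed under "Known limitations".

### Self-reactions

For identical reactants the tabulated constant follows the convention
−d[A]/dt = 2k[A]². The IRT pair kernel must then reproduce an encounter
rate of 2k: the engine carries separate pair columns (`k_act_pair`,
`R_eff_pair`) obtained by partitioning 2k~eff~, while the conventional k
is kept for bulk kinetics and scavenging. This was validated against the
analytic single-pair reaction probability and a brute-force
Brownian-dynamics oracle.

## Track generation and calibration

The 1-ps distribution is deliberately simple: per-species Poisson counts
with expectation (yield × spur energy / 100), Gaussian positions with two
width classes — one for thermalised electrons (and their geminate
hydronium), one for radicals born at ionisation sites. Low-LET tracks are
lines of spurs with centre-to-centre spacing (mean spur energy)/LET;
high-LET tracks are cylinders with Gaussian radial profiles, periodic in
the axial coordinate.

**Design decision — spur spacing.** Independent spurs
(`spacing = Inf`) are placed ≥ 0.9 mm apart so they cannot interact; the
finite-spacing low-LET track treats the axial coordinate as periodic, so a
0.5–2 µm segment stands in for a long constant-LET track without edge
losses.

`calibrate_spur_parameters` fits the two widths and four initial yields so
that the simulated escape yields at 0.2 µs in deaerated 0.4 M acid match
the accepted values (H 3.70, OH 2.90, H₂ 0.40, H₂O₂ 0.80 molecules/100 eV,
with g(e⁻~aq~) < 0.05). The fit uses Nelder–Mead on a logit-transformed
box: widths in [2, 12] nm (electron) and [0.3, 3] nm (radical), yield
scales within ±40% of the literature-guided 1-ps values. Common random
numbers keep the objective smooth; a verification run with an independent
seed and a larger sample decides acceptance at 5% per species.

```{r calibrate}
set.seed(1)
fit <- calibrate_spur_parameters()
attr(fit, "residuals")
```

## IRT stage

Each unordered pair gets an independent first-reaction time drawn from the
analytic pair kernel (closed-form inversion for fully controlled pairs, a
radiation-boundary kernel with bisection for partially controlled pairs);
background solutes contribute exponential scavenging times with
pseudo-first-order constants that also carry an activation component
unaffected by viscosity. The earliest event is executed, products are
placed, affected pairs are resampled, and the process repeats until the
hand-off time. The inner loop is C++ (a priority queue with lazy updates);
results are bit-reproducible for a given seed because all randomness flows
through R's RNG.

Two properties anchor correctness:

- **Exact time dilation.** With every reaction fully diffusion-controlled
  and no background solutes, scaling D → D/f leaves the entire event
  sequence invariant with t → t·f. The engine reproduces this exactly,
  event by event.
- **Brownian-dynamics oracle.** For 2–3 particle systems, brute-force
  Brownian dynamics with the Erban–Chapman partial-absorption step and
  mirror reflection agrees with the IRT estimate within statistical
  tolerance.

## Bulk stage and ferric channels

After hand-off the surviving radicals are dilute, so their kinetics are
linear in the pseudo-first-order approximation (Fe²⁺, O₂, acid
concentrations held fixed). The ferric yield decomposes into the OH, HO₂
and H₂O₂ (Fenton) channels, tagged through both stages; a closed-form
asymptote provides a 10⁻⁴-level oracle for the integrator.

## Problem sizes and runtimes (one core)

| task | size | time |
|---|---|---|
| calibration | 24 segments × 30 spurs per objective call | ~5 min |
| low-LET scenario | 50 histories × 75 spurs | ~10 s |
| LET 25 scenario | 20 histories × 1 µm segments | ~1 min |
| LET 72 scenario | 20 histories × 0.5 µm segments | ~1 min |

## Known limitations

These are model-fidelity limits, not bugs; the acceptance tests that probe
them fail honestly rather than being loosened.

- **H₂ escape yield.** In 0.4 M acid the hydrated electron is scavenged by
  H₃O⁺ within ~0.3 ns, so intra-track e⁻+e⁻/e⁻+H recombination
  contributes little H₂; with initial yields bounded within ±40% of the
  literature values the calibrated H₂ escape yield plateaus near 0.3
  rather than 0.40, and H₂O₂ overshoots by a correlated amount. The
  ferric stoichiometry is insensitive to this (H₂ carries no weight in
  the asymptotic yield; the implied stoichiometric G is within 0.4% of
  the target).
- **Strong-viscosity suppression.** With the partition rule above
  (k~act~ viscosity-invariant), slowing diffusion mostly *dilates* the
  intra-track chemistry rather than changing its outcome: the only
  symmetry-breakers are the growth of the reaction probability per
  encounter (α → 1) and the non-dilating activation-limited scavenging.
  The simulated G(100 s) therefore falls only mildly with *f*, far less
  than reference values at f = 10–100 (which would require the
  activation-limited constants — e.g. the Fenton reaction — to scale as
  1/f as well, contradicting the partition rule). The monotone decrease
  with *f* is reproduced; its magnitude is not.
- **High-LET penumbra.** The single-Gaussian radial cylinder has no
  δ-ray penumbra, so at 72 keV/µm the core is too dense and the yield is
  underestimated beyond the sampling error.
- **OH-channel completion time.** With 1 mM Fe²⁺ the OH + Fe²⁺
  pseudo-first-order time constant is 2.9 µs, so the OH channel is ~97%
  (not ≥ 99%) complete at 10 µs; the stated check is kept and fails by
  this margin.
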