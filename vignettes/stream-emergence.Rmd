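---
title: "Emergent neural crest streams from chase-and-run tissue interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emergent neural crest streams from chase-and-run tissue interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological question and the model

Cranial neural crest (NC) cells leave the dorsal neural tube as a continuous
mass and then migrate ventrally in discrete streams. `ncstreams` implements a
two-dimensional cellular Potts model (CPM) in which those streams are an
*emergent* consequence of known cell-cell interactions between the NC and the
adjacent epibranchial placode tissue — no pre-existing corridor of guidance
cues is built into the model:

* **Chase**: placodes secrete the chemokine Sdf1 (substance `S`), which
  attracts NC cells.
* **Run**: on NC-placode contact both cells undergo contact inhibition of
  locomotion (CIL) and repolarize away from the contact.
* **Co-attraction**: NC cells secrete a diffusible co-attractant (`A`) that
  attracts other NC cells, balancing NC-NC CIL.
* **Confinement**: placodes deposit a short-range diffusible inhibitor (`I`)
  that repels NC, so inhibitor walls consolidate wherever placodes persist.

Placodal cells have no chemotaxis and placode-placode contacts carry no CIL.

### Lattice dynamics

Cells are domains of sites on a `lattice_width x lattice_height` grid
(x = anterior-posterior axis, y = dorso-ventral axis, y growing ventrally).
An elementary event picks a random target site and attempts to overwrite its
label with that of a random Moore neighbor, or with medium (retraction) in
10% of attempts. One Monte Carlo step (MCS) is one such attempt per lattice
site. The attempt is accepted with probability `min(1, exp(W - dH))`, where

    H = sum_i lambda_V (V_i - V_T)^2  +  sum_<xy> J(tau_x, tau_y) [x != y]

is the usual Potts energy (area constraint plus contact energies over the
8-neighborhood, the same neighborhood used for copies), and the work bias

    W = chemotaxis + springs + polarized motility

contains: *extension-only chemotaxis*, `sum_s lambda_s (c_s(target) -
c_s(source))`, applied only when a cell extends into a medium site, never at
contact sites or during retraction, with the extending cell's weights
(placodes: zero); *persistent adhesion springs* between linked cells,
`lambda_M (|r_ij| - d0) rhat_ij . drhat_i`, with rest length
`d0 = 2 sqrt(V_T / pi)`; and *polarized motility* `lambda_P phat_i . drhat_i`.

**Displacement scale in `W` (design decision).** The spring and motility
terms are forces projected on the displacement a copy causes. Projecting on
the bare centroid displacement (magnitude ~ `1/V_T` sites) makes these terms
two orders of magnitude weaker than the contact energies: the printed
parameter scale (`lambda_P` of 6-12 against `J` of 3-20) then cannot move
cells at all, and the tissue freezes. Projecting on the *unnormalized* lever
arm from centroid to the copied site (magnitude ~ cell radius) overshoots:
cell speeds reach several times the calibrated value and the tissues
intermix. The package therefore projects on the **unit** vector from the
cell's centroid to the modified site — the direction of the induced centroid
motion at site scale — which puts the printed weights on the same scale as
the contact energies and reproduces both sustained invasion and the intended
speed regime. This choice is a genuinely open point of the printed model
definition and is fixed here once, not exposed as a knob.

### Per-MCS cell state updates

After the `N` copy attempts of an MCS, in fixed order:

1. **Links.** Contacting unlinked pairs connect with probability 0.1/MCS;
   pairs that lost contact disconnect; other linked pairs break with
   probability `max(0, min(1, (|r_ij| - d0)/100))`.
2. **CIL.** Each *new* contact involving an NC cell gives each participant an
   independent chance (`p_CIL_NC`, `p_CIL_PL`) to enter the CIL state; the
   state clears once no triggering contact remains. The switching draw
   happens once per new contact event, not per MCS of sustained contact.
3. **Polarity.** `p <- (1 - deltaP) p + dr` with `dr` the centroid
   displacement over the MCS and `deltaP` by type and contact status. CIL
   cells are additionally repolarized by `-lambda_CIL` times the normalized
   sum of vectors to the neighbors they have a CIL interaction with (for
   placodes: contacting NC only — summing over *all* neighbors would point a
   front placode's bias toward its own tissue and invert the run).
4. **Fields.** One MCS of reaction-diffusion time (below).
5. **EMT.** The dorsal edge is scanned left to right for cell-free windows of
   one cell width by half a cell height (5 x 3); each receives a new NC cell
   (fresh id, zero polarity) that grows toward `V_T` under the area
   constraint. This models the continuous dorsal production of migratory NC.

Attempts that would erase a cell's last site are rejected (the model has no
cell death); cells may transiently fragment, as no connectivity constraint is
imposed.

### Reaction-diffusion fields

Each substance obeys `dc/dt = D lap(c) - delta c + S(sigma)` on the cell
lattice extended by a halo of 100 sites on every side (fields only; cells
never enter the halo), integrated with explicit forward Euler, 5-point
Laplacian, and 40 substeps per MCS — comfortably inside the stability bound
`max(D)/substeps <= 0.25` for the fastest substance (`D = 8`). The outer halo
boundary is zero-flux; the halo exists to emulate open space, and reflecting
walls 100 sites away keep total mass bookkeeping clean. Sources are evaluated
once per MCS from the current cell configuration and held fixed across
substeps; fields update after the MCS's copy attempts. NC sites secrete `A`
and take up `S` (clamped at the available concentration); placode sites
secrete `S` and `I`. Convergence is first order in the substep size and is
tested as such; the substep-count default is part of the model definition,
and the solution at other substep counts differs at the discretization order,
not at round-off.

## Parameters

All rates are per MCS, lengths in lattice sites (s.u.); the physical
calibration is 3.5 um/site and 10 s/MCS (so 0.1 s.u./MCS = 2.1 um/min and
3600 MCS = 10 h). Defaults (see `nc_params()`): secretion `S_A = 5`,
`S_S = 20`, `S_I = 0.7`; diffusion `D_A = D_S = 8`, `D_I = 0.005`; decay
`delta_A = delta_S = 0.006`, `delta_I = 0.0006` (so Sdf1 has range
`sqrt(D/delta) ~ 36.5` s.u. while the inhibitor range, ~2.9 s.u., is about
half a cell diameter — pericellular deposition); NC chemotaxis weights
`lambda_A = 1`, `lambda_S_eff = 150`, `lambda_I = -100`; motility
`lambda_P = 6` (NC) and `12` (placode) with polarity decay 0.3/0.08 (NC
free/contact) and 0.5/0.1 (placode); `lambda_CIL = 0.5`; `lambda_V = 5`,
`V_T = 25`; contact energies `J(NC,0) = J(PL,0) = 5`, `J(NC,NC) = 3`,
`J(NC,PL) = 20`, `J(PL,PL) = 10`. The high heterotypic contact energy plus
the short-range inhibitor produce the interfacial repulsion of the
chase-and-run; `J(PL,PL) = 2 J(PL,0)` puts the placode tissue exactly at the
wetting transition, a deliberately loose epithelium.

Three quantities the printed model leaves open are fixed as follows:

* **`p_CIL_NC = p_CIL_PL = 1`.** The CIL switching probabilities have no
  printed default; the placodal probability is treated elsewhere as a
  perturbation axis swept *downward*, implying a saturated default.
* **`U_S = 20`.** Sdf1 uptake by NC exists but has no printed rate. Matching
  the placodal secretion rate makes the NC front a strong local sink; this
  self-generated gradient steepens the attraction exactly at the advancing
  front and is what nucleates several separate streams. Small uptake values
  (0-5) were examined and produce slower fronts (mean per-MCS NC speed close
  to the calibrated 0.1 s.u./MCS rather than ~0.15) but coarser morphology —
  typically a single wide stream. The default keeps the strong-sink regime;
  `U_S` remains a config knob.
* **`lambda_M(NC-NC) = 1`** with `lambda_M = 5` for NC-placode and
  placode-placode links. The persistent-adhesion table value (a single
  global 5) conflicts with the adhesion-perturbation scale on which 0 is
  "low" and 2 is "high" NC-NC adhesion: a control value of 5 would sit above
  its own "high" perturbation, and stream width grows steeply and
  non-linearly with this parameter, so the control must lie strictly between
  0 and 2. The midpoint is used; both readings are reachable through
  `set_params()`.

## Randomness and reproducibility

A single RNG stream (R's generator, seeded by `set.seed` in
`init_simulation()`) drives every stochastic element, consumed in a
documented order per attempt (site, retraction flag, neighbor, acceptance —
no-ops and auto-rejections consume no acceptance draw) and per MCS (link
breakage over sorted pairs, link formation over sorted pairs, CIL draws over
sorted new pairs). Runs are bit-reproducible given (parameters, seed), which
the test suite asserts, and scenario results carry their seed lists and
parameter dumps in run manifests with file checksums.

## Morphometrics

Streams are quantified by the NC density probability function `rho(r)`: the
probability that a site at offset `r` from an NC-occupied site is also
NC-occupied, averaged over reference sites, with offsets leaving the lattice
excluded from numerator and sample count alike. The estimator pools each
occupied pair from both of its ends, making `rho(r) = rho(-r)` exact; the
one-sided variant is biased near the lattice boundary where reference counts
become small and one-sided, which can pin the profile above the 0.5 level
and spuriously report "no crossing". Characteristic width `W` and length `L`
are the distances between the first loci where the axis profiles through the
origin fall below 0.5 (50% NC presence), located by linear interpolation
between bracketing offsets (an integer-crossing convention differs by at
most one site). A profile that never falls below 0.5 before its support ends
yields the undefined sentinel `NA` — the no-streams outcome — which ensemble
summaries tally as a no-stream fraction rather than averaging. Ensemble maps
pool numerators and counts across replicates (count-weighted), matching
sample-count-shaded correlation maps.

Stream counts are automated (visual counting is the field practice):
connected runs of NC occupancy along the transect at half the initial
placodal depth, merging gaps shorter than 2 sites. Mean speeds are per-MCS
centroid displacement magnitudes averaged over cells and time; note this
measure includes boundary-fluctuation churn, so it exceeds the translocation
speed obtained from coarsely sampled trajectories (`mean_speed()` on
50-MCS-sampled tracks gives the migration-speed reading).

## What the scenarios emulate — and what they do not

`run_scenario()` replicates the default two-tissue configuration: 2 rows of
NC patches dorsally, 13 rows of placode patches beneath, on 180 x 95 sites
(about 0.6 x 0.33 mm), run 3600 MCS (10 h) with zero initial concentrations.
This emulates the pre-migratory cranial NC/preplacodal arrangement and its
spontaneous reorganization into ventrally invading streams, the concurrent
emergence of an inhibitor pattern between streams, and the perturbations:
chemotaxis knockout (no invasion), placodal CIL knockout (unsegmented
invasion), adhesion and CIL-probability sweeps, and width scaling at fixed
initial row counts (constant linear density along the AP axis).

It does not emulate: the third dimension and out-of-plane intercalation
(which in reality relieves placode compaction and limits stream length),
cell division and death, graft surgery, the fibronectin substrate,
molecularly distinct inhibitors (a single lumped species stands for all),
or leader/follower expression differences (any leader behavior is emergent).
Passing tests therefore support the *mechanism* — long-range attraction plus
short-range repulsion at a tissue interface segments an invasion front —
not a quantitative embryo-scale prediction.

Replicate-to-replicate variability of the final morphology is substantial:
stream number at the default width fluctuates between 1 and 4 and the
measured `W` accordingly; ensembles of 20 replicates give stable means,
while the reduced ensembles used in the test suite (2-4 replicates, chosen
to keep a full run of the suite within a coffee break on one CPU) carry
standard errors in `W` of order tens of s.u. The acceptance script uses 4
replicates at the full 3600 MCS and reports ensemble means.

## Numerical and degenerate-input choices

* Copy and bond neighborhood: Moore (8 neighbors); reduces lattice anisotropy.
* Neighbor draws landing outside the closed lattice are void attempts.
* Retraction flag is drawn before neighbor selection.
* `exp(W - dH)` is evaluated only for negative exponents (else accept).
* Lattice width not divisible by 5 drops the rightmost partial patch column;
  a lattice too small for one patch column or 15 patch rows is a
  configuration error.
* Empty NC masks give an undefined density map; `width_length` on it returns
  sentinels, never throws.
* Zero-magnitude CIL contact-vector sums skip the CIL bias for that step.
* Cell ids are assigned row-major at initialization; EMT cells take fresh
  `max + 1` ids.

## Known limitations

* The control morphology is more variable than the mechanism's published
  description suggests; with the printed parameter values the model as
  reconstructed here under-produces dorsal EMT insertions relative to what
  sustained full-depth streams would need, so the measured stream length
  ensemble-averages below the stream-spanning regime and single replicates
  occasionally coarsen into one wide stream.
* Mean per-MCS speeds run ~50% above the calibrated 0.1 s.u./MCS in the
  strong-uptake default regime (see the `U_S` discussion above).
* The explicit field solver costs most of the runtime (three fields x 40
  substeps x the halo-extended lattice); an implicit or FFT solver is out of
  scope.
```
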