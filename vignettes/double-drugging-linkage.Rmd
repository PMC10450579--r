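---
title: "Two-state linkage analysis of orthosteric-allosteric double-drugging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state linkage analysis of orthosteric-allosteric double-drugging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doubledrug)
```

## The model and its assumptions

`doubledrug` treats a kinase as a two-state ensemble: an active (open) and
an inactive (closed) conformation exchanging with unliganded equilibrium
constant `k_eq = [active]/[inactive]`, so `k_eq = 0.67` means a 40% active
apo ensemble. One orthosteric and one allosteric ligand bind with
state-specific dissociation constants; `Inf` encodes a state that is not
bound at all. The grand partition function over the eight species is the
product of per-state binding polynomials weighted by the state's intrinsic
weight, with one extra degree of freedom per state: a dimensionless
intrastate coupling factor multiplying the doubly bound species. The model
therefore separates two mechanistically distinct sources of cooperativity:

* **conformational selection** — both couplings at 1; each ligand shifts
  the ensemble and thereby changes the partner's apparent affinity. For
  two ligands exclusive for the inactive state the cooperativity factor is
  exactly `1 + k_eq`: an equilibrium shift alone cannot exceed that
  ceiling.
* **intrastate (direct) coupling** — a coupling different from 1 encodes
  genuinely different affinity for the partner-bound complex within the
  same conformation, e.g. a modulator that grips the drug-bound inactive
  state tighter than the apo inactive state.

Assumptions worth stating: exactly two conformations; one ligand per site;
binding is at equilibrium (preincubation protocols are treated as
equilibrated, never kinetically); apparent dissociation constants are
defined at half-occupancy in *free* ligand concentration, with conversion
to total-concentration space done only by the experiment-level mass
balance. "Saturating partner" is evaluated as an analytic limit of the
closed form, not as a large number.

The cooperativity factor `alpha = Kd_app(partner absent)/Kd_app(partner
saturating)` is algebraically identical at the two sites (the
thermodynamic cycle closes term by term), and the package tests enforce
agreement to 1e-9 relative on random models. Two boundary behaviours are
deliberate: a ligand binding both states with equal affinity factorizes
out of the partition function (`alpha` exactly 1), and a mutually
exclusive pair (each ligand exclusive for the opposite state) has
`alpha = 0` at both sites — infinitely negative cooperativity — rather
than an error.

## Activity model

Observed rates are modeled under k_cat/K_m conditions: `k_obs` is `k_max`
times the summed population of catalytically competent species. The
default competence weights encode the package's central mechanistic
reading: every inactive-state species is silent (the closing-competent
conformation does not turn over), every orthosteric-bound species is
silent (active-site occlusion), and allosteric-bound active-state species
are fully competent (a purely conformational modulator does not block
chemistry). Substrate and ATP are not explicit species; the known
ATP-induced shift of the conformational equilibrium under assay conditions
can be represented by re-parameterizing `k_eq` per condition, and is
deliberately not automated.

Free ligand concentrations inside `k_obs()` come from exact mass balance
at the assay's enzyme concentration (20 nM by default), solved by nested
monotone root finding, so ligand depletion by tight binders is handled
exactly. Either total may be `Inf`; the saturating limit restricts the
ensemble to the species carrying that ligand.

## Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| `k_eq` | — | (required) | apo active/inactive ratio; 0.67 for the Aurora A system |
| `kd_*_active/inactive` | nM | `Inf` | state-specific affinities; `Inf` = non-binder |
| `coupling_active/inactive` | — | 1 | intrastate coupling of the doubly bound species |
| `k_max` | min^-1 | 1 | rate scale of a fully active uninhibited ensemble |
| `e_total` | nM | 20 | assay enzyme concentration (10 nM in the fluorescence titrations) |
| `residual` | fraction | 0.10 | residual-activity level for dose-reduction metrics |

## Experiment forward models and numerical conventions

**ITC.** Protocols carry the cell volume (µL), cell and syringe
concentrations (µM) and per-injection volumes; the ligand-of-interest Kd
is in nM, enthalpies in kJ/mol, heats in µJ. Each injection dilutes the
existing cell contents by `(1 - v/V0)` and adds titrant `S·v/V0` (the
standard perfusion displacement). Heats are referenced to the change in
bound *fraction* of the initial cell protein,
`q_i = 1e-3 · ΔH · V0 · n · P0 · Δfb`, a convention chosen so that the
cumulative heat converges exactly to `n·ΔH·V0·P0` at titrant excess while
keeping the Wiseman isotherm shape; commercial analysis software does not
publish its internal accounting, so the package states its own and uses it
consistently in both simulation and fitting. Competitive replacement (a
weak competitor prebound in the cell to bring a too-tight titrant into the
fittable window) is modeled mechanistically through the two-ligand
one-site mass balance each injection — a monotone cubic solved by
bracketed root finding with Newton polish to machine precision — with the
analytic shift formula `Kd,app = Kd·(1 + [C]/Kd,weak)` retained as a
cross-check (they agree within 1% whenever the competitor is in ≥ 50-fold
excess over the protein). One-site fits estimate `kd`, `ΔH`, `n` and a
constant per-injection offset, discard the first injection when the
thermogram is flagged accordingly, and flag Wiseman c-values
(`cell_conc/kd`) outside `[1, 1e4]` as poorly identified. A thermogram
whose heats carry no signal (all equal) is rejected as degenerate rather
than fitted.

**Fluorescence titrations.** The tight-binding quadratic
`F = F0 + A·((I+Et+Kd) - sqrt((I+Et+Kd)^2 - 4·Et·I))/(2·Et)` — baseline
plus amplitude times the bound enzyme fraction — is evaluated in a
cancellation-stable form and fitted with the enzyme concentration fixed.
Fitted Kds below half the enzyme concentration are flagged
`near_stoichiometric`: in that regime the curve approaches a step function
at `I = Et` and the Kd is not identifiable, which is why the package
(like a careful experimentalist) simulates tighter-Kd curves for
comparison rather than trusting such fits.

**Dose-response.** Inhibition curves are summarized with the
four-parameter logistic. Because the hill-sign swap
`(top, bottom, hill) -> (bottom, top, -hill)` describes the same curve,
fits are canonicalized to `hill > 0`, making `top` the zero-dose plateau;
descending inhibition curves then have `top >= bottom`. The
dose-for-residual metric inverts the 4PL in closed form at
`r × reference`, with the reference taken per curve (each curve's own
uninhibited rate); targets outside the open plateau interval are reported
as unreachable — exactly the situation of a partial allosteric inhibitor
whose plateau sits at 70% activity when 10% residual is requested. Fits
whose data do not approach both plateaus within 20% of the dynamic range
are flagged `plateaus_unresolved`.

**Estimation.** All fitters share one least-squares engine
(Levenberg–Marquardt, gradient tolerance 1e-8, positive parameters on the
log scale with delta-method standard errors). Standard errors come from
the linearized covariance at the optimum and the 68.3% confidence interval
is estimate ± 1 SE, the convention used for binding fits; quantities
derived from inhibition curves instead get leave-one-out jackknife errors
`sqrt((n-1)/n · Σ(θ_i - θ̄)^2)`, jackknifing over points (one failed
refit is tolerated and dropped; more than one aborts). If the supplied
start does not strictly converge, up to four additional deterministic
starts are drawn log-uniformly over positive finite bounds under a fixed
internal seed — robustness without nondeterminism; identical inputs always
give identical fits. Starts sitting exactly on a box bound are nudged
1e-8 inside, where the Marquardt step would otherwise stall. Global
linkage fits refuse structurally unidentifiable requests (fewer
observations than free parameters, or a single condition that cannot
separate state affinities from the ensemble constant).

## Synthetic data: what it emulates and what it does not

The generators reproduce the statistical structure of the three readouts:
additive Gaussian heat noise on thermograms, multiplicative fractional
noise on fluorescence and on observed rates, all as pure functions of
(parameters, seed). They do not emulate raw power traces, baseline drift,
plate effects, titrant dilution errors or inter-day variability — so
passing recovery tests demonstrates that the estimators are unbiased and
well-conditioned under the stated noise model at realistic design points,
not that every laboratory systematic is survivable.

The named presets pin every printed anchor of the two studied systems
(`k_eq = 0.67`; danusertib apparent Ki 0.87 nM; the 16/2/3-fold monobody
cooperativities; imatinib 15 vs 72.4 nM and its two- and fourfold negative
cooperativity with asciminib; the 30%/93% saturating-inhibition plateaus)
and document every absolute value that is *not* printed (monobody and SKI
state affinities, rate scales, residual activities of the inhibiting
monobodies) as invented, directly in the preset's provenance notes.

Three reconciliation choices deserve emphasis, because the printed anchors
are not mutually consistent under pure conformational selection:

* For the regulatory-domain Abl construct, the fivefold construct
  preference of imatinib fixes the apo open fraction at 15/72.4 ≈ 0.21,
  and the 93% inhibition plateau fixes the open fraction at asciminib
  saturation at 0.07 × that; an open-exclusive imatinib would then show
  14-fold, not fourfold, negative cooperativity. The preset reconciles all
  three anchors with an open-state coupling factor (0.25/0.07 ≈ 3.6),
  i.e. asciminib's allosteric propagation modifies imatinib's affinity
  within the open state. The isolated kinase domain uses the same device
  (coupling 0.5/0.7) to hold its twofold anchor together with the 30%
  plateau. An alternative reading — ATP shifting `k_eq` between the ITC
  and assay conditions — is representable by re-parameterizing `k_eq`, but
  is not automated.
* The SKI preset adopts the ensemble reading under which asciminib leaves
  SKI's affinity unchanged: an apo ensemble already far shifted to the
  closed state. Its `k_eq` therefore differs from the imatinib preset's,
  reflecting genuinely different anchor sets rather than a single
  self-consistent parameterization.
* The inhibiting monobodies are modeled as partial inhibitors binding both
  states with inactive preference (invented residual activities 30% and
  10% at saturation); an inactive-exclusive modulator would abolish all
  activity at saturation and leave nothing for an orthosteric titration in
  its presence to measure. The intrastate coupling is then solved from the
  documented fold via `alpha = c·(1+k_eq)·(1-s)`.

## Numerical tolerances and problem sizes

Closed-form apparent Kds agree with numeric half-occupancy roots to 1e-9
relative (bisection bracketed on `[kd_min·1e-6, kd_max·1e6]`); mass-balance
solvers conserve totals to 1e-10 relative and the competitive solver
reduces to the one-ligand quadratic to 1e-12 at zero competitor;
zero-noise simulate/fit round trips recover parameters to 0.1%. Saturation
consistency is checked at 100× and 1000× the partner's *apparent* Kd (the
ensemble-level scale a titration actually sees; multiples of a state Kd do
not saturate a partner whose preferred state is rare). The test-suite and
reproduction-script study sizes — 1000 random models for structural
invariants, 20 seeded replicates for each Monte-Carlo recovery, 25
injections per thermogram, 12-point titrations — were chosen as the
smallest designs at which the medians and means in question are stable to
well within their stated tolerances.

## Known limitations

* Exactly two states and one ligand per site; no kinetics (no kinITC, no
  association/dissociation rates).
* 4PL summaries of tight-binding inhibition curves (apparent Kd at or
  below the enzyme concentration) are systematically distorted in total
  dose — `k_obs()` itself handles depletion exactly, and the
  4PL-vs-direct-root consistency checks are run at dilute enzyme where the
  mechanistic curve is exactly hyperbolic.
* Synergy metrics are mechanistic dose-reduction factors relative to the
  zero-modulator row; no Bliss/Loewe reference-model scores.
* IC50s are not converted to Ki (that requires ATP and Km values the
  framework does not carry), and enthalpy decompositions of the
  conformational equilibrium are out of scope.
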