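---
title: "A reaction-diffusion model of Caulobacter cell polarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reaction-diffusion model of Caulobacter cell polarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caulopolar)
```

## The biological problem

*Caulobacter crescentus* divides asymmetrically: each division yields a
motile swarmer cell, in which phosphorylated CtrA (CtrA~P) blocks the
chromosomal origin and prevents DNA replication, and a sessile stalked
cell, in which CtrA is cleared and replication starts immediately. The
asymmetry is anchored by three self-assembling scaffolding proteins:
PopZ (both poles), PodJ (new pole) and SpmX (old pole). The scaffolds
recruit the DivJ kinase and PleC phosphatase to opposite poles, which
sets a spatial pattern of phosphorylated DivK; DivK~P, through DivL,
flips the bifunctional kinase/phosphatase CckA, and CckA in turn
controls both the phosphorylation and (through unphosphorylated CpdR)
the proteolysis of CtrA. `caulopolar` implements this chain end to end
on a growing, dividing one-dimensional cell and reproduces the
asymmetric partitioning of CtrA~P between the daughters.

## The activator-substrate-depletion (A-SD) mechanism

Each scaffold is described by two fields, a fast-diffusing monomer
(the substrate) and a slow-diffusing polymer (the activator). For PopZ:

$$
\frac{\partial [\mathrm{PopZ_m}]}{\partial t} =
  k_s - (k_d + \mu)[\mathrm{PopZ_m}]
  + k_{depol}[\mathrm{PopZ_p}]
  - k_{dnv}\bigl(1 + \alpha_{PopZPodJ}[\mathrm{PodJL_T}]\bigr)[\mathrm{PopZ_m}]
  - k_{aut}[\mathrm{PopZ_m}][\mathrm{PopZ_p}]^2
  + D_m \partial_x^2 [\mathrm{PopZ_m}]
$$

with the mirrored signs for the polymer. The quadratic dependence of
autocatalytic polymerization on the polymer concentration reflects
branching growth: free ends catalyze addition at branch sites, both
proportional to the amount of polymer. Because the monomer diffuses
orders of magnitude faster than the polymer (the monomer diffusivity
follows the empirical mass law $D = 4.3\times10^3/\mathrm{MW}^2 + 0.65\;
\mu m^2 s^{-1}$), the pair forms a Turing system: a local polymer
excess consumes monomer globally and grows into a discrete focus.
`run_popz_subsystem()` exposes this pair in isolation; a 1% polymer
excess at one pole grows into a macroscopic polar focus while an
exactly uniform state remains uniform.

Long-form PodJ follows the same scheme with autocatalysis suppressed by
total SpmX, and its synthesis is both methylation-gated and inhibited
by CtrA~P. SpmX (whose equations the model reconstructs in the same
A-SD form) nucleates preferentially on PopZ polymer and is excluded by
PodJ polymer, so the two client scaffolds occupy opposite poles.
Autocatalysis of PopZ and PodJ is 25% faster in the two polar
compartments, a fixed factor standing in for the higher affinity of
scaffolds for curved polar wall.

Two structural choices here were genuinely open and are worth stating.
First, the protease PerP truncates PodJL into PodJS as a conversion
flux (`k_{d,PodJ2}[\mathrm{PerP}]`), preserving protein: the late-cycle
PerP pulse must convert essentially all PodJL polymer before division,
because any surviving PodJL polymer at the flagellar pole re-seeds the
next cycle's PodJL field at the wrong pole and inverts the lineage's
polarity. Second, SpmX nucleation carries a PodJ-polymer inhibition
term (`alpha_SpmXPodJ`); without that polar exclusion the second PopZ
focus recruits SpmX to the new pole late in the cycle and the
cycle-to-cycle map destabilizes.

## The signaling layer

The model's 39 state fields comprise the four scaffold monomer/polymer
pairs, PerP, and the signaling proteins in cytosolic and
polar-membrane-bound forms (suffix `_b`). Binding to the pole is mass
action with a rate enhanced by the local concentration of the
recruiting scaffold polymer — SpmX for DivJ, PodJ for PleC and DivL
(DivL also via PopZ), bound DivL and PopZ for CckA, PopZ for DivK and
CpdR. Catalysis is mass action throughout:

* DivJ binds DivK and phosphorylates it; the phosphotransfer step runs
  only in the membrane-bound complex, i.e. DivJ kinase activity is
  coupled to its polar localization (the kinase-dead mutant
  `divJ_H338A` zeroes only this step, leaving binding intact).
* PleC in its phosphatase conformation binds DivK~P, dephosphorylates
  and releases it; the complex can instead switch PleC to a kinase
  conformation (stimulated by DivK~P itself), which phosphorylates
  DivK directly and relaxes back to the phosphatase.
* DivL binds DivK~P; the DivL:DivK~P complex switches CckA from kinase
  to phosphatase, layer-matched (membrane CckA responds to the
  co-localized membrane complex).
* CckA kinase phosphorylates CtrA and CpdR; CckA phosphatase reverses
  both; unphosphorylated CpdR drives proteolysis of both CtrA forms.

With these pieces the wild-type cycle unfolds as: SpmX nucleates on the
inherited old-pole PopZ within ~10 min; DivJ docks and DivK~P rises;
DivL:DivK~P flips CckA to phosphatase, CpdR is dephosphorylated and
CtrA is degraded and dephosphorylated, so mean CtrA~P falls below the
replication threshold ~22 min after birth. During S phase the fork
passes *podJ* and *ctrA*: PodJL fires its new-pole focus and recruits
PleC and DivL, and CtrA synthesis resumes. The fork passage at *pleC*
floods the cell with PleC phosphatase, DivK~P collapses, CckA returns
to its kinase state, and CtrA~P recovers before division. After Z-ring
closure each half re-equilibrates separately: the stalked half (with
DivJ) clears CtrA~P, the swarmer half (with PleC/DivL) keeps it high.

## Cell-cycle events

Replication initiates at the first downward crossing of the
length-weighted mean CtrA~P below the threshold `theta` (if the mean is
already below `theta` at 15 min, `T_ini = 15`; if it never crosses by
300 min the run is terminated). Termination is `T_ini + 90` min; each
methylation-site promoter (*ctrA*, *pleC*, *perP*, *podJ*) switches to
its hemi-methylated, fully transcribing state when the bidirectional
replication fork reaches its coordinate (linear interpolation of the
90-min S phase along the replichore) and back at termination, when the
synthesis multiplier returns to the leak fraction `eps_meth`. The
Z-ring closes 5 min after termination — from then on diffusion across
the midcell interface is blocked while reactions continue — and the
daughters separate 25 min later. Division splits the ten compartments
into halves, re-grids each daughter to ten compartments
piecewise-constantly (amount-conserving), and reorients the swarmer so
the mother's new pole becomes its old pole. The shipped gene
coordinates are package defaults chosen to reproduce the observed
order of fork passages (notably *perP* late in S phase); they are
plain CSV and overridable.

## Numerics

The PDEs are discretized into `N = 10` compartments (configurable) with
reflecting no-flux second-difference diffusion; at `N = 10` both
printed end-compartment forms are one-sided mirror stencils, which is
what conservation requires. Each compartment grows exponentially at
`mu = ln(4.4/2)/150 ≈ 0.0053/min` (cell length 2 um at birth, ~4.4 um
at separation after a 150-min cycle); growth is applied analytically
inside the right-hand side and dilution `-mu C` sits in the reaction
terms. Integration uses a stiff solver (`deSolve::lsodar`) with a
banded numeric Jacobian (half-bandwidth 39, the per-compartment state
dimension), relative tolerance 1e-6 and absolute tolerance 1e-9;
threshold crossings are located by the solver's root finder. Negative
excursions of order the absolute tolerance are left in the state and
only clipped where a rate law requires nonnegativity (Hill inputs).
Simulations chain five cycles by feeding each swarmer daughter forward;
by cycle 3 the event sequence is periodic (cycle 4 vs 5 kymograph
correlation > 0.99 per species) and cycle 5 is the reporting cycle.

## Parameters and calibration

The 110 named constants ship in `default_parameters()`: 69 fixed
(physical constants, timing, diffusivities, binding/unbinding rates)
and 41 estimated (scaffold polymerization kinetics, recruitment
strengths, catalytic rates, CtrA synthesis/proteolysis, and the
threshold `theta`). Time is in minutes, length in micrometers,
concentrations in dimensionless scaled units — only ratios and the fit
to scaled data are meaningful. The default values are this package's
own calibration: they were tuned against the wild-type behavior the
calibration objectives encode (initiation near 25 min, bipolar PopZ,
transient new-pole DivK~P accumulation, limit-cycle convergence) and
then verified against the mutant catalog, following the same
estimate-then-verify loop the objectives are designed for. One known
deviation: the second (new-pole) PopZ focus in this calibration emerges
at ~127 min, later than the ~50 min seen experimentally; advancing
PodJL polymerization far enough to fix this destabilized the
cycle-to-cycle map, and the stable calibration was kept.

`objective_f1()` scores the fit of simulated whole-cell totals (sum
over all forms of a protein, weighted by compartment length — what a
western blot measures) against normalized series for PodJL, PodJS and
total CtrA at 9, 9 and 8 time points with weights 80, 80 and 400, over
cycles 2 and 3, each series scaled onto the simulation by the
least-squares factor; it adds the replication-timing penalty
`max(0, |T_ini - 25| - 5)^2` once per evaluation (the formula's
placement between the cycle sum and the penalty is ambiguous; one
penalty per evaluation was chosen and is the convention throughout).
`objective_f2()` adds the spatial penalties (weights 100 and 1):
`SP_PopZ` requires the cycle-averaged new-pole PopZ to reach 4x and the
old-pole 1.5x the central mean, `SP_DivK` requires new-pole DivK~P to
reach 2x the central mean; surpluses are free.

`estimate_parameters()` minimizes `(f1, f2)` with a nondominated-
sorting genetic algorithm (fast nondominated sort, crowding distance,
simulated binary crossover, polynomial mutation, elitist selection)
over the estimated group within 0.4x-1.5x of the seed values. The seed
vector is injected into the initial population, so successive rounds
resume from the previous round's verified winner; the manual
mutant-verification step between rounds is documented, not automated.
The search can run on a coarser grid (`N = 4`) as a pre-fit pass and be
reseeded at `N = 10`. Default GA budget (population 12, 5 generations)
is deliberately small; real calibration campaigns should raise both.

## The synthetic-data generator

`generate_fixture_data()` stands in for digitized western-blot series:
it simulates the wild type at a reference parameter set, samples
whole-cell totals of PodJL, PodJS and total CtrA at the canonical time
point counts over cycles 2 and 3, normalizes each series by its
maximum, and applies seeded multiplicative lognormal noise with a given
coefficient of variation. It emulates the sampling structure and
noise scale of blot densitometry, not its systematic artifacts
(saturation, background subtraction, loading variation), and it shares
the model's own structure — so calibration tests against it demonstrate
that the pipeline recovers known parameters from clean or noisy data of
the right shape, not that the model is identified by real blots.

## Worked example

```{r example, eval = FALSE}
p <- default_parameters()
cycles <- run_strain("WT", p, n_cycles = 5)
tr <- reporting_cycle(cycles)
event_log(tr)
#>    event  time
#> 1  T_ini  22.4
#> 2  T_term 112.4
#> 3  T_zring 117.4
#> 4  T_sep  142.4

## mutant comparison
wt <- tr
dpleC <- reporting_cycle(run_strain("dpleC", p, n_cycles = 5))
mutant_divkp_ratio(dpleC, wt)
#> [1] 2.49
```

## Limitations

GcrA, DnaA and CcrM regulation are not modeled (replication initiation
is the CtrA~P threshold rule only); Z-ring constriction is a scheduled
event, not a mechanism, so division-defect morphologies (strong PodJ
overexpression, branching filaments) are out of reach; geometry is
one-dimensional with uniform growth; the model is deterministic. The
knockout of DivJ blocks replication initiation in the model even though
the real deletion is viable — a known discrepancy of this network
reconstruction. Mutant DivK~P ratios have the observed directions but
their magnitudes depend on the calibration; they should be re-derived
after any recalibration.
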