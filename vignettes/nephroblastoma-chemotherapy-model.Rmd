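---
title: "A discrete cytokinetic model of nephroblastoma response to preoperative chemotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A discrete cytokinetic model of nephroblastoma response to preoperative chemotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nephrosim)
```

## The model and its assumptions

`nephrosim` simulates a solid tumor as an age-structured population of five
cell classes: stem cells (unlimited mitotic potential), LIMP cells
(limited mitotic potential — committed progenitors that perform at most
`N_LIMP` mitoses before terminal differentiation), terminally
differentiated cells, and apoptotic and necrotic cells awaiting clearance.
Stem and LIMP cells occupy either the cycling phases G1/S/G2/M or the
dormant G0 phase; every phase is resolved into hourly age bins, and the
engine advances in fixed 1 h steps. All per-hour rates in the parameter
table are used directly as per-step fractions, which is what makes the
1 h step the natural resolution.

The class structure encodes the biology that drives response to therapy:

* **Stem division balance.** A mitosis is symmetric with probability mass
  `P_sym` (two stem daughters) or asymmetric (one stem daughter plus one
  LIMP daughter with full potential `m = N_LIMP`). A LIMP mitosis at
  remaining potential `m` yields two daughters at `m − 1`; at `m − 1 = 0`
  the daughters are terminally differentiated.
* **Dormancy.** Each newborn stem/LIMP daughter enters G0 with mass
  `P_sleep` (a proxy for the tumor's oxygen and nutrient status), else G1.
  G0 is modeled as a hard deadline: after `T_G0` hours a dormant cell
  either re-enters G1 (fraction `P_G0toG1`) or dies through necrosis. We
  chose the deadline-plus-branch reading (rather than a continuous exit
  hazard) because `T_G0` is defined as the time a dormant cell can survive
  before necrotic death.
* **Spontaneous death.** All living stem/LIMP cells — including G0
  residents, which are living cells — are subject to the apoptosis
  fraction `R_A` per hour; differentiated cells die at `R_ADiff`
  (apoptosis) and `R_NDiff` (necrosis). Dead cells occupy volume until
  their lysis products clear, `T_A` hours for apoptosis and `T_N` for
  necrosis.

Populations are real-valued (mean-field expectations), not integer
stochastic: a 1 mm³ geometrical cell holds on the order of 10⁶ cells, so
fractional bookkeeping is the appropriate limit and makes every reported
quantity deterministic. A seeded `stochastic_round()` mode exists for
small-population experiments and is off by default.

Within a step the rules apply in a fixed, documented order (spontaneous
death, aging, mitosis, G0 exit, clearance, hit-cell advancement), so
trajectories are bit-stable across runs.

### Phase split of the cycle

Only the total cycle duration `Tc` is a model parameter. The split into
G1/S/G2/M defaults to 40:39:13:8 percent of `Tc` — typical human
cell-cycle proportions — rounded to whole hours by largest remainder. The
split does not affect free-growth kinetics at all (only `Tc` enters the
renewal equation below); it merely positions the end-of-S death point for
actinomycin-D-hit cells within the cycle, shifting individual death times
by hours. It is configurable per parameter set.

## Pharmacodynamics

Drugs act through cell kill ratios (CKR = 1 − survival fraction): the
fraction of eligible cells lethally hit at the instant of administration.
Marking moves cells into hit compartments; the total cell count is
conserved exactly, and death occurs later, at the drug's mechanism-specific
point of the rudimentary cycle the hit cells keep traversing:

* vincristine binds in all cycling phases and kills at the **end of M**
  (mitotic-spindle poison); it never touches dormant cells;
* actinomycin-D binds in all phases including G0 and kills at the
  **end of S** (DNA intercalation blocks synthesis).

Design choices where the mechanism description leaves room:

* **Additive combination, capped.** A combined administration marks
  `CKR_total = min(1, CKR_VCR + CKR_ACT)` of each cycling compartment,
  attributed to the two drugs in proportion to their individual CKRs.
* **ACT-hit cells already past S** (in G2 or M at marking) die at the end
  of M without dividing — they cannot re-run a synthesis phase they have
  completed.
* **ACT-hit dormant cells** leave G0 on the next step and traverse the
  rudimentary G1 + S before dying; a lethally damaged cell has no reason
  to wait out the dormancy deadline.
* Hit cells are excluded from further marking and from the spontaneous
  apoptosis hazard; they are already fated.

### The administration pattern

The packaged protocol places four combined administrations at days 3, 10,
17 and 24 of a 28-day course (day 0 and day 28 being the two imaging
instants). Vincristine is given at every administration; actinomycin-D at
administrations 1 and 3 only (days 3 and 17), i.e. weekly vincristine with
fortnightly actinomycin-D. This is the actual structure of the
preoperative AV regimen for unilateral stage I–III nephroblastoma, and the
packaged virtual tumors reproduce the published volume reductions and
final compositions under exactly this pattern, while actinomycin-D at all
four instants over-predicts every published reduction by 8–15 percentage
points. Both the per-event CKRs and the actinomycin-D placement
(`act_events`) are configurable, so a fully combined schedule is one
argument away.

## Equilibrium initialization and growth kinetics

A freely growing tumor settles into a stationary composition in which
every compartment is multiplied by the same factor λ each hour; `k =
log(λ)` is the growth-rate constant and `T_d = ln2/k` the doubling time.
Initializing every geometrical cell from this dominant eigenvector (scaled
to the cell density) is essential: any other composition produces an
artificial transient — a burst or dip of mitoses — during the first days
of a simulation, exactly where treatment effects are being measured.

The eigenpair is computed exactly rather than by power iteration. The
drug-free transition structure is block-triangular: the stem block is the
only self-renewing loop, the LIMP cascade and the dead-cell queues are
pass-through chains (nilpotent, eigenvalue 0), and the differentiated pool
decays at the scalar rate `1 − R_ADiff − R_NDiff`. The stem block's
dominant factor is the root of its renewal (Euler–Lotka) equation

$$(1+P_{sym})\,\Big(\tfrac{1-R_A}{\lambda}\Big)^{T_c}
  \Big[(1-P_{sleep}) + P_{sleep}\,P_{G0\to G1}\,
  \Big(\tfrac{1-R_A}{\lambda}\Big)^{T_{G0}}\Big] = 1,$$

solved by bisection to 1e-15; the dominant eigenvalue of the full
structure is the larger of this root and the differentiated decay rate
(for strongly shrinking parameter sets the long-run composition is the
differentiated pool and its death products — the stem lineage dies out
faster). The eigenvector then follows from a few inverse-iteration solves
at that analytically known shift, to a residual of 1e-12 on the normalized
state. This is robust where power iteration is not: near criticality the
subdominant spectral gap shrinks below 1e-3 and iterative schemes need
1e5+ steps or limit-cycle. A dense one-hour `transition_matrix()` is built
by independent code and the test suite checks it against the stepping
kernel exactly, and the fitted slope of ln(total) from simulated free
growth against the eigenvalue route to within 2%.

## The lattice

The 3D mesh discretizes the tumor into geometrical cells (GCs) of 1 mm³
(configurable), each holding a full age-resolved state;
10⁹ cells/cm³ gives the typical initial content `nbc = 1e6`. Each step is
two scans: the cytokinetic update of every GC (with optional per-region
parameter overrides), then occupancy rebalancing with thresholds at
0.5×`nbc` and 1.5×`nbc`:

* a GC exceeding the maximum sheds half its content outward: the shed half
  is inserted at the first site on the greedy path toward the nearest
  empty site, displacing the path contents one GC outward and creating a
  boundary GC — expansion;
* a GC below the minimum empties into its most populated 6-neighbor and is
  deleted — shrinkage.

Ties in target selection and path steps are broken in a fixed axis order
(+x, −x, +y, −y, +z, −z), so lattice runs are deterministic. Rebalancing
only moves cells, never creates or destroys them; because the cytokinetics
of this model stage are density-independent and linear, the aggregate
trajectory of a homogeneous lattice tumor coincides with the well-mixed
("equivalent homogeneous tumor") mode, which the tests assert to within
1% and which is how the packaged clinical scenarios are run. The
thresholds keep per-GC content within a factor 1.5 band of `nbc`, so the
GC-count volume tracks the population-derived volume (total cells /
density) within that band — between rebalancing events the two drift
apart by construction, which is why all reported volumes and reductions
use the population-derived volume.

Masks are accepted as plain 3D logical arrays (6-connected); NIfTI volumes
can be read with any NIfTI reader and passed as arrays.

## Reported metrics

* Volume reduction: `100 × (1 − V_final/V_baseline)`, evaluated 1 day
  after completion of therapy for the typical tumor and 3 days after for
  the adapted scenarios T1–T4 (the published reporting convention).
* Growth fraction = cycling (G1+S+G2+M) share; dormant = G0 share. Hit
  cells still traversing the rudimentary cycle are tallied in the phase
  class they currently occupy — they take up volume until cleared — which
  keeps both decompositions (proliferating + dormant + differentiated +
  dead, and stem + LIMP + differentiated + dead) exhaustive at 100%.
* Reductions and compositions are invariant to the initial volume (the
  dynamics are linear), so the packaged scenarios default to 100 cm³ and
  the choice is immaterial; the test suite asserts this invariance.

## Sensitivity analysis

`rank_parameters()` performs one-at-a-time sweeps of all twelve
tumor-dynamics parameters and sorts them by a sorting criterion; the
packaged criterion is the normalized range — (max − min) of the output
over the sweep divided by the absolute output at base values. It is
scale-free, zero exactly for insensitive parameters, invariant to sweep
direction, and pluggable (any curve functional can be ranked).

The default ranges are a documented judgment call. For the parameters the
packaged scenarios genuinely span (`Tc` 20–58 h, `T_G0` 34–102 h, `P_sym`
0.42–0.79, `P_sleep` 0.27–0.41, `CKR_total` 0.48–0.72) we use the scenario
span widened by 20%. For the rest we use moderate, roughly factor-two
perturbations around the reference values (`T_N` 10–40 h, `T_A` 3–12 h,
`R_A` 0.0005–0.002, `R_ADiff` 0.0015–0.006, `R_NDiff` 0.0005–0.002,
`P_G0toG1` 0.005–0.02, `N_LIMP` 1–5): the extreme differentiated-cell
death rates that one fitted scenario assigns (0.05/h) describe a
particular blastemal tumor, not a typical plausible range, and sweeping
them would conflate scenario fitting with population-level plausibility.
All ranges are arguments. With these ranges the ranking under the
volume-reduction output places `P_sleep` and `P_sym` far ahead of the
rest — the tumor's dormancy (oxygenation) status and the symmetric/
asymmetric stem-division balance — with the drug cytotoxicity
(`CKR_total`), cycle duration and stem/LIMP apoptosis rate in the next
tier, as the test suite asserts.

`dyad_grid()` evaluates two-parameter combinations for both free-growth
rate and post-therapy reduction, masking grid points without monotone free
growth or without volume reduction. The grids reproduce the expected
structure: growth accelerates with `P_sym` and slows with `P_sleep`
(parallel-stripe level sets), kill ratios leave free growth exactly
untouched, and reductions deepen with `CKR_total`, long cycles, and high
spontaneous apoptosis. One caveat the grids expose: in this engine,
raising `P_G0toG1` slightly *reduces* the net volume reduction (recycled
dormant cells accelerate regrowth between administrations), so the sign of
that secondary effect depends on engine conventions and we do not treat it
as a reproducible claim.

## What the virtual tumors emulate — and what they do not

The packaged scenarios are synthetic tumors constrained by clinical
observables (imaging volume reduction, histological composition) of a
preoperatively treated nephroblastoma, not mechanistic reconstructions.
Their agreement with the published characteristics shows that the engine
reproduces the cytokinetic consequences of the parameter choices; it does
not validate the parameters against biology beyond those constraints.
Known simplifications: exponential (not Gompertzian) free growth, so long
free-growth horizons overestimate late volumes; transition rates held
constant over the four-week course; no explicit pharmacokinetics — dose
and exposure are collapsed into per-administration CKRs; no
density-dependent vincristine toxicity; dormancy driven by parameters, not
by a resolved oxygen/nutrient field, so spatial heterogeneity of hypoxia
is absent; and no immune or stromal interactions.

Scenario T3 deserves a note: it fits the observed shrinkage purely by
raising both CKRs (to a combined 0.7). Its reduction is the one packaged
quantity that is sensitive to engine conventions the published description
does not pin down (phase split, hit-cell handling, administration
pattern); our engine places it at ~79% against the published 72%, while
the four scenarios that perturb biology rather than the kill ratios all
land within the reporting precision. A kill-ratio-only fit transfers least
well between implementations — which is itself an argument for adapting
models on multiscale data rather than volume alone.

## Numerical conventions and problem sizes

Durations are whole hours; states are numeric vectors of ~600–730
compartments depending on `Tc`, `T_G0`, `T_N` and `N_LIMP`. Free-growth
fits use 500 h horizons with a 48 h burn-in; therapy runs use the 672 h
protocol horizon. The test suite exercises lattice runs on small meshes
(up to ~1000 GCs for construction, tens of GCs for multi-week dynamics)
and 5×5 sensitivity grids with 5-point sweeps — sizes chosen so the whole
suite documents the engine's behavior in well under a minute while the
same code paths scale to clinical volumes (a 100 cm³ well-mixed course
takes well under a second; a 1000-GC lattice course, minutes).
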