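---
title: "Methods: models, parameters and design choices in micellkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in micellkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micellkit)
```

micellkit asks one scientific question from three directions: do the shapes
of isothermal titration calorimetry (ITC) curves of gemini surfactants
encode structural transitions of their micelles?  The package provides
(i) sigmoid-model thermodynamics for enthalpograms, (ii) a coarse-grained
lattice Monte Carlo simulator of gemini self-assembly, and (iii) small-angle
scattering shape analysis, plus seeded generators of synthetic data so that
every stage is testable without experimental input.  This vignette explains
the models, their assumptions, the tunable parameters, and the design
decisions taken where the methodology was genuinely open.

## 1. Enthalpogram models and micellisation thermodynamics

A demicellisation titration yields the dilution enthalpy $\Delta H_d$
against the cumulative surfactant concentration $C_s$ (mol dm$^{-3}$).
Away from the critical micelle concentration (c.m.c) the curve follows two
straight baselines, and the step between them is described by a generalized
logistic (modified Boltzmann) model:

$$
\Delta H_d(C_s) \;=\; \Delta H_d^{(f)}(C_s) \;+\;
\frac{\Delta H_d^{(i)}(C_s) - \Delta H_d^{(f)}(C_s)}
     {\bigl[1 + e^{(C_s - C_{cmc})/\Delta C_s}\bigr]^{\,n}},
$$

with linear pre- and post-micellar baselines
$\Delta H_d^{(i)} = H_{ia} + H_{ib} C_s$ and
$\Delta H_d^{(f)} = H_{fa} + H_{fb} C_s$.  The low-concentration limit is
the initial baseline and the high-concentration limit the final baseline;
`eval_sigmoid()` implements exactly this form.  The printed form of this
model in the surfactant literature commonly carries a typographical bracket
ambiguity; the form above is the unique reading that satisfies both
baseline limits, and it is the one we fit.

Bell-shaped enthalpograms that appear in a window of intermediate
temperatures are treated as two conjoined steps over a shared
piecewise-linear baseline (`eval_double_sigmoid()`): the first step is
micellisation (centre near the c.m.c), the second the micelle shape
transformation (centre $C_{trans}$).  With the three baselines $L_1, L_2,
L_3$ the model is $L_3 + (L_2-L_3)\,g_2 + (L_1-L_2)\,g_1$, each $g$ a
generalized-logistic step, so each concentration regime reproduces its own
baseline.

**Locating the c.m.c.** The c.m.c is defined as the zero of
$\partial^2 \Delta H_d / \partial C_s^2$, found by a bracketing root finder
on a central finite-difference second derivative (step $10^{-3}$ of the
fitted width).  For a symmetric step ($n = 1$, flat baselines) this is the
fitted centre exactly; for $n \neq 1$ or sloped baselines the inflection
shifts, multiple roots can exist, and the root nearest the fitted centre is
returned.  For double-sigmoid fits the rule is applied within a window of a
few widths around each centre, yielding (c.m.c, $C_{trans}$).  The
implementation is tested against an independent dense-grid scan
($10^5$ points) to $10^{-6}$ mol dm$^{-3}$.

**Fitting.** `fit_enthalpogram()` uses Levenberg–Marquardt least squares
(minpack.lm), weighted by $1/\sigma^2$ when uncertainties are present.
Starting values are data-driven: baselines from end segments that exclude
the transition regions, centres from the extrema of a smoothed numerical
derivative, widths from the derivative-peak spread, exponents at 1.  A
deterministic multi-start (width rescaled by 3 and 1/3) recovers the rare
cases where the first start is degenerate.  Exponents are fitted per curve
(the alternative — sharing $n$ across temperatures — is not adopted because
nothing in our synthetic or reference material constrains it).  Fits whose
centres leave the data range are refused rather than reported.

**Thermodynamics.** For an ionic surfactant with counterion binding degree
$\beta$,

$$\Delta G_{mic} = (0.5 + \beta)\, R T \ln X_{cmc},\qquad
T\Delta S_{mic} = \Delta H_{mic} - \Delta G_{mic},$$

with $R = 8.314462618$ J mol$^{-1}$ K$^{-1}$.  The mole fraction uses the
molarity convention $X = C/(C + 55.345)$, the 55.345 mol dm$^{-3}$ being
water's molarity at 298.15 K; this constant is an argument
(`water_molarity`) and its temperature dependence is deliberately *not*
applied by default, because back-solving $\beta$ from published
$\Delta G$ values under this convention lands in the conductometrically
sensible range ($\beta \approx 0.56$–$0.61$).  $\beta$ itself is a
*required input* per temperature — it comes from conductivity experiments,
not from this package — and `solve_beta()` inverts the relation when only
$\Delta G$ is tabulated.  `micellisation_enthalpy()` evaluates the fitted
baselines at the inflection and returns their difference; for two-step fits
the adjacent baseline pair of each step is used, and the transition rows of
a thermodynamic table use $C_{trans}$ in place of the c.m.c in the same
relations.

A subtlety worth recording: when $T\Delta S$ and $\Delta S$ are recomputed
from *rounded* published ($\Delta H$, $\Delta G$) pairs, the input rounding
($\pm 0.005$ each) propagates to about $0.01$ kJ mol$^{-1}$ in $T\Delta S$
and up to $0.05$ J mol$^{-1}$ K$^{-1}$ in $\Delta S$; the acceptance tests
use exactly those propagated tolerances, not looser ones.

## 2. The lattice Monte Carlo model

A single gemini surfactant is coarse-grained as an A8-B2-A6-B2-A8
pentablock chain of $N = 26$ monomers: A monomers are CH$_2$-scale
tail/spacer segments (solvophobic), B monomers the two cationic heads (two
B per head, solvophilic).  Chains live on the face-centred cubic lattice
realized as the even-parity sites of an $L^3$ cubic grid ($L^3/2$ sites,
coordination $z = 12$, bond length $a\sqrt 2$), periodic in all directions;
unoccupied sites are solvent (S).  Bonds never stretch or break.

The energy model has a single scale: $\varepsilon_{AB} = \varepsilon_{AS} =
\varepsilon = \chi k T/(z-2)$ and all other pairs athermal.  The reduced
energy $E^* = E/\varepsilon$ is therefore the count of A–B plus A–S
nearest-neighbour contacts — a non-negative integer — and the reduced
temperature is $T^* = kT/\varepsilon$.  Contacts bonded within a chain are
counted too: this is the simplest reading of a pairwise contact energy, it
only shifts $E^*$ by a configuration-independent constant for intra-chain
A–B *bonded* pairs, and it cancels from all differences.  Because
$\varepsilon_{AB} = \varepsilon_{AS}$, B monomers are energetically
equivalent to solvent; the distinction matters for cluster analysis and
visualisation, not for the Hamiltonian.

**Moves.** The simple-motion algorithm displaces one monomer at a time to a
vacant nearest-neighbour site such that every bond to its chain neighbours
remains of length $a\sqrt 2$.  One Monte Carlo step (MCS) attempts to move
each of the $n_c N$ monomers once, in a fresh random permutation.  The
proposal (uniform monomer order, uniform choice among the 12 directions) is
symmetric, and acceptance is Metropolis, $\min(1, e^{-\Delta E^*/T^*})$, so
detailed balance holds; the test suite verifies this against an exhaustive
Boltzmann enumeration of a tetramer on a $4^3$ box ($\chi^2$ on thinned
samples).  Energy updates are incremental with an optional full-recount
cross-check that must agree *exactly*.

**Chain counts.** The published configuration sizes for $L = 78$ follow
from the monomer budget $\phi L^3/2$ divided by $N$; the fractional count
is rounded first to the nearest tenth of a chain and then to the nearest
integer (half to even).  This two-stage convention reproduces all ten
published counts (182 … 1825), which a single-stage nearest-integer
rounding does not (it gives 183 at $\phi = 0.02$); `chain_count()`
documents it.

**Parallel tempering.** Replicas at a ladder of reduced temperatures swap
configurations between adjacent pairs (alternating even/odd pairings every
`swap_every` MCS) with acceptance $\min(1, \exp[(1/T^*_i - 1/T^*_j)(E^*_i -
E^*_j)])$.  The production protocol is: athermal equilibration, PT
equilibration, then data collection with swapping off.  The full protocol
($78^3$, 72 replicas, $3{+}3{+}2 \times 10^6$ MCS) is exposed via
`mc_schedule("paper")` but is cluster-scale; all tests and examples use the
desk preset ($L = 30$, 12 replicas, $10^5$ MCS per stage), which the
methods below were sized for.

**Observables.** Per temperature we record the reduced energy per chain,
the specific heat from the fluctuation formula $C_V = (\langle E^{*2}\rangle
- \langle E^*\rangle^2)/(n_c T^{*2})$ (the normalization per chain is our
choice; no formula is standard), the mean-squared radius of gyration per
chain from unwrapped coordinates, and the aggregation number $N_a$ as the
*number-average* chains per cluster (chain-weighted average available),
with clusters defined by A–A nearest-neighbour contacts between different
chains.

**Phase labels.** Each cluster gets three deterministic diagnostics:
relative gyration-tensor asphericity (0 for a sphere, 1 for a rod), a
coarse skeleton branch-point count (cluster mapped to cells of edge 3, the
cell graph reduced to its minimum spanning tree, leaves pruned twice,
vertices of degree ≥ 3 counted), and percolation flags per axis (detected
when the breadth-first unwrapping of the cluster closes a loop with a
non-zero coordinate mismatch).  The label rules — elongated above
asphericity 0.4; percolating plus ≥ 2 branch points → channels (CH);
percolating with fewer → cylinder (C); otherwise the chain-weighted
elongated fraction below 0.1 → micellar (M), below 0.5 → M/R, else R/CH —
are package conventions, exposed in `phase_thresholds()` and validated on
constructed fixtures (compact blobs, a torus-spanning filament, a branched
two-junction network).  Transitions between these morphologies are not
sharp, so labels near boundaries should be read qualitatively.

**Temperature ladder for desk-scale phenomenology.** The default
`pt_ladder()` spans $T^* \in [1, 5]$, the range where published snapshots
of this system live.  At desk scale ($L = 30$, $\phi = 0.02$) the specific
heat of *this* model still rises at $T^* = 5$ — the critical micelle
temperature sits higher — so the phenomenology tests use a ladder on
$[1.5, 9]$, chosen once to bracket the transition.  That is a prerequisite
for observing the $C_V$ maximum, not a tuned threshold.

**Known desk-scale limitation.** In large systems, aggregates near the
transition (weak segregation) are bigger than deep in the segregated
regime.  At desk scale the opposite ordering appears: with tens of chains,
low-temperature coarsening merges most chains into a few clusters, so
$N_a$ at low $T^*$ exceeds $N_a$ near the $C_V$ peak.  We therefore do not
assert the weak/strong-segregation $N_a$ ordering in tests; reproducing it
requires production-scale boxes and schedules.

## 3. Small-angle scattering analysis

**Guinier.** In the low-$Q$ regime $I(Q) = I(0)\exp(-Q^2 R_g^2/3)$;
`guinier_fit()` performs a weighted linear regression of $\ln I$ on $Q^2$,
iterating the window to self-consistency under the cap $Q R_g \le 1.3$ (the
globular bound; configurable).  Window oscillations between two sizes are
resolved toward the tighter window.  The observed $(Q R_g)_{max}$ feeds
`shape_indicator()`: globular for $0.9 < x < 1.3$, elongated for $x < 0.8$,
and an explicit *indeterminate* class in the published gap
$0.8 \le x \le 0.9$ and above 1.3, rather than silent extrapolation.
Guinier analysis uses $\ln I$ vs $Q^2$ axes; the Kratky transform is
$Q^2 I(Q)$ vs $Q$ — the two are deliberately kept distinct.

**Kratky.** `kratky_transform()` is exact, with $\sigma \mapsto Q^2\sigma$;
`kratky_compactness()` flags a compact particle when the lightly smoothed
transform has a single interior maximum with a genuine fall-off (final
value < 80 % of the peak), which separates spheres from Debye-chain curves.

**PDDF.** `pddf_ift()` solves
$I(Q) = 4\pi \int_0^{D_{max}} p(r)\,\mathrm{sinc}(Qr)\,dr$ on a fixed
101-point $r$-grid with $p(0) = p(D_{max}) = 0$, second-derivative
smoothness regularization, optional non-negativity (the default; solved by
projected quasi-Newton on the augmented least-squares system), and
uncertainty weighting.  The regularization weight is dimensionless
(relative to the ratio of operator norms) and chosen by an L-curve
criterion — the corner of (log residual, log seminorm) over a geometric
grid — unless given explicitly.  $R_g^2 = \int r^2 p\,dr / (2\int p\,dr)$.
`estimate_dmax()` brackets the support end between the last grid point of
the contiguous support (biased short) and the zero of a linear fit to
$\sqrt{p}$ through the descending tail (biased long, since regularization
broadens the tail; $\sqrt p$ is asymptotically linear because $p$ vanishes
quadratically at $D_{max}$ for compact particles), and returns the bracket
midpoint.  On synthetic spheres this recovers $2R$ within one grid step at
noise levels up to 1 %.

**Units.** Curves carry their $Q$ unit (nm$^{-1}$ or Å$^{-1}$);
`convert_q_unit()` rescales exactly, and analyses are unit-safe (tested).

## 4. Synthetic data generators

`gen_itc_curve()` forward-evaluates a single- or double-step model on a
concentration grid spanning one fifth of the first centre to 2.5 times the
last centre (60 points by default — the density of a multi-day titration)
and adds homoscedastic Gaussian noise (default $\sigma$ = 0.05 kJ mol$^{-1}$,
a realistic power-compensation noise floor).  `gen_scattering_curve()`
builds a sphere form factor, optionally averaged over a lognormal size
distribution with volume-squared weighting, plus flat background, an
optional low-$Q$ power-law upturn emulating micelle aggregation, and
relative Gaussian noise on a log-spaced $Q$ grid over 0.063–5.8 nm$^{-1}$
(a typical pinhole-instrument window).  Both return the ground truth beside
the curve and are deterministic for a fixed seed without touching the
caller's RNG stream.

What these generators emulate is the *statistical structure* each analysis
assumes: sigmoid steps with linear baselines and additive noise; compact
polydisperse scatterers with background and aggregation upturn.  What they
do not emulate: injection-by-injection ITC heats and instrument baselines,
inter-particle structure factors, instrument resolution smearing, or
absolute intensity calibration.  Passing the round-trip tests therefore
demonstrates estimator correctness and calibration under the stated noise
models — not robustness to every artefact of real instruments.

## 5. Descriptor arithmetic

`equal_volume_radius()` is $(3V/4\pi)^{1/3}$; `micelle_density()` is
$N M / (N_A V)$ with IUPAC 2021 atomic masses and
$N_A = 6.02214076\times10^{23}$.  The 8-s-8 gemini dication formula is
C$_{20+s}$H$_{46+2s}$N$_2$ (two octyl tails, four N-methyls, an $s$-carbon
spacer).  Bromide counterions are excluded from the micelle mass by
default: that convention reproduces all seven published density columns to
within $6\times10^{-4}$ g cm$^{-3}$, while including them does not; a flag
restores them for sensitivity analysis.  The published descriptor table
packs seven micelle models under four surfactant headers; the
column-to-surfactant assignment bundled in `cosmo_micelle_descriptors()`
is the unique one consistent with the density check and is documented as
inferred.  `spacer_energy_increment()` returns the magnitude of the
least-squares slope of single-molecule SCF energy against spacer length.

## 6. Interfaces and problem sizes

The package's interface is its exported functions, this vignette, and
`scripts/acceptance.R`; being an analysis library in the style of the
established Bioconductor/CRAN modelling packages, it ships no shell
executable.  Delimited-text readers/writers cover enthalpograms
(`concentration_mol_dm3, dH_kJ_mol[, sigma]`), three-column scattering
files with a unit comment, and extended-XYZ snapshots.

Problem sizes used throughout the tests and the acceptance script — chosen
as the smallest sizes at which each property is statistically decisive:
ITC batteries of 200 fits at 60–80 points; the tetramer enumeration
(44,928 states) against $2\times10^6$ thinned sweeps; desk-preset assembly
runs at $L = 30$ with 12 replicas and $10^5$ MCS per stage at
$\phi = 0.02$, and 6-replica anneals at $\phi = 0.04$–$0.16$; scattering
batteries of 100 curves at 120 $Q$-points.  The production-scale protocol
is available unchanged through `mc_schedule("paper")`.
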