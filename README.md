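# micellkit

Tools for deciding whether the *shape* of an isothermal titration
calorimetry (ITC) curve encodes structural transitions of micellar
aggregates — built around cationic gemini surfactants
(alkanediyl-α,ω-bis(dimethylalkylammonium) bromides, "8-s-8"), but general
in its machinery.  The package is an analysis library for three audiences:
calorimetrists reducing enthalpograms to micellisation thermodynamics,
simulators studying coarse-grained surfactant self-assembly, and
scattering practitioners doing model-free shape analysis.

## What it computes

**ITC.** Enthalpograms ΔH_d(C_s) are fitted with a modified Boltzmann
(generalized-logistic) step between linear baselines,

    ΔH_d(C) = ΔH_f(C) + [ΔH_i(C) − ΔH_f(C)] / (1 + exp((C − C_cmc)/ΔC))^n,

or, for the bell-shaped curves seen in a window of temperatures, with two
conjoined steps whose centres are the c.m.c and the aggregate-transition
concentration C_trans.  The c.m.c is the zero of ∂²ΔH_d/∂C², the
micellisation enthalpy is the baseline difference at that point, and the
ionic-surfactant thermodynamics follow ΔG_mic = (0.5 + β)RT ln X_cmc and
TΔS = ΔH − ΔG, with the counterion binding degree β supplied per
temperature (or back-solved from a published ΔG).

**Lattice Monte Carlo.** A gemini molecule is an A8-B2-A6-B2-A8 pentablock
chain on an FCC lattice (coordination 12, bond length a√2) in explicit
solvent, with contact energies ε_AB = ε_AS = ε = χkT/(z−2) and all other
pairs athermal.  Single-monomer moves with Metropolis acceptance, parallel
tempering across a temperature ladder, and per-temperature observables:
energy per chain, fluctuation specific heat, mean-squared radius of
gyration, aggregation number, and a deterministic morphology label
(micellar M, M/R, R/CH, channels CH, cylinders C) from cluster asphericity,
skeleton branch points and percolation.

**Small-angle scattering.** Guinier fits (ln I vs Q² under a QR_g ≤ 1.3
window, iterated to self-consistency), the (QR_g)max shape indicator,
Kratky transforms with a compactness flag, a regularized indirect Fourier
transform to the pair distance distribution p(r) with non-negativity and
L-curve regularization, D_max estimation, and the sphere relation
R_g² = (3/5)R².

**Synthetic data.** Seeded generators for both data types, returning
ground truth beside each curve, so the full pipeline runs and is tested
with no external data.

## Worked example

Generate a noisy synthetic enthalpogram at 298.15 K, fit it, and reduce it
to thermodynamics with β = 0.61:

```r
library(micellkit)
truth <- c(h_ia = 5.2, h_ib = 3, h_fa = 1.1, h_fb = -2,
           cmc = 0.071, width = 0.005, n = 1)
g   <- gen_itc_curve(truth, noise_sd = 0.05, n_points = 60,
                     temperature = 298.15, seed = 7)
fit <- fit_enthalpogram(g$curve, steps = 1)
fit
#> ITC single-sigmoid fit (weighted residual sd 0.9609)
#>        estimate std_error
#> h_ia   5.130234  0.043068
#> h_ib   6.095125  1.380105
#> h_fa   1.085955  0.051900
#> h_fb  -1.879555  0.371190
#> cmc    0.072259  0.001402
#> width  0.005573  0.000365
#> n      1.211081  0.224652
thermo_from_fit(fit, beta = 0.61)
#>   process       temperature concentration beta  x        dg     dh     tds  ds
#> 1 micellisation 298.1       0.07139       0.61  0.001288 -18.31 -4.614 13.7 45.94
```

The fitted c.m.c (0.0723 ± 0.0014 mol dm⁻³) covers the generating value
0.071; ΔG < 0 and TΔS > 0 read as spontaneous, entropy-driven
micellisation; ΔH = −4.61 kJ/mol is the baseline gap at the inflection.

Scattering, same pattern — generate a polydisperse sphere curve with
R_g = 1.7 nm and recover shape and size model-free:

```r
g  <- gen_scattering_curve(radius_from_rg(1.7), i0 = 10,
                           poly_sigma = 0.08, noise = 0.02, seed = 3)
gf <- guinier_fit(g$curve)
gf
#> Guinier fit: Rg = 1.787 nm, I0 = 9.987, (Q Rg)max = 1.282, 65 points
shape_indicator(gf$qrg_max_observed)
#> [1] "globular"
pddf_ift(g$curve, d_max = 4.5)
#> PDDF: Dmax = 4.5, alpha = 3.16e-06, Rg(p) = 1.773, peak at r = 2.25
```

A desk-scale self-assembly run (about a minute):

```r
run <- run_assembly(30, phi = 0.02, temps = pt_ladder(1.5, 9, 12),
                    schedule = mc_schedule("desk"), seed = 1)
run$observables   # tstar, e_per_chain, cv, rg2, na, phase per temperature
```

The specific heat shows a single maximum (the critical micelle
temperature) and the energy per chain drops as micelles form on cooling.
`mc_schedule("paper")` exposes the production protocol (78³ box, 72
replicas, 8×10⁶ MCS) unchanged.

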