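# chiptwin

Digital twins of liver-on-chip drug depletion experiments: compartmental
modelling, intrinsic clearance estimation, sensitivity analysis and in
vitro–in vivo extrapolation (IVIVE) of human hepatic clearance.

## Why

Drug depletion measured in hepatic in vitro systems (liver-on-chips, 3D
spheroids, plated hepatocytes) is conventionally analysed with a
one-compartment model, `log C(t) = -(CL_c/V) t + log C0`, which lumps
permeation, partitioning and metabolism into one loss term and
systematically underpredicts human clearance. `chiptwin` maps the chip
hardware and the cell biology onto a three-compartment linear ODE model —
media (m), interstitium (i), intracellular (c):

```
V_m dC_m/dt = -k1 C_m + k2 C_i
V_i dC_i/dt =  k1 C_m - (k2 + k3) C_i + k4 C_c
V_c dC_c/dt =  k3 C_i - (k4 + CL_c) C_c
```

with `k1 = fu_media * P_endothelial * SA`, `k2 = k1 / K_int:med`,
`k3 = K_int:water * PA`, `k4 = K_cell:water * PA`. The rate constants
derive from compound physicochemistry (logP, MW, fraction unbound;
Poulin–Theil partitioning, a permeability QSPR, a logit-logP intracellular
binding model) and from chip presets encoding published hardware
(`cnbio`, `javelin`, `hurel1`, `hurel2`, …). The system is solved
analytically by eigendecomposition, `C(t) = X exp(Lt) X^-1 C0`, with a
stiff numerical fallback.

Intrinsic on-chip clearance `CL_c` (and the media/cell exchange area) is
estimated by Nelder–Mead multi-start minimisation of the relative residual
cost `sum(((obs - pred)/pred)^2)` plus an unbound intracellular-to-media
partitioning (Kp_uu) anchor. The fitted clearance scales to human through
hepatocellularity (`(CL_c/cells) * HC * LW * SF / fu_inc`) and the
well-stirred liver model `CL_H = Q_H fu_b CL_int / (Q_H + fu_b CL_int)`.
Local (one-at-a-time) and Sobol global sensitivity analyses, a seeded
synthetic-data generator with known ground truth, and a conventional
one-compartment comparator complete the workflow.

## Worked example

Fit a triplicate depletion series (here generated with known truth
`CL_c = 0.03 mL/min` and 10% lognormal noise) on the single-chamber
recirculating chip preset, then extrapolate to human:

```r
library(chiptwin)
chip <- load_chip_preset("cnbio")
drug <- compound_record("drugX", logp = 3.0, mw = 330, fu_media = 0.55,
                        ionisation = 1, rbp = 0.9)
ex  <- generate_depletion(chip, drug, cl_c = 0.03, noise = "lognormal",
                          cv = 0.1, replicates = 3, seed = 7)
fit <- fit_twin(ex$observed, chip, drug,
                options = ct_fit_options(kpuu_obs = ex$truth$kpuu, seed = 1))
fit
#> <estimation_result>
#>   CL_c = 0.03093 mL/min   SA = 0.8338 cm2   ssq = 0.0248
#>   Kp_uu pred = 1.115 (anchor: observed, obs = 1.11)   SF = 1
#>   converged: TRUE after 65 evaluations; CL_c CV across starts 8e-05

predict_human_clearance(fit$cl_c_hat, chip, drug, sf = fit$sf)
#>   compound cl_int_u_h_ml_min_kg cl_h_pred_ml_min_kg   method_tag
#> 1    drugX             317.9285            18.70693 digital_twin
```

The twin recovers the true clearance within 3% (`0.0309` vs `0.03`); the
final objective `0.0248` sits at the noise floor for 8 time points at 10%
CV. The human prediction (`18.7 mL/min/kg`) approaches the hepatic blood
flow bound of 20.7 mL/min/kg — a high-extraction compound. The
conventional analysis of the same data,

```r
fit_one_compartment(ex$observed, v_ml = chip$media_volume_ml)
#> conventional CL = 0.002865 mL/min (half-life 387 min)
```

reports a ten-fold lower clearance because media depletion is limited by
uptake across the endothelial barrier, not by metabolism — the
underprediction the digital twin removes.

Sensitivity of intracellular exposure to the nine model parameters:

```r
model <- ct_sensitivity_model(chip, drug, cl_c = 0.1)
local_sensitivity(model$fn, model$baseline)        # signed elasticities
sobol_sensitivity(model, n_base = 1024, seed = 1)  # first/total-order
```

A command-line wrapper over the same functions ships at
`system.file("cli", "chiptwin.R", package = "chiptwin")` with subcommands
`simulate`, `fit`, `sensitivity`, `ivive`, `generate`.

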