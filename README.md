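# wkcalib

Calibration of three-element Windkessel (3EWM) outlet boundary conditions
for reduced-order models of aortic blood flow.

Computational models of the thoracic aorta — healthy or dissected — need an
outlet boundary condition at every branch that stands in for the downstream
vasculature. The standard choice is the 3-element Windkessel: a
characteristic impedance *Z* in series with a parallel peripheral
resistance *R* and compliance *C*, relating branch pressure and flow by

    (1 + Z/R) Q + Z C dQ/dt = P/R + C dP/dt.

Population-generic parameter values mispredict individual flow splits,
drastically so in aortic dissection where the wide false lumen suggests low
resistance while the real physiology diverts flow into the true lumen and
supra-aortic branches. `wkcalib` makes the parameters patient-specific:

1. **Estimate** per-branch (Z, R, C) from 1D vessel geometry (centerline
   length, mean cross-sectional area), arterial pulse wave velocity, and
   brachial pressure targets: Z = ρc/A₀; R by distributing the net
   resistance R_T = P_mean/Q̄_in across branches so that
   1/R_T = Σ 1/(Z_j + R_j) holds exactly; C from the vessel compliance
   A₀l/(ρc²) scaled to the distal tree.
2. **Generate** a periodic pressure waveform per branch with a lumped RLC
   arterial-tree model (22 segments for the bundled dissected aorta, 9 for
   the healthy one) driven by the measured inlet flow waveform.
3. **Calibrate** each branch's (Z, R, C) by Nelder-Mead minimisation of the
   least-squares difference ε = Σᵢ (Q_WK(tᵢ) − Q_meas(tᵢ))² between the
   periodic Windkessel flow (backward-Euler 0D model, flow-out causality)
   and the measured branch flow waveform, e.g. plane-averaged 4D Flow-MRI
   series.
4. **Report** hemodynamic metrics: TAWSS, OSI, systolic/diastolic/pulse/
   mean pressure, perfusion fractions, and pulse wave velocity estimated
   from multi-plane waveforms by the intersecting-tangents foot method.

Every input can also be synthesised (seeded) so the full pipeline runs and
is tested without any patient data. See the methods vignette
(`vignettes/windkessel-calibration.Rmd`) for the model equations,
discretisation, and design choices.

## Worked example

The built-in demo emulates a dissection study end-to-end: "true"
peripheral Windkessels whose perfusion split differs from the geometric
expectation generate the measured branch waveforms; the pipeline then
estimates, simulates, and calibrates.

```r
library(wkcalib)
report <- run_full_pipeline(pipeline_config(seed = 1L))
print(report)
#> <pipeline_report> 6 branches, seed 1
#> estimated parameters (Z 1e7, R 1e9 Pa s m^-3, C 1e-10 m^3/Pa):
#>  branch Z_1e7 R_1e9 C_1e10
#>     RSA 11.50 2.400  0.909
#>    RCCA 34.60 7.230  0.126
#>    LCCA 13.90 2.890  0.548
#>     LSA 15.20 3.180  0.923
#>   DAoTL  3.71 0.775  4.780
#>   DAoFL  1.81 0.377  9.730
#> ...
#> error reduction (%):
#>  branch reduction_pct screen
#>     RSA      98.74976   pass
#>    RCCA      99.80889   pass
#>    LCCA      98.29665   pass
#>     LSA      98.93385   pass
#>   DAoTL      99.66318   pass
#>   DAoFL      99.60759   pass
```

The estimated impedance column reproduces the reference dissection values
(11.5, 34.6, 13.9, 15.2, 3.71, 1.81 ×10⁷ Pa s m⁻³); calibration then cuts
the flow-waveform error by 98–99.8% per branch and restores the perfusion
split that the geometric estimates mispredict:

```r
report$perfusion
#>  branch measured estimated calibrated
#>     RSA   0.1199    0.0807     0.1199
#>    RCCA   0.0498    0.0268     0.0498
#>    LCCA   0.0800    0.0670     0.0800
#>     LSA   0.0896    0.0608     0.0895
#>   DAoTL   0.4200    0.2501     0.4204
#>   DAoFL   0.2407    0.5146     0.2404
```

Here `measured` is the split of the truth-generated waveforms, `estimated`
the split produced by the geometry-based initial parameters, and
`calibrated` the split after fitting — the calibrated column recovers the
measured one to a fraction of a percentage point, while the estimates had
overloaded the false lumen (0.51 vs 0.24) at the true lumen's expense.

Individual stages are plain functions: `estimate_windkessel()`,
`simulate_network()`, `calibrate_branch()`, `perturbation_sensitivity()`,
`tawss()`, `osi()`, `pwv_from_planes()`, and the synthetic generators
`synth_inlet_flow()`, `synth_wk_truth_pair()`, `synth_plane_delays()`,
`synth_wss_series()`, `aorta_geometry()`. A thin command-line front end is
installed at `inst/cli/wkcalib` (subcommands `run`, `estimate`, `synth`,
`pwv`, ...).

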