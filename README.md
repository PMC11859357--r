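# nirglucosim

Simulation and analysis toolkit for studying **blood-flow interference in
near-infrared non-invasive glucose measurement** on human skin.

Glucose sensing by NIR diffuse reflectance reads absorbance changes of order
10⁻³ a.u. per mmol/L at 1000–1700 nm. Local blood-volume changes — postural,
thermal, emotional, or insulin-driven — alter the absorption and scattering
of the vascularised dermal layers and produce spectral changes of the same
order and similar shape, which is the central obstacle the pre-stimulation
(skin pre-heating) measurement strategy addresses. This package implements
the full computational chain needed to study that interference:

* **Skin optical model** — a seven-layer forearm skin (glass probe window,
  stratum corneum through subcutaneous tissue) with chromophore mixing
  μₐ = C_B μₐ,B + C_H₂O μₐ,H₂O + C_Other μₐ,Other per layer and the
  Mie power-law scattering rule μs′ ∝ r²ρₛ(2πr/λ)^0.37 (nₛ/n₀−1)^2.09.
  A blood-volume change ΔC_B/C_B in the two blood-net layers perturbs
  absorption linearly (Δμₐ = ΔC_B(μₐ,B − μₐ,Other)) and scattering
  identically (Δμs′/μs′ = ΔC_B/C_B).
* **Monte Carlo transport** (Rcpp) — MCML-style weighted photons,
  Henyey–Greenstein scattering, Fresnel boundaries, Russian roulette, ring
  detectors at source–detector separations 0.9–2.3 mm, per-photon seeded
  RNG streams (bit-reproducible), full energy audit, and a
  diffusion-dipole closed form (`farrell_reflectance`) as validation
  oracle.
* **Measurement algebra** — differential absorbance A_D = ln(I₁/I₂) with
  exact common-mode rejection, arm-elevation blood-spectrum extraction
  (A_D,blood = A_D0 − A_D1, three averaged repeats), and
  glucose-equivalent conversion of spectral changes.
* **OGTT statistics** — per-case OLS calibration of reference glucose on
  A_D(1550 nm) (Pearson R, RMSE in mmol/L) and cohort binning at
  R = 0.85/0.7/0.5.
* **Synthetic data** — seeded generators for chromophore/scattering
  fixtures, arm-elevation paired spectra, and OGTT cohorts with
  condition-dependent insulin-coupled blood-flow drift (suppressed under
  pre-stimulation).

## Worked example

Fit a synthetic pre-stimulated OGTT case and compare the two study
conditions:

```r
library(nirglucosim)

params <- ogtt_gen_params()           # study-condition defaults
case <- gen_ogtt_case(params, "pre_stimulated", seed = 4)
fit_case(case)
#> <case_fit> R=0.948, RMSE=0.38 mmol/L, slope=796.0 mmol/L per a.u. (n=25)

ctl <- gen_ogtt_case(params, "control", seed = 4)
fit_case(ctl)
#> <case_fit> R=0.520, RMSE=1.03 mmol/L, slope=317.8 mmol/L per a.u. (n=25)
```

The pre-stimulated case calibrates cleanly — R is the Pearson correlation
between A_D(1550 nm) and the meter reference, and the RMSE is the residual
of the linear calibration in mmol/L — while the same subject with
insulin-driven blood-flow drift loses half the correlation and nearly
triples the residual: the package-level restatement of why blood-flow
control matters.

Simulate the skin and perturb its blood volume:

```r
chrom <- gen_chromophore_fixture()
model <- default_skin_model()
res <- run_mc(model, chrom, source_spec(1550),
              config = mc_config(n_photons = 1e5, seed = 3))
res$detected$fraction        # detected fraction per ring, 0.9 -> 2.3 mm
#> [1] 0.00515 0.00323 0.00175 0.00120 0.000859

d <- blood_perturbation_spectrum(model, chrom, perturbation_spec(),
                                 config = mc_config(n_photons = 3e5, seed = 4))
```

The numbered scripts under `analysis/` run the complete chain (model
tables, transport validation, perturbation-spectrum decomposition,
arm-elevation blood spectra, OGTT cohort table) and write their outputs
under `results/`:

```sh
Rscript analysis/01_skin_model.R
# ... through ...
Rscript analysis/05_ogtt_cohorts.R
```

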