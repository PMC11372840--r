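# cosmoscreen

COSMO-SAC phase equilibria for amorphous solid dispersion (ASD) screening.

Formulating a poorly soluble drug as an amorphous dispersion in a polymer
carrier raises two thermodynamic questions: how much crystalline drug (API)
the amorphous polymer can dissolve (solid–liquid equilibrium, the
solubility curve), and whether the amorphous drug–polymer mixture itself
demixes (liquid–liquid equilibrium — amorphous–amorphous phase separation,
AAPS). `cosmoscreen` answers both predictively with the COSMO-SAC
activity-coefficient model, for formulation scientists who want to rank
polymer carriers before running DSC experiments.

## What it computes

The activity coefficient of component *i* in the binary mixture is

    ln γ_i = ln γ_i^res + ln γ_i^comb + ln γ_i^dsp

* **residual**: electrostatic misfit + hydrogen-bond segment interactions
  from three-class (NHB/OH/OT) σ-profiles, solved self-consistently;
* **combinatorial**: Staverman–Guggenheim (SG) or free-volume (FV,
  built on v^F = v − v^HC with Bondi hard-core volumes);
* **dispersion**: one-constant Margules, ln γ₁ = A·x₂².

Six configurations (`CS`, `CS-SG`, `CS-FV`, `CS-dsp`, `CS-dsp-SG`,
`CS-dsp-FV`) toggle the optional terms. On top of ln γ the package solves

* API solubility: `ln(x·γ_API) = −Δ_fus g / RT`, with Δ_fus g from the
  melting point, fusion enthalpy and the full (linear-in-T) heat-capacity
  integrals;
* AAPS binodals via the isoactivity condition
  `x_i^L1 γ_i^L1 = x_i^L2 γ_i^L2` (direct Newton and alternating-tangents
  solvers), spinodals, and full phase diagrams with UCST/LCST detection
  and metastability flags;
* polymer σ-profiles by the replication approach: quantum chemistry on a
  short oligomer, then bin-exact duplication of the central monomer
  unit(s) to the unit count implied by the polymer molar mass;
* screening statistics (AAD/AD/AARD vs experimental tables) and polymer
  rankings.

## Worked example

```r
library(cosmoscreen)

# an analytic binary system whose ln(gamma) reduces to Margules with A = 2.2
sys <- gen_analytic_system(A = 2.2, M = c(230, 25000), Tm = 450, dHfus = 30)
cfg <- config_from_name("CS-dsp-FV")

# drug solubility at 400 K
x400 <- solve_sle(sys, cfg, 400)
x_to_w(as.numeric(x400), 230, 25000)
#> x_API(400 K) = 0.050507, w_API = 0.000489

# amorphous-amorphous coexistence at 300 K
solve_lle(sys, cfg, 300)
#> tie-line x = (0.248530, 0.751470)

# a full diagram for a fixture with temperature-dependent A(T) = 720/T,
# whose critical condition A = 2 puts the UCST at exactly 360 K
cfgU <- model_config(combinatorial = "none", dispersion = TRUE,
                     dispersion_A = function(T) 720 / T)
build_phase_diagram(gen_analytic_system(0), cfgU, seq(330, 390, by = 5))
#> <phase_diagram> analytic-api / analytic-poly over 330.0-390.0 K
#>   SLE points: 13;  binodal tie-lines: 7;  AAPS: yes (metastable)
#>   UCST = 360.00 K

# rank carriers: ties within the band resolve in favor of no phase split
pred <- data.frame(polymer = c("PVPK12", "PVPVAc64", "PLGA50"),
                   w_api = c(0.52, 0.41, 0.40),
                   aaps = c(FALSE, FALSE, TRUE))
rank_polymers(pred, band = 0.02)
#>   rank  polymer w_api  aaps
#> 1    1   PVPK12  0.52 FALSE
#> 2    2 PVPVAc64  0.41 FALSE
#> 3    3   PLGA50  0.40  TRUE
```

The solubility line reads: at 400 K the model dissolves about 5 mol-% API
in this (deliberately unfavorable, A = 2.2) carrier, i.e. less than 0.05
weight-% because the polymer is 100× heavier. The diagram output flags an
AAPS region whose binodal lies entirely below the solubility curve — a
metastable demixing risk inside the supersaturated region.

For real systems, supply `.cosmo` files (or ready `.sigma` profiles), a
component property CSV (`name, M, v, v_hc, eps, dispersion_class, Tm,
dHfus, dCp_a, dCp_b, sigma_file`), and use the same calls — or the CLI:

```sh
exec/cosmoscreen sigma drug.cosmo --out drug.sigma
exec/cosmoscreen replicate trimer.cosmo spec.json --out polymer.sigma
exec/cosmoscreen diagram --config run.json
exec/cosmoscreen stats --exp exp.csv --pred pred.csv --out report/
```

Fusion constants of seven reference drugs (GSF, IBP, IMC, NIF, NPX, PCM,
SIM) ship in `table1_api()`.

## Scope

Binary, monodisperse drug–polymer systems; no quantum chemistry (σ-profiles
are inputs); no glass-transition overlays, kinetics, ternary systems or
polydispersity. See `vignettes/asd-screening.Rmd` for the model details,
numerical choices and limitations.
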