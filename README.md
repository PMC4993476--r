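# vasox

Simulation of blood vessel networks and oxygen transport in normal and
tumorous tissue, built to interpret diffuse optical measurements of
breast tissue. Optical mammography sees only two coarse numbers per
tissue volume — total hemoglobin concentration `c_Hb` and tissue blood
oxygen saturation `Y = c_HbO / c_Hb` — and vasox provides the microscopic
forward model that connects them to vascular architecture: it grows
synthetic arterio-venous networks on a lattice, remodels them under a
growing tumor spheroid (sprouting angiogenesis, vessel dilatation, wall
degeneration, collapse and regression, solid-stress compression), solves
network hemodynamics, and couples intravascular oxygen advection to
tissue diffusion with Michaelis–Menten consumption.

The core models, in the field's standard notation:

* Hill oxyhemoglobin binding `S(P) = P^n / (P^n + P_S50^n)` and blood
  oxygen content `c = alpha_p P + H c0 S(P)`;
* Poiseuille network flow `q = pi r^4 dp / (8 eta l)` with the
  Pries–Secomb in vivo apparent viscosity `eta_rel(r, H)`
  (Fahraeus–Lindqvist effect) and empirical phase separation of red
  blood cells at bifurcations, conserving `sum q_v = 0` and
  `sum H_v q_v = 0` at every node;
* axial intravascular transport `q dc/dx = -2 pi r gamma (P - P_t)`
  with the mass-transfer coefficient from a Nusselt fit
  `Nu(r) = 4.7 (1 - exp(-r/8 um))`, coupled to steady tissue diffusion
  `alpha_t D_t lap P_t - M(P_t) + Q = 0` with line sources along the
  vessels, solved to a fixed point (tolerance 0.1 mmHg);
* tissue observables: line density, relative blood volume, perfusion,
  `c_Hb`, `Y`, length-weighted saturation, oxygen extraction fraction,
  metabolic rate of oxygen consumption.

See `vignettes/methods.Rmd` for the models, parameter defaults and
numerical choices.

## Worked example

```r
library(vasox)

cfg <- sim_config(L = 2000, geometry = "RC5")   # 2 mm box, one A-V pair
net <- generate_network(cfg, seed = 42)          # t = 0 host vasculature
hs  <- solve_hemodynamics(net, cfg)              # pressures, flows, H
ox  <- solve_coupled(hs$net, hs$flow, cfg)       # coupled PO2 fields
observable_record(hs$net, hs$flow, ox, cfg)
```

On this 2 mm fixture the record prints (one row, abridged):

```
      L_D  rBV   c_Hb    Y S_mean   OEF  MRO2  rJ_in mean_P mean_Pt   rBF
  108.092 0.84 21.824 0.73  0.724 0.249 3.341 13.398  41.13  39.222 0.064
```

`L_D` is the vessel line density (mm^-2), `rBV` the vascular volume
fraction (%), `c_Hb` the tissue hemoglobin concentration (umol/l), `Y`
the RBC-volume-weighted blood oxygen saturation, `OEF` the oxygen
extraction fraction, `MRO2` the consumption rate (ulO2 ml^-1 min^-1) and
`rBF` the perfusion (ml g^-1 min^-1). The oxygenation numbers land on
the full-scale normal-tissue ensemble values; at this reduced domain
size the vascular trees are shallower than at full scale, so the
volume-weighted morphology (`rBV`, `c_Hb`) averages somewhat lower
across root geometries — the vignette discusses the scaling.

Tumor stages run through `run_tumor_growth()` and whole ensembles
through `cohort_plan()` / `run_cohort()`. A thin command-line front end
over the same functions is in `inst/cli/vasox-cli.R`.

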