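# stepkin

Crystal step-growth kinetics for molecular crystals: solubility
thermodynamics, step-velocity analysis, kink-density accounting from lattice
bond chains, 2D-nucleation habit prediction, and kinetic Monte Carlo
simulation of step edges and layer growth — built around anhydrous
theophylline Form II growing on its (200) face as the worked system.

## The scientific problem

When a molecular crystal grows classically — molecule by molecule, with new
layers born by 2D nucleation and spread by step flow — its kinetics are set
by the *kinks* along the steps: the sites where an attaching molecule gains
maximal lateral bonding. The equilibrium kink density of a step whose
column heights differ by at most one unit is

    n̄ₖ⁻¹ = 2 / [exp(ω/k_BT) + 2],

with ω the kink formation energy. Kink-rich steps (small ω) grow linearly
in the driving force, v = β(C/Cₑ − 1); kink-poor steps (large ω) must
generate kinks by 1D nucleation of new molecular rows and respond
superlinearly. On theophylline (200), π–π stacking chains run along [010]
and hydrogen-bond chains along [011], so the two step directions have very
different kink energies: moving an edge molecule to an intact segment of the
same edge (the Burton pathway) creates four kinks at the cost of two π–π
bonds for [001]-advancing steps, but only in-plane van der Waals contacts
for [010]-advancing steps. That anisotropy propagates upward: it decides
which crystal faces are fast, hence whether the habit is a ribbon or an
isometric sheet, and whether an etched groove heals perfectly or fills with
voids.

The package implements this chain quantitatively:

* **Thermodynamics** — van 't Hoff analysis of Cₑ(T)
  (∂lnCₑ/∂(1/T) = ΔH°/R on the molarity scale), ΔG° = RT ln Cₑ,
  equilibrium kink density, the 2D nucleation barrier
  ΔG*₂D = πΩhγ²/Δμ, and the face growth rate R = hv/l.
* **Crystallographic arithmetic** — a minimal CIF cell-block reader, cell
  volume, calculated density, formula weight, and the admissible AFM step
  heights (full cell |a| = 2.413 nm and glide-related half cell).
* **Step tracking** — bilinear profile extraction from height maps,
  change-point step detection with full/half classification, gated
  tracking, velocity fits, and a permutation test of the
  velocity-independence signature of direct incorporation.
* **Kinetic laws** — linear, free-exponent power, and fixed-quadratic
  v(C) fits with AICc selection and anisotropy-ratio curves.
* **Bond-chain accounting** — explicit Burton-pathway ledgers on the (200)
  lattice and calibration of bond schemes against the crystallization
  enthalpy (−½ the per-molecule bond sum).
* **Kinetic Monte Carlo** — rejection-free engines (Rcpp) for a restricted
  solid-on-solid step edge and an anisotropic lattice gas of the (200)
  layer, with detailed-balance audits, groove etching, and healing
  experiments.
* **Synthetic data** — seeded generators for every measured input
  (solubility series, AFM height maps, v(C) tables, absorbance series,
  groove fixtures), each with a ground-truth manifest.

## Worked example

```r
library(stepkin)

# 1. Solubility thermodynamics from synthetic Ce(T) measurements
pts <- gen_solubility(rel_noise = 0.03, seed = 1)
fit_vant_hoff(pts)
#> Van 't Hoff crystallization thermodynamics (molarity scale)
#>   dH0cryst = -20.86 +/- 0.26 kJ/mol
#>   dS0cryst = -35.30 +/- 0.90 J/mol/K
#>   dG0cryst(298.15 K) = -10.34 kJ/mol
#>   n = 4, R^2 = 0.99969

# 2. Kink density at the [010] kink energy of ~4 kJ/mol
equilibrium_kink_density(4e3, 298.15)
#> [1] 0.2848693        # below the entropic cap of ~0.3

# 3. Kink-energy anisotropy from the bond chains
scheme <- calibrate_scheme(-20.5e3, 4e3, E_pi = 10e3, E_hb = 2e3)
kink_creation_cost("[001]", scheme)$per_kink   # pi-pi limited
#> [1] 5000
kink_creation_cost("[010]", scheme)$per_kink   # vdW limited
#> [1] 4000   # calibrated to the 4 kJ/mol target

# 4. A growing step edge at C/Ce = 1.3
r <- simulate_step_edge(step_sim_config(edge_length = 128,
                                        omega_J_mol = 4e3,
                                        saturation_ratio = 1.3,
                                        n_events = 2e5, seed = 7))
r$velocity        # 0.086 sites/s, positive: growth
r$kink_density    # 0.31, near the equilibrium 0.285

# 5. Groove healing anisotropy (matched conditions and seed)
cfg <- surface_sim_config(64, 64, E_010_J_mol = 15e3, E_001_J_mol = 1e3,
                          E_011_J_mol = 2e3, dmu_J_mol = 1.5e3,
                          n_events = 1e4, seed = 1)
g <- gen_groove_fixture(64, 64, "[001]", width = 6)
heal(g$lattice, cfg)$healed_fraction
#> [1] 1              # [001]-elongated groove: perfect recovery
g2 <- gen_groove_fixture(64, 64, "[010]", width = 6)
heal(g2$lattice, cfg)$healed_fraction
#> [1] 0.083          # [010]-elongated groove: barely refills
```

The interpretation: the fitted ΔH°, ΔS° place ΔG°(298 K) near −10.3 kJ/mol,
matching RT ln Cₑ at the measured solubility; the kink density at ω ≈ 4
kJ/mol sits just under the entropic maximum, which is why [010] steps grow
linearly in concentration; and grooves whose walls advance in the
kink-rich [010] direction refill essentially completely while the
orthogonal orientation lags — the simulation realization of the observed
self-healing anisotropy.

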