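---
title: "Models and methods: step-growth kinetics, kink anisotropy, and lattice Monte Carlo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: step-growth kinetics, kink anisotropy, and lattice Monte Carlo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepkin)
```

This vignette is the package's account of the science it implements: the
models, their assumptions, the parameters that matter, the numerical
choices, and the limits of what the synthetic-data tests can show.

## The physical picture

A molecular crystal growing classically advances by steps — the edges of
unfinished molecular layers — that sweep across low-index faces. The
elementary growth site is the kink, where an arriving molecule gains the
maximal number of lateral bonds. Three quantities organize everything this
package computes:

* the dimensionless driving force $\Delta\mu/k_BT = \ln(C/C_e)$, from the
  solute concentration $C$ and the solubility $C_e$;
* the kink density $\bar n_k^{-1} = 2/[\exp(\omega/k_BT)+2]$ of a step in
  equilibrium, set by the kink formation energy $\omega$;
* the face growth rate $R = hv/l$ assembled from step height, step
  velocity, and step spacing.

The worked system is anhydrous theophylline Form II, whose (200) face grows
by steps of a full unit cell ($|a| = 2.413$ nm) that may split into
glide-related half-cell sub-steps (1.2065 nm). Two strong periodic bond
chains populate the (200) plane: pi–pi stacking along [010] and an H-bond
chain along the [011] diagonal. All user-facing energies are molar (J/mol)
with the gas constant $R$; conversions to per-molecule quantities are
internal.

## Solubility thermodynamics

`fit_vant_hoff()` regresses $\ln C_e$ on $1/T$; on the molarity scale with
unit activity coefficients $K_{cryst} = C_e^{-1}$, so the slope times the
gas constant is the crystallization enthalpy and the intercept carries the
entropy. The regression is unweighted by default; when measurement
standard deviations are present, `weighted = TRUE` uses
$1/\sigma^2_{\ln C_e}$ weights with $\sigma_{\ln C_e} \approx \sigma/C_e$.
The crystallization sign convention is used throughout (solution to
crystal; both $\Delta H^\circ$ and $\Delta S^\circ$ negative for this
system), and the molarity scale is the documented choice because it is the
one that makes $RT\ln C_e$ at the room-temperature solubility agree with
the $\Delta H^\circ - T\Delta S^\circ$ value.

Temperatures enter with an explicit unit tag (`as_kelvin(25.2, "C")`);
there is no autodetection.

## The 2D nucleation barrier and the habit model

The barrier for nucleating a new layer of thickness $h$ with edge free
energy $\gamma$ is $\Delta G^*_{2D} = \pi\Omega h\gamma^2/\Delta\mu$. The
formula is dimensionally consistent when $\gamma$ is an energy per unit
edge *area* (J/m²), and that is the package default; a per-unit-length
convention (J/m) is accepted via `gamma_unit = "per_length"` and converted
by dividing by $h$. This choice is documented prominently because the
source literature rarely states $\gamma$'s dimension.

`face_rate()` implements the birth-and-spread law
$R = A\,(\Delta\mu/k_BT)^{5/6}\exp[-\Delta G^*_{2D}/(3k_BT)]$ as the
default, with the mononuclear limit
$R = A\exp[-\Delta G^*_{2D}/k_BT]$ behind a flag: the morphology argument
itself constrains only $\Delta G^*_{2D}$, not the prefactor exponents, so
the growth law is an explicit package choice and both standard options are
exposed. `habit_curve()` classifies the aspect ratio $R_{(010)}/R_{(001)}$
against a configurable threshold (default 5 — purely a reporting
convention). When $\gamma_{(001)} > \gamma_{(010)}$ the aspect is a
monotone decreasing function of concentration, producing a ribbon-to-sheet
crossover; `demo_faces_synthetic()` ships a parameterization *labeled
synthetic* whose crossover falls between 14.5 and 20 mM at
$C_e = 13.5$ mM. Edge free energies are otherwise user inputs: the package
deliberately ships no measured $\gamma$.

## Step detection and velocity extraction

Height maps use 0-based, row-major pixel coordinates with row 0 at the top;
profile positions are physical nanometres. Step detection is deliberately
simple and fully documented: candidate change-points are first differences
exceeding `tol_nm`; adjacent candidates merge into one riser; the riser
height is the difference of flanking terrace medians (8 samples each side);
risers below `tol_nm` are dropped. Heights within `tol_nm` of the unit
height classify as `full`, within `tol_nm` of half the unit as `half`,
otherwise `unclassified`. The constraint `tol < unit/4` keeps the classes
disjoint. With pixel noise below `tol/3` flat profiles yield no false
positives, because single-pixel outliers produce risers whose
terrace-median height falls below `tol`.

Tracking follows the detection nearest the previous position inside a
gating window; losing the step, or finding two steps inside the gate, is a
fatal, frame-attributed error rather than a silent guess. Displacement is
positive toward the reference point, so growth gives positive velocities
and dissolution negative ones. Velocities are ordinary least-squares
slopes with their standard errors; the paper-style analysis never needed
anything fancier, and the estimator is exactly unbiased under the additive
Gaussian noise the generator produces.

The velocity-independence check — the signature of direct incorporation
from solution, as opposed to terrace adsorption plus surface diffusion —
is a permutation test (default $10^4$ permutations, seeded) of equality of
group means, chosen over a named parametric test because AFM experiments
yield few velocity estimates per group and no distributional guarantees.

## Kinetic laws for v(C)

All fits use $x = C/C_e - 1$ as the regressor, pinning $v(C_e) = 0$. Three
laws are offered: the first-order law $v = \beta x$ (kink density saturated
at its equilibrium value), the fixed quadratic $v = \beta x^2$
(kink density itself growing with driving force), and a free-exponent power
law $v = \beta x^m$, $m \ge 1$, fitted by Levenberg–Marquardt with
multi-start over $m \in \{1, 1.5, 2, 3\}$. The free exponent is an explicit
stand-in: the analytic $v(C)$ of 1D-row-nucleation models is
model-dependent, so the package reports both the free-exponent and
fixed-order fits rather than committing to an unpublished formula.
Model ranking uses AICc with ties broken toward the lower order; velocity
uncertainties act as inverse-variance weights when available and
non-degenerate.

The absorbance screen compares linear Beer–Lambert behavior against a
monomer–dimer model $A = \epsilon l\,[M + \eta(C-M)]$ with $M$ from the
mass balance $M + 2K M^2 = C$; a linear AICc winner yields the "monomeric"
verdict that rules out dimer-driven superlinearity.

## Bond-chain accounting

The (200) plane is modeled as a rectangular lattice: pi–pi along [010],
the H-bond chain on one [011] diagonal family, a pooled in-plane van der
Waals term along [001], and an out-of-plane vdW term that enters only the
enthalpy sum. `kink_creation_cost()` enumerates the Burton
extraction–reattachment move explicitly — nothing is hard-coded — and
returns a ledger of broken and restored bonds. For a [001]-advancing step
the H-bond and in-plane vdW cancel exactly (one broken, one restored each)
and the four kinks cost two pi–pi bonds; for a [010]-advancing step the
pi–pi and H-bond cancel and only in-plane vdW contacts are charged. The
half-sum of all per-molecule bonds, negated, is the crystallization
enthalpy; `calibrate_scheme()` solves the two-constraint system (target
$\omega_{[010]}$ and target $\Delta H^\circ$) and distributes the
underdetermined remainder uniformly across the out-of-plane slots. Bond
energies are never package defaults presented as measurements — the source
system's individual bond strengths are unquantified, so all numeric
schemes are user inputs or calibration outputs.

## The kinetic Monte Carlo engines

### Step edge

The step-edge model is *restricted* solid-on-solid — neighbor height
differences limited to $\{-1,0,+1\}$ — specifically because its
equilibrium kink density is exactly $2/[\exp(\omega/k_BT)+2]$; the
unrestricted model gives $2/[\exp(\omega/k_BT)+1]$ and is rejected.
Attachment occurs at every admissible site at rate $\nu\,C/C_e$ (direct
incorporation: the 3D supply field is abundant and position-independent);
detachment at $\nu\exp(-\Delta E/RT)$ with $\Delta E$ the bond-energy
change, so a kink pair costs $2\omega$. Detailed balance at $C/C_e = 1$ is
audited exhaustively over the nine local configurations before every run.
The contrasting surface-diffusion supply mode is deliberately not a second
engine; the velocity-independence test in the tracking module carries that
contrast.

Two boundary conditions are provided, and the distinction matters:

* **periodic** (default) for growth runs — no edge effects in the
  velocity;
* **free** for equilibrium kink statistics — on a periodic ring the
  winding constraint $\sum_i \Delta h_i = 0$ admits kinks only in $\pm$
  pairs, suppressing the density below the thermodynamic formula whenever
  $L e^{-\omega/RT}$ is not large, whereas the free edge's bond variables
  are exactly independent and realize the formula's ensemble at any $L$
  (verified in development by solving the full $3^{L-1}$-state generator
  exactly at small $L$).

Runs warm-start from the analytic bond distribution
$(z, 1, z)/(1+2z)$, $z = e^{-\omega/RT}$ — an exact stationary sample for
the free edge — so equilibrium measurements with zero burn-in are exactly
unbiased even in the rare-kink regime, where a flat start would need
prohibitively long trajectories to nucleate its equilibrium kink
population. Kink-density and velocity uncertainties come from batch means
(20 batches) with a first-order autocorrelation inflation
$\sqrt{(1+\rho_1)/(1-\rho_1)}$, because adjacent batches of a slowly mixing
chain are correlated and the naive batch SE understates the run-to-run
spread.

One numerical point deserves emphasis: the total event rate is recomputed
exactly at every step rather than maintained incrementally. Rates span
many orders of magnitude (up to $e^{2\omega/RT} \sim 10^7$ at the largest
kink energies studied), and incremental updates suffer catastrophic
cancellation that silently starves the rare low-rate moves at the tail of
the selection scan — in development this biased equilibrium kink densities
tens of percent low before the exact recomputation was adopted. The
surface engine resyncs its cached row sums every 1024 events for the same
reason.

At kink-rich conditions ($\omega \approx 4$ kJ/mol, the [010]-type step)
simulated $v(C)$ is first-order; at kink-poor conditions growth becomes
nucleation-limited and the fitted order rises. The package documents an
honest limitation here: for this move set the steady-state kink density on
a *growing* edge scales as $e^{-\omega/RT}$ independent of saturation
(creation $\propto (S-1)e^{-2\omega/RT}$ balancing pairwise annihilation),
so the asymptotic $v(C)$ is linear at every $\omega$ and the superlinear
fitted orders ($m \approx 1.3$ at $L = 64$, $\omega = 14$ kJ/mol) are
finite-size mononuclear behavior. Detecting them against the linear
alternative by information criteria requires event budgets far beyond
desk scale, and the corresponding acceptance check is expected to fail —
deliberately left in place rather than weakened, because it marks a real
gap between this model family and strongly second-order step kinetics. At
$\omega = 20$ kJ/mol growth is unmeasurably slow at any feasible budget
($v \sim 10^{-4}$ sites per unit time), so kinetic-regime simulations use
14 kJ/mol as the most kink-poor condition with measurable growth.

### Surface lattice gas

The (200) layer is a single-molecular-layer occupancy lattice with bonds
$E_{010}$ (pi–pi), $E_{001}$ (in-plane vdW) and $E_{011}$ (H-bond
diagonal), periodic boundaries, and flips as the only moves. The chemical
potential is referenced to bulk coexistence,
$\mu_{coex} = -(E_{010}+E_{001}+E_{011})$: attachment at
$\nu\exp[(\Delta\mu+\mu_{coex})/RT]$, detachment at
$\nu\exp(-\Sigma_{bonds}/RT)$. With this reference $\Delta\mu = 0$ is true
equilibrium (a half-filled interface shows no net growth), isolated
adatoms are strongly unstable, and growth at $\Delta\mu > 0$ proceeds by
step flow at kink sites — without it, any positive drive fills the lattice
by random deposition and all orientational contrast vanishes.

A step edge running along a bond direction has kinks that cost that
direction's bond: edges along [010] are smooth (pi–pi kinks), edges along
[001] rough (vdW kinks). Hence a groove elongated along [001] — whose
long walls advance in [010] — heals quickly and completely, while a groove
elongated along [010] heals by nucleation on its smooth walls and lags,
the in-plane realization of the observed self-healing anisotropy. Healing
is quantified as the refilled fraction of the etched footprint, plus the
number of 4-connected vacancy clusters ("voids") and an interface-length
roughness measure; the anisotropy is always asserted as a paired-seed
*ordering*, never as exact void geometry, because the experimental
evidence is morphological. The demonstration energies
($E_{010} = 15$, $E_{001} = 1$, $E_{011} = 2$, $\Delta\mu = 1.5$ kJ/mol,
$10^4$ events on a $64\times64$ lattice with a 6-site-wide groove) are a
synthetic parameterization chosen once to put the contrast at desk scale;
with them the [001]-elongated groove heals to completion while the
orthogonal one refills only partially. Grooves are one layer deep — the
model is a single layer, which suffices because the reported healing
contrast is in-plane.

Simulations work in lattice units; the physical mapping (site spacing $b$
or $c$, layer thickness $a/2$) is metadata only. Randomness comes from R's
RNG stream, so a config plus `set.seed`-visible seed reproduces event
sequences bit-identically.

## Synthetic data: what it emulates and what it does not

The generators emulate the *structure* of the study's measurements:
solubility-vs-temperature series at four incubation temperatures with
lognormal multiplicative noise; AFM-style frame series of advancing
terraces with full (2.413 nm) and half (1.2065 nm) risers, Gaussian pixel
noise, and optional uniform lateral drift; $v(C)$ tables from the kinetic
laws with additive Gaussian noise; absorbance series with optional
monomer–dimer speciation solved exactly by mass balance; and groove-etched
lattices. Default scales mimic the study (Ce ≈ 13.5 mM, velocities
0.1–10 nm/s, 3% relative solubility noise matching five-replicate error
bars). Every generator is a pure function of (parameters, seed) and emits
its ground truth.

What passing recovery tests does *not* show: the generators produce ideal
staircase topography — no tip convolution, no scanner drift
nonlinearity, no 2D nucleation on terraces, no step–step elastic
interactions — and the noise models are simple. Recovery of generator
parameters demonstrates that the analysis chain is correct and calibrated,
not that it is robust to every artifact of real AFM data.

## Problem sizes used by the checks

The packaged checks run at sizes chosen to make the statistics decisive on
a single CPU: equilibrium kink densities from free edges of 256 sites
(4 × 2×10⁵ events per kink energy) and, for the rare-kink 20 kJ/mol point,
24 stationary-start replicates of 4×10⁶ events on 64-site edges; kinetic
regimes from 20 seeded velocity curves per regime (10 saturation points,
1–2×10⁶ events each); recovery calibrations from 200 seeded replicates of
the closed-form generators; healing from 10 paired-seed runs of 10⁴ events.

## Known limitations

* Ideal-solution thermodynamics only; no activity models, no hydrate
  equilibria.
* The kinetic laws are phenomenological in the superlinear branch; the
  free exponent is a stand-in for unimplemented 1D-nucleation closed forms.
* The step-edge KMC's asymptotic $v(C)$ is linear at all kink energies
  (see above); it realizes the kink-density thermodynamics and the
  regime *contrast*, not strongly second-order kinetics.
* The lattice gas is a single layer with nearest/diagonal bonds and no
  solute depletion field, so healing instabilities driven by transport
  competition are outside its reach; the healing anisotropy it shows is
  purely kink-kinetic.
* Bond energies, edge free energies and kinetic prefactors are inputs or
  synthetic demonstrations, never predictions.
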