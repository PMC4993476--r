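---
title: "Models and numerics behind vasox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics behind vasox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

vasox simulates how the architecture of the blood vessel network in
normal and tumorous tissue shapes the tissue-level observables that
diffuse optical imaging of the breast can measure: total hemoglobin
concentration $c_{Hb}$, tissue blood oxygen saturation
$Y = c_{HbO}/c_{Hb}$, perfusion, and oxygen extraction. The pipeline has
four stages — synthetic host network generation, tumor vascular
remodeling, network hemodynamics, and coupled intravascular/tissue oxygen
transport — each exposed as ordinary R functions. This vignette explains
the models, the numerical choices, and the places where the design was
genuinely open.

## Synthetic host vasculature

Arterio-venous networks are grown on a face-centered-cubic lattice with
nearest-neighbour spacing $h_{gen} = 130\,\mu m$ inside a cubic domain
$(0, L)^3$. Nine root-node geometries (RC1–RC9) set where feeding
arterioles and draining venules touch the boundary, from face-filling
alternating patterns to a single arterio-venous pair. Trees grow by
random attachment of linear (one bond) and tripod (branching site)
elements to open terminal branches; overlap is forbidden, which keeps
trees acyclic and mutually disjoint. Open ends of opposite type are then
linked by capillaries ($r = 2.5\,\mu m$; arterial and venous terminal
segments are $2.5$ and $3.8\,\mu m$), and parent radii follow Murray's
law $r_c^3 = r_a^3 + r_b^3$ from the terminals up.

Two aspects of the generation algorithm are not fully specified by its
published description and were resolved here as follows.

* **Lattice geometry.** The generation lattice is stated to be
  face-centered cubic, but FCC nearest-neighbour bonds are face
  diagonals and cannot coincide with an axis-aligned 10 um fine grid, as
  a side remark elsewhere suggests. We follow the FCC statement: it is
  the explicit one, and a nearly filled FCC bond forest reproduces the
  reported line density of about $111\,mm^{-2}$ at $h_{gen}=130\,\mu m$,
  which a simple-cubic reading cannot (its ceiling is about
  $75\,mm^{-2}$). Remodeling consequently subdivides segments along
  their own axes rather than snapping to a cubic fine grid.
* **Capillary linking and refinement.** With capillaries restricted to
  exactly one lattice bond between two open ends, only about a fifth of
  open ends find a partner and the subsequent dead-end pruning erases
  half the network. We therefore let a capillary be a straight chord of
  at most two bond lengths ($\le 260\,\mu m$) from an arterial open end
  to the terminal region of a venule (a venous open end, or any venous
  node within two bonds of one, degree permitting, at most two links per
  end) — terminal venules collecting several capillary inflows is the
  physiological picture. Refinement then iterates a prune-and-regrow
  cycle: wall shear stress is computed on the capillary-connected
  network with uniform inlet hematocrit; capillary-connected terminals
  whose shear falls well below the median terminal shear retract
  (logistic probability in shear); unconnected dead-end chains collapse;
  and the trees regrow from every node with spare degree into the freed
  space. The cycle repeats until the capillary count is stable to 2%
  over five sweeps. The regrowth lets arterial and venous trees invade
  each other's territory, which is what produces the fine
  interdigitation and homogeneous capillary distribution of the final
  network; the shear set point is taken per sweep as the median terminal
  shear, so the process is self-scaling and needs no absolute stress
  parameter.

## Tumor growth and vascular remodeling

A spherical tumor of initial radius $250\,\mu m$ expands at
$2\,\mu m/h$ for $600\,h$ (final diameter about $2.9\,mm$). Remodeling
runs in 1 h steps on the fine-resolution network:

* **Sprouting.** Vessel nodes outside the tumor but within the
  growth-factor shell $R_{tum} < |x| < R_{tum} + R_g$
  ($R_g = 200\,\mu m$), with no branching point within $80\,\mu m$ of
  network path, spawn a $2.6\,\mu m$ sprout with probability
  $\Delta t / t_{sprout}$ ($t_{sprout} = 2\,h$). Sprout tips extend by
  one bond with the same probability, connect when they touch an
  existing vessel (connections that would create a degree-4 junction are
  rejected), and are removed with their chain if they have not become
  perfused within $t_{migr} = 50\,h$.
* **Circumferential growth.** Segments resident inside the tumor for at
  least $12\,h$ dilate. The published description gives the
  endothelial-cell picture (wall cells double every $t_{prol} = 144\,h$)
  but not the rate law; since the wall cell count is proportional to the
  radius, we integrate $dr/dt = \ln 2 \cdot r / t_{prol}$ — exponential
  growth with doubling time $t_{prol}$ — capped at
  $r^{max}$ (10 um; 14 um under compression, to keep mean capillary
  caliber comparable).
* **Wall degradation and collapse.** Tumor segments lose wall stability
  at $\Delta w = 0.05\,\mu m/h$; segments with $w = 0$ and wall shear
  stress below $f^{coll} = 0.25$ Pa are removed (probability 1), and the
  stranded dead ends are pruned back to the nearest junction that still
  connects to both an arterial and a venous root. The initial stability
  is tied to a radius-dependent healthy wall thickness,
  $w_0(r) = \min(r/2, 10\,\mu m)$; only the decay rate and the $w = 0$
  gate matter for the dynamics.
* **Compression (scenario CMPR).** All vessels acquire a compressed
  radius $\tilde r = \psi(|x|)\, r$ with $\psi = \xi_{cpr}$ deep inside
  the tumor, 1 outside, and a linear ramp of half-width $200\,\mu m$
  across the rim; $\xi_{cpr}$ is drawn once per run from U(0.5, 1). The
  compressed radius feeds all flow and oxygen computations, and is
  recomputed each step as the tumor expands.

Within each step the processes run in a fixed order (sprout initiation,
migration, dilatation, degradation, collapse) with randomized visit
order, followed by a hemodynamics update; the published description
leaves the order open and we found no sensitivity beyond the seed.

## Hemodynamics

Blood flow is Poiseuille flow on the graph: conductance
$g = \pi r^4 / (8 \eta l)$, mass conservation $\sum_v q_v = 0$ at every
interior node, Dirichlet pressures at the roots. The apparent viscosity
$\eta = \eta_{plasma}\,\eta_{rel}(r, H)$ uses the Pries–Secomb in vivo
parameterization (including the endothelial-surface-layer factor); the
classic in vitro law is available for comparison. Red cells partition
unevenly at diverging bifurcations (phase separation, Pries et al.):
the RBC flux fraction into a daughter is a logistic function of its
blood flow fraction, favoring the faster branch; merging nodes mix
conservatively, $\sum_v H_v q_v = 0$. Hematocrit is propagated in
decreasing-pressure order — a valid topological order, since potential
flow admits no flow-directed cycles — and pressure and hematocrit are
alternated with 0.5 under-relaxation until the largest hematocrit change
falls below $10^{-4}$.

The root pressure-radius curve is not fully determined by the published
model. We use saturating-exponential curves (arterial pressures rising
with root radius from a capillary plateau of 31 mmHg towards 89 mmHg,
venous falling towards 14 mmHg) whose radius scale (6 um) was calibrated
once, with `scripts/calibrate_bc.R`, so that the t = 0 ensemble
reproduces a normal-tissue perfusion near 0.053 ml g$^{-1}$ min$^{-1}$.

The sparse node systems are solved by a direct Cholesky factorization
(`Matrix`); at the problem sizes used here this is faster and more robust
than iterative solvers, and residuals are at machine precision.

## Oxygen transport

Blood carries dissolved and hemoglobin-bound oxygen,
$c = \alpha_p P + H c_0 S(P)$ with the Hill curve
$S(P) = P^n/(P^n + P_{S50}^n)$ ($n = 2.7$, $P_{S50} = 27$ mmHg). Along a
perfused segment the axial advection equation
$q\,dc/dx = -2\pi r\, j_{tv}$ with transvascular flux
$j_{tv} = \gamma (P - P_t)$ is integrated by implicit Euler in the
conservative form $q c(P_{k+1}) + \Delta x\, 2\pi r \gamma (P_{k+1} -
P_t) = q c(P_k)$, whose scalar step equation is monotone and solved by
safeguarded Newton/bisection to $10^{-9}$ mmHg. Integration points are
spaced about $h_v = 4\,\mu m$ with the last point on the segment end.
The mass-transfer coefficient comes from a Nusselt-number fit
$Nu(r) = 4.7\,(1 - e^{-r/8\,\mu m})$, $\gamma = Nu\, D_p \alpha_p / 2r$,
with the saturation dependence dropped (an effective $S \approx 0.9$).
At junctions the inflowing red cells equilibrate instantly to a common
partial pressure found by bisection on the oxygen mass balance. Arterial
inlets use $P^{BC}(r) = \min(55 + r, 100)$ mmHg.

Tissue oxygen obeys a steady diffusion equation with Michaelis–Menten
consumption $M(P) = M_0 P/(P + P_{M50})$ and line sources along the
vessels, discretized with trilinear (P1) elements on a regular grid of
spacing $h = 40\,\mu m$ with Neumann boundaries; mass lumping makes the
discrete operator the standard 7-point Laplacian. The exchange matrix is
diagonalized (tissue PO2 under a vessel taken from the owning grid site),
justified because the oxygen diffusion length (about
$300\,\mu m$ in normal tissue and $150\,\mu m$ in tumor at 40 mmHg) far
exceeds $h$. The vessel sweep and the linearized tissue solve alternate
until both fields change by less than $\epsilon = 0.1$ mmHg in the
maximum norm; the tissue systems (SPD, diagonal plus Laplacian) are
solved by a Jacobi-preconditioned conjugate gradient on the implicit
stencil, written in C++ for speed, as is the vessel sweep itself.
Unperfused segments equilibrate to the local tissue PO2 and contribute
their exchange weights but no axial transport, preserving the source
bookkeeping. Tumor versus normal consumption parameters switch by grid
site according to $|x - center| \le R_{tum}$.

Checks worth knowing about: the plasma-only single tube matches the
exponential closed form to better than 0.5%; junction mixing conserves
oxygen flux to $10^{-6}$; and the global balance (root influx minus
outflux versus total consumption) closes within 2% on adequately
supplied fixtures. On severely undersupplied fixtures (a single
capillary feeding a cubic millimetre) the fixed point sits at
near-zero tissue PO2, where the balance residual is dominated by the
linearization lag and the 0.1 mmHg stopping rule — a property of the
scheme, not a bug; the reported uncertainty of absolute PO2 values at
$h = 40\,\mu m$ is of order 10–20% anyway.

## Scenarios and observables

Three model variants: BASE (tumor $M_0$ four times normal, $P_{M50}$
halved), CMPR (additionally the radius compression above), METAB (tumor
$M_0$ drawn per run from a lognormal with median 0.0149 ml O2/ml/min and
$\sigma = 0.3$, i.e. a spread of about 32% of the median).

Observables follow the standard definitions: $c_{Hb} = MCHC \cdot
\sum_v \pi r_v^2 l_v H_v / |\Omega|$ (reported in umol/l using the
64,500 g/mol tetramer mass), $Y$ as the RBC-volume-weighted mean of the
per-segment length-averaged saturation, $\langle S \rangle$ as its
length-weighted counterpart, line density $L_D$, relative blood volume,
surface density, perfusion as root influx per volume (with the
sphere-surface flux construction and the
$rBF_{scaled} = rBF_{norm} \cdot rBF_{tum}/rBF_{sph,norm}$ rescaling for
the small tumor sphere), $MRO_2$ as the volume mean of $M(P_t)$,
$rJ_{in} = c_0 H \langle S_{in}\rangle_q\, rBF$, and
$OEF = MRO_2 / rJ_{in}$. Segments belong to a region if their midpoint
does; radial profiles use 100 um shells.

## Problem sizes, what the tests show, and limitations

The study conditions are an $8\,mm$ box and 90 networks (ten per root
geometry); that is a cluster-scale computation. The package defaults
keep those values, but the test suite and the bundled cohort profile run
at reduced scale: unit fixtures at $L \le 1.3\,mm$, the t = 0 ensemble
at $L = 2\,mm$ with one replicate of five geometry families, and the
tumor remodeling checks at $L = 1.3\,mm$ with a coarsened fine lattice
(130 um) and 120 h of growth. At this scale the generator reproduces the
full-scale line density closely (ensemble means 92–110 vs 111 mm$^{-2}$),
while volume-weighted quantities ($rBV$, $c_{Hb}$) are biased low by
roughly a quarter because the vascular trees are shallower — fewer
Murray generations mean thinner trunks. The ensemble tests therefore
check direction and magnitude against the full-scale reported values at
their reported standard deviations; a reduced-scale shortfall in
$c_{Hb}$ of a few umol/l is expected and documented rather than
compensated. Tumor-stage checks at desk scale are direction-of-effect
checks (tumor $c_{Hb}$ above normal; rim hematocrit depleted relative to
the core; compression lowering perfusion), not quantitative
reproductions of the 600 h ensembles. One full-scale effect does not
reproduce at desk scale at all: hematocrit enrichment of the tumor core
above the host baseline. That enrichment requires massive central
regression leaving few dilated trunks, and regression fires only where
wall shear drops below $f^{coll} = 0.25$ Pa — a regime created by the
dense 10 um angiogenic plexus diluting flow. On a coarsened fine lattice
the sparser plexus keeps core shear an order of magnitude above the
threshold, so the core gains rather than loses vessels and its
hematocrit stays near (slightly below) baseline. The corresponding
checks are kept at full strength and simply fail at desk scale.

The synthetic generator emulates lattice-grown interdigitating trees
with homogeneous capillary spacing. It does not emulate anatomical
feeding architectures, vessel tortuosity below the lattice constant,
non-stationary or chaotic capillary flow, heterogeneous (necrotic)
tumor tissue, or pinch-off-style occlusion — so passing tests show the
transport machinery is faithful to the stated model, not that the model
captures every feature of real breast tissue. Numerical limitations:
the uniform tissue grid resolves the perivascular PO2 decay only
coarsely at $h = 40\,\mu m$ (refining to 20 um shifts tumor means by a
few mmHg and $Y$ by about 0.02); adaptive meshes would help. The
hematocrit fixed point can fail its formal tolerance on networks with
marginally stable flow directions, in which case the best iterate is
used and flagged.
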