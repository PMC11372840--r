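---
title: "Screening drug-polymer compatibility with COSMO-SAC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening drug-polymer compatibility with COSMO-SAC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosmoscreen)
```

## The problem

Amorphous solid dispersions (ASD) stabilize a poorly water-soluble drug
(API) by dissolving it molecularly in a polymer carrier. Two thermodynamic
questions decide whether a given drug-polymer pair is viable:

1. **Solubility (SLE).** How much crystalline API dissolves in the amorphous
   polymer at a given temperature? Below the saturation curve the dispersion
   is supersaturated and will eventually recrystallize.
2. **Miscibility (LLE).** Does the amorphous mixture itself demix into two
   amorphous phases (amorphous-amorphous phase separation, AAPS)? A binodal
   inside the working composition range is a formulation risk even when
   solubility looks adequate.

`cosmoscreen` answers both questions predictively with the COSMO-SAC
activity-coefficient model, requiring only quantum-chemically derived
σ-profiles, a handful of pure-component properties, and — for the drug —
its fusion properties.

## The model

### Activity coefficients

The natural log of the activity coefficient of component $i$ in a binary
mixture is the sum of three contributions,

$$\ln\gamma_i = \ln\gamma_i^{res} + \ln\gamma_i^{comb} + \ln\gamma_i^{dsp},$$

and the six supported model configurations (`CS`, `CS-SG`, `CS-FV`,
`CS-dsp`, `CS-dsp-SG`, `CS-dsp-FV`) correspond to switching the
combinatorial term between *none*, Staverman-Guggenheim (SG) and
free-volume (FV), and toggling the dispersion term. The residual term is
always active.

**Residual.** The molecular surface is represented by a 51-bin histogram of
surface area versus screening charge density σ on the fixed grid
$[-0.025, 0.025]$ e/Å², split into three hydrogen-bond classes
(non-hydrogen-bonding NHB, hydroxyl OH, other OT). Segment activity
coefficients $\Gamma(\sigma)$ solve the self-consistent equation

$$\Gamma^s(\sigma_m)^{-1} = \sum_t \sum_n p^t(\sigma_n)\,\Gamma^t(\sigma_n)
\exp\!\left(-\frac{\Delta W(\sigma_m^s, \sigma_n^t)}{RT}\right),$$

with the exchange energy combining an electrostatic misfit term
$c_{ES}(T)(\sigma_m+\sigma_n)^2$ and a hydrogen-bonding term
$-c_{hb}(s,t)(\sigma_m-\sigma_n)^2$ active only for OH/OT segment pairs of
opposite charge sign. All universal constants (misfit constants, the three
HB coefficients, effective segment area 7.25 Å²) are the 2010 parameter set
of the open-source reference implementation, pinned in
`cosmosac_params("2010")` and never refit here.

**Combinatorial.** The SG term uses normalized cavity volume and area
($r_0 = 66.69$ ų, $q_0 = 79.53$ Ų, $z = 10$). The FV alternative
replaces volume fractions by free-volume fractions built from
$v^F_i = v_i - v^{HC}_i$, the liquid molar volume minus the hard-core
(Bondi/van der Waals) volume; this matters for polymers, whose packing
leaves a different free-volume percentage than small molecules. $v$ is
used at its 298 K value throughout — the FV ratio $v^F/v$, not $v$ itself,
carries the physics, and it is nearly temperature-independent when both
components expand similarly. `hardcore_volume()` implements the fast
atomic-increment estimate of the van der Waals volume (atomic volumes
minus 5.92 cm³/mol per bond and ring corrections).

**Dispersion.** A one-constant Margules form
$\ln\gamma_1^{dsp} = A x_2^2$ with
$A = w\,[(\epsilon_1+\epsilon_2)/2 - \sqrt{\epsilon_1\epsilon_2}]$,
$w = 0.27027$ (negative for a few molecule-class pairings such as
water with pure HB acceptors). Molecular $\epsilon$ values come either
from the component table or from atom-type contributions via
`dispersion_epsilon()`; the convention here is an atom-count-weighted mean
in which plain C–H hydrogens contribute zero but count in the denominator
(the source formulation does not pin this down; supplying $\epsilon$
directly side-steps the convention entirely).

### From COSMO files to σ-profiles

`parse_cosmo()` reads the Gaussian-dialect `.cosmo` segment file (one
fixed dialect; others are rejected rather than guessed). Each segment's raw
σ is then averaged over all segments with radius- and distance-dependent
weights (`average_charge_density()`, $r_{av} = 0.5$ Å, $f_{decay} = 3.57$),
and `build_profile()` apportions each segment's area linearly between its
two neighboring grid bins. Segments owned by hydrogen-bonding atoms are
split between their HB class and NHB by the switching function
$P^{HB}(\sigma) = 1 - \exp(-\sigma^2/2\sigma_0^2)$, $\sigma_0 = 0.007$
e/Å², so nearly neutral surface never counts as hydrogen bonding. Binning
conserves total area exactly.

### Polymers by replication

Quantum chemistry on a real macromolecule is unaffordable, so polymer
σ-profiles are built from a short capped oligomer: the binned contribution
of the central monomer unit(s) is added $n_{rep}$ more times so that the
virtual macromolecule carries the unit count implied by the reported molar
mass (`count_units()`; nearest-integer rounding, e.g.
$32{,}000 / 44.053 \approx 726.4 \rightarrow 726$ for poly(vinyl
alcohol)). For a trimer the central unit ends up present $N_{units}-2$
times beside the two edge units; for an alternating A-B-A-B tetramer each
central unit ends up $N_{type}-1$ times. Because binning is linear in the
segments, adding binned unit contributions is bin-exact equivalent to
duplicating the segments themselves — the test suite checks this against a
brute-force duplication oracle. Cavity area and volume accumulate with the
same additive rule (`replicate_area_volume()`) and feed the SG parameters.
Per-unit cavity volume is not observable from the segment file, so it
defaults to apportioning the oligomer volume by unit surface area
(overridable via `unit_volume`).

### Phase equilibria

* **SLE** (`solve_sle()`): root of
  $\ln x + \ln\gamma_{API}(x) + \Delta_{fus}g/RT = 0$ on $(10^{-12}, 1]$,
  with $\Delta_{fus}g$ from the melting point, enthalpy of fusion and the
  full heat-capacity integrals supporting the linear form $a + bT$
  (`delta_fus_g()`; exactly zero at $T_m$, so the melting point anchors
  the curve). The bracket scan mixes log-spaced and linear points; if
  several roots exist the largest (closest to ideal) wins, with a warning.
* **LLE** (`solve_lle()`): the miscibility gap is detected from the lower
  convex hull of a 200-point scan of $\Delta g_{mix}/RT$, then refined
  either by a damped Newton solve of the 2×2 isoactivity system (*direct*)
  or by the alternating-tangents iteration, which alternately re-tangents
  each phase using the exact derivative
  $dg/dx = \ln a_1 - \ln a_2$. Both must agree; the trivial root is
  rejected.
* **Spinodal** (`spinodal()`): sign changes of the numerically
  differentiated curvature of $\Delta g_{mix}/RT$.
* **Phase diagrams** (`build_phase_diagram()`): SLE over the grid, binodal
  traced by continuation in temperature (previous tie-line seeds the next
  solve), UCST/LCST bracketed to 0.01 K at the boundaries where the split
  vanishes — closed loops (UCST above LCST) fall out naturally as a split
  interval interior to the grid. The AAPS flag records any split; the
  metastability flag records a binodal lying entirely below the solubility
  curve (every tie-line supersaturated, $w \ge w_{sat}(T)$). The polymer
  never crystallizes: SLE is one-sided by design.

### Screening metrics

`deviations()` computes AAD, AD and AARD (in %) of predicted versus
experimental weight-fraction solubility. The sign convention is
$\Delta w = w^{calc} - w^{exp}$, chosen so that a *positive* AD means the
model overestimates solubility. AARD is reported but flagged unreliable
when experimental values approach zero, and it is never used for ranking.
`rank_polymers()` orders carriers by predicted solubility at a reference
temperature (default 298.15 K); AAPS decides only within a configurable
solubility band (default 0.02 in weight fraction) because the source
procedure combining the two signals is not fully public — the implemented
rule is an explicit approximation. Polymer families (e.g. several PVP
grades) can be collapsed to one entry via a grouping map (mean solubility,
AAPS if any member shows it).

## Numerical choices

* Segment iteration: successive substitution with 50 % damping, relative
  tolerance $10^{-8}$ (default), 500 iterations; non-convergence is an
  error carrying the last residual. Property tests tighten to $10^{-12}$ —
  below about $3\times10^{-13}$ the iteration hits machine-precision limit
  cycles, which is why the tight test tolerance is $10^{-12}$, not
  $10^{-13}$.
* All composition-independent quantities at a given temperature (exchange
  kernel, pure-component segment activities) are computed once per solver
  call and reused across the composition search.
* σ outside the grid clamps to the end bins with a warning; profile
  construction never loses area.
* Everything is plain double-precision base R; the 153-dimensional solves
  need no compiled code.

## What the synthetic fixtures do and do not establish

`gen_segment_set()` builds closed spherical cavities with positive areas
summing exactly to the header area, unit-structured atoms, and per-unit σ
offsets — enough structure to exercise parsing, averaging, binning and
replication, and deterministic per seed. `gen_analytic_system()` builds a
pair of components whose residual and combinatorial terms vanish
identically and whose dispersion constant is prescribed in closed form, so
every equilibrium solver can be checked against textbook symmetric-Margules
results (critical point at $A = 2$, $x = 1/2$; UCST at $A(T_{UCST}) = 2$
for $A = c/T$). Green tests on these fixtures establish the correctness of
the machinery — parsing, binning, replication algebra, solver convergence —
but **not** predictive accuracy for real drug-polymer systems, which
requires DFT-derived σ-profiles and experimental reference data outside the
scope of this package's test data. The packaged `table1_api()` constants
are real fusion properties of the seven reference drugs and can be combined
with user-supplied σ-profiles for real predictions.

## Design decisions that were genuinely open

* The averaging constants, HB switching width and grid are stated defaults
  of the 2010 parameter set; all are exposed rather than hard-coded.
* Copolymer unit counts round per type from the ratio-weighted mean
  monomer mass; the literature rounding rule for copolymers is not
  documented, so no copolymer count is asserted against published values.
* The dispersion parameter of a virtual macromolecule can be taken from
  the oligomer or recomputed from replicated atom counts; neither is
  asserted as canonical, and supplying `eps` directly is the recommended
  path.
* Both LLE branches near SLE crossings are reported with flags rather than
  suppressed; equilibrium-vs-metastable branch selection is left to the
  user.

## Limitations

Binary, monodisperse, amorphous systems only: no ternary/moisture systems,
no polydispersity, no branched polymers, no glass-transition overlays, no
kinetics. Temperature-independent liquid molar volumes. No quantum
chemistry: σ-profiles are inputs, not outputs. Tacticity enters only
through which oligomer file is supplied.
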