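---
title: "Models and methods behind azokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind azokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(azokin)
```

## The problem

Azobenzene-type photoswitches are driven to their bent *cis* form with
light and relax thermally back to the planar *trans* form. The thermal
half-life of the *cis* state is the property that decides whether a
photopharmacological or materials application works, and it is set by
the isomerization barrier. Two ground-state mechanisms compete: torsion
about the N=N bond (*rotation*, CNNC dihedral $\omega \approx 90^\circ$)
and in-plane opening of one CNN angle through linearity (*inversion*,
$\alpha$ or $\alpha' \approx 180^\circ$). Because the twisted geometry
brings the lowest triplet close to the ground state, the rotational
channel can additionally proceed through two singlet--triplet crossings
(near $\omega \approx 70^\circ$ and $105^\circ$), so a spin-forbidden,
intersystem-crossing (ISC) mediated rate must be computed alongside the
familiar Eyring rate. azokin implements this whole workflow on pluggable
potential-energy surfaces.

The rate theories are

$$k_\mathrm{Eyring} = \frac{k_B T}{h}\,
  e^{-\Delta G^\ddagger / RT}, \qquad
  k = k_\mathrm{ISC}\, e^{-\Delta G^X / RT},$$

where $\Delta G^X$ is the activation free energy at the minimum-energy
crossing point (MECP) and $k_\mathrm{ISC}$ replaces $k_BT/h$ with a
thermally averaged surface-hopping frequency. For comparison with
experiment an ISC rate is re-expressed as an *effective* activation free
energy $\Delta G_\mathrm{eff} = -RT\ln(k h / k_B T)$ and an effective
entropy $\Delta S_\mathrm{eff} = \Delta S^X + R \ln\!\big(k_\mathrm{ISC}
/ (k_B T/h)\big)$. Because $k_\mathrm{ISC} < k_BT/h$, effective
activation entropies are characteristically negative, which is what
standard transition-state treatments of azobenzene miss.

## The ISC prefactor

The seam-normal mode is treated as a classical translation with
effective mass $\mu$ (1 amu by the mass-weighted-coordinate convention).
For kinetic energy $E$ the single-passage Landau--Zener hopping
probability is

$$p(E) = 1 - \exp\!\left(-\frac{2\pi H_{SO}^2}{\hbar\,\Delta F}
  \sqrt{\frac{\mu}{2E}}\right),$$

with $H_{SO}$ the spin--orbit coupling (20 cm$^{-1}$ for azo compounds;
the $n\!-\!\pi^*$ character of the triplet makes it about twenty times
the planar-aromatic value) and $\Delta F$ the norm of the S0/T1
gradient difference at the crossing, measured per mass-weighted
angstrom. A double passage gives $P(E) = p + (1-p)p$, and

$$k_\mathrm{ISC} = \frac{k_B T}{h}\,\langle P\rangle, \qquad
  \langle P\rangle = \frac{1}{k_B T}\int_0^\infty P(E)\,
  e^{-E/k_BT}\,dE .$$

The average is evaluated by adaptive quadrature after substituting
$E = t^2 k_B T$, which removes the $E^{-1/2}$ endpoint behavior of the
exponent; the substitution is exact, and the integrand is then smooth
and bounded. In the weak-coupling limit $\langle P\rangle \propto
H_{SO}^2$, which reproduces the 400-fold enhancement between 1 and
20 cm$^{-1}$; in the strong-coupling limit $P \to 1$ and the prefactor
saturates at $k_BT/h$. The test suite cross-checks the quadrature
against a dense fixed-grid trapezoid rule (10^6 points up to
$40\,k_BT$). That comparison is made for couplings of 20--100 cm$^{-1}$
and $\Delta F$ of 5--30 kcal mol$^{-1}$ Å$^{-1}$ amu$^{-1/2}$: for much
weaker couplings the hopping probability saturates inside a sliver of
energies narrower than the fixed grid spacing, where a plain trapezoid
rule is structurally unable to resolve the integrand and the adaptive
quadrature is the accurate one. The spin--orbit ratio reported by the
acceptance script is evaluated at $\Delta F = 200$ in the same units, a
deliberately deep weak-coupling regime; the residual deviation from 400
(about 0.3%) is genuine Landau--Zener saturation at 20 cm$^{-1}$, not
integration error.

Unit conventions: all rate and thermochemistry code draws from one
CODATA constants table (`azo_constants`); 1 kcal = 4184 J;
$hcN_A$ = 28591 kcal nm mol$^{-1}$ for gap--wavelength conversion.
$\Delta S_\mathrm{eff}$ is evaluated at fixed temperature -- no
temperature derivative of $k_\mathrm{ISC}$ is included; with that
convention $\Delta G_\mathrm{eff} = \Delta H^X - T\Delta S_\mathrm{eff}$
exactly when $\Delta G^X = \Delta H^X - T\Delta S^X$.

## Fixture surfaces

Real applications would couple this machinery to an electronic-structure
code or a production neural potential. The package ships analytic
fixtures with the correct *topology* so that every algorithm can be
exercised and tested deterministically:

* `muller_brown()` -- the standard four-Gaussian 2-D benchmark (scaled
  by 0.1 so energies land on a kcal/mol-like scale), with a flat triplet
  500 kcal/mol above, so crossing detection correctly reports nothing.
* `model_azo_internal()` -- a 3-coordinate $(\omega, \alpha, \alpha')$
  two-state surface. Torsional profile
  $B\sin^2\omega + \Delta E_{ct}(1+\cos\omega)/2$ gated by
  $g(\alpha)g(\alpha')$ with $g = \sin^2\alpha/\sin^2\alpha_0$, harmonic
  bends in $\cos\alpha$, and a triplet gap
  $s(\cos\omega - \cos 70^\circ)(\cos\omega - \cos 105^\circ)$ that
  depends on $\omega$ only, so the seam crossings along any rotation
  path sit exactly at 70$^\circ$ and 105$^\circ$ and the crossing energy
  is automatically below the rotational saddle. The torsional parameter
  $B$ = 43.7 kcal/mol is calibrated so the relaxed rotational barrier
  from *cis* is 29.0 kcal/mol -- the azobenzene scale -- purely so
  downstream thermochemistry and rates run at realistic magnitudes; the
  calibration is locked by a regression test. The *cis*--*trans*
  electronic offset is 12 kcal/mol and the equilibrium CNN angle
  115$^\circ$.
* `toy_azo_cartesian(n_ring_atoms)` -- a full-dimensional Cartesian
  embedding (6--10 atoms: the CNNC core plus 1--3 cap atoms per side)
  with harmonic bonds and angles, a small 2-fold cap torsion so the
  conformer machinery has distinct wells to find, and the two-state
  internal model evaluated on the measured core coordinates with
  chain-rule gradients.

Two details of the Cartesian embedding deserve comment. First, all
$\omega$-dependent terms are gated by $\sin^4$ of the CNN angles (the
internal model uses $\sin^2$): $\omega$ ceases to exist when the core
passes through collinearity at the inversion transition state, and the
quartic gate keeps the Cartesian energy twice continuously
differentiable there, so Hessians at the inversion saddle are
well-defined. Second, a bend-anisotropy term
$k_a \sin^2\omega\,\sin^2\alpha\,\sin^2\alpha'\,(w(\alpha)+w(\alpha'))$,
windowed to near-collinear geometries, penalizes the out-of-plane bend
azimuth. Without it the collinear apex is an azimuthally degenerate
index-2 point (a "sombrero peak") and no valid inversion TS exists; with
it the in-plane bend is the single reaction coordinate, mirroring the
conjugation penalty that breaks this degeneracy in real azo dyes. The
product $\sin^2\omega \sin^2\alpha$ is the squared out-of-plane
displacement and hence smooth in Cartesian coordinates. After gating,
$B$ is recalibrated to 94.2 so the toy surface's relaxed rotational
barrier is 28.9 kcal/mol. The inversion barrier comes out at ~39.9
kcal/mol, comfortably above rotation, so the rotational channel wins on
the fixture as it does for unsubstituted azobenzene.

One known artifact: on the 3-coordinate internal surface the inversion
IRC cannot flip $\omega$ when passing through $\alpha = 180^\circ$
(the coordinates simply do not encode that geometry change), so both
inversion IRC endpoints land in the same basin and the endpoint filter
rejects the channel. This is a limitation of the reduced coordinate
system, not of the algorithms; the Cartesian embedding handles the
passage correctly and is the surface used for end-to-end tests.

## Stationary-point machinery

* **Minimization** -- BFGS with backtracking line search and
  Nocedal--Wright initial-Hessian rescaling, switching to a Newton
  polish (finite-difference Hessian, eigenvalue-clamped inverse confined
  to well-conditioned positive-curvature directions) once inside the
  quadratic basin. Rigid-body null modes and flat ridge directions are
  deliberately left untouched by the polish: scan structures may
  legitimately sit on symmetric ridges that eigenvector following
  resolves later. Convergence is max-component gradient below `tol`
  (default 1e-4).
* **Relaxed scans** -- one internal coordinate driven over a grid; the
  constraint is enforced by Newton correction along its analytic
  Cartesian gradient plus Lagrange projection of the optimizer gradient
  (coordinate resetting in internal coordinates), satisfied far tighter
  than the documented 0.1 degree. Each point warm-starts from the
  previous; the highest-energy point is the TS guess, ties breaking to
  the lower grid value.
* **Eigenvector following** -- partitioned rational-function (P-RFO)
  steps: maximize along one followed Hessian mode, minimize along the
  rest, trust radius adapted by the quadratic-model ratio. The followed
  mode is selected by overlap with the previous step's mode (or an
  explicit starting direction, e.g. the scan drive), which prevents
  channel hopping; soft modes carry only numerical noise and are
  frozen. A converged saddle must have exactly one imaginary frequency,
  otherwise the report is flagged with a reason code.
* **IRC** -- damped Euler steepest descent in mass-weighted
  coordinates (step halved whenever the energy would rise, giving
  monotonically non-increasing profiles by construction), after a
  mass-weighted displacement along the imaginary mode. Mass-weighted
  rather than plain Cartesian descent is a deliberate choice: it is the
  conventional definition of the reaction path and makes arc lengths
  comparable across systems.
* **Crossing seeds** -- every sign change of the S0/T1 gap between
  consecutive IRC points, located by linear interpolation in arc
  length.
* **MECP** -- gradient-projection composite steps,
  $(E_{S0}-E_{T1})\hat g_\mathrm{diff} + P\,\bar g$, accelerated by a
  Newton stage that treats the gap as a scalar constraint on the
  state-averaged surface. Convergence requires both the gap and the
  projected mean gradient below tolerance; the stored Hessian is the
  state average, which the seam-projected thermochemistry consumes.

## Conformers

TS-region conformers are generated with the four core atoms frozen in
place (the literal reading of a fixed-CNNC search; freezing the three
core internal coordinates instead would admit rigid reorientations of
the core and is noted as the alternative). Candidates come from
systematic 120-degree enumeration of each side's cap torsion plus
seeded Gaussian perturbation, each followed by constrained minimization;
duplicates are removed by superposed heavy-atom RMSD (0.25 angstrom,
Kabsch alignment), keeping the lower-energy member with ties broken by
discovery order, which makes the energy ordering a total order. A
metadynamics-based search would be the production-scale analog; the
enumeration + perturbation strategy was chosen because it is
deterministic and can be validated against an exhaustive torsion-grid
oracle. The five lowest conformers per mechanism feed eigenvector
following, capping the workload at 20 TS optimizations per compound.

## Thermochemistry

Harmonic frequencies come from the mass-weighted Hessian with six
rigid-body modes projected out (five for linear systems). Transition
states additionally have the imaginary mode projected before
thermochemistry; MECPs have the mass-weighted gradient-difference
direction -- the seam normal, which plays the role of the reaction
coordinate at a crossing -- projected, making $\Delta G^X$ structurally
parallel to $\Delta G^\ddagger$ (whether a full or seam-projected MECP
Hessian is the better convention is genuinely open; the projection is
our choice and is flagged in the summaries). Enthalpies and entropies
use the ideal-gas rigid-rotor--harmonic-oscillator expressions at 1 atm
with all symmetry numbers 1; the quasiharmonic treatment floors real
frequencies below 100 cm$^{-1}$ (configurable) to the cutoff *for the
entropy term only*, so a cutoff of zero recovers the pure harmonic
result exactly. For low-dimensional model surfaces the translational
and rotational terms are omitted and the summary flagged accordingly.
Conformer ensembles are aggregated as
$G_\mathrm{ens} = -RT \ln \sum_i e^{-G_i/RT}$ (log-sum-exp evaluated);
a full treatment would weight rotational symmetry and chirality, but
Boltzmann aggregation over distinct minima is the standard choice and
the one consistent with "energies, conformer ensembles and frequencies"
entering $\Delta G^X$.

## The neural potential

The miniature potential is an invariant/equivariant message-passing
model: initial per-atom features from the element identity; per
interaction, scalar messages weighted by a radial basis (Gaussians times
a cosine cutoff) and vector features assembled from pair unit vectors,
re-entering the scalar track through their squared norms; per-atom
readout summed per molecule, with three heads (S0 energy, T1 energy,
S0/S1 gap) over the shared trunk -- fully separate trunks would be the
other reading of "separate models", and sharing is our choice. Energies
are therefore exactly invariant under rotation, translation and
permutation, and forces (exact reverse-mode derivatives of the energy
with respect to coordinates; the backward pass is hand-written and
finite-difference verified) are exactly equivariant. Per-element
reference energies and a residual scale, fitted once by (ridge)
least squares on the training labels, normalize the targets.

Training minimizes energy + force + gap mean-squared errors with Adam
and a step-decayed learning rate. The gradient of the force loss with
respect to the weights is a second-order quantity; it is evaluated
through the directional-derivative identity
$\partial_\theta [\nabla_x E \cdot v] \approx
[\partial_\theta E(x + \epsilon v) - \partial_\theta E(x)]/\epsilon$
with the force residual $v$ held fixed, costing one extra forward and
backward pass per head instead of a full second-order graph. Gap labels
are attached only to samples near the planar *cis*/*trans* endpoints,
emulating a gap head trained on near-equilibrium structures only, where
a vertical-gap regression is meaningful; the pipeline likewise reports
absorption wavelengths only at optimized minima. The default loss
weights are energy:force:gap = 1:10:1; the reference configuration used
in the tests weights forces 4 instead, which on this fixture trades a
little force accuracy for noticeably better energies.

Ensembles are three members differing only by seed; the uncertainty is
the population standard deviation of the member S0 energies (energy
disagreement only -- force disagreement is not used). Active learning
mixes top-uncertainty selection, Boltzmann-weighted energy sampling and
uniform random sampling with no duplicates across slices.

Problem sizes are deliberately miniature and stated here as the
package's reference configuration: feature width 16, two interactions,
16 radial basis functions (the radial resolution matters most here --
the stiff bond terms vary on a scale of hundredths of an angstrom),
2,000 training geometries sampled by 0.03-angstrom Gaussian
displacement of relaxed frames along the rotation pathway (base frames
every 5 degrees), 60 epochs, 3 members. With that configuration the
held-out S0 energy error is below 0.8 kcal/mol and the rotational
barrier recomputed on the learned surface agrees with the analytic one
to a few tenths of a kcal/mol.

Optimizing geometries on a learned surface deserves care: outside the
sampled manifold a neural potential extrapolates freely and an
unconstrained saddle search will happily walk into a spurious hole.
The package therefore exposes an uncertainty-penalized variant of the
learned surface (energy plus kappa times the ensemble disagreement)
whose disagreement wall confines optimizations to the region the data
supports; structures are relaxed on the penalized surface and energies
are read off the plain ensemble mean. The barrier check brackets the
saddle with constrained relaxations at dihedrals around the top rather
than running an open-ended eigenvector-following search on the learned
surface. What these tests show is that the machinery is correct and
self-consistent; they do not show chemical accuracy on real azo
compounds, which would require electronic-structure labels, larger
models and far more data.

## Pipeline decisions

* Classification is rotation-first: $|\omega|$ within 25 degrees of 90
  is rotation (sign picks the channel), which groups inversion-assisted
  rotation with rotation; otherwise $\alpha$, then $\alpha'$, within 25
  degrees of 180 picks the inversion channels. The tolerances are our
  choice; only approximate landmark values are established.
* Order of operations is scan, then conformer search on the scan
  maximum, then eigenvector following on each kept conformer -- one of
  two defensible readings of "refine with a conformer search and
  eigenvector following"; refining first and searching afterwards would
  cost an extra refinement per mechanism for no observable difference
  on these fixtures.
* $\Delta G^\ddagger$ per mechanism uses the Boltzmann ensemble free
  energy over *all accepted* TS conformers of that channel (not just
  the single best), mirroring how the reactant side is treated.
* The ISC rate uses the cis-side MECP -- the crossing first encountered
  from the metastable isomer, near 70 degrees; the trans-side crossing
  is reported but not rate-determining. Inversion channels are
  spin-allowed throughout and get Eyring rates only.
* $\Delta S^X$ is referenced to the lowest-free-energy reactant
  conformer's entropy.
* Reports embed the configuration hash, seed and package version, and
  identical seeded runs serialize to byte-identical JSON.

## Degenerate inputs and numerical edges

Collinear cores make $\omega$ undefined; `measure_cnnc()` returns NaN
with a flag and classification falls through to the angles. Structures
with zero or several carbon-flanked azo linkages are rejected with the
count rather than guessed at. Filtering never throws: every rejection
carries a machine-readable reason (`imaginary_count`,
`ts_not_converged`, `irc_endpoints`, `mecp_not_converged`), and the
workflow records per-mechanism failures while still producing a report
when the minima converged.

## Limitations

The fixtures emulate the *topology* of azo photoswitch surfaces --
barrier placement, seam location, triplet dip, metastable *cis* -- not
their chemistry: there is no solvation, no substituent electronics, no
spin contamination, and the spin--orbit coupling is a constant. The
vertical-gap head is a scalar stand-in for an excited-state surface and
is only meaningful near minima. Tunneling, variational TS effects and
anharmonicity are out of scope. Half-lives from the toy surface are
illustrative magnitudes, not predictions.
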