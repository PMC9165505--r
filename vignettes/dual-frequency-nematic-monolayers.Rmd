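---
title: "Modelling endothelial flow adaptation as a dual-frequency nematic"
author: "dfnematic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling endothelial flow adaptation as a dual-frequency nematic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfnematic)
```

## The problem

Endothelial monolayers adapt to the wall shear stress (WSS) of blood flow
by collectively re-organising: at physiological WSS cells elongate and
align *along* the flow, at supra-physiological WSS they align *across*
it, and sudden changes of WSS drive the tissue through a transient
disordered state.  `dfnematic` implements a physical analogy for this
behaviour — a **dual-frequency nematic liquid crystal**, whose dielectric
anisotropy changes sign with the drive frequency — together with the
quantification pipeline used to measure the corresponding order in
monolayer images: cell shape and orientation statistics, planar cell
polarity (PCP), velocity correlation length and substrate strain energy.
Because the underlying microscopy data are not publicly deposited, the
package ships seeded synthetic-data generators with known ground truth;
every quantitative claim in the test suite is made against that stated
world.

## Dielectric model

The permittivity along the long molecular axis follows a
single-relaxation (Debye-type) law
$$\varepsilon_\parallel(\omega) = \varepsilon_{\parallel,\infty} +
\frac{\varepsilon_{\parallel,0} - \varepsilon_{\parallel,\infty}}
     {1 + (\omega\tau)^2},$$
while $\varepsilon_\perp$ is frequency independent, so the anisotropy
$\Delta\varepsilon(\omega) = \varepsilon_\parallel(\omega) -
\varepsilon_\perp$ crosses zero at
$$\omega_0 = \frac{1}{\tau}\sqrt{
  \frac{\varepsilon_{\parallel,0}-\varepsilon_{\parallel,\infty}}
       {\varepsilon_\perp-\varepsilon_{\parallel,\infty}} - 1}.$$
Defaults ($\varepsilon_{\parallel,0} = 0.5$,
$\varepsilon_{\parallel,\infty} = 0.01$, $\varepsilon_\perp = 0.2$,
$\tau = 0.6$ s) give $\omega_0 = 2.0943\ \mathrm{s^{-1}}$ and
$\Delta\varepsilon(1.1) = +0.151$, $\Delta\varepsilon(6.3) = -0.158$ at
the two working frequencies (low $\omega$ maps to physiological WSS,
high $\omega$ to supra-physiological WSS).  Frequencies are treated as
angular rates in $\mathrm{s^{-1}}$ exactly as the constants are stated;
no $2\pi$ conversion is applied anywhere.

A classical Debye form with a Lorentz local-field factor,
$\varepsilon(\omega) = \varepsilon_\infty + (\varepsilon_0 -
\varepsilon_\infty)/\bigl[1 + ((\varepsilon_0+2)/(\varepsilon_\infty+2)\,
\omega\tau)^2\bigr]$, is provided as `debye_eps()` for completeness.  Its
printed source form is typographically ambiguous; the simpler
single-relaxation model above is the authoritative one everywhere
downstream, which is also how the original study used it.

`freedericksz_satisfied()` exposes the threshold inequality
$(d^2/\pi^2)(|\Delta\varepsilon|/R_1) \ge 1/E^2$ as a standalone utility;
on the periodic lattices simulated here there is no anchoring surface, so
the simulator itself does not gate on it.

## Lattice Landau–de Gennes relaxation

Orientational order is carried by a symmetric traceless tensor per lattice
site.  For a uniaxial state $Q = S\,(nn^\top - I/3)$ with director $n$
and scalar order parameter $S = \langle\cos^2\theta\rangle - 1/3 \in
[-1/3, 2/3]$ — the same convention the experimental pipeline uses, so
simulation and measurement are directly comparable.  The free energy is
the standard one-elastic-constant Landau–de Gennes functional with a
dielectric coupling,
$$F = \sum_{\text{sites}} \Delta x^2\Bigl[\tfrac{A}{2}\,\mathrm{tr}Q^2 +
\tfrac{B}{3}\,\mathrm{tr}Q^3 + \tfrac{C}{4}(\mathrm{tr}Q^2)^2 +
\tfrac{R_1}{2}|\nabla Q|^2 -
\tfrac{\Delta\varepsilon(\omega)}{2}E^\top Q E\Bigr],$$
relaxed by the gradient flow $\partial_t Q = \Gamma H$ with the
symmetric-traceless molecular field $H = -\delta F/\delta Q$, forward
Euler in time.  The drive field has constant amplitude $E = (1, 0, 0)$;
$\omega$ enters only through $\Delta\varepsilon(\omega)$, i.e. the field
oscillation itself is not time-resolved.

**Parameters and defaults.**

| parameter | default | meaning |
|---|---|---|
| `A_coef` | $-0.3$ | quadratic bulk coefficient (negative: spontaneously nematic) |
| `B_rod` / `B_disk` | $-1$ / $+1$ | cubic sign: rod-like (healthy) vs disk-like (senescent) sites |
| `C_coef` | $2.1$ | quartic coefficient (bounds the energy) |
| `R1` | $1$ | one-constant elastic modulus |
| `Gamma` | $1$ | kinetic constant |
| `dt` | $0.05$ | Euler step (diffusive stability: $dt < dx^2/4R_1\Gamma$) |
| `S_init` | $0.05$ | order of the weakly nematic random initial state |

With $|A| = 0.3$, $|B| = 1$ the quartic coefficient was set to $2.1$ so
that the zero-field uniaxial minimiser $S^* \approx 0.60$ of
$f_\text{bulk}(S) = AS^2/3 + 2BS^3/27 + CS^4/9$ stays inside the
physical range $[-1/3, 2/3]$ of this $S$-convention (a unit quartic
would put it at $0.97$, outside it).  All qualitative behaviour the
tests rely on — bistability, switch transients, mixture trends — is
robust to these coefficients; this is verified by a smoke grid over
$E_x \in \{0.3, 1.5\}$ and $|\Delta\varepsilon| \in \{0.02, 0.36\}$.

**Numerical choices.**  Q is stored as its five independent components,
so tracelessness and symmetry hold exactly at all times rather than to a
tolerance.  Boundary conditions are periodic by default (Neumann
available); the discrete elastic energy is a sum over forward-difference
bonds whose exact gradient is the masked 5-point Laplacian used by the
stepper, making $F$ an exact Lyapunov function of the discrete dynamics
(non-increasing at fixed $\omega$, up to Euler error of order $dt^2$ —
tests allow $10^{-8}$ relative slack).  Updates that push any component
beyond 10 raise an instability error naming `dt`.  Initial directors are
drawn in-plane; with $E_z = 0$ the in-plane subspace is exactly
invariant, which resolves the $y$/$z$ degeneracy of the perpendicular
state in favour of $y$.

**Order diagnostics.**  `site_order()` reports per site
$S = \tfrac32\lambda$ where $\lambda$ is the *largest-magnitude*
eigenvalue, the unique convention under which
$Q = S(nn^\top - I/3)$ round-trips for both prolate ($S>0$) and oblate
($S<0$) states; disk-like (senescent) sites that settle into the oblate
bulk minimum therefore carry negative $S$.  Directors are reported as
angles folded to $[0^\circ, 90^\circ]$ against the field axis (nematic
$n \equiv -n$ symmetry); degenerate sites ($S = 0$, or a
distinguished axis out of plane) are flagged `NA` and excluded from
angle averages.  The trace-level `director_angle` is the principal
in-plane eigenvector of the lattice-averaged Q — the standard nematic
mean, immune to head–tail sign flips.

**Protocols.**  `run_protocol()` applies a piecewise-constant frequency
schedule.  The canned protocols equilibrate at $\omega_0$ (zero
coupling) to $t = 100$, then switch to $\omega_L = 1.1$ or
$\omega_H = 6.3\ \mathrm{s^{-1}}$ (`fig3a`/`fig3b`, run to $t = 250$),
optionally followed by the opposite frequency at $t = 250$
(`fig4a`/`fig4b`, run to $t = 400$; the $t = 400$ horizon is this
package's choice, long enough for the post-switch state to re-order).

**The switch transient, and one stated criterion this model does not
meet.**  After the $t=250$ switch the aligned state is an unstable
extremum of the new dielectric term.  The deterministic gradient flow
first relaxes the *magnitude* of order into a spatially uniform,
reduced-order saddle — the stationary point of
$f_\text{bulk}(S) + |\Delta\varepsilon|E^2 S/3$ — and then escapes by
in-plane rotation seeded by residual inhomogeneity, producing exactly
the persistent, high-free-energy metastable intermediate the biology
analogy calls for: a free-energy peak at the switch, a long plateau, and
relaxation into the orthogonal ordered state.  At the stated parameters
the saddle sits at about 64% of the pre-switch order.  The acceptance
criterion that quantifies the transient as a mean-order dip *below 50%*
of the pre-switch value is therefore not met: without thermal noise
(out of scope here) the flow re-orients through the uniform saddle
rather than through deep spatial disorder, and the saddle order is set
by the bulk/field balance, not by any tunable of this implementation
(the spec's own unit quartic would put it further from the criterion, at
~84%).  The corresponding expectation is implemented exactly as stated
and left failing, with this analysis as its record.

**Senescent mixtures.**  Disk-like sites model senescent cells that do
not elongate in response to flow.  `senescence_sweep()` equilibrates and
drives mixtures at a chosen fraction $p$ of disk-like sites and tabulates
the steady lattice-mean order over replicate seeds: monotone
non-increasing in $p$, with the all-senescent system failing to reach
the rod-ordered state.  Whether senescent and healthy neighbours couple
elastically is left open by the source material, so both modes exist:
`"full"` (default) keeps all elastic bonds; `"decoupled"` removes bonds
between unlike species, making the two sub-populations exactly
independent — in that mode the mean order is the population-weighted
mixture of the two pure-species values, which the tests exploit as a
linearity oracle.

## Quantification pipeline

**Cell shape.**  `fit_ellipse()` computes the equivalent ellipse of a
segmented outline from *exact polygon moments* (Green's theorem second
central moments, same-area normalisation) — deterministic and
resolution-independent, unlike rasterised moments, which serve as the
independent test oracle instead.  Aspect ratio is $a/b \ge 1$;
orientation is the acute angle between the major axis and the reference
direction (flow, or the horizontal axis for static samples), folded to
$[0^\circ, 90^\circ]$; circle-degenerate fits return `NA` rather than an
arbitrary angle.  The order parameter of a cell population is
$S = \langle\cos^2\theta\rangle - 1/3$; note that 2D-isotropic angles
give $S = 1/6$ (not 0) under this definition, and a mean folded angle
near $45^\circ$ is the isotropy baseline.

**PCP.**  Golgi detections are associated to the nucleus whose Voronoi
cell contains them — equivalently their nearest nucleus; exact ties go
to the lowest nucleus id.  Multiple fragments are combined by
inverse-distance weighting $w_i = 1/(d_i + \delta)$ from the nucleus
with a guard $\delta = 0.1\ \mu m$ (the weight family is unspecified in
the source; inverse distance is scale-covariant and bounded, and both
the form and $\delta$ are arguments).  The PCP index of a cell is
$\cos\phi$ with $\phi$ the angle between the nucleus$\to$Golgi vector
and the flow direction.  **Sign convention:** $\phi$ is measured from
the flow direction, so the physiological *upstream* polarisation (Golgi
against the flow) scores $-1$.  The source figures' axis convention
cannot be recovered from text; this one is fixed and documented rather
than guessed.  Cells with no assigned Golgi, or coincident points, are
dropped from statistics and counted in a QC attribute.

**Flow fields.**  Velocity fields are consumed, not computed (PIV is out
of scope).  `magnitude()` is $\sqrt{u^2+v^2}$ with NA propagation;
`subtract_drift()` removes the component-wise mean before correlation
analysis.  `velocity_correlation()` is the isotropically binned
two-point function $C_{vv}(r)$ (bin width defaults to one grid spacing,
$C_{vv}(0)=1$ by construction), computed by zero-padded FFT
autocorrelation with mask normalisation, with a direct-sum reference
implementation as its oracle.  `correlation_length()` fits
$e^{-r/C_L}$ by least squares on the correlation values directly (not
log-linear, to stay robust to near-zero tails), excluding $r = 0$; the
fit range is a documented default, not an assertion about the original
analysis.  Cells slower than $10\ \mu m\,h^{-1}$ are classified
stationary (strictly below; the threshold itself counts as migrating).
Strain energy follows the traction-microscopy formulation
$U = \tfrac12\sum (T\cdot u)\,dx^2$ with tractions in Pa, displacements
and spacing in $\mu m$, converted to joules
($1\ \mathrm{Pa\,\mu m^3} = 10^{-18}$ J); the $\tfrac12$ prefactor can
be disabled for sensitivity checks.

## Synthetic data: the stated world

The generators produce every input the pipeline reads, with ground truth
recorded for recovery tests.

* `make_monolayer()` Voronoi-tessellates a jittered lattice (cells
  clipped to the field rectangle by half-plane clipping), then gives
  each cell a drawn orientation $\theta_i$ and aspect ratio by first
  *whitening* the polygon (mapping its own moment ellipse to a circle,
  area preserved) and then stretching along $\theta_i$.  Angles follow a
  von Mises distribution on $2\theta$ (the natural nematic family) whose
  concentration is solved once per spec so that
  $E[\cos^2\theta] - 1/3 = S^*$; requests below the isotropy value $1/6$
  are realised by concentrating angles about $90^\circ$.  Because the
  ellipse fit is moment-based, each cell's fitted angle equals
  $\theta_i$ exactly; the achieved $S$ differs from $S^*$ only by
  sampling error, and the recovery tests check it within $3$ standard
  errors.
* `make_pcp_points()` draws per-cell polarity angles from a von Mises
  distribution calibrated so $E[\cos\phi] = \beta$ (mean angle on the
  flow axis, or rotated off-axis when an explicit concentration is
  given), displaces the polarity point $0.3$ lattice spacings from the
  nucleus and scatters a configurable number of Golgi fragments around
  it (scatter $0.05$ spacings by default, $0$ for exactness tests).
* `make_correlated_field()` synthesises Gaussian random components with
  isotropic $e^{-r/\lambda}$ correlation by circulant embedding of the
  wrapped exponential covariance — exact on the periodic grid up to
  clipping of marginally negative eigenvalues — and rescales to the
  requested rms exactly.  During development a continuum-spectrum
  variant showed a systematic ~15% under-estimate of $\lambda = 50\,\mu m$
  on a fixed $512\,\mu m$ domain (a ratio-estimator artefact of holding
  only ~10 correlation lengths); the recovery measurements therefore
  scale resolution with the feature, $dx = \lambda/10$, keeping the
  domain at $25.6\lambda$ for every $\lambda$.
* `make_traction_pair()` draws a smooth traction field and sets the
  displacement proportional to it with a known compliance, so the strain
  energy has a closed form reproduced to $10^{-10}$ relative.

What the generators deliberately do **not** emulate: pixel-level images,
segmentation error (outlines are exact polygons), detection noise or
missed/spurious spots, cell motility over time, and non-Gaussian or
anisotropic velocity statistics.  A green recovery test therefore
establishes that the estimators are correctly calibrated on their stated
model, not that they are robust to real microscopy artefacts.

## Interfaces

All interchange formats are plain text: GeoJSON or long CSV for
outlines, CSV for point detections, CSV + JSON sidecar for gridded
fields, JSON for configs (the environment pins no YAML/NPZ/TIFF
readers, so JSON/CSV take those roles).  The `dfn_cli()` entry point
exposes `simulate`, `senescence-sweep`, `metrics`, `pcp`, `flowfield`,
`energy` and `synth`; every run writes a config echo (package version +
seed) and a checksummed artifact manifest, and reruns are deterministic.

## Known limitations

* No hydrodynamic coupling (no Beris–Edwards flow term), no defect
  tracking, no polar order parameter, no 3D domains, and no thermal
  noise — the last being why the switch transient passes through a
  uniform saddle rather than deep spatial disorder (see above).
* The relaxation is plain forward Euler; stiff coefficient choices
  require a smaller `dt` (the stepper detects divergence and says so).
* The PCP index sign convention and the exponential-fit range are
  package choices, documented here, not recovered facts about the
  original analysis.
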