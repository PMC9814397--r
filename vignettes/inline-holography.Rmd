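---
title: "Point-source in-line holography: model, reconstruction and tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Point-source in-line holography: model, reconstruction and tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(holotrace)
```

## The imaging model

A lensless in-line holographic microscope is a point source (a pinhole of
roughly one wavelength diameter) at the origin, a pixelated sensor a
distance $d$ away on the optical axis, and nothing in between except the
sample. The source emits a spherical reference wave
$A_\mathrm{ref}(\boldsymbol\xi) = e^{ikR}/R$ with $R = |\boldsymbol\xi|$
and $k = 2\pi n_m/\lambda$. A small object at position $\mathbf{s}$
scatters a secondary spherical wave, and the sensor records the
interference intensity

$$I(\boldsymbol\xi) \;=\; \bigl|A_\mathrm{ref} + A_\mathrm{scat}\bigr|^2
 \;=\; |A_\mathrm{ref}|^2
 + 2\,\mathrm{Re}\!\left[A_\mathrm{ref}^* A_\mathrm{scat}\right]
 + |A_\mathrm{scat}|^2 .$$

The middle term is the hologram proper. Subtracting an object-free
*background* exposure (`contrast_hologram()`) removes the
$|A_\mathrm{ref}|^2$ pedestal and all static artefacts; subtracting
*consecutive frames* of a video (`difference_sequence()`) additionally
removes stationary objects, leaving only what moves.

`simulate_hologram()` implements the first-Born point-scatterer model:
each scatterer re-radiates the incident field times a complex amplitude,
and scattered fields superpose linearly (verified against independent
direct summation in the tests). Extended particles are cubic lattices of
point scatterers (`discretize_sphere()`) whose total strength is
independent of the lattice spacing. Mie resonances, polarization and
multiple scattering are outside the model. The paper-class instrument
gives no absolute scattering cross-sections, so the amplitude is a free
parameter; `scattering_amplitude()` converts a target *fringe visibility*
(the natural observable) into an amplitude for a given particle depth.
Sensor noise is additive Gaussian, clipped at zero, with the RNG seeded
explicitly — there is no camera-specific noise model to reproduce.

A sampling guard computes the finest fringe frequency each scatterer
produces at the sensor corners. Notably, the reference geometry itself
(5.5 µm pixels, $d = 5$ mm, NA 0.75) aliases at the sensor periphery for
any object deeper than a few hundred µm — high-NA in-line holography
relies on objects sitting close to the pinhole, where reference and
scattered waves subtend nearly equal angles and the fringes stay coarse.
The guard therefore warns rather than errors by default
(`on_undersampled = "warn"`).

## Kirchhoff–Helmholtz reconstruction

Numerical refocusing evaluates
$$K(\mathbf{r}) \;=\; \sum_{\boldsymbol\xi} I_c(\boldsymbol\xi)\,
  \exp\!\left(i k\,\frac{\boldsymbol\xi\cdot\mathbf{r}}{|\boldsymbol\xi|}\right)
  \Delta A$$
over all sensor pixels $\boldsymbol\xi = (X, Y, d)$, with $I_c$ the
contrast hologram. Two implementations are provided:

* `kh_reconstruct_direct()` — the literal $O(N^4)$ double sum. It is
  exact up to floating point and serves as the *oracle* for the fast
  path; it is only practical below ~$64^2$ pixels.
* `kh_reconstruct_fast()` — each sensor pixel contributes a plane-wave
  component at frequency $k\,(X,Y)/|\boldsymbol\xi|$; the transform is a
  type-1 non-uniform FFT, implemented by exponential-of-semicircle kernel
  gridding (C++), an oversampled FFT and kernel deconvolution. Because the
  output grid is integer-indexed, reducing the frequencies mod $2\pi$ is
  *exact*, so the fast path agrees with the direct sum to ~$10^{-11}$
  relative RMS (the test suite enforces $10^{-6}$) while scaling as
  $O(N^2\log N)$ — a $2048^2$ hologram reconstructs in seconds.

**Depth parameterization.** A stationary-phase analysis of this kernel
against the spherical-wave forward model shows that a scatterer at
physical source distance $z$ comes to focus at the kernel coordinate
$\zeta = dz/(d-z)$, which coincides with $z$ only in the usual operating
regime $z \ll d$. So that users think entirely in physical distances, the
package evaluates the kernel on the refocus surface parameterized by
$\zeta(z)$, with the lateral grid pitch $p\,\zeta/d$; the grid *index*
then corresponds to the object plane at the cone-beam magnified pixel
$p\,z/d$ (magnification $M = d/z$), which is what `ReconstructedField`
reports as `object_pixel`. At high NA a small residual aberration remains
(the kernel is the far-field limit of exact spherical back-propagation);
its focus bias grows roughly like $0.6\,z^2/d$ and is negligible in the
near-pinhole regime used throughout the tests. Reconstruction is on
planes (whether the reference instrument reconstructs on planes or
spheres is unstated; planes are the conventional choice).

`field_views()` returns the intensity $|K|^2$, amplitude $|K|$ and phase
$\arg K \in (-\pi, \pi]$ views; phase at exactly zero amplitude is
defined as 0.

## Autofocus

`autofocus()` scans a depth interval coarsely and then repeatedly shrinks
a bracketed grid around the running best depth (dividing the step by 8
per pass) until the grid is at least as fine as `refine_to`, 0.001 µm by
default. A bracketed grid was chosen over golden-section search because
the focus curve carries fine twin-image interference ripples on top of
the broad focus peak; grid refinement is insensitive to them and remains
fully deterministic.

The default focus metric is the *peak-to-mean* intensity ratio over the
central window (10% of each edge excluded). Raw peak intensity is
unusable as a global metric here for two reasons discovered during
development: the output window degenerates as $z \to 0$, piling all
energy into a few pixels, and the periodic fast transform wraps
defocused fringe energy onto the window boundary, producing spuriously
sharp edge maxima. Normalising by the mean and cropping the border
removes both failure modes. `"max_intensity"` and `"tenengrad"`
(gradient energy, better for extended objects) remain available.

## Optical metrology

With screen width $W$ and source–screen distance $d$, the package uses
the half-angle-sine numerical aperture
$$\mathrm{NA} = \frac{W/2}{\sqrt{(W/2)^2 + d^2}},$$
from which the diffraction limits follow:
lateral $\lambda_\mathrm{eff}/(2\,\mathrm{NA})$ and axial (depth)
$\lambda_\mathrm{eff}/(2\,\mathrm{NA}^2)$, with
$\lambda_\mathrm{eff} = \lambda/n_m$. For the reference geometry
(2048 × 5.5 µm, $d$ = 5 mm, 405 nm in air) these evaluate to NA 0.7478,
271 nm lateral and 362 nm depth — the figures the tests assert. An
alternative ratio convention $W/(2\sqrt{(d/2)^2 + d^2})$ circulates in
the literature of this instrument class; it exceeds 1 for wide screens
and is inconsistent with the resolution figures above, so it is exposed
(`formula = "ratio"`) but never used internally. In water immersion the
effective wavelength drops to ~305 nm and both limits shrink
accordingly.

Particle sizing uses intensity (or phase) crosscuts through a
reconstruction (`crosscut()`, bilinear interpolation, positions in µm)
and the full width at half maximum (`fwhm()`). The FWHM baseline defaults
to the profile minimum because reconstruction backgrounds are nonzero;
`"zero"` is available for model profiles. Phase crosscuts can be
unwrapped (`unwrap_phase()`) before conversion to optical path.

Quantitative phase relations: a thickness $t$ of index $n_\mathrm{obj}$
in a medium $n_m$ shifts the phase by
$\Delta\psi = (n_\mathrm{obj} - n_m)\,2\pi t/\lambda$ (signed, not
wrapped), equivalently an optical path difference
$\mathrm{OP} = \lambda\,\Delta\psi/(2\pi) = (n_\mathrm{obj}-n_m)\,t$.
`phase_shift()`, `optical_path()`, `refractive_index_difference()` and
`thickness_from_phase()` are exact mutual inverses (property-tested to
$10^{-12}$); the classic calibration case is glycerin drops
($n = 1.4729$) in type F immersion oil ($n = 1.518$) at 405 nm.

## 3D particle detection

`detect_particles()` works on a `reconstruct_volume()` stack and uses a
three-stage scheme chosen for focal stacks whose background is
*structured diffraction*, not plain noise:

1. each plane is standardized by its own median/MAD (the reconstruction
   scale varies strongly with depth, so stack-global statistics conflate
   scale with signal); voxels above `threshold_sigma` are candidates;
2. 3D local maxima are particle seeds; weaker maxima within 6 pixels
   laterally and 6 planes axially are suppressed (defocus sidelobes), and
   seeds below `seed_rel` (default 0.15) of the strongest seed are
   dropped — in the test fixtures genuine foci score thousands of robust
   sigma while ghosts from pair interference stay below ~1000;
3. each seed grows over voxels above half its peak score, so the
   reported bounding boxes are FWHM boxes, the same convention used for
   crosscut sizing.

The axial box size is reported as `length_um`: the optical axis is the
low-resolution direction, and particles closer together in $z$ than the
depth resolution merge into one axially elongated detection — the
mechanism the source instrument's operators invoke to explain why
measured lengths exceed widths. Note that even a *single* point image is
axially elongated here: the intrinsic axial/lateral FWHM ratio of an
undeconvolved coherent point image at NA 0.75 is ~3, so length/width
ratios should not be read as particle aspect ratios.

Detection works best in the shot-noise-limited regime the fixtures
emulate (fringe visibility ~0.25, noise ~10% of the reference level). In
*noiseless* weak-scatterer stacks the MAD floor collapses onto the
structured diffraction background and threshold rules misfire; this is a
known limitation, not a target regime.

## 4D trajectories

The trajectory workflow mirrors the instrument's: record at 16 fps
(62.5 ms frame interval), difference consecutive holograms, reconstruct
every difference frame at a fixed plane and sum the intensities
(`trajectory_map()`) — a moving particle draws a chain of spots, two
positions per difference frame. For quantitative work, per-frame
detections are linked by greedy nearest-neighbour assignment
(`link_tracks()`): candidate links are taken in order of increasing 3D
distance, links beyond `max_step` (default 10 object pixels) are
forbidden, unmatched detections start new tracks, and ties break towards
the lower detection index, so linking is deterministic. Gap closing is
deliberately absent. `track_kinematics()` reports path length, net
displacement, mean speed and straightness (net/path $\in [0,1]$).

## Synthetic experiments

`generate_fixture()` reproduces the study's bench conditions as
simulations: polystyrene-latex sphere runs with log-normal diameter
distributions whose modes fall in the 100–160 nm (`psl100`) and
150–300 nm (`psl200`) bands, a sub-100 nm metal-oxide mixture
(`mixed_oxide`, $n \approx 2.0$), a constant-velocity video
(`moving_psl`, 16 fps) and object-free backgrounds (`background_only`).
Defaults chosen once and documented here: reference intensity 100
arbitrary camera units, noise SD 10 (per-pixel fringe SNR of a few, the
regime real nanoparticle holograms occupy), fringe visibility 0.25,
particles in the middle of the depth range, everything deterministic
given `seed`. The generator emulates geometry, diffraction, motion and
additive sensor noise; it does **not** emulate shot noise statistics,
camera fixed-pattern noise, cuvette reflections, turbulence or
polydisperse refractive indices — so passing tests validate the
algorithms, not the instrument's full physics.

## Problem sizes and numerical choices

The test suite and the worked examples run on scaled geometries chosen
once for desktop runtimes:

* *analytic metrology* uses the full 2048² instrument geometry (nothing
  is simulated);
* *imaging round trips* use a 256² crop of the same 5.5 µm sensor with
  the source at $d = 625$ µm — this preserves NA = 0.7478 and therefore
  the 271/362 nm limits exactly, and objects sit 8–40 µm from the
  pinhole, the instrument's own high-magnification regime, where the
  fringes are Nyquist-clean across the sensor;
* *mid-volume depth scans* use a fine-pitch low-NA geometry (2.2 µm
  pixels, $d = 5$ mm) so that scatterers anywhere in (0.2 d, 0.8 d)
  stay Nyquist-sampled; recovery there is asserted against that
  geometry's own depth resolution.

Other fixed choices: NUFFT kernel width 12 with oversampling 2
(accuracy far beyond the $10^{-6}$ oracle bound); gridding corrections
memoised per grid size; volume scans at half the depth resolution
(axial Nyquist); Wiener deconvolution regularised at `nsr = 0.05`
against the simulated coherent PSF of the geometry, with the transfer
function normalised to unit RMS so background noise is not amplified;
atomic file writes (write-then-rename); all lengths in µm, with units
embedded in exported CSV headers.

## Known limitations

* The scattering model is first-Born; very strong scatterers make the
  $|A_\mathrm{scat}|^2$ term visible in contrast holograms (simulations
  remain valid, but detection statistics change regime).
* Twin images are suppressed only by background subtraction and
  deconvolution, as in the source instrument; no iterative phase
  retrieval.
* The high-NA kernel bias (~$0.6\,z^2/d$) limits absolute depth accuracy
  away from the near-pinhole regime.
* Detection assumes sparse scenes; overlapping defocus cones of dense
  ensembles will merge.
* Real-data statistics of the source study (dimension tables from
  ambient air and snow samples) depend on raw holograms that are not
  available, and are not reproduced numerically anywhere in this
  package.
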