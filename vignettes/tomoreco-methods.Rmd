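---
title: "Reconstruction methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstruction methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomoreco)
```

tomoreco reconstructs X-ray (or neutron) projection data by filtered back
projection, for parallel and cone beam, plain tomography, laminography
(tilted rotation axis) and per-projection trajectories such as helical CT,
together with the projection-space processing that real data need before
and after reconstruction: reference-field normalization, zinger and
scintillator-spot repair, propagation-based phase retrieval, sinogram ring
filtering and non-local means denoising. This vignette explains the models
behind each stage, the conventions and defaults the package fixes where the
underlying methods leave choices open, and what the synthetic validation
data do and do not establish about real measurements.

## Geometry model

All geometry lives in a right-handed frame attached to the center of the
reconstructed volume: the beam travels along $+y$, detector columns $u$ run
along $+x$, detector rows $v$ along $+z$, and at zero laminographic tilt the
rotation axis is $+z$. Source and detector positions are given in mm
relative to the volume center and may be supplied per projection, which is
all that is needed to describe helical scans or slow drifts of the setup.
The point where the rotation axis projects onto the detector is
`(axisU, axisV)`, in 0-based fractional pixel coordinates of pixel centers.

A volume point $p$ (sample frame, mm) observed at rotation angle $\theta$
sits at lab position $R_a(-\theta)\,p$, where $R_a$ is the rotation about
the (tilted, rolled) axis direction. The sign convention is fixed by the
parallel-beam projection formula

$$u = u_\mathrm{axis} + x\cos\theta + y\sin\theta,$$

in effective-pixel units. Orientation triples (detector, volume) are
intrinsic rotations about $x$, then $y$, then $z$; the axis direction is
$R_y(\mathrm{roll})\,R_x(\psi)\,\hat e_z$ with $\psi$ the laminographic
tilt. None of the sign or composition-order conventions are claimed to
match any particular instrument; they are documented here and on
`?ScanGeometry`, and `projectVoxel()` is the single authority both the
forward simulator and the back projector share, so the package is
self-consistent by construction. The cone-beam mapping is a central
projection from the source position; rays parallel to the detector plane
are flagged out-of-view (`NA`) rather than raising an error, and contribute
zero during back projection.

`magnification(ssd, sdd) = (ssd + sdd)/ssd` and
`effectivePixelSize(pitch, M) = pitch/M` reproduce the standard cone-beam
setup arithmetic; with a 700 mm source–sample and 1000 mm sample–detector
distance and a 200 µm detector:

```{r}
M <- magnification(700, 1000)
M
effectivePixelSize(200, M)
```

## Filtered back projection and the voxel-value contract

Detector rows are ramp-filtered in Fourier space (`ramlakFilter()`): rows
are symmetrically padded (edge replication or zeros) to a power of two,
multiplied by $|\nu|$ in cycles per sample, inverse transformed and
cropped. The DC gain is exactly zero, so a constant row filters to zero.
The default padding is generous — sixteen times the row length — because a
short ramp's sharp frequency cut leaves a broad negative halo around the
object: at 2x padding the background next to a reconstructed disk is biased
by about 1% of the interior value, at 16x by under 0.05%, and the interior
itself moves from about 1% to about 0.1% accuracy. FFTs are cheap at these
lengths, so accuracy wins; `padFactor` exposes the trade-off. An optional
cosine apodization window is available for noisy data.

Back projection is voxel-driven: each output voxel is mapped through
`projectVoxel()` for every projection and the filtered projection is
sampled bilinearly (linearly for single-row sinograms), with samples
outside the detector contributing zero. The angular weight is
$\Delta\theta$ for a 180° parallel scan and $\Delta\theta/2$ for full-turn
scans, where every ray is measured twice. Working throughout in
detector-pixel units makes the reconstruction quantitative in the sense
that, for monochromatic absorption input (the negative log of flat-field
corrected data), voxel values equal $\Delta x\,\mu$ — the effective pixel
size times the linear attenuation coefficient. The suite verifies this on
an analytic cylinder (256 angles, $128^2$ grid) to 3%; the measured error
is an order of magnitude smaller.

Cone-beam data follow the Feldkamp–Davis–Kress scheme: each projection is
pre-weighted by $\mathrm{ssd}/\sqrt{\mathrm{ssd}^2 + u'^2 + v'^2}$ before
filtering, and each voxel contribution by $(\mathrm{ssd}/U)^2$, with $U$
the source-to-voxel distance component along the beam axis. With the source
moved to $10^6\times$ the object size the cone result reproduces the
parallel one to well under 1% relative RMS, which ties the two code paths
together.

For per-projection trajectories (helical scans) a voxel is only inside the
cone for part of the scan, so a global angular weight misnormalizes voxels
near the ends of their illumination window and biases centroids. In that
case the package normalizes per voxel by $\pi/N_\mathrm{seen}$, the count
of projections whose rays actually hit the detector for that voxel; this
reduces exactly to the global weight when every voxel sees every
projection. Exact helical redundancy weighting (e.g. Tam–Danielsson
windowing) is out of scope; the approximation is validated by recovering
the centroids of three spheres in a three-turn helical scan to about 0.01
voxels.

Only the detector rows that the requested output region can project onto
are read and filtered, which keeps region-limited reconstructions cheap;
the row window is derived from the projected region corners with a safety
margin of one pixel.

## Parameter sweeps and axis estimation

Because the center of rotation is the one parameter that is always unknown,
`sweepReconstruct()` reconstructs the same horizontal slice repeatedly
while walking one geometry parameter (`axis_u`, `lamino_tilt`, `axis_roll`
or `angle_offset`); `sliceMetric()` (standard deviation inside the
inscribed circle) is maximal at the correct value because misplacing the
axis smears edges and loses contrast. `estimateAxis()` offers this
sweep-based search (coarse-to-fine, 4-fold refinement per level) and a
faster pair-correlation method: the projection nearest 0° is
cross-correlated with the horizontally mirrored projection nearest 180°,
and the correlation peak, refined by a parabolic fit, gives the axis as
$(W - 1 + s)/2$. On the synthetic disk both land within far less than half
a pixel of the ground truth; 180°-scans without an exact opposed frame use
the nearest available one and tolerate one angular step of mismatch.

## Phase retrieval

Both retrievals act on flat-corrected transmission frames, are linear,
shift-invariant Fourier-domain filters, and pad frames by half their size
with edge replication before filtering to suppress wrap-around.

**Transport of intensity** (single-material): divide the frame's spectrum
by $1 + \frac{\lambda}{4\pi}\frac{\delta}{\beta}(d_x k_x^2 + d_y k_y^2)$,
with independent $x$/$y$ distances for anisotropic setups. With
`output = "thickness"` the result becomes the projected thickness
$-\ln(\cdot)/\mu$ in meters ($\mu = 4\pi\beta/\lambda$); with
`output = "phase"` it is additionally scaled by $-2\pi\delta/\lambda$, so a
parallel-beam FBP of the phase maps yields voxels equal to the unitless
per-pixel phase shift $-2\pi\Delta x\,\delta/\lambda$ (verified on a
cylinder to 3%). At zero distance the kernel is identically one and the
thickness output reduces exactly to Beer–Lambert inversion. When
$\delta/\beta$ is unknown, a direct regularization $\alpha$ may replace it
($1/\alpha$ takes its place in the kernel).

**Contrast transfer function** (pure-phase weak object): the forward model
for the intensity contrast at distance $d$ is
$\hat C_d(k) = 2\sin\!\big(\lambda d |k|^2/(4\pi)\big)\,\hat\varphi(k)$.
The inverse is a per-frequency Tikhonov least squares over the $K$
distances, $\hat\varphi = \overline{s\hat C} / (\overline{s^2} + \alpha)$,
averaged (not summed) over distances so that $\alpha$ keeps its meaning for
any $K$ and repeating a distance reproduces the single-distance result
exactly. The DC value and the CTF zeros are set by the regularization;
$\alpha = 0$ is refused because the kernel always vanishes at DC. The
original's richer CTF family is deliberately reduced to pure-phase CTF plus
homogeneous TIE. The round-trip test uses a compact band-limited weak-phase
object because pad-and-crop is only an approximate inverse for signals
that reach the frame edge; on a $96^2$ frame the retrieval error is about
0.5% relative RMS at $\alpha = 10^{-3}$.

## Ring and spot artifacts

Narrow rings are vertical stripes in a sinogram. A signal constant along
the angle axis lives entirely on the zero angular-frequency row of the 2D
spectrum, so `suppressStripesFourier()` multiplies each coefficient by
$1 - \exp(-j_a^2/2\sigma^2)$ ($j_a$ the angular-frequency index), sparing
the detector-frequency-zero column (which carries the per-angle mean, hence
the sinogram mean is preserved to machine precision) and, via
`maxWidthPx`, all detector frequencies below $1/\mathrm{maxWidth}$, which
bounds how wide a stripe the filter may touch. The default
$\sigma = 2$ angular-frequency bins removes a constructed column-constant
offset essentially completely (column-mean variance reduction over 99%).
Two caveats are documented deliberately: the notch also removes the
angle-constant part of the *true* sinogram at the affected detector
frequencies — this is exactly why ring-filtered reconstructions are no
longer quantitative — so ring-suppression metrics in the suite compare
against the filtered-clean baseline; and the Gaussian notch is only
approximately idempotent on generic data (the mask is not 0/1), while on
stripe-dominated sinograms a second application changes nothing beyond
$10^{-6}$ of the data range.

Broad rings come from scintillator defects. They are handled in projection
space: `findLargeSpots()` thresholds the absolute deviation from the frame
median (seeds), grows 8-connected regions over a lower threshold, and
`inpaintHorizontal()` replaces masked runs by linear interpolation between
the nearest valid neighbors in each row (constant extension at row edges;
fully masked rows borrow the nearest repaired row). Inpainting is exact on
affine rows and idempotent. Connectivity (8 vs 4) and the
median-referenced thresholds are package choices, fixed and tested rather
than inherited from any instrument convention.

Zingers — isolated extreme pixels from direct hits on the sensor — are
repaired by `removeOutliers()`: a pixel is replaced by its
$(2r+1)^2$-neighborhood median only if it deviates from that median by more
than a threshold, in the chosen direction (bright, dark, both), with
reflected borders. Pixels within the threshold are bit-identical to the
input.

## Non-local means

`nlmDenoise()` implements patch-based averaging: neighbor weights are
$\exp(-\max(D^2 - 2\sigma_\mathrm{noise}^2, 0)/h^2)$ with $D^2$ the patch
mean squared difference; the center pixel receives the maximum neighbor
weight (a standard choice the original literature leaves open, as is the
reflect-padding boundary policy). The reference implementation loops over
pixels in compiled code; the fast variant computes, per search-window
shift, all patch distances at once from cumulative sums (integral images)
of the shifted squared-difference image. Both operate on the same
reflect-padded domain and agree to within summation-order rounding
($\sim 10^{-14}$ of the data range), far inside the $10^{-5}$ equivalence
the suite asserts. Outputs are convex combinations of window values, and on
a Poisson-noisy phantom slice the RMSE against ground truth strictly
decreases.

## Half-acquisition stitching

A 0–360° scan with the axis near the detector edge holds two 0–180° scans
of complementary halves. `stitchHalfAcquisition()` mirrors the opposed
frame, aligns its axis column with the direct one (sampling at fractional
positions by linear interpolation when $2\,u_\mathrm{axis}$ is not an
integer), and blends the overlap with a linear ramp — the blend shape is a
package choice. Output width is $\mathrm{round}(2(u_\mathrm{axis}+0.5))$.
When the axis sits at integer-plus-half alignment the stitched stack equals
an analytic wide-detector scan to machine precision; fractional axes incur
only interpolation blur. Overlaps above 80% of the frame width warn (the
axis is then too central for the trick to gain much field of view).

## Synthetic data: what it covers and what it does not

The validation loop closes without any external data. Phantoms are unions
of ellipsoids and z-capped elliptic cylinders with per-primitive
attenuation $\mu$ (mm$^{-1}$) and optional $\delta$;
`analyticProject()` computes exact chord lengths by quadratic intersection
in the primitive frame along exactly the rays `projectVoxel()` defines, for
any beam and axis geometry, and an independent ray-marching projector
(`sampleProject()`) cross-validates the chords to 0.5%.
`toTransmission()`, `makeFlatsDarks()` and `injectArtifacts()` add counts
scaling, Poisson noise, dark levels, zingers, a fixed scintillator blob and
per-column gain errors, each reproducible from an explicit seed that never
touches the caller's RNG state. On a noiseless simulated scan,
flat-field correction plus log recovers the analytic line integrals to
$10^{-6}$ (the only loss is the float32 TIFF storage of the counts).

The simulator emulates geometry, counting statistics and the named
artifact classes. It does not model scatter, beam hardening or
polychromatic spectra, detector point-spread, source size, or mechanical
vibration, so passing tests demonstrate correctness of the implemented
operators and their inversions — not robustness to every physical effect in
real beamline data.

Default study conditions used by the test suite and the acceptance script
were chosen once to be representative while fitting comfortably on one CPU
core: the voxel contract on a $128^2$ grid with 256 angles; cone/parallel
and laminography comparisons on $64^2$ detectors with 64–128 angles; the
helical scan with three turns of 80 projections each on a $48^2$ detector,
0.8 mm feed per turn at 2x magnification; NLM equivalence on $64^2$
frames; flat-field levels of $10^4$ counts over a dark level of $10^2$.

## Batch processing

`planBatch()` walks an input tree for directories holding the
darks/flats/tomo triple (the directory names are a package default,
overridable in `discoverLayout()`), preserves relative paths, skips data
sets already present in the output tree, and emits a printable,
executable stage plan in a fixed canonical order: stitching, outlier
removal, spot inpainting, flat-field (with absorptivity), phase retrieval,
ring filtering, axis estimation, reconstruction, crop/rotate, quantization,
NLM, orthogonal slices. `runPlan()` executes each data set under error
isolation — one failure does not abort the batch — and writes float TIFF
slices plus a plain-text `parameters.txt` sufficient to re-run the
reconstruction identically (the suite asserts bit-identical volumes on
re-run). A thin command-line front end (`inst/cli/tomoreco-cli.R`) exposes
the same operations as shell subcommands, with `!`-chained stages in its
`preprocess` subcommand.

One storage note: no installed R package writes IEEE-float TIFF (the
available writers quantize to [0, 1] integers), so the package includes a
minimal uncompressed float32 grayscale TIFF writer (single and multi-page);
reading goes through `tiff::readTIFF`, which handles the float sample
format exactly. 8/16-bit output refuses non-integral values — quantize
explicitly with `clipQuantize()` first.

## Known limitations

- FDK is approximate off the mid-plane, as always; large cone angles show
  the usual intensity drop. Laminography inherits the missing-cone blur in
  $z$ (visible as an axially elongated point response).
- Helical normalization is the $\pi/N_\mathrm{seen}$ approximation
  described above, not an exact redundancy weighting.
- Ring filtering trades quantitativeness for artifact suppression, by
  construction.
- The CTF inversion is the pure-phase weak-object variant; strong phase or
  mixed-object data need the TIE path or external tools.
- Short-scan (less than 180° plus fan) weighting is not implemented; such
  scans warn and reconstruct with the plain weight.
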