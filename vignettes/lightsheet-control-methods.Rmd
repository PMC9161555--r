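---
title: "Methods: waveform synthesis, Fourier autofocus and streaming acquisition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: waveform synthesis, Fourier autofocus and streaming acquisition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lightsheetr)
```

`lightsheetr` implements the computational core of a digital scanned
light-sheet microscope (DSLM) control platform for whole-brain imaging in
larval zebrafish, paired with a fully synthetic hardware model — a
nuclear-labeled brain phantom and a camera whose blur grows with
beam/focal-plane misalignment — so every algorithm can be exercised and
tested without a microscope. This vignette is the package's account of the
underlying methods: the models, the tunable parameters and their defaults,
the numerical choices, and what the simulator does and does not emulate.

Unit conventions, used everywhere without exception: positions in
micrometres (um), times in milliseconds (ms), voltages in volts (V), rates
in hertz (Hz).

## The scan program and its control waveforms

A volumetric scan images `n_planes` axial planes per volume at `frame_rate`
frames per second while the detection objective (DO) travels from
`do_start` to `do_end`. All command trains are generated on one sample
clock (`sample_rate`, default 50 kHz — fast enough that one sample is
0.02 ms against millisecond-scale timing requirements) and have identical
length, one volume period.

**Camera triggers.** One pulse per plane, 1 ms wide by default (pulse
overlap is validated against the frame period). Pulse amplitudes encode
position within the volume: 4.5 V for the first plane, 4.0 V for middle
planes, 3.5 V for the last. All amplitudes sit above the 3.3 V triggering
threshold, so a behavioral-recording system listening on the same line
receives every trigger yet can count volumes simply by thresholding at a
higher voltage. A single-plane volume is marked with the first-plane
amplitude: downstream software detects volume *starts*, so the
start-of-volume marker wins the tie.

**Piezo command.** The DO must move continuously — a piezo stage carrying
an objective cannot follow a stepwise command with sub-millisecond
accuracy — so the commanded trajectory is a linear ramp over the forward
95% of the volume period followed by a half-cosine flyback in the final 5%
(`flyback_fraction`). The piezo responds with a lag of order 10 ms, which
the platform compensates by advancing the whole periodic waveform by
`piezo_delay` (default 15 ms, typical range 10–20). Because scanning is
continuous and periodic, the advance is a circular shift of the
steady-state waveform, not zero padding. Conversion from position to
command volts uses a fixed gain of 0.1 V/um (`piezo_gain`); real rigs
override it with their stage's calibration.

**Axial beam command.** The excitation beam must track the DO focal plane.
Without a calibration the command is the straight line mapping
`[do_start, do_end]` to `[beam_volt_start, beam_volt_end]`; with a
calibration function (below) each sample is the calibrated voltage at the
instantaneous DO position, with no extrapolation permitted outside the
calibrated domain.

**Sheet-forming sweep.** The fast galvo axis sweeps the beam across the
field once per plane to form the virtual sheet. With a rolling-shutter
sCMOS camera the sweep is confined to the central `shutter_open_fraction`
of the exposure (default 0.8), the window in which all rows integrate
simultaneously, with constant holds before and after. The waveform shape
outside that constraint (sawtooth with instantaneous retrace at the plane
boundary) is a design choice of this package; only the shutter-synchronous
sweep window is essential.

## Eye exclusion

During whole-brain imaging the side beam's scan range crosses the eye. The
experimenter draws an elliptic region (center and semi-axes in the lateral
y–z projection, in um) and the gating module turns the side laser off
whenever the current plane's z and the beam's in-plane position fall
inside the ellipse. The half-chord at axial offset `dz` from the ellipse
center is `semi_y * sqrt(1 - (dz/semi_z)^2)`. Three deliberate choices:
gating is computed from each plane's nominal z (planes are thin relative
to an eye of ~300 um), boundary samples count as inside (safety first),
and the front beam — which scans the narrow strip between the eyes — is
never gated. No padding margin is added beyond the drawn ellipse; the ROI
is the experimenter's safety margin.

## The Fourier focus measure

A misaligned excitation beam illuminates tissue away from the detection
focal plane; the image blurs and loses high-spatial-frequency power. The
focus measure quantifies exactly that:

1. 2-D FFT of the image; power spectrum, centered.
2. Polar resampling on `floor(min(H, W) / 2)` radial bins × 360 angular
   samples (bilinear interpolation), then an average over angle. The DC
   pixel is removed before resampling: its power (the squared image sum)
   is orders of magnitude above everything else and would otherwise leak
   into the lowest radial bins through the interpolation.
3. Logarithm with a relative floor, `log(power + 1e-12 * max(power))`.
   Because the floor is relative, scaling the image by any constant shifts
   the whole curve additively and changes nothing downstream.
4. Threshold at `mean + 3 * sd` of the *baseline band* — the outer 25% of
   radial bins, which in fluorescence images carry only noise — and count
   the bins above threshold. The count is the focus measure; the largest
   such bin, `f_max`, is the maximum frequency component.

The image resolution estimate is half the wavelength of that component:
`image_dim * pixel_dim / (2 * f_max)`, with 0.405 um per camera pixel on
the reference detection path; for non-square images the shorter dimension
is used for both the polar grid and the formula.

The measure is invariant under multiplicative intensity scaling (threshold
and spectrum shift together under the log) and decreases monotonically
with defocus blur. One subtlety the phantom exposed: the threshold is
anchored by the *camera noise floor* in the baseline band. Blur on the
instrument happens before photons reach the camera, so noise is never
blurred; if one instead blurs an already-captured noisy frame, the
baseline band itself is attenuated below the log floor and the threshold
loses its reference. Equally, a hypothetical noiseless 16-bit camera shows
structured quantization contouring at heavy blur that the adaptive
threshold misreads. Real sCMOS read noise (modeled at sigma = 2 counts,
at least one LSB) dithers quantization away, and all sharpness properties
in the test suite are therefore evaluated through the camera model —
defocus first, noise second — at the simulator's default noise.

## Autofocus sweep and Gaussian peak fit

A sweep acquires 41 planes at 1 um spacing centered on the current beam
alignment, computes the focus measure for each, and rescales the counts to
`[0, 1]` (0 = poorest, 1 = best in the sweep; an all-equal sweep is a
degenerate-sweep error that aborts autofocus rather than returning a
meaningless answer). A four-parameter Gaussian
`offset + amplitude * exp(-(x - center)^2 / (2 * width^2))` is then fitted
by bounded Levenberg–Marquardt least squares and the fitted center is the
best focal plane.

Numerical choices for the fit, all of which mattered in practice:

* **Bounds.** Center inside the swept range; width in
  `[0.75 * step, span]`; amplitude in `[0.05, 1.5]`; offset in
  `[-0.5, 0.5]` (data are normalized, so these are generous).
* **Multi-start over width.** Initial widths `span/4`, `span/8`,
  `span/16` and `2 * step`, keeping the converged fit with the lowest
  residual. A single wide start can settle in a local optimum with the
  width pinned at its bound on narrow peaks.
* **Center start off the grid.** The start is the argmax nudged by
  `0.123 * step`: starting exactly on a symmetric grid point can make the
  initial Jacobian singular.
* **Failure is loud.** No convergence, a center escaping the swept range,
  or a width collapsing onto its lower bound (the signature of a single
  spike rather than a focus peak) raise an error so the caller can widen
  the sweep.

## Scan-axis calibration

The galvanometer angle is not exactly linear in the beam's axial position,
so a linear start/end alignment leaves the beam defocused mid-volume. The
calibration routine runs one autofocus sweep at each of five DO positions
evenly spaced over the volume (independently per beam), converts each best
beam offset to a command voltage through `beam_gain` (0.01 V/um in the
simulator), and interpolates the five knots with a cubic spline. The
interpolant passes exactly through every knot, refuses extrapolation, and
reports its maximum deviation from the line through the end knots — the
error a linear alignment would commit. Cubic interpolation through knots
sampled from a quadratic reproduces the quadratic identically, which is
how the simulator's known nonlinearity (a configurable mid-range sag,
default 0.04 V) validates recovery: the test suite requires the recovered
sag to agree with the ground truth within one sweep step expressed in
volts.

## Streaming acquisition

The real platform moves frames with three threads per camera: a reader
drains the camera driver's circular buffer into a first-in-first-out
system-memory queue, a writer drains that queue into uncompressed HDF5
files, and a preview consumer receives an intermittent copy. The contracts
are: the reader never blocks the source, the writer preserves arrival
order, every produced frame is written exactly once (preview frames may be
dropped, written frames never), and the queue depth stays bounded whenever
the disk keeps pace.

R is single-threaded, and those contracts are properties of the queue
discipline, not of threads. The package therefore runs the identical
discipline as a deterministic discrete-event simulation: frames arrive on
the camera clock, the writer services the queue head after a configurable
per-frame write time, and the maximum observed depth is recorded. File
I/O is real; only time is simulated. This makes zero-loss and
bounded-memory *provable* in tests — the suite checks 1000 frames
losslessly and in order, a 60 s run with the writer throttled to exactly
the source rate (depth stays below a small constant, the desk-scale
stand-in for a 30-minute stability benchmark), and two interleaved
sources emulating two-camera mode. A sustained queue above the high-water
mark (default two volumes, or 400 single-plane frames) for longer than a
5 s grace period triggers a controlled abort: the disk cannot keep up and
the run's statistics say so.

Files hold one volume each (or 100 frames per file in single-plane mode,
remainders flushed to a final short file at stop) as a single
uncompressed unsigned 16-bit `(frame, row, col)` dataset with sequence
numbers, timestamps and scan metadata as attributes, named
`vol_%06d.h5` / `chunk_%06d.h5` under a `run_<timestamp>` directory with
a timestamped XML settings copy beside the data — every run is
reproducible from its own directory.

## Settings persistence

All configuration lives in one flat XML document (version attribute "1"):
the scan program, the optional eye ROI, optional calibration knots, and a
free-form device map. Unknown elements are preserved on load rather than
dropped, so vendor extensions survive an edit cycle. Floats are serialized
with shortest-round-trip precision, making save → load the identity on
every field; the test suite asserts this for 100 randomized
configurations. Validation names every violated field.

## The phantom: what it emulates, and what it does not

`generate_phantom()` builds a volume of Gaussian-profile nuclei
(radius 2–2.5 um, i.e. diameter under 5 um, matching zebrafish neuronal
nuclei expressing a nuclear-localized indicator) at non-overlapping random
positions on a dim background, all randomness flowing from one seed.
The camera model extracts the slice at the DO focal plane, blurs with an
isotropic Gaussian of sigma `base_blur + blur_gain * |misalignment|`
(defaults 0.5 px and 0.6 px/um), adds Poisson-like shot noise and Gaussian
read noise (sigma 2 counts), and quantizes to 16 bits. The ground-truth
DO-to-voltage mapping is linear or quadratic with configurable sag.

This is deliberately not an optics simulation: defocus is a Gaussian, not
a PSF; there is no scattering, no depth-dependent attenuation, no
anisotropy (real images at the bottom of a brain are blurry in ways this
model does not capture). What the phantom guarantees — and all that the
correctness of the algorithms requires — is a sharpness landscape that is
unimodal in misalignment with its maximum at zero, plus exact knowledge of
the mapping the calibration must recover. Passing tests therefore
demonstrate algorithmic correctness against that ground truth, not
image-quality performance on real tissue.

Problem sizes used by the test suite are chosen to probe the contracts at
desk scale: 96³-voxel phantoms with 60 nuclei for focus work, 32³ for
streaming (content is irrelevant there), 1000-frame zero-loss runs, 60 s
throttled stability runs, 20 random-misalignment recovery trials. The
whole-brain preset itself (45 planes at 45 Hz over 220 um) is exercised
end-to-end with small frames.

## Known limitations

* No bidirectional scanning, MEMS/ETL waveform variants, or hardware
  galvo/DAQ/camera drivers — the module boundaries are where device
  bindings would attach.
* The GPU variant of the focus measure is not implemented; the reference
  path is vectorized R and computes a 41-plane sweep on 96×96 frames in
  well under a second.
* Single-camera HDF5 layout and file naming are this package's clean-room
  choices; they are documented above and in `finalize_file()` rather than
  inherited from any particular acquisition system.
* The piezo lag is compensated, not modeled: the simulator assumes the
  commanded advance exactly cancels the mechanical delay.
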