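---
title: "Methods: probe alignment, fiber-angle estimation and SWE quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probe alignment, fiber-angle estimation and SWE quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pennalign)
```

## Scope and model

Shear-wave elastography (SWE) estimates tissue stiffness from the speed of
induced shear waves (SWV, m/s), displayed as a color map over a B-mode
image. The velocity estimator tracks displacements along the horizontal
image axis; when muscle fascicles run at a pennation angle $\theta$ to that
axis and the shear wave follows the fibers, the measured SWV is the
projection $v\cos\theta$ of the along-fiber velocity $v$. Aligning the probe
so fibers appear horizontal ($\theta \to 0$) removes the bias at acquisition
time; `cosine_correction()` inverts the projection when a residual angle is
known (`correction(v cos θ, θ) = v` to machine precision, tested).

The package implements the full alignment pipeline on synthetic data:
screen-layout detection, fiber-orientation estimation, closed-loop motor
control, SWE quantification with quality control, and descriptive
statistics. No scanner hardware, reconstruction algorithm or human data is
involved; the in vivo results of the study this emulates are therefore
deliberately out of scope, and nothing here claims to reproduce them.

## Fiber-orientation estimation

Fascicles appear as bright, roughly parallel lines in longitudinal B-mode
images. `estimate_fiber_angle()` composes:

1. **Adaptive Canny** (`adaptive_canny()`): lower threshold $t$ starts at 50
   and rises in steps of 10 until edge pixels are *strictly* under 10% of
   the ROI. The upper threshold is fixed at $2t$ and the aperture at 3: the
   procedure prescribes a single iterated scalar (one start value, one step),
   and a fixed ratio is the standard way to keep hysteresis meaningful while
   iterating one number. The kernel (Sobel, L1 gradient magnitude,
   non-maximum suppression, 8-connected hysteresis) is implemented in
   `src/vision.cpp` because the R stack available offline has no
   image-processing package; it follows the same algorithm family as the
   OpenCV detector the original system used.
2. **Adaptive probabilistic Hough** (`adaptive_hough()`): accumulator
   threshold starts at 100 and decreases by 1 until at least ten segments
   are found. Unstated parameters are defaults chosen so fascicle-scale
   lines dominate: distance resolution 1 px, angle resolution 1°, minimum
   segment length 20% of the ROI width, maximum bridged gap 5 px — all
   configurable. The randomized point selection is driven by a fixed seed
   (default 42), so each per-threshold run is deterministic and the adaptive
   loop is *exactly* a brute-force sweep; the tests verify this equivalence
   against independent sweeps. Below an accumulator floor of 10 the detector
   fails loudly rather than returning a junk angle.
3. **Median angle**: per segment with endpoints $(x_a, y_a), (x_b, y_b)$,
   the angle is $\mathrm{atan2}(y_a - y_b,\; x_b - x_a)$ mapped to
   $(-90°, 90°]$. Because $y$ grows downward on screen, positive angles
   ascend left to right; a signed convention is kept because the motor must
   know the rotation direction. The median (mean of the two middle values
   for even counts) is taken directly on signed angles — no circular
   statistics, justified because fascicle angles live well inside
   $(-90°, 90°)$ — and is robust to a minority of spurious segments
   (property-tested with 4 outliers among 12 segments).

Segment endpoints are actual edge pixels, so angular precision is set by
segment length, not by the 1° accumulator resolution; on the default
phantom, recovery is well within 1°.

## Screen-layout detection

The scanner shows the plain B-mode panel and the B-mode-plus-color-map panel
side by side, each tagged with an "S" symbol in its top-left corner. The
layout is detected once per recording on the initial frame and reused:

- `locate_symbols()` matches the 9×9 binary glyph template by normalized
  cross-correlation (acceptance score 0.8 by default; the original
  publication names no matcher) and keeps the two highest-scoring,
  horizontally separated matches. The horizontal distance is $d$.
- `locate_swe_roi()` classifies a pixel as *colored* when the population
  standard deviation of its three 8-bit channel values exceeds 10 — the only
  per-pixel spread consistent with "not representing a grayscale color" —
  and returns the tight bounding box of colored pixels. When anchors are
  available, the search is restricted to the region right of the midpoint
  between the two symbols so colored UI elements cannot leak in; without
  anchors the whole frame is searched.
- `translate_to_bmode_roi()` applies $x_B = x_{SWE} - d$, $y_B = y_{SWE}$.

Boxes are half-open $[x_1, x_2) \times [y_1, y_2)$ in 0-based screen
coordinates (inclusivity is a package convention; the source procedure does
not state one). The threshold 10 presumes 8-bit channels.

## SWE quantification and quality control

`decode_frame()` maps each colored ROI pixel to the nearest lookup-table
entry of the color scale and converts the index to velocity
$v = v_{min} + (v_{max} - v_{min})\,i/255$; the frame mean averages colored
pixels only (invalid pixels are excluded, never zero-imputed). Input is
quantized to 8 bits before the nearest-neighbor search (frames are 8-bit
captures), which lets the search run once per distinct color; LUT-distance
ties resolve to the lowest index.

Quality control is two-level and *inclusive* at both boundaries
(boundary-tested to within one pixel / one frame):

- a frame is valid iff its colored fraction is ≥ 75%;
- a trial is included iff ≥ 30% of its analyzed frames are valid. Frames
  failing the 75% rule still count in this denominator. The source text's
  parenthetical glosses "valid" at the trial level as frames that *fail*
  criterion 1, which contradicts the word "valid"; the package reads a valid
  frame as one *meeting* criterion 1, the reading consistent with the high
  passive-trial frame percentages the study reports.

For contraction trials (everything except passive), the first
$\lceil 2 \cdot \text{frame rate} \rceil$ frames are discarded before any
aggregation — at the 19 Hz video rate, not the 1–2 Hz color-map update rate,
since exclusion operates on video frames. Repetition averaging
(`summarize_condition()`) uses included repetitions only; a task with no
included repetition is flagged missing (NA), never zero.

## Closed-loop control

The controller is proportional with $k_p = -0.2$ and control target 0°; its
output is an **incremental** rotation per measurement cycle, since the error
is re-measured every frame. The commanded rotation $k_p m$ is divided by the
1.8° step size, added to a carried fractional residual, and rounded half
away from zero (symmetric for both directions). Two consequences, both
design choices worth recording:

- **Residual carry.** Without it, $|k_p m| < 0.9°$ would never move the
  motor: a 4.5° deadband incompatible with the ~2° alignment accuracy the
  original system achieved. Carrying the remainder lets arbitrarily small
  persistent errors accumulate into whole steps.
- **Half-step convergence window.** Pure accumulation keeps integrating even
  when $|m| \le 0.9°$, where a 1.8° actuator cannot improve the error; the
  loop would drift into a slow limit cycle of amplitude up to a full step.
  `control_step()` therefore stops accumulating (and zeroes the residual)
  once the measured angle is within half a step, pinning the settled loop
  inside ±0.9°.

With an ideal sensor and vanishing step size the measured angle decays
geometrically with ratio exactly $1 + k_p = 0.8$ per cycle (tested at step
size $10^{-4}$°). With quantization, a static 20° offset reaches the ±0.9°
band within 15 cycles; the per-cycle bound $0.8^k \cdot 20° + 0.9°$ from the
geometric oracle plus half-step slack holds up to a transient allowance of
0.05° — the residual carry can exceed the steady-state half-step slack by
$O(10^{-3})$° at a single boundary cycle, which the unit test absorbs
explicitly rather than silently.

The simulator books the probe rotation in image coordinates, so the apparent
fiber angle each cycle is $\theta_{true}(t) + \phi_{probe}$ and the negative
gain drives it to zero. Motor commands of fewer than five steps execute
directly (default 0.02 s/step); larger commands use the symmetric profile
$v(i) = v_{max}(1 - e^{-\mathrm{ramp}_i/\tau})$, $\mathrm{ramp}_i =
\min(i, n+1-i)$, $\tau = \max(1, n/5)$, which keeps every per-step velocity
below $v_{max} = 1.75$ rad/s (fuzz-tested to 200 steps); $\tau$ and the
direct rate are unspecified upstream and configurable here. End switches
clamp travel at ±45°, discarding untaken steps and zeroing the residual.
`reference_motion()` reproduces encoder-free homing: traverse the full span,
count steps, rotate half back; a 90° span at 1.8° steps gives 50 counted, 25
back, home at 0°.

A sensor failure during a closed-loop cycle holds the motor for that cycle
and is logged, so transiently undetectable fibers degrade gracefully.

## The synthetic phantom: what it states, and what it does not

The generator's defaults are a single, fixed "world":

| Parameter | Default | Why |
|---|---|---|
| ROI size | 200 × 200 px | of the order of the ~1–1.5 cm ROI at screen resolution; square so oblique fibers keep enough in-ROI length |
| fiber spacing / thickness | 28 / 3 px | fascicle-scale periodicity; keeps the Canny edge fraction under 10% across ±30° without threshold starvation |
| intensities | 200 on 40 | strong but not saturating B-mode contrast |
| speckle σ | 5 (tests: 0–30) | additive Gaussian surrogate; *not* multiplicative speckle physics |
| frame rate | 19 Hz | the video sampling rate of the emulated system |
| durations | 5 s passive/MVC, 7 s submaximal | the emulated experimental protocol |
| rest pennation / rise | 20° + 8°·a(t) | resting gastrocnemius-scale pennation; increases with activation |
| SWV model | 2 + 5·a(t) m/s | resting-to-contracted range inside the 0–10 m/s scale |
| valid-pixel model | 0.97 − 0.6·a² (frame-to-frame σ 0.15) | matches the reported per-condition valid-pixel percentages’ trend: quality collapses at high contraction |
| color scale | 0–10 m/s, LUT (i, 0, 255−i) | the vendor LUT is unpublished; the default is explicit, strictly non-gray and pairwise distinct |

Activation ramps to the task level over 1 s and holds. All randomness flows
through per-frame seeds derived from the trial seed; identical arguments
give bit-identical output, and the caller's RNG stream is never perturbed.

What a green test does **not** establish: performance on real speckle
(multiplicative, correlated), curved or heterogeneous fascicles, aponeurosis
capture by the ROI (the documented failure mode of the original system, not
solved here), vendor colormaps, or any in vivo SWV magnitude. Under the
default world, 75% MVC and MVC trials are frequently excluded by the 30%
rule — harsher than the emulated study, where most 75% trials survived;
this is a property of the stated world, not a calibration target.

## Numerical conventions

- Rounding for step commands and for table display: half away from zero.
- Reference tables reproduce under the **population** (÷n) standard
  deviation; this was decided by back-checking the printed cells, and the
  tests assert that the sample (÷(n−1)) convention does *not* reproduce
  them. Two printed cells are arithmetically inconsistent with their own
  columns (one mean, one mean/std pair) and are treated as source typos:
  excluded from the verified set, not "corrected".
- "Agreement to printed precision" means within one unit in the last printed
  decimal: one verified std cell is printed as 38.99 while exact
  recomputation gives 38.9951.
- Degenerate inputs fail with classed conditions (`pa_*_error`) rather than
  returning sentinel numbers: zero-contrast phantoms yield no lines, blank
  edge images yield no segments, all-gray panels yield no ROI, and all
  propagate.

## Known limitations

Single global angle per frame (no fascicle tracking or curvature); no OCR of
on-screen scale text, so the color-scale limits are configuration; the PNM
codec and optional `png` cover I/O (no TIFF offline); the Hough kernel's
deterministic seeding trades OpenCV's run-to-run variability for exact
reproducibility of the stopping rules.
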