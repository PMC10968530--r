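---
title: "Measuring contractility and elasticity of probe-loaded cardiac tissue fibers"
author: "iwire package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring contractility and elasticity of probe-loaded cardiac tissue fibers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iwire)
```

## The measurement problem

An engineered cardiac tissue construct (ECTC) is a fiber of
hiPSC-derived cardiomyocytes in a hydrogel, suspended between two anchor
wires inside a molded channel (10 mm between the wires in the reference
device).  A calibrated flexible probe, moved by a motorized stage,
deflects the fiber transversely at its midpoint; a fast camera
(160-200 frames/s, 12-15 s movies) records the probe tip.  From the tip
trajectory one can recover, per recording:

* the probe force (the probe is a linear spring),
* the axial tension in the fiber (from the deflection geometry),
* per-beat systolic, diastolic and developed forces,
* the spontaneous beating rate,
* and, across a protocol of stage positions, the diastolic
  stretch-stress curve whose linear-region slope is the Young's modulus
  of the passive fiber.

The raw optical recordings behind published studies of this platform
are not deposited, so the package pairs the analysis chain with a
generator of synthetic recordings whose ground truth is known exactly.
Every downstream stage is validated against that ground truth (and
against independent brute-force oracles) rather than against
irreproducible experimental values.

## Mechanical model

The fiber is idealized as two straight elastic half-segments of
unloaded length $L_0$ (default 5 mm) meeting at the probe.  With the
tip displaced transversely by $y$, each half has stretched length
$\ell(y) = \sqrt{L_0^2 + y^2}$ and engineering strain
$\varepsilon(y) = (\ell - L_0)/L_0$.  Transverse equilibrium of the tip
node reads

$$ k\,(\Delta - y) \;=\; 2\,T(\varepsilon)\,\frac{y}{\ell(y)}, $$

where $k$ is the probe stiffness (mN/mm), $\Delta$ the stage position,
and $T$ the axial tension per half-fiber.  The tension model combines a
linear passive law and a length-dependent (Frank-Starling) active term:

$$ T(\varepsilon, t) = A\,E\,\varepsilon \;+\;
   \iota\,T_{max}\,\mathrm{FS}(\varepsilon)\,a(t), \qquad
   \mathrm{FS}(\varepsilon) =
   \frac{\varepsilon^h}{\varepsilon^h + \varepsilon_{50}^h}, $$

with cross-section $A = \pi d^2/4$ (mm^2), modulus $E$ (kPa; the unit
identity 1 kPa mm^2 = 1 mN keeps everything in mN), inotropy
multiplier $\iota$, peak active tension $T_{max}$ (mN), and a
normalized bi-exponential twitch
$a(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}$ restarted every beat
period.  The same geometry is inverted on the analysis side:
$T = F\,\ell/(2y)$ and $\sigma = T/A$, $\varepsilon = (\ell - L_0)/L_0$
at diastole give the stretch-stress curve.

This two-segment string model is the minimal statically determinate
description consistent with a midpoint point-load; it is a declared
convention of the package, not a reconstruction of any particular
published appendix.  Possible refinements (probe contact width, fiber
sag, pre-strain) are deliberately excluded; a pre-strain parameter
would be the first extension and defaults to zero (strain is measured
against the unloaded wire-to-wire geometry).

A regime remark: with moduli of a few kPa, a 0.4 mm fiber and applied
transverse forces of 0.4-0.75 mN, equilibrium diastolic deflections are
several millimetres and diastolic strains are large (0.4-0.7).  The
model is self-consistent there (the passive law stays linear in
engineering strain by construction), but the numbers should be read as
properties of the idealized string, not of a small-strain expansion.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `halfLength` | 5 | mm | unloaded half-span between wire and probe |
| `diameter` | 0.4 | mm | fiber diameter; sets $A$ |
| `kProbe` | 0.5 | mN/mm | probe spring constant (regression-calibrated) |
| `youngsModulus` | 5.4 | kPa | passive modulus (control phenotype) |
| `activeTension` | 0.15 | mN | peak active axial tension per half-fiber |
| `beatRate` | 0.76 | Hz | spontaneous rate (control phenotype) |
| `tauRise`, `tauDecay` | 0.05, 0.2 | s | twitch shape (time-to-peak ~92 ms) |
| `fsStrain50`, `fsHill` | 0.02, 2 | - | Frank-Starling half-activation and slope |
| `inotropy`, `chronotropy` | 1, 1 | - | drug multipliers on $T_{max}$, $f_0$ |
| `cv` | 0.2 | - | between-construct lognormal CV |
| `fps`, `duration` | 180, 14 | Hz, s | acquisition (protocol ranges 160-200, 12-15) |
| `centroidNoiseSd` | 2 | um | per-frame centroid localization noise |

The default stage protocol targets diastolic transverse forces of
0.424, 0.530, 0.636 and 0.742 mN, i.e. the four-level lateral-tension
protocol of the platform; with $\varepsilon_{50} = 0.02$ these levels
sit on the plateau of the Frank-Starling curve.  Treatment multipliers
in the bundled paper-like configuration are derived from the reference
phenotypes (chronotropy 0.89/0.76 for the responsive line, 1.5/1.09
for beta-adrenergic stimulation, inotropy 1.25).  `activeTension` =
0.15 mN was chosen once so that developed probe forces fall in the
0.1-0.2 mN range typical of the platform's force traces.

## Numerical choices

**Equilibrium solving.**  $g(y) = k(\Delta - y) - 2T(\varepsilon)y/\ell$
is strictly decreasing on $[0, \Delta]$, so the root is unique and
bracketed.  The public solver (arbitrary tension function) uses
`uniroot` plus a bisection polish to a residual below $10^{-12}$ mN;
the generator's closed-form path uses vectorized bisection, and for
long frame vectors an activation-grid warm start followed by
safeguarded vectorized Newton iterations (terminating at
$\max|g| \le 10^{-12}$ mN).  Stage positions for a target diastolic
force are solved directly in the tip coordinate (the transverse
reaction is monotone in $y$), then $\Delta = y + F/k$, which makes the
force round trip exact by construction (tolerance $10^{-9}$ mN).

**Beat detection.**  Peaks are local maxima with topographic prominence
of at least 30% of the force range, separated by at least 0.25 s.  The
per-beat diastolic baseline is the minimum force between the preceding
and the current peak ("the minimal force during relaxation" per cycle),
not a global minimum.  Two guards make the detector honest on degenerate
input: a trace whose total range is below six noise floors (noise floor
= 1.4826 x median absolute frame-to-frame difference) is declared
beat-free - a purely range-relative prominence rule cannot reject white
noise by itself - and detected beats with developed force below twice
the noise floor are dropped and counted in QC.  Peak times are refined
by a three-point parabolic fit clamped to one frame.  This makes the
frequency estimator continuous-valued instead of quantized to the frame
grid, which matters for the calibration of the paired statistics below;
it does not change which samples are beats.  The frequency estimator is
the peak-span ratio $(n_{peaks}-1)/(t_{last}-t_{first})$, robust for
12-15 s recordings with ~10 beats.

**Modulus fitting.**  The stretch-stress curve needs at least four
stage positions.  The "linear part" is chosen automatically as the
contiguous window of at least 4 points maximizing $R^2$ (ties: larger
window, then earlier start), checked in tests against an exhaustive
all-windows search; fits with best $R^2 < 0.8$ are refused with a
diagnostic.  Group values are reported as mean with both SD and SE,
explicitly labeled, since conventions differ between figure captions
and methods sections.

**Statistics.**  Comparisons use Student's t (pooled variance unpaired,
difference scores paired) at $\alpha = 0.05$, with explicit degenerate
branches: two constant equal arms give $p = 1$; a paired design with
constant non-zero difference is flagged through an exact-difference
branch rather than dividing by zero.  The pairing unit for the pre/post
chronotropy test is the recording (construct x tension level), matching
the platform's reported $N$ = recordings; because this pseudo-replicates
constructs, a per-construct-mean mode is also emitted.  No
multiple-testing correction is applied across tension levels by
default.  Seeds fan out from one master seed through a counter-based
linear-congruential map, so adding a stage never perturbs downstream
draws.

**Imaging.**  Synthetic movies render the probe tip as a bright disk
(radius 10 px at 10 um/px) with a linear partial-coverage edge ramp two
pixels wide, quantized to 8 bits.  Analysis binarizes each frame with
exhaustive 256-level Otsu thresholding, keeps the largest 8-connected
component (ties: larger size, then smaller minimal row, then column),
and takes a sub-pixel centroid.  Centroid weights are the intensity
excess over the binarization threshold: pixels at the membership margin
then carry ~zero weight, so the centroid is insensitive to exactly
which edge pixels the threshold includes.  With these choices the
noiseless render-and-track round trip recovers the generator trace to
well under 0.1 um RMS (0.01 px).  Frames with empty foreground (at most
2% per stack) are linearly interpolated and flagged.

## What the generator does and does not emulate

Emulated: fiber-probe mechanics at equilibrium per frame; plateaued
force-tension (Frank-Starling) behavior; spontaneous beating with
inotropic and chronotropic drug multipliers; between-construct
lognormal variability (CV 0.2; twitch time constants share one
multiplier so their order is preserved); centroid localization noise
(2 um SD); optional rendered movies with pixel noise.

Not emulated: electrophysiology and arrhythmia, beat-to-beat rate
variability within a recording, viscoelasticity and hysteresis, matrix
remodeling, probe nonlinearity, illumination drift and motion blur.
Passing recovery tests on synthetic data therefore demonstrates the
correctness of the analysis chain under the stated model - not that the
model captures every feature of real recordings.  In particular, the
type-I calibration of the paired test holds under independent
per-recording noise; real repeated recordings may be serially
correlated.

## Simulation sizes used in the checks

The test and acceptance harnesses size their simulations to hold
Monte-Carlo error well below the asserted tolerances while staying
single-core friendly: a 10x10x10 parameter grid against the 1 um-level
energy-grid oracle; one 2520-frame noiseless movie for the imaging
round trip; 1000 noisy calibration tables; 100 noisy constructs for
modulus recovery; 600-800 simulated null studies (9 constructs x 4
levels x 2 arms each, 160 fps, 12 s) for the type-I rate, and 100-seed
batches for power at the reference chronotropy effect.  At these sizes
the full suite runs in roughly a quarter of an hour on one CPU.

## Known limitations

* The string model ignores bending stiffness and distributed load; at
  very small deflections the tension inverse $T = F\ell/(2y)$ is
  ill-conditioned and is guarded by a tip-position floor (1e-3 mm).
* Developed force responds sublinearly to the inotropy multiplier
  (the stiffer the passive background, the more of the extra active
  tension is absorbed by geometry): a 1.25 multiplier yields a ~23%
  developed-force increase at the protocol levels.  Effect multipliers
  are therefore calibrated quantities, not identical to observed
  percent changes.
* Between-construct CV, twitch time constants and active tension are
  plausible field values, fixed once; they are not fitted to any
  dataset.
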