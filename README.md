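# iwire

Contractility and elasticity analysis for engineered cardiac tissue
constructs (ECTCs) measured on an I-Wire-style platform: a fiber of
cardiomyocytes suspended between two anchor wires, deflected transversely
at its midpoint by a calibrated flexible probe, and filmed at high frame
rate while it beats spontaneously.

The package is for experimentalists and modelers who need to turn
probe-tip movies (or pre-extracted centroid traces) into mechanics:
probe force, axial fiber tension, per-beat systolic/diastolic/developed
force, Frank–Starling force–tension curves, beating-rate chronotropy,
and Young's modulus from the diastolic stretch–stress curve.  Because
the platform's raw optical data are typically unavailable, the package
also ships a first-class synthetic-recording generator with exact ground
truth, so the whole chain is testable end to end.

## Model in brief

The fiber is two elastic half-segments of unloaded length `L0` meeting
at the probe tip.  At tip deflection `y`, each half has length
`l = sqrt(L0^2 + y^2)` and strain `eps = (l - L0)/L0`; transverse
equilibrium against the linear-spring probe (stiffness `k`, stage at
`Delta`) reads

```
k (Delta - y) = 2 T(eps) y / l,
T(eps, t) = A E eps + inotropy * Tmax * FS(eps) * a(t),
FS(eps) = eps^h / (eps^h + eps50^h)
```

with `A = pi d^2/4` the cross-section (1 kPa·mm² = 1 mN), `E` the
Young's modulus, `Tmax` the peak active tension, `FS` a Hill-type
length-dependent (Frank–Starling) activation and `a(t)` a normalized
bi-exponential twitch.  The analysis side inverts the same geometry:
`T = F l / (2 y)`, `sigma = T / A`, and the slope of the linear part of
the diastolic `sigma(eps)` curve is the reported modulus.  See the
methods vignette (`vignettes/iwire-methods.Rmd`) for assumptions,
defaults and numerical choices.

## Worked example

Simulate one recording at the first protocol force level, analyze it,
and recover the generator's ground truth:

```r
library(iwire)

geom <- ConstructGeometry()            # L0 = 5 mm, d = 0.4 mm
p    <- TissueParams()                 # E = 5.4 kPa, f0 = 0.76 Hz, ...
cal  <- probeCalibration(0.5)          # k = 0.5 mN/mm

delta <- stageForTargetForce(0.5, 0.424, p, geom)
rec   <- generateRecording(p, geom, AcquisitionParams(), 0.5, delta,
                           seed = 7)
summarizeRecording(rec@trace, cal, geom, recordingId = "demo")
```

```
  recordingId appliedForce devForceMean   devForceSd  beatRate nBeats nDropped
1        demo    0.4226846    0.1561523 0.0006054106 0.7596985     11        0
    tipDia tensionDia strainDia noBeat
1 5.151827   0.294512 0.4358456  FALSE
```

Reading the row: the median per-beat diastolic probe force is 0.423 mN
(the protocol target was 0.424 mN), each beat develops ~0.156 mN of
extra probe force, and the spontaneous rate estimate is 0.760 Hz against
a generative setting of 0.76 Hz.  The diastolic tip position (5.15 mm)
maps to an axial tension of 0.295 mN and a half-segment strain of 0.436.

A full two-line, pre/post study with paired statistics, force–tension
curves and per-construct moduli:

```r
report <- runStudy(paperLikeConfig(seed = 1))
report@comparisons        # paired chronotropy/inotropy + between-line tests
report@elasticity         # per-construct Young's moduli by group
```

A YAML version of the bundled configuration is in
`inst/extdata/paperlike_config.yaml`; `runStudy()` accepts the file path
directly and `writeStudyReport()` emits the CSV/JSON bundle.

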