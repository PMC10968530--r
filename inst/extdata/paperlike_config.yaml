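seed: 1
geometry:
  halfLength: 5.0
  diameter: 0.4
  pixelScale: 10.0
calibration:
  kProbe: 0.5
acquisition:
  fps: 180.0
  duration: 14.0
  centroidNoiseSd: 2.0
arms:
- label: CC3
  nConstructs: 9
  cv: 0.2
  params:
    youngsModulus: 5.4
    beatRate: 0.76
    activeTension: 0.15
  treatments:
  - label: control
    inotropy: 1.0
    chronotropy: 1.0
  - label: rapamycin
    inotropy: 1.25
    chronotropy: 1.171052631579
- label: TSP8-15
  nConstructs: 8
  cv: 0.2
  params:
    youngsModulus: 6.8
    beatRate: 0.93
    activeTension: 0.15
  treatments:
  - label: control
    inotropy: 1.0
    chronotropy: 1.0
  - label: rapamycin
    inotropy: 1.0
    chronotropy: 1.0
- label: CC3-iso
  nConstructs: 8
  cv: 0.2
  params:
    youngsModulus: 5.4
    beatRate: 1.09
    activeTension: 0.15
  treatments:
  - label: control
    inotropy: 1.0
    chronotropy: 1.0
  - label: isoproterenol
    inotropy: 1.3
    chronotropy: 1.376146788991
analysis:
  alpha: 0.05
  targetForces:
  - 0.424
  - 0.53
  - 0.636
  - 0.742
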