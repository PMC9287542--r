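# Ten-task benchmark configuration: task-level NSD tolerances (mm) chosen
# by the annotating clinicians, ROI label maps and challenge phases.
tasks:
  - name: Brain
    phase: development
    tolerance_mm: 5
    rois:
      - {label: 1, name: edema}
      - {label: 2, name: non-enhancing tumor}
      - {label: 3, name: enhancing tumor}
  - name: Heart
    phase: development
    tolerance_mm: 4
    rois:
      - {label: 1, name: left atrium}
  - name: Hippocampus
    phase: development
    tolerance_mm: 1
    rois:
      - {label: 1, name: anterior}
      - {label: 2, name: posterior}
  - name: Liver
    phase: development
    tolerance_mm: 7
    rois:
      - {label: 1, name: liver}
      - {label: 2, name: liver tumor}
  - name: Lung
    phase: development
    tolerance_mm: 2
    rois:
      - {label: 1, name: lung tumor}
  - name: Pancreas
    phase: development
    tolerance_mm: 5
    rois:
      - {label: 1, name: pancreas}
      - {label: 2, name: pancreatic tumor mass}
  - name: Prostate
    phase: development
    tolerance_mm: 4
    rois:
      - {label: 1, name: peripheral zone}
      - {label: 2, name: transition zone}
  - name: Colon
    phase: mystery
    tolerance_mm: 4
    rois:
      - {label: 1, name: colon cancer primaries}
  - name: HepaticVessel
    phase: mystery
    tolerance_mm: 3
    rois:
      - {label: 1, name: hepatic vessel}
      - {label: 2, name: hepatic tumor}
  - name: Spleen
    phase: mystery
    tolerance_mm: 3
    rois:
      - {label: 1, name: spleen}
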