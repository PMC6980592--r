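# Polytrauma Grading Score (PTGS): registry-derived points system with three
# strata (stable < borderline < unstable); patients in extremis are excluded
# by design. Borderline markers follow the published description (admission
# systolic blood pressure < 75 mmHg, NISS > 50 points, 15 or more pRBC
# units); the INR coagulation criterion and the unstable bands and point
# table are a reconstruction and overridable.
name: PTGS
strata: [stable, borderline, unstable]
aggregation: point_sum
band_points: {stable: 0, borderline: 1, unstable: 2}
point_table: {borderline: 1, unstable: 3}
criteria:
  - parameter: systolic_bp
    pathway: hemorrhage
    direction: low_is_worse
    required: true
    cuts:
      borderline: {value: 75, inclusive: false}
      unstable: {value: 60, inclusive: false}
  - parameter: niss
    pathway: injury_severity
    direction: high_is_worse
    required: true
    cuts:
      borderline: {value: 50, inclusive: false}
      unstable: {value: 66, inclusive: true}
  - parameter: prbc_24h
    pathway: hemorrhage
    direction: high_is_worse
    required: true
    cuts:
      borderline: {value: 15, inclusive: true}
      unstable: {value: 25, inclusive: true}
  - parameter: inr
    pathway: coagulation
    direction: high_is_worse
    required: true
    cuts:
      borderline: {value: 1.4, inclusive: true}
      unstable: {value: 2.0, inclusive: true}
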