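# Modified Clinical Grading System (mCGS): modification of the CGS that
# drops fibrinogen (and the other omitted coagulation parameters), relaxes
# the soft-tissue and hypothermia bands, and counts transfusion as pRBC
# units within 24 hours of injury instead of 2 hours of admission. Every
# retained cut is equal to or laxer than the CGS cut on the same parameter,
# so the modification can only shift patients toward more stable grades.
name: mCGS
strata: [stable, borderline, unstable, in_extremis]
aggregation: worst_criterion
criteria:
  - parameter: lactate
    pathway: acid_base
    direction: high_is_worse
    required: true
    cuts:
      borderline: {value: 2.0, inclusive: true}
      unstable: {value: 4.0, inclusive: true}
      in_extremis: {value: 8.0, inclusive: true}
  - parameter: ph
    pathway: acid_base
    direction: low_is_worse
    required: true
    cuts:
      borderline: {value: 7.35, inclusive: false}
      unstable: {value: 7.25, inclusive: false}
      in_extremis: {value: 7.10, inclusive: false}
  - parameter: base_excess
    pathway: acid_base
    direction: low_is_worse
    required: true
    cuts:
      borderline: {value: -2.0, inclusive: false}
      unstable: {value: -6.0, inclusive: false}
      in_extremis: {value: -10.0, inclusive: false}
  - parameter: platelet_count
    pathway: coagulation
    direction: low_is_worse
    required: true
    cuts:
      borderline: {value: 110, inclusive: false}
      unstable: {value: 90, inclusive: false}
      in_extremis: {value: 70, inclusive: false}
  - parameter: prothrombin_ratio
    pathway: coagulation
    direction: low_is_worse
    required: true
    cuts:
      borderline: {value: 80, inclusive: false}
      unstable: {value: 70, inclusive: false}
      in_extremis: {value: 50, inclusive: false}
  - parameter: systolic_bp
    pathway: hemorrhage
    direction: low_is_worse
    required: true
    cuts:
      borderline: {value: 100, inclusive: false}
      unstable: {value: 90, inclusive: false}
      in_extremis: {value: 60, inclusive: false}
  - parameter: prbc_24h
    pathway: hemorrhage
    direction: high_is_worse
    required: true
    cuts:
      borderline: {value: 8, inclusive: true}
      unstable: {value: 14, inclusive: true}
      in_extremis: {value: 32, inclusive: true}
  - parameter: chest_ais
    pathway: soft_tissue
    direction: high_is_worse
    required: false
    cuts:
      borderline: {value: 3, inclusive: true}
      unstable: {value: 4, inclusive: true}
      in_extremis: {value: 5, inclusive: true}
  - parameter: abdomen_moore_grade
    pathway: soft_tissue
    direction: high_is_worse
    required: false
    cuts:
      borderline: {value: 3, inclusive: true}
      unstable: {value: 4, inclusive: true}
      in_extremis: {value: 5, inclusive: true}
  - parameter: extremity_soft_tissue_ais
    pathway: soft_tissue
    direction: high_is_worse
    required: false
    cuts:
      borderline: {value: 3, inclusive: true}
      unstable: {value: 4, inclusive: true}
      in_extremis: {value: 5, inclusive: true}
  - parameter: temperature_core
    pathway: soft_tissue
    direction: low_is_worse
    required: false
    cuts:
      borderline: {value: 34.0, inclusive: false}
      unstable: {value: 32.0, inclusive: false}
      in_extremis: {value: 29.0, inclusive: false}
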