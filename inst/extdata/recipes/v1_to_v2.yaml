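# First abstraction iteration: clinically guided state clustering and
# variable condensation. Nodal status collapses to the resectable /
# unresectable distinction, performance-status and comorbidity scales are
# coarsened, surgical contraindications and organ-function indicators are
# each condensed into one expert-asserted summary node, and the two neck
# dissection options are condensed into a single therapy node (five therapy
# nodes remain).
steps:
  - op: merge
    # eight TNM N-categories clustered to the three clinically decisive
    # patterns: no nodal disease, limited (dissectable) involvement, advanced
    # (unresectable) nodal disease
    variable: N_stage
    groups:
      none: [N0, Nx]
      limited: [N1, N2a, N2b, N2c]
      advanced: [N3a, N3b]
  - op: merge
    variable: karnofsky_index
    groups:
      high: ["100", "90"]
      moderate: ["80", "70", "60"]
      low: ["50", "40", "30", "20", "10"]
  - op: merge
    variable: comorbidity_severity
    groups:
      minor: [none, mild]
      major: [moderate, severe]
  - op: merge
    variable: extranodal_extension
    groups:
      present: [present]
      absent_or_unknown: [absent, unknown]
  - op: condense
    # local-extension detail condensed into one expert-asserted
    # resectability/contraindication node; infiltration depth and trismus add
    # only marginal information and are absorbed
    sources: [carotid_infiltration, skull_base_infiltration,
              prevertebral_infiltration, airway_compromise,
              infiltration_depth, trismus]
    derived: {name: surgical_contraindication, states: [absent, present],
              role: diagnostic}
    mapping:
      kind: cases
      cases:
        - when_any:
            carotid_infiltration: [present]
            skull_base_infiltration: [present]
            prevertebral_infiltration: [present]
            airway_compromise: [present]
          value: present
      default: absent
  - op: add_edge
    from: surgical_contraindication
    to: primary_surgery
  - op: add_edge
    from: surgical_contraindication
    to: radiotherapy_primary
  - op: condense
    sources: [renal_function, liver_function, cardiac_function, pulmonary_function]
    derived: {name: organ_function, states: [adequate, impaired], role: diagnostic}
    mapping:
      # chemotherapy tolerance is gated by renal and cardiac function; hepatic
      # and pulmonary status carry only marginal information and are dropped
      kind: cases
      cases:
        - when_any:
            renal_function: [impaired]
            cardiac_function: [impaired]
          value: impaired
      default: adequate
  - op: add_edge
    from: organ_function
    to: chemotherapy
  - op: condense
    sources: [neck_dissection_ipsilateral, neck_dissection_contralateral]
    derived: {name: neck_dissection,
              states: [recommended, conditional, excluded], role: target}
    mapping:
      kind: cases
      cases:
        - when_any:
            neck_dissection_ipsilateral: [recommended]
            neck_dissection_contralateral: [recommended]
          value: recommended
        - when_any:
            neck_dissection_ipsilateral: [conditional]
            neck_dissection_contralateral: [conditional]
          value: conditional
      default: excluded
  - op: add_edge
    from: N_stage
    to: neck_dissection
  - op: add_edge
    from: extranodal_extension
    to: neck_dissection
  - op: add_edge
    from: general_health
    to: neck_dissection
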