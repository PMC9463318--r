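# Second abstraction iteration: canonical-model restructuring. Transitivity
# between the parent sets of distinct therapy nodes is resolved (independence
# of causal influence), health summaries are discretized into Boolean pairs,
# the surgical nodes are condensed into one Boolean feasibility node, the
# remaining therapy nodes are binarized (true = eligible option), and the
# best-supportive-care summary becomes a leaky noisy-OR gate over the
# general-condition risk indicators. Four Boolean therapy nodes remain.
steps:
  - op: resolve_transitivity
    targets: [primary_surgery, neck_dissection, radiotherapy_primary,
              radiotherapy_concurrent, chemotherapy]
  - op: merge
    variable: general_health
    groups:
      "true": [poor]              # true = severely reduced general condition
      "false": [good, reduced]
  - op: merge
    variable: prognosis
    groups:
      "true": [poor]              # true = poor-prognosis constellation
      "false": [favorable, intermediate]
  - op: merge
    variable: surgical_contraindication
    groups:
      "true": [present]
      "false": [absent]
  - op: merge
    # nodal status discretized to Boolean unresectable nodal disease
    variable: N_stage
    groups:
      "true": [advanced]
      "false": [none, limited]
  - op: condense
    sources: [primary_surgery, neck_dissection]
    derived: {name: surgery, states: ["true", "false"], role: target}
    mapping:
      kind: cases
      cases:
        - when_any:
            primary_surgery: [recommended, conditional]
          value: "true"
      default: "false"
  - op: add_edge
    from: surgical_contraindication
    to: surgery
  - op: add_edge
    from: T_stage
    to: surgery
  - op: add_edge
    from: general_health
    to: surgery
  - op: binarize
    variable: radiotherapy_primary
    true_states: [recommended]
  - op: binarize
    variable: radiotherapy_concurrent
    true_states: [recommended]
  - op: binarize
    variable: chemotherapy
    true_states: [recommended]
  - op: merge
    variable: best_supportive_care
    groups:
      "true": [considered]
      "false": [not_considered]
  - op: noisy_or
    effect: best_supportive_care
    causes: [surgical_contraindication, general_health, prognosis]
    links: [0.40, 0.55, 0.30]
    leak: 0.02
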