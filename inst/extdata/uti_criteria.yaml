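# Criteria configuration for the 16-test UTI diagnostic study replica.
# Weights are linguistic terms on the built-in five-level triangular
# fuzzy scale. Directions and generator classes are package assumptions
# (the original expert matrix is unpublished): specimen volume, cost and
# result time are minimized, everything else maximized.
criteria:
  - id: C1
    name: specimen volume
    direction: minimize
    weight: Very Low
    class: cost_like
  - id: C2
    name: specimen type
    direction: maximize
    weight: Low
    class: linguistic5
  - id: C3
    name: cost
    direction: minimize
    weight: High
    class: cost_like
  - id: C4
    name: efficiency
    direction: maximize
    weight: High
    class: linguistic5
  - id: C5
    name: result time
    direction: minimize
    weight: Very High
    class: time_like
  - id: C6
    name: point of care testing
    direction: maximize
    weight: Very High
    class: binary
  - id: C7
    name: applicability/direct from sample
    direction: maximize
    weight: Moderate
    class: binary
  - id: C8
    name: practicality for patients
    direction: maximize
    weight: Moderate
    class: linguistic5
  - id: C9
    name: practicality for personnel
    direction: maximize
    weight: Moderate
    class: linguistic5
  - id: C10
    name: limitation/pathogen identification
    direction: maximize
    weight: High
    class: linguistic5
  - id: C11
    name: sensitivity
    direction: maximize
    weight: High
    class: percentage
  - id: C12
    name: specificity
    direction: maximize
    weight: High
    class: percentage
  - id: C13
    name: PPV
    direction: maximize
    weight: High
    class: percentage
  - id: C14
    name: NPV
    direction: maximize
    weight: High
    class: percentage
  - id: C15
    name: antimicrobial susceptibility testing
    direction: maximize
    weight: High
    class: binary
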