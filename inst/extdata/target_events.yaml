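# Target adverse-event sets, name -> list of MedDRA preferred terms.
# The default analysis set is the single PT OSTEOPENIA; related bone-density
# PTs are provided as an alternative, broader set for sensitivity analyses.
osteopenia:
  - OSTEOPENIA
osteopenia_broad:
  - OSTEOPENIA
  - BONE DENSITY DECREASED
  - OSTEOPOROSIS
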