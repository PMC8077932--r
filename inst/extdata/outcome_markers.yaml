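# Marker-term scorer configuration for the five symptomatic outcomes.
# Each outcome maps to a list of terms; a post is positive for an outcome
# when it contains any of the terms (multiword terms match as phrases).
# These lexicon scorers are a pluggable stand-in with the same per-post
# binary interface as trained symptom classifiers.
depression:
  - hopeless
  - worthless
  - downhearted
anxiety:
  - anxious
  - nervous
  - uneasy
stress:
  - stressed
  - overloaded
  - frazzled
suicidal_ideation:
  - suicidal
  - selfharm
psychosis:
  - hallucinating
  - paranoid
  - delusional
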