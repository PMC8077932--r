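# Seed terms for the five clinically salient antidepressant side-effect
# domains. Edit or extend freely; categories drive the co-occurrence
# prevalence tables.
sleep:
  - sleep
  - asleep
  - insomnia
  - nap
weight:
  - weight
  - pounds
eating:
  - eat
  - eating
  - appetite
  - food
  - hungry
pain:
  - pain
  - ache
  - migraine
sexual:
  - sex
  - sexual
  - asexual
  - libido
  - viagra
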