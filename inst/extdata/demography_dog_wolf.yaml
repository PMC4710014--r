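# Illustrative dog/wolf demography for the coalescent null.
#
# Schema:
#   populations:      list of {name, size}        (diploid N, extant demes)
#   splits:           list of {time, derived, ancestral}
#                     (generations before present; backwards in time the
#                      derived deme's lineages re-label into the ancestral)
#   size_changes:     list of {time, population, size}
#   migration:        list of {from, to, rate}
#                     (backwards-in-time per-generation lineage rate)
#   migration_changes: list of {time, from, to, rate}
#   mu:               mutation rate per bp per generation
#   window_length:    window size in bp
#   blocks:           independent non-recombining blocks per window
#
# The dog bottleneck size sits in the published 700-3,200 range for the
# population ancestral to all dogs; split time and migration are
# placeholders with the right order of magnitude, not inferred values.
populations:
  - name: dog
    size: 2500
  - name: wolf
    size: 10000
splits:
  - time: 3000
    derived: dog
    ancestral: wolf
size_changes:
  - time: 3000
    population: wolf
    size: 15000
migration:
  - from: dog
    to: wolf
    rate: 1.0e-4
  - from: wolf
    to: dog
    rate: 1.0e-4
mu: 1.0e-8
window_length: 500000
blocks: 50
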