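# Default run configuration: simulate the full biomass-to-nanopaper design
# at the reference tensile-index variance partition and analyse it.
seed: 101
generator:
  grand_mean: 60
  metric: tensile_index
  seed: 101
  components:
    Variety: 6.74
    "Section:Variety": 57.40
    Energy: 110.59
    Nanopaper: 1.28
    "Strip:Nanopaper": 0.01
    Residual: 137.34
model:
  coding: literal
genetic_terms: ["Variety", "Section:Variety"]
clustering:
  samples: {measure: euclidean, linkage: ward, k: 4}
  metrics: {measure: correlation, linkage: average, k: 3}
quality:
  - name: Q1
    metrics: [tensile_index]
  - name: Q5
    metrics: [sed_aspect_ratio, wrv]
output_dir: results
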