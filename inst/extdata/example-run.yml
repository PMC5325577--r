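# Example pipeline configuration (flat YAML subset).
# Simulates a small population and runs the full analysis:
#   Rscript inst/cli/thram.R report --config example-run.yml --outdir run1
simulate: true
traits: hip,elbow
h2: 0.5,0.3
n_founders: 100
n_generations: 3
n_per_gen: 150
n_sires: 20
n_dams: 50
iterations: 5000
burn_in: 1000
thin: 5
seed: 1
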