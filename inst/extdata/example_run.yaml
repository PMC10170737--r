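# Example run configuration for the htnrec command-line interface.
#   Rscript inst/cli/htnrec.R simulate  --config example_run.yaml
#   Rscript inst/cli/htnrec.R evaluate  --config example_run.yaml
#   Rscript inst/cli/htnrec.R recommend --config example_run.yaml --vignette VIG001
seed: 1
schema:
  - name: gender
    kind: categorical
  - name: age
    kind: numeric
    half_width: 5
engine:
  scope: local          # local (RE-loc) or global (RE-glob)
  mode: mean            # mean (endpoint-driven) or pop (popularity)
  top_n: 3
  post_filter: absolute # off | absolute | absolute_relative (-eb engines)
  fallback_on_empty: true
generator:
  n_patients: 1000
  n_vignettes: 100
  n_experts: 5
  expert_policy: oracle
paths:
  dir: htnrec_run       # all artifacts are read from / written to this dir
  # rules: defaults to the shipped synthetic demo rule base
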