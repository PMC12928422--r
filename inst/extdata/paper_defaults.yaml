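# Pipeline configuration reproducing the study's analysis settings on the
# shipped zone-mean table. `input` and `registry` are resolved against the
# installed package's extdata when run through run_pipeline(); replace them
# with your own paths for new data.
input: zone_means_long.csv
registry: pah_registry.csv
policy: zero
mode: paper_compat
group_by: [zone]
mc:
  iterations: 100000
  seed: 1
  percentiles: [2.5, 50, 97.5]
  exposure: stochastic
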