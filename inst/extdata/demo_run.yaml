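# Demonstration pipeline configuration: a small synthetic scene with the
# default six driver regions, attributed with the canonical three climate
# variables.  Run with
#   runPipeline(system.file("extdata", "demo_run.yaml",
#                           package = "grasstrend"), outputDir = "demo_out")
scene:
  nRows: 24
  nCols: 24
  nYears: 20
seed: 7
alpha: 0.05
selection:
  variables: [temperature, precipitation, sunshine]
hotplots:
  enabled: true
  nPermutations: 199
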