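# End-to-end demonstration: simulate three source environments, two
# sink samples with known ground truth, rarefy, track, compare.
seed: 42
outputDir: demo-out
stages:
  simulate: true
  calibrate: false
  robustness: false
  compare: true
simulate:
  nTaxa: 80
  nSources: 3
  samplesPerSource: 3
  concentration: 0.5
  separation: 1.0
  depth: 2000
  sinks:
    - id: sinkA
      depth: 1000
      proportions: {Env1: 0.7, Env2: 0.3}
    - id: sinkB
      depth: 1000
      proportions: {Env3: 0.5, Unknown: 0.5}
rarefy:
  depth: 1000
gibbs:
  burnIn: 200
  restarts: 10
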