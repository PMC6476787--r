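# Example configuration for inst/scripts/tundradiv.R
simulate: true
seed: 7
reps: 200
stages: "alpha,beta,trends,metacom"
out: "results/synthetic_run"
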