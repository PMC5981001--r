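# small demonstration run: six simulated agents in an ON/OFF crossover
seed: 42
p_norm: 2
simulate:
  n_agents: 6
  design: ON_OFF_crossover
out_dir: og_output
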