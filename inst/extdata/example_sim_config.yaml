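# Example simulation configuration (arguments of simulation_config()).
# Sizes are kept small here so the example runs in seconds; the package
# defaults describe the reference study condition.
species_tree: "(((spA:0.4,spB:0.4):0.3,(spC:0.4,spD:0.4):0.3):0.4,spOUT:0.9);"
outgroup: spOUT
stages_per_species: 6
n_replicates: 3
n_ogs: 400
duplication_prob: 0.1
loss_prob: 0.05
branch_rate: 1.5
stage_drift: 0.35
ancestral_stage_sd: 0.5
stage_phi: 0.8
replicate_sd: 0.1
planted_dco_fraction: 0.05
planted_noise_sd: 0.1
seed: 1
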