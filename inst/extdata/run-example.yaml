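# Example configuration for the detectability experiment driver.
# Keys mirror the arguments of run_experiment(); states_mm is converted
# to metres (0 = healthy, no hemorrhage).
states_mm: [0, 10, 20, 30]
locations: cortical
algorithms: [ld, mo]
seed: 1
n_electrodes: 16
noise_rel: 0.00067
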