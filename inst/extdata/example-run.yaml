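# Example configuration for run_release_study() / the simulate subcommand.
seed: 17                      # master seed; recorded in every output
scenarios: [fatty_4C, fatty_24C, hydrophilic_4C, hydrophilic_24C]
n_replicates: 3               # films per condition
noise_cv: 0.05                # multiplicative measurement noise (CV)
n_roots: 12                   # series order used in fitting
plateau_points: 3             # trailing points averaged for C_S_inf fallback
output_dir: release_outputs
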