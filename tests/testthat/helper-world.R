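# Small shared truth worlds, built once per test run.

tw_small <- build_world(sim_config(seed = 42, loci_per_motif = 8,
                                   motif_lengths = 1:6, p_variant = 0.3))
tw_small_sample <- sim_sample(tw_small, "s1", seed = 9)
tw_small_truth <- truth_calls(tw_small, tw_small_sample)
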