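process_type	total_events	percentage
in_situ_speciation	17440.6	39.18479
founder_event_speciation	8259.6	18.55731
allopatry	14.3	0.032129
subset_sympatry	42.96	0.096521
dispersal	7090.9	15.93153
extinction	11660.24	26.19772
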