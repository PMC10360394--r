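quantity	n
cohort	7100
significant_carriers	85
susceptibility_carriers	194
either_carriers	279
carriers_with_dx_or_high	130
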