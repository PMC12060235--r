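group	n	nc_mean	nc_sd	mcw_mean	mcw_sd
all	99	31.26	9.75	267.61	30.27
registered	15	37.41	9.92	276.58	29.06
top10pct	10	51.67	4.74	321.67	10.35
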