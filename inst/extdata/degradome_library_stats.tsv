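library	raw_reads	unique_raw_reads	mapped_reads	mapped_percent	input_cdnas	covered_cdnas	covered_percent
CT	12654699	8431161	9382112	74.14	223441	200249	89.62
NT	10844042	7202445	6954750	64.13	223441	198805	88.97
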