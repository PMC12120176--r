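tool	zone	lof_in_zone	n_lof	func_in_zone	n_func
AM	path	284	337	142	1182
AM	benign	37	337	978	1182
BD	path	269	337	151	1182
BD	benign	32	337	851	1182
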