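sample_id	method	platform	condition	replicate	qpcr_total
i-shotgun-live-1	shotgun	illumina	live	1	4.1e+07
i-shotgun-control_live-1	shotgun	illumina	control_live	1	9800000
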