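# 24x MS2 cassette at the 3' end of a 3.6 kb transcript
pre_cassette_bp: 1800
cassette_bp: 1800
post_cassette_bp: 0
loops_total: 24
step_bp: 150
step_time_s: 6
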