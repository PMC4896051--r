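prot_id	delta_t_ms	n_post	post_freq_hz	n_reps	rep_freq_hz	sg	stdev	stderr
dt-100	-100	3	50	60	0.1	1.0600335291694	0.05	0.05
dt-75	-75	3	50	60	0.1	0.856550477792787	0.05	0.05
dt-50	-50	3	50	60	0.1	0.730914907925155	0.05	0.05
dt-25	-25	3	50	60	0.1	0.818761659128299	0.05	0.05
dt-10	-10	3	50	60	0.1	1.00824582335476	0.05	0.05
dt+10	10	3	50	60	0.1	1.31525262078731	0.05	0.05
dt+25	25	3	50	60	0.1	1.38203009768547	0.05	0.05
dt+50	50	3	50	60	0.1	0.969138285894726	0.05	0.05
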