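condition	cascade	step_a	step_b	str_diff	effect_size	pi_d	d_pi	c1_reported	c2_reported	c3_reported	similar_reported
non_stressed	SRME	Src	Raf1	0.2	0.1	0.5	0.6	TRUE	TRUE	TRUE	TRUE
non_stressed	SRME	Raf1	MEK1	0.0	0.0	0.5	0.5	TRUE	TRUE	TRUE	TRUE
non_stressed	SRME	MEK1	ERK	0.5	0.2	0.4	0.6	TRUE	TRUE	TRUE	TRUE
non_stressed	SRME	ERK	p53	0.2	0.6	0.3	0.9	FALSE	FALSE	FALSE	FALSE
non_stressed	AMMJ	ASK1	MKK4	0.2	0.6	0.3	0.9	FALSE	FALSE	FALSE	FALSE
non_stressed	AMMJ	ASK1	MKK3	0.0	0.0	0.5	0.5	TRUE	TRUE	TRUE	TRUE
stressed	SRME	Src	Raf1	0.7	0.1	0.5	0.6	TRUE	TRUE	TRUE	TRUE
stressed	SRME	Raf1	MEK1	0.8	0.1	0.5	0.6	TRUE	TRUE	TRUE	TRUE
stressed	SRME	MEK1	ERK	0.1	0.0	0.5	0.5	TRUE	TRUE	TRUE	TRUE
stressed	SRME	ERK	p53	2.3	0.7	0.7	0.9	FALSE	FALSE	FALSE	FALSE
stressed	AMMJ	ASK1	MKK4	0.4	0.3	0.4	0.8	TRUE	TRUE	FALSE	TRUE
stressed	AMMJ	MKK4	JNK	0.4	0.2	0.6	0.7	TRUE	TRUE	FALSE	TRUE
stressed	AMMJ	JNK	HSF1	0.7	0.7	0.7	0.9	FALSE	FALSE	FALSE	FALSE
stressed	AMMJ	HSF1	Tau	0.0	0.0	0.5	0.5	TRUE	TRUE	TRUE	TRUE
stressed	AMMJ	ASK1	MKK3	0.3	0.3	0.5	0.6	TRUE	TRUE	TRUE	TRUE
stressed	AMMJ	MKK3	JNK	0.7	0.5	0.6	0.6	FALSE	TRUE	TRUE	TRUE
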