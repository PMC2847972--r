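species	chromosome	marker	position_cM	confidence
eggplant	E4	b1	0	high
eggplant	E4	b2	7	high
eggplant	E4	lcX	11	low
eggplant	E4	b5	14	high
eggplant	E4	b4	21	high
eggplant	E4	b3	28	high
eggplant	E4	TG386	35	high
eggplant	E4	T677	42	high
eggplant	E4	a1	49	high
eggplant	E4	a2	56	high
eggplant	E4	a3	63	high
eggplant	E4	a4	70	high
eggplant	E4	a5	77	high
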