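species	chromosome	marker	position_cM	confidence
tomato	T10	b1	0	high
tomato	T10	b2	10	high
tomato	T10	lcX	15	high
tomato	T10	b3	20	high
tomato	T10	b4	30	high
tomato	T10	b5	40	high
tomato	T10	TG386	50	high
tomato	T4	T677	0	high
tomato	T4	a1	10	high
tomato	T4	a2	20	high
tomato	T4	a3	30	high
tomato	T4	a4	40	high
tomato	T4	a5	50	high
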