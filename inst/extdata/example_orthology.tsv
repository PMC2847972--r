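group_id	species	marker
og_b1	tomato	b1
og_b1	eggplant	b1
og_b2	tomato	b2
og_b2	eggplant	b2
og_lcX	tomato	lcX
og_lcX	eggplant	lcX
og_b3	tomato	b3
og_b3	eggplant	b3
og_b4	tomato	b4
og_b4	eggplant	b4
og_b5	tomato	b5
og_b5	eggplant	b5
og_TG386	tomato	TG386
og_TG386	eggplant	TG386
og_T677	tomato	T677
og_T677	eggplant	T677
og_a1	tomato	a1
og_a1	eggplant	a1
og_a2	tomato	a2
og_a2	eggplant	a2
og_a3	tomato	a3
og_a3	eggplant	a3
og_a4	tomato	a4
og_a4	eggplant	a4
og_a5	tomato	a5
og_a5	eggplant	a5
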