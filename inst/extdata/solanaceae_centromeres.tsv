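# Approximate centromere positions of the reference chromosomes on the
# synthetic 20-marker scaffold (between scaffold markers of rank 10 and 11,
# i.e. gap 10). cM positions assume the scaffold's uniform 5 cM spacing.
chromosome	position_cM	left_marker	right_marker
T1	47.5	T1_M10	T1_M11
T2	47.5	T2_M10	T2_M11
T3	47.5	T3_M10	T3_M11
T4	47.5	T4_M10	T4_M11
T5	47.5	T5_M10	T5_M11
T6	47.5	T6_M10	T6_M11
T7	47.5	T7_M10	T7_M11
T8	47.5	T8_M10	T8_M11
T9	47.5	T9_M10	T9_M11
T10	47.5	T10_M10	T10_M11
T11	47.5	T11_M10	T11_M11
T12	47.5	T12_M10	T12_M11
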