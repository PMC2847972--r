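# Translocation breakpoint regions on the reference axis, one row per
# event-side. Coordinates are gap indices on the synthetic reference marker
# scaffold (20 markers per chromosome; gap g lies between the markers of
# rank g and g+1): the figures behind these observations are not
# machine-readable, so ranks are synthetic, constructed to satisfy every
# stated overlap and centromere-proximity relation. The centromere of each
# scaffold chromosome occupies gap 10.
event_id	lineage	ref_chromosome	gap_lo	gap_hi	note
tr_T1_N_a	Nicotiana	T1	3	4	upper chromosome-1 translocation breakpoint in the most distant lineage
tr_T1_N_b	Nicotiana	T1	16	17	lower chromosome-1 translocation breakpoint in the most distant lineage
tr_T3_P	pepper	T3	14	16	pepper chromosome-3 translocation; overlaps the distant lineage's breakpoint, away from the centromere
tr_T3_N	Nicotiana	T3	15	17	distant-lineage chromosome-3 translocation; overlaps the pepper breakpoint
tr_T3_Eins	eggplant	T3	4	5	insertion site of the chromosome-5 segment into eggplant chromosome 3
tr_T4_E	eggplant	T4	9	11	eggplant chromosome-4 translocation breakpoint, near the centromere
tr_T4_P	pepper	T4	10	12	pepper chromosome-4 translocation breakpoint, near the centromere
tr_T5_E	eggplant	T5	9	10	eggplant chromosome-5 excision breakpoint, near the centromere
tr_T5_P	pepper	T5	10	11	pepper chromosome-5 translocation breakpoint, near the centromere
tr_T5_N	Nicotiana	T5	9	11	distant-lineage chromosome-5 translocation breakpoint, near the centromere
tr_T5_E2	eggplant	T5	15	16	second eggplant excision on chromosome 5, lower arm
tr_T8_P	pepper	T8	5	6	breakpoint of the non-reciprocal translocation producing pepper chromosomes 1 and 8
tr_T9_P	pepper	T9	10	12	pepper chromosome-9 translocation breakpoint, near the centromere
tr_T9_N	Nicotiana	T9	11	13	distant-lineage chromosome-9 translocation breakpoint, near the centromere
tr_T10_E4	eggplant	T10	7	8	chromosome-10 markers moved to eggplant chromosome 4
tr_T10_E10	eggplant	T10	13	14	chromosome-10 markers moved to eggplant chromosome 10
tr_T11_E	eggplant	T11	9	11	eggplant chromosome-11 translocation breakpoint, near the centromere
tr_T11_P	pepper	T11	10	12	pepper chromosome-11 translocation breakpoint, near the centromere
tr_T11_N	Nicotiana	T11	10	11	distant-lineage chromosome-11 translocation breakpoint, near the centromere
tr_T12_E	eggplant	T12	10	12	eggplant breakpoint separating the two chromosome-12 derived segments, near the centromere
tr_T12_P	pepper	T12	11	13	pepper breakpoint separating its chromosome-12 derived segments, near the centromere
tr_T12_N	Nicotiana	T12	11	12	distant-lineage chromosome-12 translocation breakpoint, near the centromere
tr_T12_E12a	eggplant	T12	3	4	breakpoint of the eggplant translocation producing its second chromosome-12 segment
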