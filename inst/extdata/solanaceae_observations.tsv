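# Solanaceae rearrangement observations, one row per event (or per narrated
# event group, with n_min..n_max events). States per species: carrier = order
# differs from the comparison order by this event; ref_order = demonstrably
# shows the non-event order; uninformative = region translocated, scrambled
# or too sparsely mapped in that species. block_lo/block_hi: reference rank
# interval of the inverted block on the synthetic reference scaffold (NA when
# not needed downstream). Reference chromosomes T1-T12 (tomato).
event_id	kind	ref_chromosome	n_min	n_max	block_lo	block_hi	state_tomato	state_potato	state_eggplant	state_pepper	state_Nicotiana	note
inv_T1_E1	inversion	T1	1	1	NA	NA	ref_order	ref_order	carrier	ref_order	ref_order	inversion seen only in eggplant chromosome 1
inv_T1_P1b_peri1	inversion	T1	1	1	8	13	ref_order	ref_order	ref_order	carrier	uninformative	pericentric inversion distinguishing pepper P1b from the chromosome-1 ancestor; distant species translocated in this region
inv_T1_P1b_peri2	inversion	T1	1	1	9	12	ref_order	ref_order	ref_order	carrier	uninformative	second pericentric inversion on P1b
inv_T1_P1b_para1	inversion	T1	1	1	2	5	ref_order	ref_order	ref_order	carrier	uninformative	paracentric inversion on P1b, top arm
inv_T1_P1b_para2	inversion	T1	1	1	14	18	ref_order	ref_order	ref_order	carrier	uninformative	paracentric inversion on P1b, bottom arm
inv_T2_shared	inversion	T2	1	1	NA	NA	ref_order	carrier	carrier	carrier	uninformative	potato and eggplant (and pepper) share one inversion relative to tomato chromosome 2
inv_T2_E2	inversion	T2	2	2	NA	NA	ref_order	ref_order	carrier	ref_order	uninformative	two further inversions in eggplant chromosome 2 not seen in pepper
inv_T2_P2	inversion	T2	2	2	NA	NA	ref_order	ref_order	ref_order	carrier	uninformative	two inversions between pepper and the chromosome-2 ancestor; most distant species unusable for timing
inv_T3_E3	inversion	T3	2	2	NA	NA	ref_order	ref_order	carrier	ref_order	ref_order	at least two inversions in eggplant chromosome-3 orthologs
inv_T3_P	inversion	T3	2	2	NA	NA	ref_order	ref_order	ref_order	carrier	uninformative	two inversions between pepper and the chromosome-3 ancestor
inv_T4_E11b	inversion	T4	3	3	NA	NA	ref_order	ref_order	carrier	ref_order	uninformative	three derived inversions on eggplant segment E11b
inv_T4_P5a	inversion	T4	1	1	NA	NA	ref_order	ref_order	ref_order	carrier	uninformative	inversion on pepper segment P5a, timing unknown
inv_T5_shared	inversion	T5	1	1	NA	NA	ref_order	carrier	carrier	carrier	uninformative	potato, eggplant and pepper share one inversion relative to tomato chromosome 5
inv_T5_ATE	inversion	T5	1	1	NA	NA	ref_order	ref_order	ref_order	carrier	carrier	pepper and the most distant species share one inversion relative to the chromosome-5 ancestor
inv_T5_E	inversion	T5	1	1	NA	NA	ref_order	ref_order	carrier	ref_order	uninformative	inversion accompanying the eggplant chromosome-5 translocation, derived in eggplant
inv_T6_top	inversion	T6	1	1	NA	NA	ref_order	ref_order	carrier	carrier	uninformative	eggplant and pepper share an inversion near the top of chromosome 6
inv_T6_bottom	inversion	T6	1	1	NA	NA	ref_order	ref_order	carrier	uninformative	carrier	eggplant and the most distant species share an inversion near the bottom of chromosome 6
inv_T6_P6	inversion	T6	1	1	NA	NA	uninformative	uninformative	ref_order	carrier	ref_order	one additional inversion private to pepper chromosome 6
inv_T7_E7	inversion	T7	1	1	NA	NA	ref_order	ref_order	carrier	ref_order	uninformative	derived inversion in eggplant chromosome 7
inv_T9	inversion	T9	1	1	NA	NA	ref_order	carrier	carrier	carrier	uninformative	one inversion separating tomato chromosome 9 from all informative relatives
inv_T10_T	inversion	T10	1	1	NA	NA	ref_order	carrier	uninformative	carrier	uninformative	derived inversion in tomato chromosome 10
inv_T10_E	inversion	T10	5	5	NA	NA	ref_order	ref_order	carrier	ref_order	uninformative	five inversions in the eggplant chromosome-10 orthologs
inv_T11_Pt	inversion	T11	1	1	NA	NA	ref_order	carrier	ref_order	ref_order	uninformative	inversion private to potato chromosome 11
inv_T11_shared	inversion	T11	2	2	NA	NA	ref_order	ref_order	carrier	carrier	uninformative	eggplant and pepper share two inversions relative to the tomato-potato ancestor
inv_T11_P	inversion	T11	1	1	NA	NA	ref_order	ref_order	ref_order	carrier	uninformative	one additional pepper inversion on chromosome 11, timing unknown
inv_T12_Pt	inversion	T12	1	1	NA	NA	ref_order	carrier	uninformative	ref_order	uninformative	inversion between tomato and potato chromosome 12; tomato agrees with pepper
inv_T12_E10b	inversion	T12	1	1	NA	NA	ref_order	ref_order	carrier	ref_order	uninformative	inversion on eggplant segment E10b, derived in eggplant
inv_T12_P12c	inversion	T12	1	1	NA	NA	ref_order	ref_order	ref_order	carrier	uninformative	inversion between pepper segment P12c and tomato chromosome 12, timing unknown
tr_T3_E3b_insert	translocation	T3	1	1	NA	NA	ref_order	ref_order	carrier	ref_order	ref_order	chromosome-5 segment inserted into eggplant chromosome 3 (embedded segment)
tr_T12_E10_insert	translocation	T12	1	1	NA	NA	ref_order	ref_order	carrier	ref_order	ref_order	chromosome-12 segment inserted into eggplant chromosome 10
tr_T10_E4_E10	translocation	T10	1	2	NA	NA	ref_order	ref_order	carrier	ref_order	ref_order	chromosome-10 markers moved to eggplant chromosomes 4 and 10; one or two events
tr_T8_P1_P8	translocation	T8	1	1	NA	NA	ref_order	ref_order	ref_order	carrier	ref_order	non-reciprocal translocation producing pepper chromosomes 1 and 8
tr_T4_P12_insert	translocation	T4	1	1	NA	NA	ref_order	ref_order	uninformative	carrier	ref_order	small chromosome-4 segment inserted into pepper chromosome 12
tr_T12_P3_insert	translocation	T12	1	1	NA	NA	ref_order	ref_order	uninformative	carrier	ref_order	small chromosome-12 segment inserted into pepper chromosome 3
tr_T4_AE	translocation	T4	1	1	NA	NA	ref_order	ref_order	carrier	uninformative	uninformative	chromosome 4 rearranged in the tomato-potato ancestor and/or eggplant
tr_T5_AE	translocation	T5	1	1	NA	NA	ref_order	ref_order	carrier	uninformative	uninformative	chromosome 5 rearranged in the tomato-potato ancestor and/or eggplant
tr_T11_AE	translocation	T11	1	1	NA	NA	ref_order	ref_order	carrier	uninformative	uninformative	chromosome 11 rearranged in the tomato-potato ancestor and/or eggplant
tr_T12_AE	translocation	T12	1	1	NA	NA	ref_order	ref_order	carrier	uninformative	uninformative	chromosome 12 rearranged in the tomato-potato ancestor and/or eggplant
tr_T3_AP	translocation	T3	1	1	NA	NA	ref_order	ref_order	ref_order	carrier	uninformative	chromosome 3 rearranged in the three-species ancestor and/or pepper
tr_T4_AP	translocation	T4	1	1	NA	NA	ref_order	ref_order	ref_order	carrier	uninformative	chromosome 4 rearranged in the three-species ancestor and/or pepper
tr_T5_AP	translocation	T5	1	1	NA	NA	ref_order	ref_order	ref_order	carrier	uninformative	chromosome 5 rearranged in the three-species ancestor and/or pepper
tr_T9_AP	translocation	T9	1	1	NA	NA	ref_order	ref_order	ref_order	carrier	uninformative	chromosome 9 rearranged in the three-species ancestor and/or pepper
tr_T11_AP	translocation	T11	1	1	NA	NA	ref_order	ref_order	ref_order	carrier	uninformative	chromosome 11 rearranged in the three-species ancestor and/or pepper
tr_T12_AP	translocation	T12	1	1	NA	NA	ref_order	ref_order	ref_order	carrier	uninformative	chromosome 12 rearranged in the three-species ancestor and/or pepper
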