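# SYNTHETIC, illustrative motif annotation for a MEF100-like PLS editing factor.
# The motif-type layout follows the described architecture of the protein
# (17 P/L/S motifs with P1 at 9 and 12, S1 at 11, P2 at 15, S2 at 17, then
# E1-E2-DYW), but the aa5/aa_last code residues are NOT transcribed from any
# published figure: they are plausible residues drawn from well-known
# PPR-code combinations. Do not use as a reference annotation.
protein_id	motif_index	motif_type	aa5	aa_last
MEF100-like	1	P1	T	N
MEF100-like	2	L1	N	D
MEF100-like	3	S1	N	D
MEF100-like	4	P1	T	D
MEF100-like	5	L1	S	N
MEF100-like	6	S1	T	N
MEF100-like	7	P1	N	S
MEF100-like	8	L1	T	D
MEF100-like	9	P1	T	N
MEF100-like	10	L1	N	N
MEF100-like	11	S1	N	D
MEF100-like	12	P1	S	N
MEF100-like	13	L1	T	D
MEF100-like	14	S1	N	S
MEF100-like	15	P2	T	N
MEF100-like	16	L2	N	D
MEF100-like	17	S2	N	S
MEF100-like	18	E1	G	N
MEF100-like	19	E2	G	D
MEF100-like	20	DYW	H	W
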