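# Published edited/total read counts at the seven differentially edited
# mitochondrial positions, for the wild type (Col-0) and the editing-factor
# loss-of-function mutant. codon_ref / codon_edit_pos give the affected
# codon and the 1-based position of the edited C within it, as implied by
# the annotation column. The codon context of the synonymous site 215479 is
# not published (only the 'synonymous' label is); GGC/3 here is a
# representative synthetic stand-in with the same consequence (G -> G).
position	site_id	annotation	codon_ref	codon_edit_pos	wt_edited	wt_total	mut_edited	mut_total
59314	nad1-493	CGT(R) to TGT(C)	CGT	1	413	433	381	6304
59321	nad1-500	TCG(S) to TTG(L)	TCG	2	1002	1130	13358	16837
291935	ccmFN2-356	TCA(S) to TTA(L)	TCA	2	38	40	0	712
215160	nad4-403	CGC(R) to TGC(C)	CGC	1	291	301	13	5429
215468	nad4-95	TCA(S) to TTA(L)	TCA	2	32	716	254	14186
215479	nad4-84	synonymous	GGC	3	197	524	1606	8731
241553	nad7-698	TCG(S) to TTG(L)	TCG	2	813	918	20	15966
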