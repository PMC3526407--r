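# Published benchmark compendium: 11 human microarray datasets (Affymetrix
# HG-U133A, 22283 probesets) with RT-PCR-verified differentially expressed
# genes, used for ROC-based ranker comparison.
# n_a, n_b: class sample sizes; n_pc: RT-PCR-confirmed DEGs; n_ka: DEGs
# reported in the originating comparison catalogue.
dataset	n_a	n_b	n_pc	n_ka
GSE8441	11	11	9	5
GSE9499	15	7	77	6
GSE2639	7	7	13	8
GSE2638	3	4	16	9
GSE3860	9	9	8	11
GSE6344	10	10	19	15
GSE7765	3	3	13	18
GSE6740_1	10	10	40	24
GSE6740_2	10	10	62	25
GSE6011	14	23	10	30
GSE2531	3	4	17	36
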