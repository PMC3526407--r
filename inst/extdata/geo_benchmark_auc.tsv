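# Published per-dataset AUC values of three rankers (Welch t-test,
# shrinkage t-test, DFC test) on the 11-dataset benchmark, under two
# preprocessing pipelines (MAS5, RMA).  n_s: total samples.
dataset	n_s	t_mas5	shrinkt_mas5	dfc_mas5	t_rma	shrinkt_rma	dfc_rma
GSE8441	22	0.92912	0.94404	0.96996	0.91206	0.92842	0.96812
GSE9499	22	0.96425	0.98255	0.98529	0.94735	0.97241	0.9718
GSE2639	14	0.99782	0.99838	0.9987	0.99851	0.99784	0.99896
GSE2638	7	0.79197	0.83621	0.86199	0.75527	0.82421	0.83175
GSE3860	18	0.98986	0.99581	0.99742	0.98647	0.99246	0.99568
GSE6344	20	0.97165	0.98078	0.98854	0.97586	0.98216	0.9889
GSE7765	6	0.96323	0.97846	0.98564	0.96267	0.98146	0.98939
GSE6740_1	20	0.99491	0.99676	0.99701	0.9972	0.99803	0.99803
GSE6740_2	20	0.99115	0.99313	0.99283	0.97599	0.98248	0.98487
GSE6011	37	0.86072	0.8674	0.90942	0.97544	0.98126	0.97892
GSE2531	7	0.91614	0.94288	0.9379	0.93889	0.94368	0.94107
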