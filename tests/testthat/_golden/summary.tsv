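metric	value
n_pas_clusters	47
n_tpa	41
n_ipa	6
n_genes_apa	10
n_diff_stability	2
median_re_cellA	-0.6228
median_re_cellB	-0.8751
median_re_cellC	-0.8291
blue_cellA	7
red_cellA	0
blue_red_ratio_cellA	NA
blue_cellB	8
red_cellB	0
blue_red_ratio_cellB	NA
blue_cellC	6
red_cellC	0
blue_red_ratio_cellC	NA
median_delta_ss_ipa	-1.8834
median_ss_lncRNA	-0.7281
median_ss_mRNA	-0.2392
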