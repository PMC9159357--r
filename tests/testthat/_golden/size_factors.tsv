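sample_id	size_factor
cellA_total_1	0.984871944773922
cellA_total_2	1.00847914267484
cellA_4sU_1	0.975057014671841
cellA_4sU_2	1.05643850864039
cellA_FT_1	0.94480941098146
cellA_FT_2	1.01424100043311
cellB_total_1	0.988565567134657
cellB_total_2	0.959814316489414
cellB_4sU_1	0.933310016313314
cellB_4sU_2	1.00240546934128
cellB_FT_1	0.97493664421814
cellB_FT_2	1.03291535450799
cellC_total_1	1.03325482539864
cellC_total_2	1.0269591484294
cellC_4sU_1	1.02664101794464
cellC_4sU_2	1.01073615088944
cellC_FT_1	1.03360151612072
cellC_FT_2	1.0025830578994
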