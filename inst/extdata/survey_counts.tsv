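key	value
srna_total	489
significant_interactions	735
site_mismatch_interactions	16
double_guide_srnas	262
no_target_srnas	163
events_16S	266
single_16S	152
multi_16S	43
events_23S	453
single_23S	255
multi_23S	79
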