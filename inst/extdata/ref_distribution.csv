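depth,final_delta_slope,se_slope,nc_acc_bin1_pct,se_nc_acc_bin1
dorsal,0.08,0.05,71.07,7.4
ventral,-0.11,0.09,69.01,7.1
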