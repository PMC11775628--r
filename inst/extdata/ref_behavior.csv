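depth,correspondence,mean_rt_ms,se_rt_ms,accuracy_pct,se_acc
dorsal,Cs,583.0,42.5,88.54,4.9
dorsal,NC,625.1,42.2,81.89,6.3
ventral,Cs,568.2,38.1,89.32,3.8
ventral,NC,599.2,32.4,84.98,4.7
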