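subregion,hemisphere_rel,correspondence,mean_log_power,se
dorsal,ipsilateral,Cs,0.67,0.04
dorsal,contralateral,Cs,0.68,0.03
dorsal,ipsilateral,NC,0.76,0.04
dorsal,contralateral,NC,0.84,0.03
ventral,ipsilateral,Cs,0.64,0.03
ventral,contralateral,Cs,0.60,0.04
ventral,ipsilateral,NC,0.66,0.03
ventral,contralateral,NC,0.65,0.03
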