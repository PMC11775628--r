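subregion,hemisphere_rel,correspondence,mean_log_power,se
dorsal,ipsilateral,Cs,1.45,0.07
dorsal,contralateral,Cs,1.75,0.09
dorsal,ipsilateral,NC,1.65,0.07
dorsal,contralateral,NC,1.73,0.07
ventral,ipsilateral,Cs,1.48,0.06
ventral,contralateral,Cs,1.55,0.08
ventral,ipsilateral,NC,1.65,0.07
ventral,contralateral,NC,1.47,0.08
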