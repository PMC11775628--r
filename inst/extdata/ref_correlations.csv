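subregion,band,measure,rho
dorsal,theta,simon_rt_ms,-0.24
dorsal,beta,simon_rt_ms,0.26
ventral,theta,simon_rt_ms,0.08
ventral,beta,simon_rt_ms,0.32
dorsal,theta,simon_acc_pct,-0.26
dorsal,beta,simon_acc_pct,-0.26
ventral,theta,simon_acc_pct,0.12
ventral,beta,simon_acc_pct,0.78
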