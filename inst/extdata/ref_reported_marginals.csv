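band,scope,mean_log_power
theta,dorsal,0.74
theta,ventral,0.64
theta,Cs,0.65
theta,NC,0.73
theta,dorsal_NC,0.80
theta,dorsal_Cs,0.68
theta,ventral_NC,0.66
theta,ventral_Cs,0.62
beta,dorsal,1.64
beta,ventral,1.54
beta,ipsilateral_Cs,1.47
beta,ipsilateral_NC,1.65
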