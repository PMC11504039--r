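metric,group,in_vitro,in_silico
rf_pct,raw,10.84,17.14
rf_pct,static,9.50,20.56
rf_pct,bioreactor,10.16,24.56
delta_p_mmHg,raw,6.38,8.10
delta_p_mmHg,static,9.84,11.50
delta_p_mmHg,bioreactor,7.37,8.40
q_rms_mls,raw,127.35,120.81
q_rms_mls,static,137.14,125.13
q_rms_mls,bioreactor,145.24,130.89
eoa_cm2,raw,0.98,0.82
eoa_cm2,static,0.84,0.72
eoa_cm2,bioreactor,1.04,0.88
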