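group,in_vitro,in_silico
raw,3.24,3.08
static,2.26,2.76
bioreactor,2.83,2.96
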