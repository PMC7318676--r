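species_id,K,temperature_C,pH,source
uridine,0.16,60,9,endpoint fit at 60 C pH 9 glycine buffer
adenosine,0.01,60,9,endpoint fit at 60 C pH 9 glycine buffer
5-ethynyluridine,0.35,60,9,endpoint fit at 60 C pH 9 glycine buffer
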