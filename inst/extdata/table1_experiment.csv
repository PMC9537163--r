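nu_cm1,mu_debye,fwhm_cm1
1135,0.30,19.4
1280,0.38,19.4
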