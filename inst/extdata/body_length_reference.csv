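species,mean_mm,sd_mm,max_mm,min_mm
Eisenia japonica,167.02,13.62,190.73,131.44
Metaphire hilgendorfi,199.28,10.05,220.38,145.33
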