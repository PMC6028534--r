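phase,total_axis_length_um,total_axis_length_sd_um,SMC4,SMC4_sd,CAP_D2,CAP_D2_sd,CAP_H,CAP_H_sd,CAP_D3,CAP_D3_sd,CAP_H2,CAP_H2_sd
prometaphase,1311.7,245.2,247952,43519,152558,20965,145478,27626,73267,14861,36451,13604
metaphase,1162.5,190.4,252652,39130,153519,22952,140965,26521,71408,14999,34543,12521
anaphase,923.1,120.7,325522,48878,216857,32900,194427,37121,71244,16174,34677,13294
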