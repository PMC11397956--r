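device,tn,der_printed,specificity_printed,accuracy_printed
chest_ecg,38059993,0.002,99.999,99.998
rr_device,37454530,0.055,99.969,99.945
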