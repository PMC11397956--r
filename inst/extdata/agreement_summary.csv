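device,quantity,activity,mean_diff_ms,reference_mean_ms,percent_printed
chest_ecg,rr,rest_pre,0.23,887.8,0.03
chest_ecg,rr,incremental,0.38,400.5,0.09
chest_ecg,rr,rest_post,0.47,574.3,0.08
rr_device,rr,rest_pre,8.48,887.8,-0.96
rr_device,rr,incremental,27.69,400.5,6.91
rr_device,rr,rest_post,13.93,574.3,2.43
chest_ecg,rr_sd,rest_pre,-0.92,95.54,-0.96
rr_device,rr_sd,rest_pre,-22.70,95.54,-23.76
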