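activity,exercise,participants,tp,fn,sensitivity_printed,fp,precision_printed
rest_pre,running,14,4658,23,99.51,27,99.42
rest_pre,cycling,7,2669,3,99.89,5,99.81
incremental,running,11,40163,175,99.56,249,99.38
incremental,cycling,7,23988,33,99.86,21,99.91
rest_post,running,12,6463,31,99.52,30,99.54
rest_post,cycling,7,3635,17,99.53,16,99.56
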