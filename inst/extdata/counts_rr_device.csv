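activity,exercise,participants,tp,fn,sensitivity_printed,fp,precision_printed
rest_pre,running,12,3658,176,95.41,211,94.55
rest_pre,cycling,7,2462,214,92.00,288,89.53
incremental,running,11,31106,6059,83.70,4005,88.59
incremental,cycling,7,18877,4924,79.31,4382,81.16
rest_post,running,12,5592,145,97.47,57,98.99
rest_post,cycling,7,3261,116,96.56,87,97.40
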