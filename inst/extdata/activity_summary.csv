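activity,exercise,participants,avg_rr_ms,avg_hr_bpm,avg_max_hr_bpm,avg_rr_sd_ms
rest_pre,running,14,927.6,64.7,85.8,97.1
rest_pre,cycling,7,808.2,74.2,98.2,92.5
incremental,running,11,390.3,153.7,201.5,53.0
incremental,cycling,7,416.5,144.1,192.0,64.8
rest_post,running,12,562.9,106.6,122.7,23.5
rest_post,cycling,7,593.8,101.0,115.7,28.5
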