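# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite runs in minutes.

# short three-activity session: 30 s rest, 60 s ramp, 30 s recovery
short_profile <- function(seed = 42, sdnn = c(50, 30, 20)) {
  protocol_profile(
    data.frame(duration_s = c(30, 60, 30),
               hr_start = c(60, 100, 100),
               hr_end = c(60, 180, 95),
               label = c("rest_pre", "incremental", "rest_post"),
               sdnn_ms = sdnn),
    seed = seed
  )
}

# constant-rate beat train (epoch ms)
steady_beats <- function(n = 60, rr_ms = 1000, start = 1.7e12) {
  start + seq_len(n) * rr_ms
}

# clean steady-rhythm record
steady_record <- function(n = 12, rr_ms = 1000, fs = 500, ...) {
  synthesize_ecg(steady_beats(n, rr_ms), fs = fs,
                 morphology = morphology_config(...))
}
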