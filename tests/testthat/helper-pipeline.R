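# Expensive shared fixtures, computed lazily once per test session.

.fixtures <- new.env(parent = emptyenv())

# one default-condition subject (seed 7 stream), preprocessed
cached_subject <- function() {
  if (is.null(.fixtures$subject)) {
    cfg <- sim_config(seed = 7L)
    rec <- simulate_swine_subject(cfg, subject_seed = 7001L,
                                  subject_id = "S01", group_id = 0L)
    sig <- preprocess_waveform(rec$waveform, "non_detrended")
    beats <- detect_beats(sig)
    .fixtures$subject <- list(cfg = cfg, rec = rec, sig = sig, beats = beats)
  }
  .fixtures$subject
}

# the full 12-subject default-condition pipeline (BLVM + PEBL, non-detrended)
cached_pipeline <- function() {
  if (is.null(.fixtures$pipeline)) {
    .fixtures$pipeline <- run_swine_pipeline(sim_config(seed = 7L))
  }
  .fixtures$pipeline
}
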