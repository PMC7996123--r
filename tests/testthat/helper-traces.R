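# Strip the run metadata (storyline, seed, clamp log) so traces can be
# compared value-by-value.
trace_df <- function(tr) {
  df <- as.data.frame(tr)
  attr(df, "storyline") <- NULL
  attr(df, "seed") <- NULL
  attr(df, "clamp_events") <- NULL
  df
}
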