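# Shared fixture builders.

test_channels <- c("C4", "nasal_pressure", "SpO2")

# The two planted recording regimes used in end-to-end studies: a severely
# fragmented, event-dense night versus consolidated sleep (stages still
# change every few minutes, as in normal sleep) with rare events.
regime_recording_spec <- function(high_risk, n_epochs, seed,
                                  channels = test_channels) {
  recording_spec(
    n_epochs = n_epochs, channels = channels,
    stage_transition_rate = if (high_risk) 30 else 12,
    respiratory_event_rate = if (high_risk) 35 else 2,
    desaturation_event_rate = if (high_risk) 30 else 2,
    seed = seed
  )
}

# One preprocessed, labeled entry for build_epoch_dataset().
make_labeled_entry <- function(spec, id = "rec") {
  r <- generate_recording(spec)
  list(psg = preprocess_recording(r$psg),
       labels = derive_epoch_labels(r$hypnogram, r$events),
       id = id)
}

# Hypnogram-only summary metrics for n recordings with per-recording
# transition rates; fast (no signal synthesis).
metrics_for_rates <- function(rates, n_epochs = 240, seed = 1) {
  out <- vector("list", length(rates))
  for (i in seq_along(rates)) {
    r <- generate_recording(
      recording_spec(n_epochs = n_epochs, channels = "C4",
                     stage_transition_rate = rates[i],
                     respiratory_event_rate = 6,
                     desaturation_event_rate = 6,
                     seed = seed + i),
      signals = FALSE)
    out[[i]] <- summarize_psg(r$hypnogram, r$events)
  }
  dplyr::bind_rows(out)
}

# 1-D embedding matrices drawn around regime centers (wide separation).
make_regime_embeddings <- function(centers, per_regime = 8, n_cols = 30,
                                   sd = 0.05, seed = 1) {
  set.seed(seed)
  embs <- list()
  truth <- integer(0)
  for (g in seq_along(centers)) {
    for (i in seq_len(per_regime)) {
      embs[[length(embs) + 1]] <-
        matrix(rnorm(n_cols, centers[g], sd), nrow = 1)
      truth <- c(truth, g)
    }
  }
  list(embeddings = embs, truth = truth)
}
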