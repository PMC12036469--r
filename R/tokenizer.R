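#' Model configuration for the epoch-embedding transformer
#'
#' One 30-s epoch is tokenized as ten non-overlapping 3-s patches per channel
#' (384 samples at 128 Hz), each linearly projected to `embed_dim`. Per
#' channel the ten tokens are followed by a learned SEP token; a learned CLS
#' token closes the sequence, giving length `11 * n_channels + 1`. The CLS
#' output feeds three task heads: 5-class sleep stage, respiratory flag, and
#' desaturation flag.
#'
#' The default is a desk-scale configuration (64-dim, 2 layers, 4 heads)
#' trainable from scratch in minutes on one CPU; the full-scale 768-dim /
#' 12-layer configuration is constructible with the same fields. The default
#' learning rate of 1e-3 suits a few epochs of from-scratch training at this
#' scale; fine-tuning a large pre-trained backbone would use a much smaller
#' rate (on the order of 1e-5).
#'
#' @param channel_order Ordered character vector of channel names.
#' @param embed_dim Internal representation size (divisible by `n_heads`).
#' @param n_layers Number of encoder blocks.
#' @param n_heads Attention heads.
#' @param patch_seconds Patch duration; with `patches_per_epoch` must tile 30 s.
#' @param patches_per_epoch Patches per channel per epoch.
#' @param sample_rate_hz Input rate after preprocessing.
#' @param stage_classes Number of sleep-stage classes (5 = W, N1, N2, N3, REM).
#' @param learning_rate Adam step size.
#' @param batch_size Epoch samples per optimization step.
#' @param n_epochs_train Training passes over the dataset.
#' @param seed Seed for initialization and batch shuffling.
#' @return An object of class `model_config`.
#' @export
model_config <- function(channel_order,
                         embed_dim = 64, n_layers = 2, n_heads = 4,
                         patch_seconds = 3, patches_per_epoch = 10,
                         sample_rate_hz = 128, stage_classes = 5,
                         learning_rate = 1e-3, batch_size = 128,
                         n_epochs_train = 5, seed = 1L) {
  assert_that(patch_seconds * patches_per_epoch == 30,
              "`patch_seconds * patches_per_epoch` must equal 30 s")
  assert_that(embed_dim %% n_heads == 0,
              "`embed_dim` must be divisible by `n_heads`")
  assert_that(length(channel_order) >= 1, "`channel_order` must be non-empty")
  structure(list(channel_order = channel_order,
                 embed_dim = as.integer(embed_dim),
                 n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 patch_seconds = patch_seconds,
                 patches_per_epoch = as.integer(patches_per_epoch),
                 sample_rate_hz = sample_rate_hz,
                 stage_classes = as.integer(stage_classes),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 n_epochs_train = as.integer(n_epochs_train),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Token-sequence length for a channel count
#'
#' Ten patch tokens plus one SEP per channel, plus the closing CLS:
#' `11 * n_channels + 1`.
#'
#' @param n_channels Number of channels (>= 1).
#' @return Integer sequence length.
#' @export
seq_token_length <- function(n_channels) {
  assert_that(all(n_channels >= 1), "`n_channels` must be >= 1")
  as.integer(11 * n_channels + 1)
}

#' Derive per-epoch labels from a hypnogram and annotations
#'
#' An epoch is flagged for an event type when annotations of that type
#' overlap it by at least five seconds in total; the sleep stage is copied
#' from the hypnogram.
#'
#' @param hypnogram Tibble with columns `epoch` and `stage`.
#' @param events Tibble with columns `start_s`, `duration_s`, `type`
#'   (types `respiratory`, `desaturation`, `arousal`).
#' @param epoch_s Epoch duration in seconds.
#' @param min_overlap_s Minimum total overlap for a flag.
#' @return Tibble with columns `epoch`, `stage`, `respiratory_flag`,
#'   `desaturation_flag`.
#' @export
derive_epoch_labels <- function(hypnogram, events, epoch_s = 30,
                                min_overlap_s = 5) {
  known <- c("respiratory", "desaturation", "arousal")
  bad <- setdiff(unique(events$type), known)
  if (length(bad) > 0) {
    abort(paste0("unknown event type(s): ", paste(bad, collapse = ", ")))
  }
  n_ep <- nrow(hypnogram)
  flag_for <- function(type) {
    ov <- numeric(n_ep)
    ev <- events[events$type == type, , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      s <- ev$start_s[i]
      e <- s + ev$duration_s[i]
      ep_lo <- max(1L, floor(s / epoch_s) + 1L)
      ep_hi <- min(n_ep, ceiling(e / epoch_s))
      for (ep in seq(ep_lo, length.out = max(0, ep_hi - ep_lo + 1))) {
        lo <- (ep - 1) * epoch_s
        ov[ep] <- ov[ep] + max(0, min(e, lo + epoch_s) - max(s, lo))
      }
    }
    as.integer(ov >= min_overlap_s)
  }
  tibble(epoch = hypnogram$epoch,
         stage = hypnogram$stage,
         respiratory_flag = flag_for("respiratory"),
         desaturation_flag = flag_for("desaturation"))
}

#' Lay out the token sequence for one epoch
#'
#' Slices per-channel 30-s signals into the patch matrix and describes the
#' token layout (patch tokens, per-channel SEP delimiters, trailing CLS).
#' The learned projection of patches happens inside the model; this operation
#' exposes the tokenizer arithmetic.
#'
#' @param epoch_signals Named list of numeric vectors, one 30-s window per
#'   channel at `cfg$sample_rate_hz`.
#' @param cfg A [model_config()].
#' @return List with `patches` (patch-length x `10 * n_channels` matrix),
#'   `layout` (tibble `position`, `kind`, `channel`), and `length`.
#' @export
build_token_sequence <- function(epoch_signals, cfg) {
  plen <- cfg$patch_seconds * cfg$sample_rate_hz
  need <- plen * cfg$patches_per_epoch
  C <- length(cfg$channel_order)
  patches <- matrix(0, plen, cfg$patches_per_epoch * C)
  layout <- vector("list", C)
  for (ci in seq_len(C)) {
    nm <- cfg$channel_order[ci]
    x <- epoch_signals[[nm]]
    assert_that(!is.null(x), paste0("missing channel: ", nm))
    assert_that(length(x) == need,
                sprintf("channel %s has %d samples; expected %d", nm,
                        length(x), need))
    patches[, (ci - 1) * cfg$patches_per_epoch + seq_len(cfg$patches_per_epoch)] <-
      matrix(x, plen)
    layout[[ci]] <- tibble(
      kind = c(rep("patch", cfg$patches_per_epoch), "SEP"),
      channel = nm
    )
  }
  layout <- bind_rows(layout)
  layout <- bind_rows(layout, tibble(kind = "CLS", channel = NA_character_))
  layout$position <- seq_len(nrow(layout))
  list(patches = patches,
       layout = layout[, c("position", "kind", "channel")],
       length = nrow(layout))
}
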