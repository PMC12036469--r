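#' Initialize the epoch-embedding transformer
#'
#' Weights are drawn N(0, 0.02^2) (layer-norm gains 1, biases 0), the
#' convention of the RoBERTa family this architecture follows. The patch
#' projection is shared across channels; learned absolute position embeddings
#' carry channel identity.
#'
#' @param cfg A [model_config()].
#' @return An object of class `sleep_model` with elements `config`, `weights`
#'   and (after training) `loss_history`.
#' @export
sleep_model_init <- function(cfg) {
  assert_that(inherits(cfg, "model_config"), "`cfg` must be a model_config")
  set.seed(cfg$seed)
  D <- cfg$embed_dim
  C <- length(cfg$channel_order)
  L <- seq_token_length(C)
  plen <- cfg$patch_seconds * cfg$sample_rate_hz
  rn <- function(nr, nc) matrix(rnorm(nr * nc, 0, 0.02), nr, nc)
  w <- list(
    Wp = rn(plen, D), bp = matrix(0, 1, D),
    sep = rn(1, D), cls = rn(1, D), pos = rn(L, D),
    g_emb = matrix(1, 1, D), b_emb = matrix(0, 1, D)
  )
  for (l in seq_len(cfg$n_layers)) {
    w[[paste0("Wq", l)]] <- rn(D, D); w[[paste0("bq", l)]] <- matrix(0, 1, D)
    w[[paste0("Wk", l)]] <- rn(D, D); w[[paste0("bk", l)]] <- matrix(0, 1, D)
    w[[paste0("Wv", l)]] <- rn(D, D); w[[paste0("bv", l)]] <- matrix(0, 1, D)
    w[[paste0("Wo", l)]] <- rn(D, D); w[[paste0("bo", l)]] <- matrix(0, 1, D)
    w[[paste0("W1", l)]] <- rn(D, 4 * D); w[[paste0("b1", l)]] <- matrix(0, 1, 4 * D)
    w[[paste0("W2", l)]] <- rn(4 * D, D); w[[paste0("b2", l)]] <- matrix(0, 1, D)
    w[[paste0("g_ln1", l)]] <- matrix(1, 1, D); w[[paste0("b_ln1", l)]] <- matrix(0, 1, D)
    w[[paste0("g_ln2", l)]] <- matrix(1, 1, D); w[[paste0("b_ln2", l)]] <- matrix(0, 1, D)
  }
  w$Ws <- rn(D, cfg$stage_classes); w$bs <- matrix(0, 1, cfg$stage_classes)
  w$Wr <- rn(D, 1); w$br <- matrix(0, 1, 1)
  w$Wd <- rn(D, 1); w$bd <- matrix(0, 1, 1)
  w$n_layers <- cfg$n_layers
  w$n_heads <- cfg$n_heads
  structure(list(config = cfg, weights = w, loss_history = NULL),
            class = "sleep_model")
}

#' Number of trainable parameters
#' @param model A [sleep_model_init()] result.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$weights, function(x) if (is.matrix(x)) length(x) else 0L, 0))
}

#' @export
print.sleep_model <- function(x, ...) {
  cfg <- x$config
  cat("<sleep_model> ", cfg$embed_dim, "-dim, ", cfg$n_layers, " layers, ",
      cfg$n_heads, " heads, ", length(cfg$channel_order), " channels (",
      format(n_parameters(x), big.mark = ","), " parameters)\n", sep = "")
  if (!is.null(x$loss_history)) {
    cat("  trained ", nrow(x$loss_history), " epochs; final loss ",
        signif(utils::tail(x$loss_history$loss, 1), 4), "\n", sep = "")
  }
  invisible(x)
}

#' Assemble an epoch-level training dataset
#'
#' Slices preprocessed recordings into per-epoch patch tensors and pairs them
#' with epoch labels. Labels may be omitted (embedding-only datasets).
#'
#' @param recordings List of entries, each a list with `psg` (a preprocessed
#'   [psg_recording()] at the model's sample rate) and optionally `labels`
#'   (from [derive_epoch_labels()]) and `id`. Alternatively a function of the
#'   recording index returning one such entry: recordings are then produced
#'   and discarded one at a time, so large cohorts never coexist in memory
#'   (requires `n_recordings`, and a constant epoch count across recordings).
#' @param cfg A [model_config()].
#' @param n_recordings Number of recordings when `recordings` is a generator
#'   function.
#' @return A list with the patch array `X` (patch_len x patches x epochs),
#'   integer `stage` (1..5, NA when unlabeled), numeric `resp`/`desat`, and
#'   `recording_id`/`epoch` indices.
#' @export
build_epoch_dataset <- function(recordings, cfg, n_recordings = NULL) {
  if (is.function(recordings)) {
    gen <- recordings
    assert_that(!is.null(n_recordings),
                "`n_recordings` is required with a generator function")
    return(build_epoch_dataset_streaming(gen, cfg, n_recordings))
  }
  plen <- cfg$patch_seconds * cfg$sample_rate_hz
  C <- length(cfg$channel_order)
  P <- cfg$patches_per_epoch * C
  n_total <- sum(vapply(recordings, function(r) r$psg$n_epochs, 0L))
  X <- array(0, dim = c(plen, P, n_total))
  stage <- integer(n_total)
  resp <- numeric(n_total)
  desat <- numeric(n_total)
  rec_id <- character(n_total)
  epoch_ix <- integer(n_total)
  off <- 0L
  for (ri in seq_along(recordings)) {
    r <- recordings[[ri]]
    ne <- r$psg$n_epochs
    for (ci in seq_len(C)) {
      nm <- cfg$channel_order[ci]
      sig <- r$psg$signals[[nm]]
      assert_that(!is.null(sig), paste0("recording ", ri, " missing channel ", nm))
      assert_that(r$psg$rates[[nm]] == cfg$sample_rate_hz,
                  paste0("channel ", nm, " not at the model sample rate"))
      # (plen, patches_per_epoch, n_epochs) view of this channel
      dim(sig) <- c(plen, cfg$patches_per_epoch, ne)
      X[, (ci - 1) * cfg$patches_per_epoch + seq_len(cfg$patches_per_epoch),
        off + seq_len(ne)] <- sig
    }
    if (!is.null(r$labels)) {
      stage[off + seq_len(ne)] <- encode_stage_labels(r$labels$stage, cfg)
      resp[off + seq_len(ne)] <- r$labels$respiratory_flag
      desat[off + seq_len(ne)] <- r$labels$desaturation_flag
    } else {
      stage[off + seq_len(ne)] <- NA_integer_
    }
    rec_id[off + seq_len(ne)] <- r$id %||% as.character(ri)
    epoch_ix[off + seq_len(ne)] <- seq_len(ne)
    off <- off + ne
  }
  list(X = X, dims = dim(X), stage = stage, resp = resp, desat = desat,
       recording_id = rec_id, epoch = epoch_ix,
       n_channels = C, n = n_total)
}

# Streaming assembly: one recording at a time into a single-precision
# buffer, so large cohorts cost half the memory of an R double array and
# recordings never coexist with the assembled tensor.
build_epoch_dataset_streaming <- function(gen, cfg, n_recordings) {
  plen <- cfg$patch_seconds * cfg$sample_rate_hz
  C <- length(cfg$channel_order)
  P <- cfg$patches_per_epoch * C
  first <- gen(1)
  ne <- first$psg$n_epochs
  n_total <- ne * n_recordings
  per_rec <- plen * P * ne
  X <- cpp_alloc_f32(per_rec * n_recordings)
  stage <- integer(n_total)
  resp <- numeric(n_total)
  desat <- numeric(n_total)
  rec_id <- character(n_total)
  epoch_ix <- integer(n_total)
  off <- 0L
  for (ri in seq_len(n_recordings)) {
    r <- if (ri == 1) first else gen(ri)
    assert_that(r$psg$n_epochs == ne,
                "streaming assembly requires a constant epoch count")
    # per-epoch layout: channel-major patch blocks (plen x P), epochs stacked
    block <- array(0, dim = c(plen, P, ne))
    for (ci in seq_len(C)) {
      nm <- cfg$channel_order[ci]
      sig <- r$psg$signals[[nm]]
      assert_that(!is.null(sig), paste0("recording ", ri, " missing channel ", nm))
      dim(sig) <- c(plen, cfg$patches_per_epoch, ne)
      block[, (ci - 1) * cfg$patches_per_epoch +
              seq_len(cfg$patches_per_epoch), ] <- sig
    }
    cpp_fill_f32(X, (ri - 1) * per_rec, as.numeric(block))
    if (!is.null(r$labels)) {
      stage[off + seq_len(ne)] <- encode_stage_labels(r$labels$stage, cfg)
      resp[off + seq_len(ne)] <- r$labels$respiratory_flag
      desat[off + seq_len(ne)] <- r$labels$desaturation_flag
    } else {
      stage[off + seq_len(ne)] <- NA_integer_
    }
    rec_id[off + seq_len(ne)] <- r$id %||% as.character(ri)
    epoch_ix[off + seq_len(ne)] <- seq_len(ne)
    off <- off + ne
    if (ri == 1) first <- NULL
  }
  list(X = X, dims = c(plen, P, n_total), stage = stage, resp = resp,
       desat = desat, recording_id = rec_id, epoch = epoch_ix,
       n_channels = C, n = n_total)
}

#' Embed every recording in a dataset
#'
#' Splits a [build_epoch_dataset()] result by recording and returns one
#' embedding matrix per recording.
#'
#' @inheritParams predict_epochs
#' @return Named list of `embedding_matrix` objects.
#' @export
embed_dataset <- function(model, dataset) {
  fw <- model_forward(model, dataset)
  ids <- unique(dataset$recording_id)
  out <- lapply(ids, function(id) {
    structure(t(fw$cls[dataset$recording_id == id, , drop = FALSE]),
              class = "embedding_matrix", recording_id = id)
  })
  setNames(out, ids)
}

# Stage classes seen by the model: all five, or the four sleep stages when
# wake is masked out of the staging task (stage_classes = 4). Masked epochs
# get an NA stage code and are excluded from the staging loss by exclusion
# from training batches.
model_stage_levels <- function(cfg) {
  if (cfg$stage_classes == 4) stage_levels()[-1] else
    stage_levels()[seq_len(cfg$stage_classes)]
}

encode_stage_labels <- function(stage, cfg) {
  code <- as.integer(factor(as.character(stage),
                            levels = model_stage_levels(cfg)))
  code
}

#' Save / load a trained model
#'
#' Single-file serialization with the configuration embedded.
#'
#' @param model A `sleep_model`.
#' @param path File path.
#' @return `load_sleep_model` returns the model.
#' @export
save_sleep_model <- function(model, path) {
  assert_that(inherits(model, "sleep_model"), "`model` must be a sleep_model")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_sleep_model
#' @export
load_sleep_model <- function(path) {
  model <- readRDS(path)
  assert_that(inherits(model, "sleep_model"), "file is not a sleep_model")
  model
}

adam_init <- function(weights) {
  trainable <- names(weights)[vapply(weights, is.matrix, TRUE)]
  list(m = lapply(weights[trainable], function(x) array(0, dim(x))),
       v = lapply(weights[trainable], function(x) array(0, dim(x))),
       t = 0L)
}

adam_step <- function(weights, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(state$m)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    weights[[nm]] <- weights[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(weights = weights, state = state)
}

#' Train the multi-task model
#'
#' Minimizes the mean of the three task losses (stage cross-entropy,
#' respiratory and desaturation binary cross-entropy) with Adam. Batch order
#' is reshuffled every epoch under the configured seed, so identical
#' model/dataset/seed runs are reproducible.
#'
#' @param model A [sleep_model_init()] result.
#' @param dataset A labeled [build_epoch_dataset()] result.
#' @param n_epochs Training passes; defaults to the config value.
#' @param verbose Print per-epoch losses.
#' @return The model with updated weights and a `loss_history` tibble
#'   (`epoch`, `loss`, `loss_stage`, `loss_resp`, `loss_desat`).
#' @export
train_multitask <- function(model, dataset, n_epochs = NULL, verbose = FALSE) {
  cfg <- model$config
  assert_that(dataset$n >= 1, "`dataset` is empty")
  # epochs with an NA stage code (unlabeled, or wake under a 4-class
  # masked-wake config) are excluded from training
  pool <- which(!is.na(dataset$stage))
  assert_that(length(pool) >= 1, "dataset has no labeled epochs")
  n_epochs <- n_epochs %||% cfg$n_epochs_train
  w <- model$weights
  st <- adam_init(w)
  set.seed(cfg$seed + 1L)
  dims <- dataset$dims %||% dim(dataset$X)
  hist <- vector("list", n_epochs)
  for (ep in seq_len(n_epochs)) {
    ord <- pool[sample.int(length(pool))]
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    acc <- c(loss = 0, loss_stage = 0, loss_resp = 0, loss_desat = 0)
    for (b in batches) {
      out <- cpp_tf_grad(w, dataset$X, dims, b,
                         dataset$stage[b], dataset$resp[b], dataset$desat[b],
                         dataset$n_channels)
      if (!is.finite(out$loss)) {
        abort(sprintf(paste0("non-finite loss at training epoch %d ",
                             "(stage %.4g, resp %.4g, desat %.4g)"),
                      ep, out$loss_stage, out$loss_resp, out$loss_desat))
      }
      upd <- adam_step(w, out$grads, st, cfg$learning_rate)
      w <- upd$weights
      st <- upd$state
      frac <- length(b) / length(pool)
      acc <- acc + frac * c(out$loss, out$loss_stage, out$loss_resp,
                            out$loss_desat)
    }
    hist[[ep]] <- tibble(epoch = ep, loss = acc[[1]], loss_stage = acc[[2]],
                         loss_resp = acc[[3]], loss_desat = acc[[4]])
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f (stage %.4f resp %.4f desat %.4f)",
                      ep, acc[[1]], acc[[2]], acc[[3]], acc[[4]]))
    }
  }
  model$weights <- w
  model$loss_history <- bind_rows(hist)
  model
}

#' Multi-task losses of the current weights on a dataset (no update)
#' @inheritParams train_multitask
#' @return One-row tibble of the mean total and per-task losses.
#' @export
compute_losses <- function(model, dataset) {
  dims <- dataset$dims %||% dim(dataset$X)
  idx <- which(!is.na(dataset$stage))
  assert_that(length(idx) >= 1, "dataset has no labeled epochs")
  acc <- c(0, 0, 0, 0)
  for (b in split(idx, ceiling(seq_along(idx) / 512))) {
    out <- cpp_tf_grad(model$weights, dataset$X, dims, b, dataset$stage[b],
                       dataset$resp[b], dataset$desat[b], dataset$n_channels)
    acc <- acc + (length(b) / length(idx)) *
      c(out$loss, out$loss_stage, out$loss_resp, out$loss_desat)
  }
  tibble(loss = acc[1], loss_stage = acc[2], loss_resp = acc[3],
         loss_desat = acc[4])
}

model_forward <- function(model, dataset, idx = seq_len(dataset$n),
                          chunk = 1024L) {
  dims <- dataset$dims %||% dim(dataset$X)
  cls <- matrix(0, length(idx), model$config$embed_dim)
  ls <- matrix(0, length(idx), model$config$stage_classes)
  lr <- numeric(length(idx))
  ld <- numeric(length(idx))
  pos <- 0L
  for (b in split(idx, ceiling(seq_along(idx) / chunk))) {
    out <- cpp_tf_forward(model$weights, dataset$X, dims, b,
                          dataset$n_channels)
    ii <- pos + seq_along(b)
    cls[ii, ] <- out$cls
    ls[ii, ] <- out$stage_logits
    lr[ii] <- out$resp_logit
    ld[ii] <- out$desat_logit
    pos <- pos + length(b)
  }
  list(cls = cls, stage_logits = ls, resp_logit = lr, desat_logit = ld)
}

#' Predict epoch labels
#'
#' @param model A trained [sleep_model_init()] result.
#' @param dataset A [build_epoch_dataset()] result.
#' @return Tibble with per-epoch predicted stage, stage probabilities, and
#'   respiratory/desaturation probabilities.
#' @export
predict_epochs <- function(model, dataset) {
  fw <- model_forward(model, dataset)
  pr <- exp(fw$stage_logits - apply(fw$stage_logits, 1, max))
  pr <- pr / rowSums(pr)
  lv <- model_stage_levels(model$config)
  colnames(pr) <- lv
  tibble(recording_id = dataset$recording_id,
         epoch = dataset$epoch,
         stage_pred = lv[max.col(pr, ties.method = "first")],
         stage_prob = pr,
         resp_prob = stats::plogis(fw$resp_logit),
         desat_prob = stats::plogis(fw$desat_logit))
}

#' Evaluate the three tasks on a labeled dataset
#'
#' Staging is scored with macro/micro F1 and macro/micro average precision
#' (one-vs-rest); the two event-detection tasks with F1 (probability
#' threshold 0.5) and threshold-free average precision.
#'
#' @inheritParams predict_epochs
#' @return Tibble with columns `task`, `metric`, `value`.
#' @export
evaluate_tasks <- function(model, dataset) {
  lv <- model_stage_levels(model$config)
  keep <- which(!is.na(dataset$stage))
  assert_that(length(keep) == dataset$n, "dataset must be fully labeled")
  pred <- predict_epochs(model, dataset)
  truth <- lv[dataset$stage]
  f1s <- f1_scores(truth, pred$stage_pred, classes = lv)
  pr <- pred$stage_prob
  ap_cls <- vapply(seq_len(ncol(pr)), function(k) {
    y <- as.numeric(truth == colnames(pr)[k])
    if (sum(y) == 0) NA_real_ else average_precision(y, pr[, k])
  }, 0)
  ap_macro <- mean(ap_cls, na.rm = TRUE)
  y_all <- as.numeric(outer(truth, colnames(pr), "=="))
  ap_micro <- average_precision(y_all, as.numeric(pr))
  ev <- function(y, p) {
    c(f1 = f1_scores(as.character(y), as.character(as.integer(p >= 0.5)),
                     classes = c("0", "1"))$per_class$f1[2],
      ap = average_precision(y, p))
  }
  r <- ev(dataset$resp, pred$resp_prob)
  d <- ev(dataset$desat, pred$desat_prob)
  bind_rows(
    tibble(task = "stage",
           metric = c("f1_macro", "f1_micro", "ap_macro", "ap_micro"),
           value = c(f1s$macro, f1s$micro, ap_macro, ap_micro)),
    tibble(task = "respiratory", metric = c("f1", "ap"), value = unname(r)),
    tibble(task = "desaturation", metric = c("f1", "ap"), value = unname(d))
  )
}

#' Embed a recording as stacked per-epoch CLS vectors
#'
#' Runs the model in evaluation mode over every 30-s epoch and stacks the
#' CLS outputs into an `embed_dim` x `n_epochs` matrix — the recording's
#' embedding matrix.
#'
#' @param model A [sleep_model_init()] result (trained or initialized).
#' @param rec A preprocessed [psg_recording()], or a [build_epoch_dataset()]
#'   result for one recording.
#' @param id Recording identifier stored on the result.
#' @return A numeric matrix of class `embedding_matrix`.
#' @export
embed_recording <- function(model, rec, id = "rec") {
  if (inherits(rec, "psg_recording")) {
    ds <- build_epoch_dataset(list(list(psg = rec, id = id)), model$config)
  } else {
    ds <- rec
  }
  fw <- model_forward(model, ds)
  structure(t(fw$cls), class = "embedding_matrix", recording_id = id)
}
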