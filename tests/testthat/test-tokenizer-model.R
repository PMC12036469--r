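test_that("the five-second overlap rule flags epochs as specified", {
  hyp <- tibble::tibble(epoch = 1:2, stage = factor(c("N2", "N2"),
                                                    levels = stage_levels()))
  lab <- function(start, dur) {
    ev <- tibble::tibble(start_s = start, duration_s = dur,
                         type = "respiratory")
    derive_epoch_labels(hyp, ev)$respiratory_flag
  }
  expect_equal(lab(7, 7), c(1, 0))      # 7 s overlap with epoch 1
  expect_equal(lab(27, 4), c(0, 0))     # 3 s + 1 s, both below threshold
  expect_equal(lab(25, 10), c(1, 1))    # exactly 5 s in each epoch
})

test_that("label derivation ignores annotation order and is idempotent", {
  set.seed(5)
  hyp <- tibble::tibble(epoch = 1:50,
                        stage = factor(sample(stage_levels(), 50, TRUE),
                                       levels = stage_levels()))
  ev <- tibble::tibble(start_s = runif(30, 0, 1450),
                       duration_s = runif(30, 5, 40),
                       type = sample(c("respiratory", "desaturation"), 30,
                                     TRUE))
  l1 <- derive_epoch_labels(hyp, ev)
  l2 <- derive_epoch_labels(hyp, ev[sample(30), ])
  expect_identical(l1, l2)
  expect_identical(derive_epoch_labels(hyp, ev), l1)
  expect_error(derive_epoch_labels(hyp, dplyr::mutate(ev, type = "snoring")),
               "unknown event type")
})

test_that("token sequence arithmetic follows the 11C + 1 convention", {
  expect_equal(seq_token_length(14), 155L)
  expect_equal(seq_token_length(1), 12L)
  for (C in 1:8) expect_equal(seq_token_length(C), 11L * C + 1L)
  cfg <- model_config(channel_order = c("C4", "EKG"))
  sigs <- list(C4 = rnorm(3840), EKG = rnorm(3840))
  ts <- build_token_sequence(sigs, cfg)
  expect_equal(ts$length, 23)
  expect_equal(nrow(ts$patches), 384)         # 3 s x 128 Hz per patch
  expect_equal(ncol(ts$patches), 20)          # 10 tokens per channel
  expect_equal(sum(ts$layout$kind == "patch" & ts$layout$channel == "C4"), 10)
  expect_equal(sum(ts$layout$kind == "SEP"), 2)
  expect_equal(ts$layout$kind[23], "CLS")
  expect_error(build_token_sequence(list(C4 = rnorm(100), EKG = rnorm(3840)),
                                    cfg), "expected 3840")
})

test_that("config invariants are enforced", {
  expect_error(model_config("C4", patch_seconds = 5), "30 s")
  expect_error(model_config("C4", embed_dim = 65, n_heads = 4), "divisible")
  full <- model_config(channel_catalogue()$channel, embed_dim = 768,
                       n_layers = 12, n_heads = 12)
  expect_s3_class(full, "model_config")
})

tiny_dataset <- function(n = 6, C = 1, seed = 4) {
  set.seed(seed)
  list(X = array(rnorm(384 * 10 * C * n, 0, 0.5), c(384, 10 * C, n)),
       stage = sample(1:5, n, replace = TRUE),
       resp = rbinom(n, 1, 0.5), desat = rbinom(n, 1, 0.5),
       recording_id = rep("a", n), epoch = seq_len(n),
       n_channels = C, n = n)
}

test_that("an untrained model with zeroed stage head scores CE = ln 5", {
  cfg <- model_config("C4", embed_dim = 16, n_layers = 1, n_heads = 2,
                      seed = 2)
  model <- sleep_model_init(cfg)
  model$weights$Ws[] <- 0
  model$weights$bs[] <- 0
  ds <- tiny_dataset()
  l <- compute_losses(model, ds)
  expect_equal(l$loss_stage, log(5), tolerance = 1e-12)
})

test_that("the total loss is the arithmetic mean of the three task losses", {
  cfg <- model_config("C4", embed_dim = 16, n_layers = 1, n_heads = 2)
  model <- sleep_model_init(cfg)
  ds <- tiny_dataset()
  l <- compute_losses(model, ds)
  expect_equal(l$loss, (l$loss_stage + l$loss_resp + l$loss_desat) / 3,
               tolerance = 1e-9)
})

test_that("confident correct heads drive the loss to zero", {
  cfg <- model_config("C4", embed_dim = 16, n_layers = 1, n_heads = 2)
  model <- sleep_model_init(cfg)
  ds <- tiny_dataset(n = 1)
  ds$stage <- 3L
  ds$resp <- 1
  ds$desat <- 0
  for (nm in c("Ws", "Wr", "Wd")) model$weights[[nm]][] <- 0
  model$weights$bs[] <- c(0, 0, 50, 0, 0)
  model$weights$br[] <- 50
  model$weights$bd[] <- -50
  expect_lt(compute_losses(model, ds)$loss, 1e-9)
})

test_that("analytic gradients match finite differences", {
  cfg <- model_config("C4", embed_dim = 8, n_layers = 1, n_heads = 2,
                      seed = 3)
  model <- sleep_model_init(cfg)
  ds <- tiny_dataset(n = 4, seed = 9)
  out <- somnotype:::cpp_tf_grad(model$weights, ds$X, dim(ds$X), 1:4,
                                 ds$stage, ds$resp, ds$desat, 1)
  loss_at <- function(w) {
    somnotype:::cpp_tf_grad(w, ds$X, dim(ds$X), 1:4, ds$stage, ds$resp,
                            ds$desat, 1)$loss
  }
  eps <- 1e-5
  set.seed(10)
  for (nm in c("Wp", "Wq1", "Wk1", "Wv1", "Wo1", "W11", "W21", "g_ln11",
               "g_ln21", "pos", "sep", "cls", "Ws", "Wr", "Wd", "g_emb")) {
    g <- out$grads[[nm]]
    for (rep in 1:2) {
      i <- sample(length(model$weights[[nm]]), 1)
      wp <- model$weights; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- model$weights; wm[[nm]][i] <- wm[[nm]][i] - eps
      num <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
      expect_lt(abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i])), 1e-3)
    }
  }
})

test_that("training reduces the loss on a separable synthetic dataset", {
  sp <- regime_recording_spec(TRUE, 40, seed = 51, channels = test_channels)
  entry <- make_labeled_entry(sp)
  cfg <- model_config(test_channels, seed = 6, batch_size = 16)
  ds <- build_epoch_dataset(list(entry), cfg)
  model <- sleep_model_init(cfg)
  l0 <- compute_losses(model, ds)$loss
  trained <- train_multitask(model, ds, n_epochs = 5)
  expect_lt(utils::tail(trained$loss_history$loss, 1), l0)
  expect_equal(nrow(trained$loss_history), 5)
  # seeded training is reproducible
  trained2 <- train_multitask(sleep_model_init(cfg), ds, n_epochs = 2)
  trained3 <- train_multitask(sleep_model_init(cfg), ds, n_epochs = 2)
  expect_identical(trained2$loss_history, trained3$loss_history)
})

test_that("embeddings have the contract shape and are deterministic", {
  sp <- recording_spec(n_epochs = 12, channels = test_channels, seed = 23)
  rec <- generate_recording(sp)
  proc <- preprocess_recording(rec$psg)
  cfg <- model_config(test_channels, seed = 2)
  model <- sleep_model_init(cfg)
  e1 <- embed_recording(model, proc, id = "x")
  e2 <- embed_recording(model, proc, id = "x")
  expect_equal(dim(e1), c(64, 12))
  expect_true(all(is.finite(e1)))
  expect_identical(unclass(e1), unclass(e2))
})

test_that("F1 and AP match hand-computed confusion matrices", {
  r <- f1_scores(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  expect_equal(r$per_class$f1, c(2 / 3, 4 / 5))
  expect_equal(r$macro, 11 / 15)
  # constant predictor on a balanced 2-class set pools to 0.5
  r2 <- f1_scores(rep(c("A", "B"), 10), rep("A", 20))
  expect_equal(r2$micro, 0.5)
  # perfect predictions
  r3 <- f1_scores(c("A", "B", "C"), c("A", "B", "C"))
  expect_equal(r3$macro, 1)
  expect_equal(r3$micro, 1)
  expect_equal(average_precision(c(1, 1, 0), c(0.9, 0.8, 0.1)), 1)
  # truth (1,0,1) by decreasing score: P at positives 1 and 2/3
  expect_equal(average_precision(c(1, 0, 1), c(0.9, 0.8, 0.7)),
               0.5 * 1 + 0.5 * 2 / 3)
  expect_warning(f1_scores(c("A", "A"), c("A", "A"), classes = c("A", "B")),
                 "absent")
})

test_that("a 4-class config masks wake out of the staging task", {
  sp <- recording_spec(n_epochs = 30, channels = test_channels,
                       stage_transition_rate = 40, seed = 61)
  entry <- make_labeled_entry(sp)
  expect_gt(sum(entry$labels$stage == "W"), 0)
  cfg <- model_config(test_channels, stage_classes = 4, seed = 6,
                      batch_size = 8)
  ds <- build_epoch_dataset(list(entry), cfg)
  expect_true(all(is.na(ds$stage[entry$labels$stage == "W"])))
  expect_true(all(ds$stage[entry$labels$stage == "REM"] == 4, na.rm = TRUE))
  model <- sleep_model_init(cfg)
  expect_equal(ncol(model$weights$Ws), 4)
  trained <- train_multitask(model, ds, n_epochs = 2)
  expect_true(all(is.finite(trained$loss_history$loss)))
})

test_that("models round-trip through single-file serialization", {
  cfg <- model_config("C4", embed_dim = 16, n_layers = 1, n_heads = 2)
  model <- sleep_model_init(cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_sleep_model(model, path)
  back <- load_sleep_model(path)
  expect_identical(back$weights, model$weights)
  expect_identical(back$config, model$config)
})

test_that("channel order is immaterial up to training noise", {
  sp <- regime_recording_spec(TRUE, 30, seed = 71, channels = test_channels)
  entry <- make_labeled_entry(sp)
  losses <- vapply(list(test_channels, rev(test_channels)), function(ord) {
    cfg <- model_config(ord, seed = 6, batch_size = 16)
    ds <- build_epoch_dataset(list(entry), cfg)
    trained <- train_multitask(sleep_model_init(cfg), ds, n_epochs = 3)
    utils::tail(trained$loss_history$loss, 1)
  }, 0)
  expect_lt(abs(losses[1] - losses[2]), 0.4 * max(losses))
})
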