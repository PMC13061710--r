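# Training, evaluation and ablation harness.

#' Training configuration
#'
#' Defaults follow the published full-scale recipe: AdamW (lr 1e-4, weight
#' decay 1e-5, beta1 0.9, beta2 0.999, eps 1e-8), cosine annealing with 5
#' linear warm-up epochs down to 1e-6, batch size 32, 100 epochs, early
#' stopping patience 10, label smoothing 0.1, combined-loss balance
#' gamma = 0.1. Scale `epochs`/`batch_size` down for desk-scale runs.
#'
#' @param lr,weight_decay,beta1,beta2,eps AdamW settings.
#' @param warmup_epochs,min_lr scheduler settings.
#' @param batch_size,epochs,patience loop settings.
#' @param label_smoothing,gamma,ual_metric,class_weighting loss settings.
#' @param seed master seed for shuffling, augmentation and dropout.
#' @export
train_config <- function(lr = 1e-4, weight_decay = 1e-5, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8, warmup_epochs = 5L,
                         min_lr = 1e-6, batch_size = 32L, epochs = 100L,
                         patience = 10L, label_smoothing = 0.1,
                         gamma = 0.1, ual_metric = "pearson",
                         class_weighting = TRUE, seed = 1L) {
  stopifnot(lr > min_lr, min_lr > 0, warmup_epochs < epochs)
  structure(list(lr = lr, weight_decay = weight_decay, beta1 = beta1,
                 beta2 = beta2, eps = eps,
                 warmup_epochs = as.integer(warmup_epochs), min_lr = min_lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 label_smoothing = label_smoothing, gamma = gamma,
                 ual_metric = ual_metric, class_weighting = class_weighting,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Desk-scale training profile
#'
#' The published recipe (100 epochs at lr 1e-4 on a large cohort) is not
#' meaningful for minutes-long CPU runs on small synthetic cohorts, so the
#' desk profile shortens the schedule and raises the learning rate in
#' proportion: at most 15 epochs (2 warm-up), peak lr 3e-3 decaying to
#' 1e-4, early-stopping patience 4, batch 32. Used by the tests and the
#' worked examples; pair it with [tiny_config()].
#'
#' @param epochs,patience,seed overridable loop settings.
#' @return a [train_config()].
#' @export
desk_train_config <- function(epochs = 15L, patience = 4L, seed = 1L) {
  train_config(lr = 3e-3, min_lr = 1e-4, warmup_epochs = 2L,
               batch_size = 32L, epochs = epochs, patience = patience,
               seed = seed)
}

#' Learning rate at a given epoch
#'
#' Linear ramp from 0 to `lr` over the warm-up epochs (reaching `lr` at
#' epoch `warmup_epochs`), then cosine decay to `min_lr` at the final
#' epoch. Epochs are 1-based.
#'
#' @param epoch epoch index in `1..epochs`.
#' @param config a [train_config()].
#' @export
lr_schedule <- function(epoch, config) {
  stopifnot(epoch >= 1, epoch <= config$epochs)
  w <- config$warmup_epochs
  if (epoch <= w) return(config$lr * epoch / w)
  tfrac <- (epoch - w) / (config$epochs - w)
  config$min_lr + (config$lr - config$min_lr) * 0.5 * (1 + cos(pi * tfrac))
}

adamw_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adamw_step <- function(params, grads, state, lr, cfg) {
  state$t <- state$t + 1L
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * g
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * g^2
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + cfg$eps)
    params[[nm]] <- params[[nm]] - lr * (upd + cfg$weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}

# normalized min-max MSE with the per-sample ranges treated as constants
ag_mse_norm_loss <- function(u, e) {
  u <- as_node(u); e <- as_node(e)
  uv <- u$value; ev <- e$value
  d <- dim(uv); n <- d[1] * d[2]; B <- d[3]
  um <- matrix(uv, n, B); em <- matrix(ev, n, B)
  rng <- function(m) {
    lo <- apply(m, 2, min); hi <- apply(m, 2, max)
    r <- hi - lo
    r[r < 1e-12] <- Inf     # constant map -> normalized to zero
    list(lo = lo, r = r)
  }
  ru <- rng(um); re <- rng(em)
  un <- sweep(sweep(um, 2, ru$lo), 2, ru$r, "/")
  en <- sweep(sweep(em, 2, re$lo), 2, re$r, "/")
  diff <- un - en
  ag_op(mean(diff^2), list(u, e), function(g) {
    gu <- sweep(2 * diff, 2, ru$r, "/") * (g / (n * B))
    ge <- sweep(-2 * diff, 2, re$r, "/") * (g / (n * B))
    dim(gu) <- d; dim(ge) <- d
    list(gu, ge)
  })
}

# one forward pass with loss; returns loss node plus numeric breakdown
training_graph <- function(model, x, y, tcfg) {
  cfg <- model$config
  gr <- model_graph(model, x, training = TRUE)
  B <- length(y)
  s <- tcfg$label_smoothing
  t1 <- (1 - s) * y + s / 2
  targets <- cbind(1 - t1, t1)
  w <- if (isTRUE(tcfg$class_weighting) && !is.null(tcfg$.class_weights)) {
    tcfg$.class_weights[y + 1]
  } else {
    rep(1, B)
  }
  ce <- ag_softmax_ce(gr$logits, targets, w)
  if (model$arch$use_ual && tcfg$gamma > 0) {
    dd <- dim(ag_value(gr$pmap))
    uup <- ag_bilinear_resize(gr$U, dd[1], dd[2])
    emap <- ag_error_map(gr$pmap, y)
    ual <- switch(tcfg$ual_metric,
      pearson = ag_pearson_loss(uup, emap),
      mse = ag_mse_norm_loss(uup, emap),
      spearman = stop("spearman is rank-based and not differentiable; ",
                      "use it for evaluation only"),
      stop("unknown ual_metric")
    )
    loss <- ag_add(ce, ag_scale(ual, tcfg$gamma))
  } else {
    ual <- NULL
    loss <- ce
  }
  list(graph = gr, loss = loss,
       cel = as.numeric(ag_value(ce)),
       ual = if (is.null(ual)) NA_real_ else as.numeric(ag_value(ual)),
       probs = attr(ce, "probs"))
}

#' Train a model
#'
#' Runs AdamW with the warm-up/cosine schedule, training-set oversampling
#' and on-the-fly augmentation; validation F1 is monitored for early
#' stopping and the best-F1 weights are retained. Validation and test data
#' are never augmented or resampled. All randomness derives from
#' `config$seed`, so a fixed seed reproduces the run.
#'
#' @param model a [build_model()] result.
#' @param tiles list of [rgb_tile()] covering the manifest.
#' @param manifest tile manifest with a `subset` column (see
#'   [apply_split()]); rows must align with `tiles`.
#' @param config a [train_config()].
#' @param augment an [augment_params()] list, or `NULL` to disable.
#' @param verbose print one line per epoch.
#' @return list of class `run_record`: `model` (best weights), `history`
#'   (per-epoch data.frame), `best_epoch`, `class_weights`.
#' @export
train_model <- function(model, tiles, manifest, config = train_config(),
                        augment = augment_params(), verbose = FALSE) {
  stopifnot(length(tiles) == nrow(manifest), "subset" %in% names(manifest))
  tr <- which(manifest$subset == "train")
  va <- which(manifest$subset == "val")
  if (!length(tr)) stop("no training tiles")
  labels_tr <- manifest$label[tr]
  cw <- if (isTRUE(config$class_weighting))
    class_weights_from_labels(labels_tr) else c(1, 1)
  config$.class_weights <- cw
  # oversample minority within the training subset only
  tr_bal <- c(tr, with_seed(derive_seed(config$seed, 7L), {
    n1 <- sum(labels_tr == 1); n0 <- sum(labels_tr == 0)
    if (n0 == n1) integer(0)
    else {
      minority <- if (n0 < n1) 0 else 1
      pool <- tr[labels_tr == minority]
      pool[sample.int(length(pool), abs(n0 - n1), replace = TRUE)]
    }
  }))

  params <- model$params
  opt <- adamw_init(params)
  hist <- list()
  best_f1 <- -Inf; best_epoch <- 0L; best_params <- params
  wait <- 0L
  ts <- model$config$tile_size

  for (epoch in seq_len(config$epochs)) {
    lr <- lr_schedule(epoch, config)
    set.seed(derive_seed(config$seed, 100L + epoch))
    ord <- sample(tr_bal)
    nb <- ceiling(length(ord) / config$batch_size)
    ep_loss <- ep_cel <- ep_ual <- 0; nseen <- 0L
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1L) * config$batch_size + 1L):
                   min(b * config$batch_size, length(ord))]
      B <- length(idx)
      x <- array(0, c(ts, ts, B, 3L))
      for (i in seq_len(B)) {
        tl <- tiles[[idx[i]]]
        if (!is.null(augment)) tl <- augment_tile(tl, augment)
        x[, , i, ] <- tl$pixels
      }
      y <- manifest$label[idx]
      model$params <- params
      ag_tape_begin()
      st <- training_graph(model, x, y, config)
      lval <- as.numeric(ag_value(st$loss))
      if (!is.finite(lval)) {
        ag_tape_end()
        stop("divergent loss (non-finite) at epoch ", epoch, ", batch ", b)
      }
      ag_backward(st$loss)
      grads <- lapply(st$graph$P, function(nd) nd$grad)
      ag_tape_end()
      upd <- adamw_step(params, grads, opt, lr, config)
      params <- upd$params; opt <- upd$state
      ep_loss <- ep_loss + lval * B
      ep_cel <- ep_cel + st$cel * B
      ep_ual <- ep_ual + (if (is.na(st$ual)) 0 else st$ual) * B
      nseen <- nseen + B
    }
    model$params <- params
    vm <- if (length(va)) {
      evaluate_model(model, tiles, manifest, subset = "val",
                     batch_size = config$batch_size)
    } else {
      NULL
    }
    vf1 <- if (is.null(vm)) NA_real_ else as.numeric(vm$f1)
    hist[[epoch]] <- data.frame(
      epoch = epoch, lr = lr, train_loss = ep_loss / nseen,
      train_cel = ep_cel / nseen, train_ual = ep_ual / nseen,
      val_f1 = vf1,
      val_acc = if (is.null(vm)) NA_real_ else as.numeric(vm$accuracy))
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  val F1 %.4f",
                      epoch, lr, ep_loss / nseen, vf1))
    }
    monitored <- if (is.na(vf1)) -ep_loss / nseen else vf1
    if (monitored > best_f1 + 1e-12) {
      best_f1 <- monitored; best_epoch <- epoch
      best_params <- params; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  model$params <- best_params
  structure(list(model = model, history = do.call(rbind, hist),
                 best_epoch = best_epoch, class_weights = cw),
            class = "run_record")
}

#' Evaluate a model on one subset
#'
#' Augmentation- and oversampling-free. Reports accuracy, precision,
#' recall, F1 (abnormal positive), AUC-ROC on the abnormal-class
#' probability, and the mean per-image Pearson correlation between the
#' (bilinearly upsampled) uncertainty map and the pixel-wise error map.
#'
#' @param model a `histomamba_model`.
#' @param tiles,manifest as in [train_model()].
#' @param subset `"train"`, `"val"` or `"test"`.
#' @param batch_size evaluation batch size.
#' @param metrics_path optional path; metrics are written there as JSON.
#' @return list: accuracy, precision, recall, f1, auc, mean_rho, counts,
#'   scores, predicted, labels.
#' @export
evaluate_model <- function(model, tiles, manifest, subset = "test",
                           batch_size = 32L, metrics_path = NULL) {
  idx <- if ("subset" %in% names(manifest))
    which(manifest$subset == subset) else seq_along(tiles)
  if (!length(idx)) stop("no tiles in subset ", subset)
  ts <- model$config$tile_size
  scores <- numeric(length(idx))
  preds <- integer(length(idx))
  rhos <- numeric(length(idx))
  nb <- ceiling(length(idx) / batch_size)
  for (b in seq_len(nb)) {
    sl <- ((b - 1L) * batch_size + 1L):min(b * batch_size, length(idx))
    ii <- idx[sl]
    x <- array(0, c(ts, ts, length(ii), 3L))
    for (i in seq_along(ii)) x[, , i, ] <- tiles[[ii[i]]]$pixels
    out <- model_forward(model, x)
    scores[sl] <- out$class_probabilities[, 2]
    preds[sl] <- out$predicted
    for (i in seq_along(ii)) {
      u <- out$uncertainty_map[, , i]
      e <- error_map(out$local_prob_map[, , i], manifest$label[ii[i]])
      uu <- resize_uncertainty(u, dim(e))
      rhos[sl[i]] <- if (stats::sd(uu) < 1e-12 || stats::sd(e) < 1e-12) 0
                     else stats::cor(as.numeric(uu), as.numeric(e))
    }
  }
  labels <- manifest$label[idx]
  cts <- confusion(preds, labels)
  res <- list(accuracy = as.numeric(accuracy(cts)),
              precision = as.numeric(precision(cts)),
              recall = as.numeric(recall(cts)),
              f1 = as.numeric(f1_score(cts)),
              auc = if (length(unique(labels)) == 2L)
                auc_roc(scores, labels) else NA_real_,
              mean_rho = mean(rhos),
              counts = cts, scores = scores, predicted = preds,
              labels = labels)
  if (!is.null(metrics_path)) {
    jsonlite::write_json(res[c("accuracy", "precision", "recall", "f1",
                               "auc", "mean_rho")],
                         metrics_path, auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Save / load a model checkpoint
#'
#' Stores weights together with the model configuration, architecture
#' switches and initialization seed.
#' @param model a `histomamba_model`.
#' @param path file path (`.rds`).
#' @name checkpoint
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = unclass(model$config), arch = model$arch,
               params = model$params, channels = model$channels,
               seed = model$seed), path)
  invisible(path)
}

#' @rdname checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  structure(list(config = structure(x$config, class = "model_config"),
                 arch = x$arch, params = x$params, channels = x$channels,
                 seed = x$seed),
            class = "histomamba_model")
}

#' Train and evaluate ablation variants
#'
#' Trains each requested variant with each seed on the given cohort and
#' returns one row per (variant, seed) with test metrics, mirroring the
#' Accuracy / F1 / AUC-ROC ablation table plus the mean U-E correlation.
#'
#' @param config a [model_config()].
#' @param tiles,manifest cohort with `subset` column.
#' @param train_cfg a [train_config()].
#' @param variants integer vector from 1..5.
#' @param seeds integer vector of run seeds.
#' @param augment augmentation settings (or NULL).
#' @param verbose print progress.
#' @return data.frame: variant, seed, accuracy, f1, auc, mean_rho.
#' @export
run_ablation <- function(config, tiles, manifest, train_cfg,
                         variants = 1:5, seeds = 1L,
                         augment = augment_params(), verbose = FALSE) {
  rows <- list()
  for (v in variants) {
    for (s in seeds) {
      tc <- train_cfg
      tc$seed <- as.integer(s)
      mdl <- build_model(config, seed = derive_seed(s, v), variant = v)
      rec <- train_model(mdl, tiles, manifest, tc, augment = augment,
                         verbose = verbose)
      ev <- evaluate_model(rec$model, tiles, manifest, subset = "test",
                           batch_size = tc$batch_size)
      rows[[length(rows) + 1L]] <-
        data.frame(variant = v, seed = s, accuracy = ev$accuracy,
                   f1 = ev$f1, auc = ev$auc, mean_rho = ev$mean_rho)
      if (verbose) {
        message(sprintf("variant %d seed %d: acc %.3f f1 %.3f", v, s,
                        ev$accuracy, ev$f1))
      }
    }
  }
  do.call(rbind, rows)
}
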