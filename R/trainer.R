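#' Training and ablation harness
#'
#' Reproduces the published training recipe: Adam (beta1 = 0.9), learning
#' rate 1e-4 decayed to 0.9 of its value at epochs 100 and 150, batch size
#' 16, 300 epochs, 256x256 inputs, Lovasz-Softmax loss. In deep-supervision
#' mode the training loss is the unweighted sum of the Lovasz-Softmax loss
#' over the four heads; inference combines heads per the model config.
#'
#' @name trainer
NULL

#' Training configuration
#'
#' @param lr Initial learning rate.
#' @param lr_decay_factor Multiplier applied at each decay epoch.
#' @param decay_epochs Sorted epochs at which the decay fires.
#' @param batch_size Mini-batch size.
#' @param epochs Number of passes over the training set.
#' @param image_size Expected square frame size.
#' @param loss `"lovasz"` (default) or `"lovasz+ce"` (adds `ce_weight`
#'   times the pixel cross-entropy, a common warm-start aid).
#' @param ce_weight Cross-entropy mixing weight when `loss = "lovasz+ce"`.
#' @param class_average Lovasz class averaging: `"all"` (default) or
#'   `"present"`.
#' @param per_image If `TRUE`, the Jaccard surrogate is computed per image
#'   and averaged; default flattens all pixels of the batch into one error
#'   vector per class (batch-level Jaccard).
#' @param val_fraction Fraction of training sweeps held out for validation.
#' @param max_steps Optional hard cap on optimiser steps (small-scale
#'   experiments); `NULL` trains the full epoch budget.
#' @param seed Base seed controlling init, shuffling and augmentation.
#' @return A `sono_train_config`.
#' @export
train_config <- function(lr = 1e-4, lr_decay_factor = 0.9,
                         decay_epochs = c(100L, 150L), batch_size = 16L,
                         epochs = 300L, image_size = 256L,
                         loss = c("lovasz", "lovasz+ce"), ce_weight = 0.5,
                         class_average = c("all", "present"),
                         per_image = FALSE, val_fraction = 0.1,
                         max_steps = NULL, seed = 0L) {
  loss <- match.arg(loss)
  class_average <- match.arg(class_average)
  if (lr <= 0 || batch_size <= 0 || epochs <= 0) {
    stop("lr, batch_size and epochs must be positive")
  }
  if (is.unsorted(decay_epochs)) stop("decay_epochs must be sorted")
  structure(list(lr = lr, lr_decay_factor = lr_decay_factor,
                 decay_epochs = as.integer(decay_epochs),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 image_size = as.integer(image_size), loss = loss,
                 ce_weight = ce_weight, class_average = class_average,
                 per_image = isTRUE(per_image), val_fraction = val_fraction,
                 max_steps = if (is.null(max_steps)) NULL else as.integer(max_steps),
                 seed = as.integer(seed)),
            class = "sono_train_config")
}

#' Learning-rate schedule
#'
#' Step decay: the rate is multiplied by `lr_decay_factor` at each epoch in
#' `decay_epochs`.
#'
#' @param cfg A [train_config()].
#' @param epoch 1-based epoch number.
#' @return The learning rate in force during that epoch.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  cfg$lr * cfg$lr_decay_factor^sum(cfg$decay_epochs <= epoch)
}

# loss and score-gradients for one batch of stacked head outputs
batch_loss_and_grads <- function(heads, truth_flat, cfg) {
  total <- 0
  seeds <- vector("list", length(heads))
  for (k in seq_along(heads)) {
    sc <- heads[[k]]$value
    d <- dim(sc)
    C <- d[3]
    scores <- matrix(aperm(sc, c(1, 2, 4, 3)), ncol = C)
    probs <- softmax_scores(scores)
    if (cfg$per_image) {
      np <- d[1] * d[2]
      l <- 0; dsc <- matrix(0, nrow(probs), C)
      for (n in seq_len(d[4])) {
        rows <- ((n - 1) * np + 1):(n * np)
        lg <- lovasz_softmax_loss_grad(probs[rows, , drop = FALSE],
                                       truth_flat[rows], cfg$class_average)
        l <- l + lg$loss
        dsc[rows, ] <- lg$dscores
      }
      l <- l / d[4]; dsc <- dsc / d[4]
    } else {
      lg <- lovasz_softmax_loss_grad(probs, truth_flat, cfg$class_average)
      l <- lg$loss
      dsc <- lg$dscores
    }
    if (cfg$loss == "lovasz+ce") {
      np_all <- nrow(probs)
      pt <- probs[cbind(seq_len(np_all), truth_flat + 1L)]
      l <- l + cfg$ce_weight * mean(-log(pmax(pt, 1e-12)))
      onehot <- matrix(0, np_all, C)
      onehot[cbind(seq_len(np_all), truth_flat + 1L)] <- 1
      dsc <- dsc + cfg$ce_weight * (probs - onehot) / np_all
    }
    total <- total + l
    seeds[[k]] <- aperm(array(dsc, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  }
  list(loss = total, seeds = seeds)
}

#' Train a segmentation model
#'
#' @param model_cfg A [model_config()].
#' @param cfg A [train_config()].
#' @param dataset List of samples `list(image = HxW matrix, labels = HxW
#'   integer matrix)`, e.g. from [phantom_dataset()].
#' @param val_dataset Optional validation samples; when `NULL`,
#'   `val_fraction` of the training samples is held out (none if the
#'   dataset is too small).
#' @param augment_cfg Optional [augment_config()] applied to each training
#'   sample with a per-(epoch, sample) seed; `NULL` disables augmentation.
#' @param out_dir Optional directory for the history JSON-lines log and
#'   the best checkpoint.
#' @param stop_fg_dice Optional early-stop target: training ends once the
#'   mean foreground (non-background) Dice on `stop_dataset` reaches this
#'   value.
#' @param stop_check_every Epoch interval between early-stop checks.
#' @param stop_dataset Samples used for the early-stop check (defaults to
#'   the training samples).
#' @param verbose Print per-epoch progress.
#' @return List with `model` (best validation mIOU weights, or final
#'   weights when no validation split), `history` (data frame: epoch,
#'   step, lr, loss, val_miou) and `best` (best validation mIOU).
#' @export
train <- function(model_cfg, cfg, dataset, val_dataset = NULL,
                  augment_cfg = NULL, out_dir = NULL, stop_fg_dice = NULL,
                  stop_check_every = 10L, stop_dataset = NULL,
                  verbose = FALSE) {
  stopifnot(inherits(model_cfg, "sono_model_config"),
            inherits(cfg, "sono_train_config"))
  if (length(dataset) == 0L) stop("empty dataset")
  if (is.null(val_dataset) && cfg$val_fraction > 0 && length(dataset) >= 10L) {
    nval <- max(1L, round(cfg$val_fraction * length(dataset)))
    idx <- with_seed(derive_seed(cfg$seed, 23L),
                     sample(length(dataset), nval))
    val_dataset <- dataset[idx]
    dataset <- dataset[-idx]
  }
  model <- build_model(model_cfg, seed = cfg$seed)
  params <- collect_params(model)
  opt <- adam_state(params)
  history <- list()
  best <- -Inf
  best_state <- NULL
  step <- 0L
  n <- length(dataset)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- if (!is.null(out_dir)) file.path(out_dir, "history.jsonl") else NULL
  done <- FALSE
  for (epoch in seq_len(cfg$epochs)) {
    lr <- lr_at_epoch(cfg, epoch)
    ord <- with_seed(derive_seed(cfg$seed, 1000L + epoch), sample(n))
    epoch_loss <- 0; nb <- 0L
    for (b0 in seq(1L, n, by = cfg$batch_size)) {
      sel <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
      imgs <- vector("list", length(sel)); labs <- vector("list", length(sel))
      for (t in seq_along(sel)) {
        smp <- dataset[[sel[t]]]
        if (!is.null(augment_cfg)) {
          smp <- augment(smp$image, smp$labels, augment_cfg,
                         derive_seed(cfg$seed, epoch * 10000L + sel[t]))
        }
        imgs[[t]] <- smp$image; labs[[t]] <- smp$labels
      }
      H <- nrow(imgs[[1L]]); W <- ncol(imgs[[1L]])
      x <- array(unlist(imgs), c(H, W, 1L, length(sel)))
      truth_flat <- unlist(lapply(labs, as.vector))
      tape <- new_tape()
      heads <- model_forward(model, x, training = TRUE, tape = tape)
      lg <- batch_loss_and_grads(heads, truth_flat, cfg)
      if (!is.finite(lg$loss)) {
        stop("non-finite loss at step ", step + 1L, "; aborting")
      }
      zero_grads(params)
      backward_run(tape, heads, lg$seeds)
      step <- step + 1L
      opt <- adam_step(params, opt, lr, step)
      epoch_loss <- epoch_loss + lg$loss; nb <- nb + 1L
      if (!is.null(cfg$max_steps) && step >= cfg$max_steps) { done <- TRUE; break }
    }
    val_miou <- NA_real_
    if (!is.null(val_dataset) && length(val_dataset)) {
      val_miou <- evaluate(model, val_dataset)$aggregate[["miou"]]
      if (val_miou > best) { best <- val_miou; best_state <- model_state(model) }
    }
    rec <- list(epoch = epoch, step = step, lr = lr,
                loss = epoch_loss / max(1L, nb), val_miou = val_miou)
    history[[length(history) + 1L]] <- rec
    if (!is.null(log_con)) {
      cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null"),
          "\n", sep = "", file = log_con, append = TRUE)
    }
    if (verbose) {
      message(sprintf("epoch %d  lr %.2e  loss %.4f  val mIOU %s",
                      epoch, lr, rec$loss,
                      ifelse(is.na(val_miou), "-", sprintf("%.4f", val_miou))))
    }
    if (!done && !is.null(stop_fg_dice) && epoch %% stop_check_every == 0L) {
      chk <- evaluate(model, stop_dataset %||% dataset)
      fg <- chk$per_class$dice[chk$per_class$class_index > 0]
      if (mean(fg) >= stop_fg_dice) done <- TRUE
    }
    if (done) break
  }
  if (!is.null(best_state)) restore_state(model, best_state)
  if (!is.null(out_dir)) save_checkpoint(model, file.path(out_dir, "best.rds"))
  hist_df <- do.call(rbind, lapply(history, function(r) as.data.frame(r)))
  list(model = model, history = hist_df,
       best = if (is.finite(best)) best else NA_real_)
}

#' Evaluate a model (or checkpoint) on a dataset
#'
#' Accumulates one confusion matrix over all samples and derives the full
#' metric report.
#'
#' @param model A `sono_model`, or a checkpoint path.
#' @param dataset List of `list(image, labels)` samples.
#' @param average Aggregation rule for mean Dice / mIOU.
#' @param batch_size Frames evaluated per forward pass.
#' @return A `sono_metrics_report`.
#' @export
evaluate <- function(model, dataset, average = c("all", "present"),
                     batch_size = 8L) {
  average <- match.arg(average)
  if (is.character(model)) model <- load_checkpoint(model)
  C <- model$cfg$num_classes
  total <- matrix(0, C, C)
  for (b0 in seq(1L, length(dataset), by = batch_size)) {
    sel <- b0:min(b0 + batch_size - 1L, length(dataset))
    H <- nrow(dataset[[sel[1]]]$image); W <- ncol(dataset[[sel[1]]]$image)
    x <- array(unlist(lapply(dataset[sel], `[[`, "image")),
               c(H, W, 1L, length(sel)))
    pred <- forward_predict(model, x)$labels
    if (length(dim(pred)) == 2L) pred <- array(pred, c(H, W, 1L))
    for (t in seq_along(sel)) {
      if (max(dataset[[sel[t]]]$labels) >= C) {
        stop("dataset label exceeds model class count")
      }
      cm <- confusion_matrix(pred[, , t], dataset[[sel[t]]]$labels, C)
      total <- total + cm$counts
    }
  }
  cm <- structure(list(counts = total, num_classes = C),
                  class = "sono_confusion")
  metrics_report(cm, average)
}

#' Run an ablation grid
#'
#' Trains and evaluates one model per configuration row, mirroring the
#' published ablations: decode modes L2/L3/L4/DS, PPM bin settings, and
#' module on/off combinations (baseline, +PPM, +AG, +both).
#'
#' @param grid A list of named lists; each entry holds [model_config()]
#'   overrides and an optional `label`.
#' @param train_dataset,test_dataset Sample lists.
#' @param base_model_cfg Baseline [model_config()] the overrides patch.
#' @param cfg A [train_config()].
#' @return Data frame: one row per config with label, Dice, mIOU, PA and
#'   mean foreground (non-background) Dice.
#' @export
run_ablation <- function(grid, train_dataset, test_dataset,
                         base_model_cfg = model_config(), cfg = train_config()) {
  rows <- lapply(seq_along(grid), function(k) {
    ov <- grid[[k]]
    label <- ov$label %||% paste0("config", k)
    ov$label <- NULL
    mc <- do.call(model_config, modifyList(unclass(base_model_cfg), ov))
    fit <- train(mc, cfg, train_dataset)
    rep <- evaluate(fit$model, test_dataset)
    fg <- rep$per_class$dice[rep$per_class$class_index > 0]
    data.frame(label = label,
               dice = rep$aggregate[["dice"]],
               miou = rep$aggregate[["miou"]],
               pa = rep$aggregate[["pa"]],
               fg_dice = mean(fg))
  })
  do.call(rbind, rows)
}

#' Standard ablation grids
#'
#' `decode`: the four decoding modes; `ppm_bins`: the three published bin
#' settings; `modules`: baseline / +PPM / +AG / +both.
#'
#' @param which One of `"decode"`, `"ppm_bins"`, `"modules"`.
#' @param bins_override Bin sets to use for the `ppm_bins` grid (the
#'   published sets need a 16x16 deepest feature map).
#' @return A grid list for [run_ablation()].
#' @export
ablation_grid <- function(which = c("modules", "decode", "ppm_bins"),
                          bins_override = NULL) {
  which <- match.arg(which)
  switch(which,
    decode = lapply(c("L2", "L3", "L4", "DS"), function(m) {
      list(label = m, decode_mode = m)
    }),
    ppm_bins = {
      sets <- bins_override %||% list(c(1, 2, 3, 4), c(1, 2, 3, 6), c(1, 2, 4, 8))
      lapply(sets, function(b) {
        list(label = paste(b, collapse = ","), ppm_bins = as.integer(b))
      })
    },
    modules = list(
      list(label = "baseline", ppm_enabled = FALSE, ag_enabled = FALSE),
      list(label = "+PPM", ppm_enabled = TRUE, ag_enabled = FALSE),
      list(label = "+AG", ppm_enabled = FALSE, ag_enabled = TRUE),
      list(label = "+PPM+AG", ppm_enabled = TRUE, ag_enabled = TRUE)
    )
  )
}
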