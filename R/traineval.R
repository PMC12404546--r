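# Training loop, metrics and multi-seed experiment driver.

#' Training configuration
#'
#' Two named presets are shipped: `"desk"` (30 epochs, lr 1e-3, small_cnn
#' batch 32) runs the full pipeline on a laptop CPU in minutes and is used by
#' the package's own experiments; `"reference"` mirrors the full-scale recipe
#' (300 epochs, SGD lr 1e-5, weight decay 1e-4) for the resnet18
#' configuration. Both drop the learning rate by 10x at 50% and 75% of the
#' epochs.
#'
#' @param epochs total epochs.
#' @param lr initial learning rate (> 0).
#' @param momentum SGD momentum.
#' @param weight_decay L2 regularization coefficient.
#' @param lr_drop_factor multiplier applied at each milestone.
#' @param lr_milestones fractions of `epochs` at which the factor applies.
#' @param batch_size_train,batch_size_eval minibatch sizes.
#' @param seed training seed (shuffling, any augmentation).
#' @param preset `"desk"` or `"reference"`; explicit arguments override the
#'   preset's values.
#' @return A `train_config`.
#' @export
train_config <- function(epochs = NULL, lr = NULL, momentum = 0.9,
                         weight_decay = 1e-4, lr_drop_factor = 0.1,
                         lr_milestones = c(0.5, 0.75),
                         batch_size_train = 32L, batch_size_eval = 32L,
                         seed = 1L, preset = c("desk", "reference")) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
                     desk = list(epochs = 30L, lr = 1e-3),
                     reference = list(epochs = 300L, lr = 1e-5))
  epochs <- epochs %||% defaults$epochs
  lr <- lr %||% defaults$lr
  if (lr <= 0) stop("learning rate must be positive")
  if (any(lr_milestones <= 0 | lr_milestones >= 1))
    stop("lr milestones must lie strictly inside (0, 1)")
  structure(list(epochs = as.integer(epochs), lr = lr, momentum = momentum,
                 weight_decay = weight_decay, lr_drop_factor = lr_drop_factor,
                 lr_milestones = lr_milestones,
                 batch_size_train = as.integer(batch_size_train),
                 batch_size_eval = as.integer(batch_size_eval),
                 seed = as.integer(seed), preset = preset),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Step schedule: the rate is multiplied by `lr_drop_factor` on entering each
#' milestone epoch (`floor(f * epochs)`, 1-based). With 300 epochs the drops
#' occur entering epochs 150 and 225.
#'
#' @param cfg a [train_config()].
#' @param epoch 1-based epoch index.
#' @return numeric learning rate.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  ms <- floor(cfg$lr_milestones * cfg$epochs)
  cfg$lr * cfg$lr_drop_factor^sum(epoch >= ms)
}

# Stack records into batch arrays; anomaly maps and the downsampled
# grayscale stack are pure functions of the images and are computed once up
# front, not per epoch.
prepare_tensors <- function(records, classes, deconv = NULL,
                            with_maps = TRUE, with_gray = TRUE,
                            grid = c(16L, 16L)) {
  if (!length(records)) stop("empty record set")
  size <- dim(records[[1]]$image)[1]
  N <- length(records)
  x <- array(0, c(size, size, 3, N))
  maps <- if (with_maps) array(0, c(size, size, 1, N))
  gray <- if (with_gray) array(0, c(grid[1], grid[2], N))
  labels <- integer(N)
  if (with_maps && is.null(deconv))
    deconv <- deconvolution_matrix(stain_matrix_hdab())
  for (n in seq_len(N)) {
    x[, , , n] <- records[[n]]$image / 255 - 0.5
    if (with_maps)
      maps[, , 1, n] <- anomaly_map_from_image(records[[n]]$image, deconv)$map - 0.5
    if (with_gray)
      gray[, , n] <- grayscale_downsample(records[[n]]$image, grid)
    labels[n] <- match(records[[n]]$label, classes)
  }
  if (anyNA(labels)) stop("record label outside the configured class set")
  list(x = x, maps = maps, gray = gray, labels = labels)
}

eval_pass <- function(model, tensors, batch_size) {
  N <- length(tensors$labels)
  K <- length(model$config$classes)
  logits <- matrix(0, K, N)
  loss_sum <- 0
  for (b in split(seq_len(N), ceiling(seq_len(N) / batch_size))) {
    r <- pge_forward(model, tensors$x[, , , b, drop = FALSE],
                     if (!is.null(tensors$maps))
                       tensors$maps[, , , b, drop = FALSE],
                     train = FALSE,
                     gray = if (!is.null(tensors$gray))
                       tensors$gray[, , b, drop = FALSE],
                     input_scaled = TRUE)
    logits[, b] <- r$logits
    loss_sum <- loss_sum + softmax_ce(r$logits, tensors$labels[b])$loss * length(b)
  }
  pred <- max.col(t(logits))
  list(logits = logits, pred = pred, loss = loss_sum / N,
       acc = mean(pred == tensors$labels))
}

#' Train a model
#'
#' Minibatch SGD with momentum, step learning-rate schedule and cross-entropy
#' loss. Logs per-epoch train/validation loss and accuracy; keeps the
#' checkpoint with the best validation macro-F1. Fully reproducible for a
#' fixed config and seed on one machine.
#'
#' @param model a [pge_init()] model.
#' @param train_records,val_records lists of `patch_record` (disjoint).
#' @param cfg a [train_config()].
#' @param curves_csv optional path: per-epoch curves are written there.
#' @param verbose print a line per epoch.
#' @return list with `model` (best checkpoint), `final_model`, `curves`
#'   (data.frame: epoch, lr, train_loss, train_acc, val_loss, val_acc,
#'   val_macro_f1), `best_epoch`.
#' @export
train <- function(model, train_records, val_records, cfg = train_config(),
                  curves_csv = NULL, verbose = FALSE) {
  if (!length(train_records) || !length(val_records))
    stop("empty train or validation split")
  classes <- model$config$classes
  with_maps <- !is.null(model$cd)
  with_gray <- !is.null(model$fwb)
  tr <- prepare_tensors(train_records, classes, with_maps = with_maps,
                        with_gray = with_gray)
  va <- prepare_tensors(val_records, classes, with_maps = with_maps,
                        with_gray = with_gray)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)

  state <- list(ihc = sgd_state_init(model$ihc$layers),
                cd = if (!is.null(model$cd)) sgd_state_init(model$cd$layers),
                fwb = if (!is.null(model$fwb)) sgd_state_init(model$fwb$layers),
                head = sgd_state_init(list(model$head$ln, model$head$fc)))
  N <- length(tr$labels)
  best <- list(f1 = -Inf, model = model, epoch = 0L)
  curves <- vector("list", cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    lr <- lr_at_epoch(cfg, epoch)
    perm <- sample.int(N)
    loss_sum <- 0; correct <- 0
    for (b in split(perm, ceiling(seq_along(perm) / cfg$batch_size_train))) {
      fw <- pge_forward(model, tr$x[, , , b, drop = FALSE],
                        if (with_maps) tr$maps[, , , b, drop = FALSE],
                        train = TRUE,
                        gray = if (with_gray) tr$gray[, , b, drop = FALSE],
                        input_scaled = TRUE)
      model <- fw$model
      ce <- softmax_ce(fw$logits, tr$labels[b])
      if (!is.finite(ce$loss))
        stop(sprintf("training aborted: non-finite loss at epoch %d (lr %.2g)",
                     epoch, lr))
      loss_sum <- loss_sum + ce$loss * length(b)
      correct <- correct + sum(max.col(t(fw$logits)) == tr$labels[b])
      grads <- pge_backward(model, fw$cache, ce$grad)

      up <- sgd_step(model$ihc$layers, grads$ihc, state$ihc, lr,
                     cfg$momentum, cfg$weight_decay)
      model$ihc$layers <- up$layers; state$ihc <- up$state
      if (with_maps) {
        up <- sgd_step(model$cd$layers, grads$cd, state$cd, lr,
                       cfg$momentum, cfg$weight_decay)
        model$cd$layers <- up$layers; state$cd <- up$state
      }
      if (!is.null(model$fwb)) {
        up <- sgd_step(model$fwb$layers, grads$fwb, state$fwb, lr,
                       cfg$momentum, cfg$weight_decay)
        model$fwb$layers <- up$layers; state$fwb <- up$state
      }
      up <- sgd_step(list(model$head$ln, model$head$fc), grads$head,
                     state$head, lr, cfg$momentum, cfg$weight_decay)
      model$head$ln <- up$layers[[1]]; model$head$fc <- up$layers[[2]]
      state$head <- up$state
    }
    ev <- eval_pass(model, va, cfg$batch_size_eval)
    rep_val <- eval_report(factor(classes[va$labels], levels = classes),
                           factor(classes[ev$pred], levels = classes))
    curves[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                  train_loss = loss_sum / N,
                                  train_acc = correct / N,
                                  val_loss = ev$loss, val_acc = ev$acc,
                                  val_macro_f1 = rep_val$macro["f1"])
    if (rep_val$macro["f1"] > best$f1) {
      best <- list(f1 = rep_val$macro["f1"], model = model, epoch = epoch)
    }
    if (verbose)
      message(sprintf("epoch %3d lr %.2g loss %.4f acc %.3f | val loss %.4f acc %.3f mF1 %.3f",
                      epoch, lr, loss_sum / N, correct / N, ev$loss, ev$acc,
                      rep_val$macro["f1"]))
  }
  curves <- do.call(rbind, curves)
  rownames(curves) <- NULL
  if (!is.null(curves_csv)) write.csv(curves, curves_csv, row.names = FALSE)
  list(model = best$model, final_model = model, curves = curves,
       best_epoch = best$epoch)
}

# ---------------------------------------------------------------------------
# Metrics
# ---------------------------------------------------------------------------

#' Per-class precision / recall / F1 and confusion matrix
#'
#' The confusion matrix has true classes as rows and predictions as columns.
#' Precision is the column-wise, recall the row-wise diagonal fraction;
#' F1 the harmonic mean. `macro` averages over classes with nonzero support
#' (absent classes are reported with support 0 and excluded, with a warning);
#' `weighted` weights per-class metrics by support.
#'
#' @param truth,pred factors (or vectors coercible to factors) on the same
#'   level set.
#' @param classes optional explicit class levels.
#' @return An `eval_report`: list with `confusion`, `per_class` (data.frame),
#'   `macro`, `weighted`, `n`.
#' @export
eval_report <- function(truth, pred, classes = NULL) {
  if (is.null(classes))
    classes <- if (is.factor(truth)) levels(truth) else sort(unique(c(truth, pred)))
  truth <- factor(truth, levels = classes)
  pred <- factor(pred, levels = classes)
  cm <- table(truth = truth, pred = pred)
  support <- rowSums(cm)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  per_class <- data.frame(class = classes, support = as.integer(support),
                          precision = as.numeric(prec),
                          recall = as.numeric(rec), f1 = as.numeric(f1))
  present <- support > 0
  if (!all(present))
    warning("classes with zero support excluded from macro averages: ",
            paste(classes[!present], collapse = ", "))
  macro <- c(precision = mean(prec[present]), recall = mean(rec[present]),
             f1 = mean(f1[present]))
  weighted <- c(precision = sum(prec * support) / sum(support),
                recall = sum(rec * support) / sum(support),
                f1 = sum(f1 * support) / sum(support))
  structure(list(confusion = unclass(cm), per_class = per_class,
                 macro = macro, weighted = weighted,
                 n = as.integer(sum(cm))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> n =", x$n, "\n\nConfusion (rows = truth):\n")
  print(x$confusion)
  cat("\n")
  print(x$per_class, row.names = FALSE, digits = 4)
  cat(sprintf("\nmacro    P %.4f R %.4f F1 %.4f\n",
              x$macro["precision"], x$macro["recall"], x$macro["f1"]))
  cat(sprintf("weighted P %.4f R %.4f F1 %.4f\n",
              x$weighted["precision"], x$weighted["recall"], x$weighted["f1"]))
  invisible(x)
}

#' Evaluate a model on labeled records
#'
#' @param model a `pge_model` (or checkpoint path).
#' @param records list of `patch_record` with labels.
#' @param batch_size evaluation batch size.
#' @return An [eval_report()].
#' @export
evaluate <- function(model, records, batch_size = 32L) {
  if (is.character(model)) model <- load_checkpoint(model)
  classes <- model$config$classes
  te <- prepare_tensors(records, classes, with_maps = !is.null(model$cd),
                        with_gray = !is.null(model$fwb))
  ev <- eval_pass(model, te, batch_size)
  eval_report(factor(classes[te$labels], levels = classes),
              factor(classes[ev$pred], levels = classes), classes)
}

# ---------------------------------------------------------------------------
# Multi-seed experiment
# ---------------------------------------------------------------------------

#' Run the with-prior vs no-prior experiment over several seeds
#'
#' For each seed: generate a fresh synthetic train/validation dataset, train
#' the prior-guided model (CD branch + attention) and the same-budget
#' baseline (backbone + head only) on the identical split, and evaluate both.
#' Reports per-seed metrics and the aggregate mean +/- sd, including the
#' macro-F1 difference (prior minus baseline).
#'
#' @param seeds integer vector of experiment seeds.
#' @param n_train_per_class,n_val_per_class patches per class.
#' @param cfg a [train_config()].
#' @param config_prior,config_baseline model configurations.
#' @param out_dir optional directory for per-seed curves, reports and a few
#'   exported CAM heatmaps.
#' @param verbose print progress.
#' @return list with `per_seed` (list of lists: reports and models' summary),
#'   `aggregate` (data.frame of mean/sd per model), `delta_macro_f1`
#'   (per-seed prior minus baseline).
#' @export
run_experiment <- function(seeds = 1:3, n_train_per_class = 100L,
                           n_val_per_class = 40L, cfg = train_config(),
                           config_prior = pge_config(),
                           config_baseline = pge_config(use_prior = FALSE,
                                                        use_attention = FALSE),
                           out_dir = NULL, verbose = FALSE) {
  per_seed <- list()
  for (s in seeds) {
    tr_data <- generate_dataset(n_train_per_class, seed = s * 1000L + 1L)
    va_data <- generate_dataset(n_val_per_class, seed = s * 1000L + 2L)
    scfg <- cfg
    scfg$seed <- s
    fits <- list()
    for (nm in c("prior", "baseline")) {
      mcfg <- if (nm == "prior") config_prior else config_baseline
      model <- pge_init(mcfg, seed = s)
      fit <- train(model, tr_data$records, va_data$records, scfg,
                   curves_csv = if (!is.null(out_dir))
                     file.path(out_dir, sprintf("curves_%s_seed%d.csv", nm, s)),
                   verbose = verbose)
      rep <- evaluate(fit$model, va_data$records, scfg$batch_size_eval)
      fits[[nm]] <- list(fit = fit, report = rep)
      if (verbose)
        message(sprintf("seed %d %-8s macro-F1 %.4f", s, nm, rep$macro["f1"]))
    }
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      export_sample_cams(fits$prior$fit$model, va_data$records, out_dir, s)
    }
    per_seed[[as.character(s)]] <- fits
  }
  metric <- function(nm, what) vapply(per_seed, function(x)
    unname(x[[nm]]$report$macro[what]), 0)
  aggregate <- do.call(rbind, lapply(c("prior", "baseline"), function(nm) {
    data.frame(model = nm,
               macro_precision_mean = mean(metric(nm, "precision")),
               macro_recall_mean = mean(metric(nm, "recall")),
               macro_f1_mean = mean(metric(nm, "f1")),
               macro_f1_sd = sd(metric(nm, "f1")))
  }))
  list(per_seed = per_seed, aggregate = aggregate,
       delta_macro_f1 = metric("prior", "f1") - metric("baseline", "f1"))
}

# Write CAM heatmaps for a few validation patches of each class.
export_sample_cams <- function(model, records, out_dir, seed,
                               per_class = 2L) {
  if (is.null(model$fwb)) return(invisible(NULL))
  labs <- vapply(records, `[[`, "", "label")
  for (cl in unique(labs)) {
    idx <- which(labs == cl)[seq_len(min(per_class, sum(labs == cl)))]
    for (i in idx) {
      p <- predict(model, records[[i]]$image)
      write_cam_png(p$cams[, , 1],
                    file.path(out_dir, sprintf("cam_seed%d_%s_%d.png",
                                               seed, cl, i)))
    }
  }
  invisible(NULL)
}
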