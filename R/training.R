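#' Training run configuration
#'
#' @param batch_size Mini-batch size (default 16).
#' @param base_lr Base learning rate (default 0.0037).
#' @param lr_strategy Learning-rate decline strategy: `"exponential_warmup"`
#'   (linear ramp from 0 to `base_lr` over the warmup fraction, then
#'   per-epoch exponential decay), `"piecewise"` (x0.1 steps at 1/3 and 2/3
#'   of training) or `"cosine"` (half-cosine to 0).
#' @param epochs Training epochs (default 15 at desk scale; 60 at full scale).
#' @param warmup_fraction Fraction of total steps spent ramping up (default
#'   0.1; exponential_warmup only).
#' @param decay_rate Per-epoch exponential decay after warmup (default 0.96).
#' @param momentum SGD momentum (default 0.9).
#' @param clip_norm Global L2 gradient-norm ceiling per step (default 5);
#'   `Inf` disables clipping. A loose safety net against the occasional very
#'   large soft-loss gradients that the low-temperature early phase can
#'   produce on a randomly initialized student; at the default it rarely
#'   engages and does not alter well-behaved runs.
#' @param schedule A [schedule_params()] for the distillation decay schedules.
#' @param distill List of distillation flags: `renormalize` (renormalize the
#'   fused teacher label, default `TRUE`), `t_squared_scaling` (default
#'   `FALSE`), `lambda_const` (if non-`NULL`, freeze the loss weight at this
#'   constant instead of the sigmoid schedule).
#' @param seed Seed governing batch shuffling.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(batch_size = 16, base_lr = 0.0037,
                       lr_strategy = c("exponential_warmup", "piecewise", "cosine"),
                       epochs = 15, warmup_fraction = 0.1, decay_rate = 0.96,
                       momentum = 0.9, clip_norm = 5, schedule = schedule_params(),
                       distill = list(), seed = 1) {
  lr_strategy <- match.arg(lr_strategy)
  stopifnot(batch_size >= 1, base_lr > 0, epochs >= 0,
            warmup_fraction >= 0, warmup_fraction < 1,
            decay_rate > 0, decay_rate <= 1,
            momentum >= 0, momentum < 1, clip_norm > 0,
            inherits(schedule, "schedule_params"))
  dflt <- list(renormalize = TRUE, t_squared_scaling = FALSE, lambda_const = NULL)
  dflt[names(distill)] <- distill
  structure(
    list(batch_size = as.integer(batch_size), base_lr = base_lr,
         lr_strategy = lr_strategy, epochs = as.integer(epochs),
         warmup_fraction = warmup_fraction, decay_rate = decay_rate,
         momentum = momentum, clip_norm = clip_norm,
         schedule = schedule, distill = dflt,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Learning rate at a training step
#'
#' @param step Step index in `[0, total_steps]`.
#' @param total_steps Total number of optimizer steps.
#' @param cfg A [run_config()].
#' @return The learning rate; non-negative, never above `base_lr` once warmup
#'   has completed.
#' @export
lr_at <- function(step, total_steps, cfg) {
  stopifnot(inherits(cfg, "run_config"), step >= 0, step <= total_steps,
            total_steps >= 1)
  progress <- step / total_steps
  switch(cfg$lr_strategy,
    exponential_warmup = {
      ws <- floor(cfg$warmup_fraction * total_steps)
      if (step < ws) {
        cfg$base_lr * step / ws
      } else {
        steps_per_epoch <- max(1, total_steps / max(cfg$epochs, 1))
        cfg$base_lr * cfg$decay_rate^floor((step - ws) / steps_per_epoch)
      }
    },
    piecewise = cfg$base_lr * 0.1^findInterval(progress, c(1 / 3, 2 / 3)),
    cosine = cfg$base_lr * (1 + cos(pi * progress)) / 2,
    stop("unknown lr strategy", call. = FALSE)
  )
}

one_hot_matrix <- function(labels, n_classes) {
  Y <- matrix(0, length(labels), n_classes)
  Y[cbind(seq_along(labels), labels + 1L)] <- 1
  Y
}

# shared mini-batch SGD loop for plain supervised training (teachers NULL)
# and DTSD distillation (teacher logits supplied); both modes consume the
# random stream identically so the lambda == 1 endpoint reproduces supervised
# training exactly
fit_network <- function(model, split, cfg, teacher_logits = NULL) {
  train <- split$train
  if (length(train) == 0L) stop("empty training partition", call. = FALSE)
  n <- length(train)
  size <- model$spec$input_size
  K <- model$spec$n_classes
  X <- images_to_matrix(train, size)
  Y <- one_hot_matrix(dataset_labels(train), K)
  Xval <- if (length(split$val) > 0) images_to_matrix(split$val, size) else NULL
  yval <- if (!is.null(Xval)) dataset_labels(split$val) else NULL

  steps_per_epoch <- ceiling(n / cfg$batch_size)
  total_steps <- max(1L, cfg$epochs * steps_per_epoch)
  distilling <- !is.null(teacher_logits)

  vel <- lapply(model$layers, function(ly) {
    if (!is.null(ly$W)) list(W = ly$W * 0, b = ly$b * 0) else NULL
  })
  hist_n <- cfg$epochs * steps_per_epoch
  history <- data.frame(step = integer(hist_n), lr = numeric(hist_n),
                        T = numeric(hist_n), lambda = numeric(hist_n),
                        l_soft = numeric(hist_n), l_hard = numeric(hist_n),
                        total = numeric(hist_n))
  epoch_metrics <- data.frame(epoch = integer(0), val_accuracy = numeric(0))

  set.seed(cfg$seed)
  step <- 0L
  best <- list(accuracy = -Inf, layers = NULL, epoch = NA_integer_)
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    for (bs in seq(1L, n, by = cfg$batch_size)) {
      step <- step + 1L
      idx <- perm[bs:min(bs + cfg$batch_size - 1L, n)]
      B <- length(idx)
      lr <- lr_at(step, total_steps, cfg)
      x <- progress_fraction(step, total_steps)
      fwd <- forward_pass(model, X[, batch_cols(idx), drop = FALSE], B,
                          keep_cache = TRUE)
      logits <- fwd$logits
      if (any(!is.finite(logits))) {
        stop("training diverged: non-finite logits at step ", step, call. = FALSE)
      }
      yb <- Y[idx, , drop = FALSE]
      if (distilling) {
        lb <- compute_distill_loss(
          logits, teacher_logits$t1[idx, , drop = FALSE],
          teacher_logits$t2[idx, , drop = FALSE], yb, x,
          params = cfg$schedule,
          renormalize = cfg$distill$renormalize,
          t_squared_scaling = cfg$distill$t_squared_scaling,
          lambda_override = cfg$distill$lambda_const)
        soft_teacher <- combine_teacher_soft_labels(
          teacher_logits$t1[idx, , drop = FALSE],
          teacher_logits$t2[idx, , drop = FALSE],
          lb$T, cfg$distill$renormalize)
        dlogits <- distill_loss_grad(logits, soft_teacher, yb, lb$T, lb$lambda,
                                     cfg$distill$t_squared_scaling)
        rec <- c(lb$T, lb$lambda, lb$l_soft, lb$l_hard, lb$total)
      } else {
        p <- temperature_softmax(logits, 1)
        l_hard <- mean(-log(pmax(rowSums(yb * p), .eps_prob)))
        dlogits <- (p - yb) / B
        rec <- c(NA_real_, 1, 0, l_hard, l_hard)
      }
      if (!is.finite(rec[5])) {
        stop("training diverged: non-finite loss at step ", step, call. = FALSE)
      }
      grads <- backward_pass(model, fwd$cache, dlogits, B)
      if (is.finite(cfg$clip_norm)) {
        gnorm <- sqrt(sum(vapply(grads, function(g) {
          if (is.null(g)) 0 else sum(g$dW^2) + sum(g$db^2)
        }, numeric(1))))
        if (gnorm > cfg$clip_norm) {
          sc <- cfg$clip_norm / gnorm
          grads <- lapply(grads, function(g) {
            if (is.null(g)) NULL else list(dW = g$dW * sc, db = g$db * sc)
          })
        }
      }
      for (i in seq_along(model$layers)) {
        if (is.null(grads[[i]])) next
        vel[[i]]$W <- cfg$momentum * vel[[i]]$W - lr * grads[[i]]$dW
        vel[[i]]$b <- cfg$momentum * vel[[i]]$b - lr * grads[[i]]$db
        model$layers[[i]]$W <- model$layers[[i]]$W + vel[[i]]$W
        model$layers[[i]]$b <- model$layers[[i]]$b + vel[[i]]$b
      }
      history[step, ] <- c(step, lr, rec[1], rec[2], rec[3], rec[4], rec[5])
    }
    if (!is.null(Xval)) {
      pred <- predict_matrix_classes(model, Xval, length(yval))
      acc <- mean(pred == yval)
      epoch_metrics <- rbind(epoch_metrics,
        data.frame(epoch = epoch, val_accuracy = acc))
      # checkpoint selection: keep the earliest epoch with the best
      # validation accuracy rather than the final-step snapshot
      if (acc > best$accuracy) {
        best <- list(accuracy = acc, layers = model$layers, epoch = epoch)
      }
    }
  }
  if (!is.null(best$layers)) {
    model$layers <- best$layers
  }
  list(model = model,
       best_epoch = best$epoch,
       history = list(steps = history[seq_len(step), , drop = FALSE],
                      epochs = epoch_metrics))
}

predict_matrix_classes <- function(model, X, n, batch_size = 64) {
  out <- integer(n)
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    lg <- forward_pass(model, X[, batch_cols(idx), drop = FALSE],
                       length(idx))$logits
    out[idx] <- max.col(lg) - 1L
  }
  out
}

#' Train a classifier on hard labels
#'
#' Plain supervised training: mini-batch SGD with momentum on the
#' cross-entropy loss under the configured learning-rate schedule. This is
#' both how teacher networks are prepared for distillation and the
#' no-distillation baseline for the student.
#'
#' @param spec A [model_spec()] (or an already-initialized `"dtsd_model"` to
#'   continue training).
#' @param split A [stratified_split()] result; only `train` (and `val`, for
#'   per-epoch accuracy) are used.
#' @param cfg A [run_config()].
#' @return List with `model` (the trained `"dtsd_model"`; when a validation
#'   partition is present, the weights of the earliest epoch with the best
#'   validation accuracy, otherwise the final weights), `best_epoch` (the
#'   selected epoch, or `NA` without validation data) and `history`
#'   (per-step loss records plus per-epoch validation accuracy).
#' @export
train_supervised <- function(spec, split, cfg = run_config()) {
  model <- if (inherits(spec, "dtsd_model")) spec else init_network(spec)
  fit_network(model, split, cfg, teacher_logits = NULL)
}

#' Train a student under dual-teacher supervised decay
#'
#' Per optimizer step: the training-progress fraction sets the temperature
#' `T` and weight `lambda` from their sigmoid schedules; both frozen
#' teachers' logits (precomputed, no gradients) are softened at `T` and fused
#' by element-wise maximum; the soft loss is the Jensen-Shannon divergence
#' between the fused label and the student's `T`-softened output, the hard
#' loss is cross-entropy against ground truth, and the student is updated on
#' `(1 - lambda) * L_soft + lambda * L_hard`.
#'
#' @param student_spec A [model_spec()] for the student (or an initialized
#'   `"dtsd_model"`).
#' @param teacher1,teacher2 Trained `"dtsd_model"` teachers over the same
#'   label space.
#' @param split A [stratified_split()] result.
#' @param cfg A [run_config()]; `cfg$distill` controls fusion and schedule
#'   overrides.
#' @return List with `model`, `best_epoch` and `history` as in
#'   [train_supervised()]; the per-step history records `T`, `lambda`,
#'   soft, hard and total loss for every step.
#' @export
distill_student <- function(student_spec, teacher1, teacher2, split,
                            cfg = run_config()) {
  model <- if (inherits(student_spec, "dtsd_model")) student_spec
           else init_network(student_spec)
  K <- model$spec$n_classes
  if (teacher1$spec$n_classes != K || teacher2$spec$n_classes != K) {
    stop("teachers and student must share the same label space", call. = FALSE)
  }
  teacher_logits <- list(
    t1 = predict_logits(teacher1, split$train),
    t2 = predict_logits(teacher2, split$train)
  )
  fit_network(model, split, cfg, teacher_logits = teacher_logits)
}

#' Evaluate a model on labeled images
#'
#' @param model A `"dtsd_model"`.
#' @param items Non-empty list of labeled images.
#' @return An object of class `"eval_report"`: `accuracy`, the
#'   `n_classes x n_classes` confusion count matrix (rows = true class,
#'   columns = predicted), and informational `per_image_seconds`.
#' @export
evaluate <- function(model, items) {
  if (length(items) == 0L) stop("`items` must be non-empty", call. = FALSE)
  t0 <- proc.time()[["elapsed"]]
  pred <- predict_classes(model, items)
  elapsed <- proc.time()[["elapsed"]] - t0
  truth <- dataset_labels(items)
  K <- model$spec$n_classes
  confusion <- matrix(0L, K, K,
                      dimnames = list(true = 0:(K - 1), pred = 0:(K - 1)))
  for (i in seq_along(truth)) {
    confusion[truth[i] + 1L, pred[i] + 1L] <-
      confusion[truth[i] + 1L, pred[i] + 1L] + 1L
  }
  structure(
    list(accuracy = mean(pred == truth), confusion = confusion,
         per_image_seconds = elapsed / length(items), n = length(items)),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f on %d images (%.4f s/image)\n",
              x$accuracy, x$n, x$per_image_seconds))
  invisible(x)
}

#' Export a training history to CSV
#'
#' Writes the per-step records (step, lr, T, lambda, l_soft, l_hard, total)
#' and, when present, the per-epoch validation metrics.
#'
#' @param history The `history` element returned by [train_supervised()] or
#'   [distill_student()].
#' @param path Output CSV path for the step records.
#' @param epoch_path Optional CSV path for per-epoch metrics.
#' @return Invisibly, `path`.
#' @export
write_history <- function(history, path, epoch_path = NULL) {
  utils::write.csv(history$steps, path, row.names = FALSE)
  if (!is.null(epoch_path) && nrow(history$epochs) > 0) {
    utils::write.csv(history$epochs, epoch_path, row.names = FALSE)
  }
  invisible(path)
}
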