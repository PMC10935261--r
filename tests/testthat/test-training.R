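make_tiny_split <- function(seed = 42, noise_sd = 0.08) {
  ds <- tiny_dataset(n_classes = 3, per_class = 40, size = 16, seed = seed,
                     noise_sd = noise_sd)
  stratified_split(ds, c(0.5, 0.25, 0.25), seed = seed)
}

tiny_cfg <- function(epochs, seed = 1, ...) {
  run_config(batch_size = 8, epochs = epochs, seed = seed, ...)
}

test_that("learning-rate schedules hit their documented anchor points", {
  cfg <- run_config(epochs = 10)
  total <- 100
  # warmup: zero at step 0, base_lr at warmup end, decaying per epoch after
  expect_equal(lr_at(0, total, cfg), 0)
  ws <- floor(0.1 * total)
  expect_equal(lr_at(ws, total, cfg), 0.0037)
  expect_equal(lr_at(ws + 10, total, cfg), 0.0037 * 0.96)
  # piecewise: x0.1 at thirds
  pw <- run_config(lr_strategy = "piecewise", epochs = 10)
  expect_equal(lr_at(10, total, pw), 0.0037)
  expect_equal(lr_at(50, total, pw), 0.00037)
  expect_equal(lr_at(90, total, pw), 0.000037)
  # cosine: base at 0, zero at the end
  cs <- run_config(lr_strategy = "cosine", epochs = 10)
  expect_equal(lr_at(0, total, cs), 0.0037)
  expect_equal(lr_at(100, total, cs), 0, tolerance = 1e-12)
  expect_equal(lr_at(50, total, cs), 0.0037 / 2)
  # never negative, never above base after warmup start
  lrs <- vapply(0:100, lr_at, numeric(1), total_steps = total, cfg = cfg)
  expect_true(all(lrs >= 0 & lrs <= 0.0037 + 1e-15))
})

test_that("network registry builds models with student smaller than teacher", {
  teacher <- init_network(model_spec("tiny-cnn-teacher", n_classes = 5,
                                     input_size = 32))
  student <- init_network(model_spec("tiny-cnn-student", n_classes = 5,
                                     input_size = 32))
  expect_lt(n_parameters(student), n_parameters(teacher))
  # deterministic initialization
  again <- init_network(model_spec("tiny-cnn-teacher", n_classes = 5,
                                   input_size = 32))
  expect_identical(teacher, again)
})

test_that("network gradients match finite differences on a micro-batch", {
  spec <- model_spec("tiny-cnn-student", n_classes = 3, input_size = 16, seed = 2)
  model <- init_network(spec)
  set.seed(9)
  B <- 2
  X <- matrix(runif(16 * 16 * 3 * B), 16 * 16, 3 * B)
  Y <- matrix(0, B, 3); Y[cbind(1:B, c(1, 3))] <- 1
  loss_of <- function(m) {
    p <- temperature_softmax(forward_pass(m, X, B)$logits, 1)
    mean(-log(pmax(rowSums(Y * p), 1e-12)))
  }
  fwd <- forward_pass(model, X, B, keep_cache = TRUE)
  p <- temperature_softmax(fwd$logits, 1)
  grads <- dtsdistill:::backward_pass(model, fwd$cache, (p - Y) / B, B)
  eps <- 1e-6
  for (li in seq_along(model$layers)) {
    if (is.null(grads[[li]])) next
    # probe a handful of weights per layer
    set.seed(li)
    for (k in sample(length(model$layers[[li]]$W), 4)) {
      mp <- model; mp$layers[[li]]$W[k] <- mp$layers[[li]]$W[k] + eps
      mm <- model; mm$layers[[li]]$W[k] <- mm$layers[[li]]$W[k] - eps
      num <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
      expect_equal(grads[[li]]$dW[k], num, tolerance = 1e-4)
    }
  }
})

test_that("supervised training is deterministic and learns the tiny dataset", {
  sp <- make_tiny_split()
  spec <- model_spec("tiny-cnn-student", n_classes = 3, input_size = 16, seed = 1)
  f1 <- train_supervised(spec, sp, tiny_cfg(15, base_lr = 0.01))
  f2 <- train_supervised(spec, sp, tiny_cfg(15, base_lr = 0.01))
  expect_identical(f1$model$layers, f2$model$layers)
  expect_identical(f1$history, f2$history)
  expect_gt(tail(f1$history$epochs$val_accuracy, 1), 0.5)
  # zero epochs: untouched initial weights, empty history
  f0 <- train_supervised(spec, sp, tiny_cfg(0))
  expect_identical(f0$model$layers, init_network(spec)$layers)
  expect_equal(nrow(f0$history$steps), 0)
})

test_that("hard-only distillation reproduces plain supervised training exactly", {
  sp <- make_tiny_split()
  tspec <- model_spec("tiny-cnn-teacher", n_classes = 3, input_size = 16, seed = 3)
  teacher <- train_supervised(tspec, sp, tiny_cfg(3, seed = 3))$model
  sspec <- model_spec("tiny-cnn-student", n_classes = 3, input_size = 16, seed = 4)
  plain <- train_supervised(sspec, sp, tiny_cfg(4, seed = 4))
  hard_only <- distill_student(sspec, teacher, teacher, sp,
                               tiny_cfg(4, seed = 4,
                                        distill = list(lambda_const = 1)))
  expect_equal(hard_only$history$steps$l_hard, plain$history$steps$l_hard,
               tolerance = 1e-6)
  expect_equal(hard_only$history$steps$total, plain$history$steps$total,
               tolerance = 1e-6)
  expect_identical(hard_only$model$layers, plain$model$layers)
  expect_identical(hard_only$history$epochs, plain$history$epochs)
})

test_that("distillation history records the scheduled decay step by step", {
  sp <- make_tiny_split()
  tspec <- model_spec("tiny-cnn-teacher", n_classes = 3, input_size = 16, seed = 3)
  teacher <- train_supervised(tspec, sp, tiny_cfg(3, seed = 3))$model
  sspec <- model_spec("tiny-cnn-student", n_classes = 3, input_size = 16, seed = 4)
  fit <- distill_student(sspec, teacher, teacher, sp, tiny_cfg(5, seed = 4))
  h <- fit$history$steps
  expect_true(all(diff(h$step) == 1))
  expect_true(all(diff(h$T) > 0))
  expect_true(all(diff(h$lambda) < 0))
  expect_equal(h$total, (1 - h$lambda) * h$l_soft + h$lambda * h$l_hard,
               tolerance = 1e-6)
  expect_true(all(is.finite(h$total)))
  # label-space mismatch refused
  bad <- init_network(model_spec("tiny-cnn-teacher", n_classes = 4,
                                 input_size = 16))
  expect_error(distill_student(sspec, bad, teacher, sp, tiny_cfg(1)),
               "label space")
})

test_that("evaluation reports accuracy consistent with its confusion matrix", {
  sp <- make_tiny_split()
  spec <- model_spec("tiny-cnn-student", n_classes = 3, input_size = 16, seed = 1)
  fit <- train_supervised(spec, sp, tiny_cfg(6))
  rep <- evaluate(fit$model, sp$test)
  expect_equal(sum(diag(rep$confusion)) / sum(rep$confusion), rep$accuracy)
  expect_equal(unname(rowSums(rep$confusion)),
               unname(as.vector(table(factor(dataset_labels(sp$test), 0:2)))))
  expect_gte(rep$per_image_seconds, 0)
  expect_error(evaluate(fit$model, list()), "non-empty")
})

test_that("checkpoints round-trip weights and label maps", {
  spec <- model_spec("tiny-cnn-student", n_classes = 3, input_size = 16, seed = 6)
  model <- init_network(spec)
  path <- tempfile(fileext = ".rds")
  on.exit(unlink(path))
  save_checkpoint(model, path, class_names = c("a", "b", "c"))
  back <- load_checkpoint(path)
  expect_identical(back$layers, model$layers)
  expect_identical(attr(back, "class_names"), c("a", "b", "c"))
  saveRDS(list(foo = 1), path)
  expect_error(load_checkpoint(path), "checkpoint")
})
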