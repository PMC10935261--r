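#' Specification of a small convolutional classifier
#'
#' The registry holds desk-scale convolutional architectures that stand in
#' for the large published backbones usually paired with knowledge
#' distillation: `"tiny-cnn-teacher"` (four 3x3 conv blocks with average
#' pooling, global average pooling, linear head; ~47k parameters) and
#' `"tiny-cnn-student"` (two conv blocks, ~1.5k parameters). Both begin with
#' an average-pooling stem so compute stays modest at 64 px inputs. The
#' student always has fewer parameters than the teacher.
#'
#' @param architecture Registry name, `"tiny-cnn-teacher"` or
#'   `"tiny-cnn-student"`.
#' @param n_classes Number of output classes.
#' @param input_size Square input side in pixels (default 64); images of a
#'   different size are resized at ingestion.
#' @param seed Seed for weight initialization.
#' @return An object of class `"model_spec"`.
#' @export
model_spec <- function(architecture = c("tiny-cnn-teacher", "tiny-cnn-student"),
                       n_classes, input_size = 64, seed = 1) {
  architecture <- match.arg(architecture)
  stopifnot(is.numeric(n_classes), n_classes >= 2,
            is.numeric(input_size), input_size >= 16,
            input_size %% 16 == 0)
  structure(
    list(architecture = architecture, n_classes = as.integer(n_classes),
         input_size = as.integer(input_size), seed = as.integer(seed)),
    class = "model_spec"
  )
}

# layer plans: stem pooling keeps conv cost low at 64 px
arch_plan <- function(architecture, n_classes) {
  switch(architecture,
    "tiny-cnn-teacher" = list(
      list(type = "pool", f = 2L),
      list(type = "conv", c_out = 16L), list(type = "relu"),
      list(type = "pool", f = 2L),
      list(type = "conv", c_out = 32L), list(type = "relu"),
      list(type = "pool", f = 2L),
      list(type = "conv", c_out = 48L), list(type = "relu"),
      list(type = "pool", f = 2L),
      list(type = "conv", c_out = 64L), list(type = "relu"),
      list(type = "gap"),
      list(type = "dense", c_out = as.integer(n_classes))
    ),
    "tiny-cnn-student" = list(
      list(type = "pool", f = 2L),
      list(type = "conv", c_out = 12L), list(type = "relu"),
      list(type = "pool", f = 2L),
      list(type = "conv", c_out = 24L), list(type = "relu"),
      list(type = "pool", f = 2L),
      list(type = "gap"),
      list(type = "dense", c_out = as.integer(n_classes))
    ),
    stop("unknown architecture: ", architecture, call. = FALSE)
  )
}

# 3x3 same-padding gather indices for an h x w grid (column-major pixels);
# out-of-bounds neighbours point at the zero-pad row npix + 1
make_conv_geom <- function(h, w) {
  npix <- h * w
  rr <- rep(seq_len(h), times = w)
  cc <- rep(seq_len(w), each = h)
  idx <- integer(npix * 9L)
  k <- 0L
  for (dc in -1:1) {
    for (dr in -1:1) {
      k <- k + 1L
      nr <- rr + dr; nc <- cc + dc
      ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      v <- rep.int(npix + 1L, npix)
      v[ok] <- nr[ok] + (nc[ok] - 1L) * h
      idx[(k - 1L) * npix + seq_len(npix)] <- v
    }
  }
  list(npix = npix, idx = idx, h = h, w = w)
}

make_pool_geom <- function(h, w, f) {
  stopifnot(h %% f == 0, w %% f == 0)
  rr <- rep(seq_len(h), times = w)
  cc <- rep(seq_len(w), each = h)
  g <- ceiling(rr / f) + (ceiling(cc / f) - 1L) * (h %/% f)
  list(group = g, f = f, h_out = h %/% f, w_out = w %/% f)
}

#' Initialize a network from its specification
#'
#' He-normal weight initialization, deterministic under `spec$seed`.
#'
#' @param spec A [model_spec()].
#' @return An object of class `"dtsd_model"` holding layer geometry and
#'   parameters.
#' @export
init_network <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  plan <- arch_plan(spec$architecture, spec$n_classes)
  set.seed(spec$seed)
  h <- w <- spec$input_size; c_in <- 3L
  layers <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    ly <- plan[[i]]
    if (ly$type == "pool") {
      ly$geom <- make_pool_geom(h, w, ly$f)
      h <- ly$geom$h_out; w <- ly$geom$w_out
    } else if (ly$type == "conv") {
      ly$geom <- make_conv_geom(h, w)
      fan_in <- 9L * c_in
      ly$W <- matrix(stats::rnorm(fan_in * ly$c_out, 0, sqrt(2 / fan_in)),
                     fan_in, ly$c_out)
      ly$b <- numeric(ly$c_out)
      ly$c_in <- c_in
      c_in <- ly$c_out
    } else if (ly$type == "gap") {
      ly$npix <- h * w
    } else if (ly$type == "dense") {
      ly$W <- matrix(stats::rnorm(c_in * ly$c_out, 0, sqrt(2 / c_in)),
                     c_in, ly$c_out)
      ly$b <- numeric(ly$c_out)
      ly$c_in <- c_in
      c_in <- ly$c_out
    }
    layers[[i]] <- ly
  }
  structure(list(spec = spec, layers = layers), class = "dtsd_model")
}

#' Number of trainable parameters
#' @param model A `"dtsd_model"`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$layers, function(ly) {
    if (!is.null(ly$W)) length(ly$W) + length(ly$b) else 0L
  }, integer(1)))
}

conv_fwd <- function(X, ly, B) {
  npix <- ly$geom$npix; C <- ly$c_in
  Xp <- rbind(X, 0)
  G <- Xp[ly$geom$idx, , drop = FALSE]
  M <- matrix(aperm(array(G, c(npix, 9L, C, B)), c(1, 4, 2, 3)),
              npix * B, 9L * C)
  Y <- M %*% ly$W
  Y <- Y + rep(ly$b, each = npix * B)
  out <- matrix(aperm(array(Y, c(npix, B, ly$c_out)), c(1, 3, 2)),
                npix, ly$c_out * B)
  list(out = out, M = M)
}

conv_bwd <- function(dOut, ly, M, B) {
  npix <- ly$geom$npix; C <- ly$c_in; Cout <- ly$c_out
  dY <- matrix(aperm(array(dOut, c(npix, Cout, B)), c(1, 3, 2)),
               npix * B, Cout)
  dW <- crossprod(M, dY)
  db <- colSums(dY)
  dM <- tcrossprod(dY, ly$W)
  G <- matrix(aperm(array(dM, c(npix, B, 9L, C)), c(1, 3, 4, 2)),
              npix * 9L, C * B)
  rs <- rowsum(G, ly$geom$idx)
  dXp <- matrix(0, npix + 1L, C * B)
  dXp[as.integer(rownames(rs)), ] <- rs
  list(dX = dXp[seq_len(npix), , drop = FALSE], dW = dW, db = db)
}

# forward pass over a batch; X is (npix x 3B) with channel-fastest columns
forward_pass <- function(model, X, B, keep_cache = FALSE) {
  cache <- if (keep_cache) vector("list", length(model$layers)) else NULL
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (ly$type == "pool") {
      if (keep_cache) cache[[i]] <- NULL
      X <- rowsum(X, ly$geom$group) / ly$f^2
    } else if (ly$type == "conv") {
      r <- conv_fwd(X, ly, B)
      if (keep_cache) cache[[i]] <- r$M
      X <- r$out
    } else if (ly$type == "relu") {
      if (keep_cache) cache[[i]] <- X > 0
      X <- X * (X > 0)
    } else if (ly$type == "gap") {
      C <- length(colMeans(X)) / B
      X <- t(matrix(colMeans(X), C, B))
    } else if (ly$type == "dense") {
      if (keep_cache) cache[[i]] <- X
      X <- X %*% ly$W + rep(ly$b, each = nrow(X))
    }
  }
  list(logits = X, cache = cache)
}

# backward pass; dlogits is B x n_classes, returns per-layer gradients
backward_pass <- function(model, cache, dlogits, B) {
  grads <- vector("list", length(model$layers))
  d <- dlogits
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    if (ly$type == "dense") {
      feat <- cache[[i]]
      grads[[i]] <- list(dW = crossprod(feat, d), db = colSums(d))
      d <- tcrossprod(d, ly$W)
    } else if (ly$type == "gap") {
      npix <- ly$npix
      d <- matrix(rep(as.vector(t(d)), each = npix) / npix, npix,
                  ncol(d) * nrow(d))
    } else if (ly$type == "relu") {
      d <- d * cache[[i]]
    } else if (ly$type == "conv") {
      r <- conv_bwd(d, ly, cache[[i]], B)
      grads[[i]] <- list(dW = r$dW, db = r$db)
      d <- r$dX
    } else if (ly$type == "pool") {
      d <- d[ly$geom$group, , drop = FALSE] / ly$f^2
    }
  }
  grads
}

# convert labeled images to the (npix x 3N) column-major feature matrix,
# resizing to the model input size when needed
images_to_matrix <- function(items, size) {
  n <- length(items)
  npix <- size * size
  X <- matrix(0, npix, 3L * n)
  for (i in seq_len(n)) {
    img <- items[[i]]$image
    if (dim(img)[1] != size || dim(img)[2] != size) {
      img <- resize_to(img, size, size)
    }
    X[, (3L * i - 2L):(3L * i)] <- matrix(img, npix, 3L)
  }
  X
}

# column block for a subset of images in an images_to_matrix() matrix
batch_cols <- function(idx) as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))

#' Logits of a trained model on labeled images
#'
#' @param model A `"dtsd_model"`.
#' @param items List of labeled images.
#' @param batch_size Forward-pass batch size (default 64).
#' @return Numeric matrix, one row per item, one column per class.
#' @export
predict_logits <- function(model, items, batch_size = 64) {
  X <- images_to_matrix(items, model$spec$input_size)
  n <- length(items)
  out <- matrix(0, n, model$spec$n_classes)
  starts <- seq(1L, n, by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, n)
    out[idx, ] <- forward_pass(model, X[, batch_cols(idx), drop = FALSE],
                               length(idx))$logits
  }
  out
}

#' Predicted class labels (0-based)
#' @inheritParams predict_logits
#' @return Integer vector of 0-based predicted classes.
#' @export
predict_classes <- function(model, items, batch_size = 64) {
  max.col(predict_logits(model, items, batch_size)) - 1L
}

#' Save / load a model checkpoint
#'
#' Checkpoints are serialized R objects embedding the architecture spec, all
#' weights, and an optional label map.
#'
#' @param model A `"dtsd_model"`.
#' @param path File path.
#' @param class_names Optional character vector mapping class indices to
#'   names.
#' @return `save_checkpoint` invisibly returns `path`; `load_checkpoint`
#'   returns the model with attribute `"class_names"`.
#' @export
save_checkpoint <- function(model, path, class_names = NULL) {
  saveRDS(list(model = model, class_names = class_names,
               format = "dtsdistill-checkpoint-v1"), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "dtsdistill-checkpoint-v1")) {
    stop("not a dtsdistill checkpoint: ", path, call. = FALSE)
  }
  structure(obj$model, class_names = obj$class_names)
}
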