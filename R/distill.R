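#' @title Soft-label fusion and distillation losses
#' @description Core probability machinery of dual-teacher supervised decay:
#'   temperature-scaled softmax, element-wise max fusion of the two teachers'
#'   soft labels, KL / Jensen-Shannon divergences, hard-label cross-entropy,
#'   and the composed total loss.
#' @name distill-core
NULL

# probability floor used inside logarithms
.eps_prob <- 1e-12

check_distribution <- function(p, arg = "p") {
  if (!is.numeric(p) || length(p) < 2L || any(!is.finite(p))) {
    stop(sprintf("`%s` must be a finite numeric vector of length >= 2", arg),
         call. = FALSE)
  }
  if (any(p < -1e-9) || abs(sum(p) - 1) > 1e-6) {
    stop(sprintf("`%s` must be a probability distribution (non-negative, sum 1)", arg),
         call. = FALSE)
  }
  invisible(p)
}

#' Temperature-scaled softmax
#'
#' Divides each logit by the temperature `T` before softmax normalization.
#' `T > 1` flattens the distribution (exposing more dark knowledge), `T < 1`
#' sharpens it. Computed shift-stably by subtracting the row maximum before
#' exponentiation.
#'
#' @param logits Numeric vector of unnormalized scores, or a matrix with one
#'   sample per row.
#' @param temperature Positive scalar temperature.
#' @return A probability vector (or row-stochastic matrix) of the same shape.
#' @examples
#' temperature_softmax(c(1, 0), 0.5)
#' @export
temperature_softmax <- function(logits, temperature = 1) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be a positive finite scalar", call. = FALSE)
  }
  temperature <- max(temperature, .t_floor)
  if (is.matrix(logits)) {
    if (ncol(logits) < 2L || any(!is.finite(logits))) {
      stop("`logits` must be finite with >= 2 classes", call. = FALSE)
    }
    z <- logits / temperature
    z <- z - apply(z, 1L, max)
    e <- exp(z)
    return(e / rowSums(e))
  }
  if (!is.numeric(logits) || length(logits) < 2L || any(!is.finite(logits))) {
    stop("`logits` must be a finite numeric vector of length >= 2", call. = FALSE)
  }
  z <- logits / temperature
  e <- exp(z - max(z))
  e / sum(e)
}

#' Element-wise maximum of two teacher predictive distributions
#'
#' Fuses two teachers' class-probability vectors by taking, in each class
#' dimension, the larger of the two probabilities. The result dominates both
#' inputs element-wise and its sum is >= 1; it is *not* itself a distribution
#' (see [combine_teacher_soft_labels()] for the renormalized soft label).
#'
#' @param p,q Probability vectors of equal length (or matrices of equal shape,
#'   one sample per row).
#' @return The element-wise maximum, same shape as the inputs.
#' @examples
#' max_out(c(0.7, 0.2, 0.1), c(0.1, 0.2, 0.7))
#' @export
max_out <- function(p, q) {
  if (length(p) != length(q)) {
    stop("`p` and `q` must have the same length", call. = FALSE)
  }
  if (is.matrix(p) != is.matrix(q)) {
    stop("`p` and `q` must both be vectors or both matrices", call. = FALSE)
  }
  pmax(p, q)
}

#' Fused dual-teacher soft label
#'
#' Temperature-softmaxes each teacher's logits at `temperature`, combines the
#' two distributions with [max_out()], and (by default) renormalizes the
#' combined vector to sum 1 so that divergence losses against it are
#' well-defined.
#'
#' @param logits1,logits2 The two teachers' logit vectors (or matrices, one
#'   sample per row) over the same label space.
#' @param temperature Positive scalar distillation temperature.
#' @param renormalize Divide the fused vector by its sum (default `TRUE`).
#'   `FALSE` returns the raw element-wise maximum for ablation.
#' @return The fused soft label, same shape as the inputs.
#' @examples
#' combine_teacher_soft_labels(c(2, 1, 0), c(0, 1, 2), temperature = 1)
#' @export
combine_teacher_soft_labels <- function(logits1, logits2, temperature = 1,
                                        renormalize = TRUE) {
  m <- max_out(temperature_softmax(logits1, temperature),
               temperature_softmax(logits2, temperature))
  if (!renormalize) return(m)
  if (is.matrix(m)) m / rowSums(m) else m / sum(m)
}

#' Kullback-Leibler divergence between two distributions
#'
#' `KL(P, Q) = sum_x p(x) * log(p(x) / q(x))` in nats, with the conventions
#' `0 * log(0 / .) = 0` and probabilities floored at 1e-12 inside the
#' logarithm so support mismatches stay finite.
#'
#' @param p,q Probability vectors of equal length.
#' @return Non-negative scalar divergence.
#' @examples
#' kl_divergence(c(1, 0), c(0.5, 0.5))  # log(2)
#' @export
kl_divergence <- function(p, q) {
  if (length(p) != length(q)) {
    stop("`p` and `q` must have the same length", call. = FALSE)
  }
  check_distribution(p, "p"); check_distribution(q, "q")
  nz <- p > 0
  sum(p[nz] * (log(pmax(p[nz], .eps_prob)) - log(pmax(q[nz], .eps_prob))))
}

#' Jensen-Shannon divergence between two distributions
#'
#' The symmetrized, bounded divergence used as the soft loss:
#' `JS(P1, P2) = KL(P1, M)/2 + KL(P2, M)/2` with `M = (P1 + P2)/2`.
#' Always lies in `[0, log 2]` (nats).
#'
#' @param p1,p2 Probability vectors of equal length.
#' @return Scalar divergence in `[0, log(2)]`.
#' @examples
#' js_divergence(c(1, 0), c(0, 1))  # log(2)
#' @export
js_divergence <- function(p1, p2) {
  if (length(p1) != length(p2)) {
    stop("`p1` and `p2` must have the same length", call. = FALSE)
  }
  m <- (p1 + p2) / 2
  0.5 * kl_divergence(p1, m) + 0.5 * kl_divergence(p2, m)
}

#' Cross-entropy of a prediction against a one-hot hard label
#'
#' `CE(label, predict) = -sum_j label_j * log(predict_j)`, which for a one-hot
#' label reduces to `-log(predict[true class])`. Predictions are floored at
#' 1e-12 inside the logarithm. The label must be exactly one-hot: this
#' operation serves the hard-label branch of the loss only.
#'
#' @param label One-hot probability vector (a single 1, rest 0).
#' @param predict Predicted probability vector of the same length.
#' @return Non-negative scalar loss in nats.
#' @examples
#' cross_entropy(c(0, 1, 0), c(0.1, 0.8, 0.1))  # -log(0.8)
#' @export
cross_entropy <- function(label, predict) {
  if (length(label) != length(predict)) {
    stop("`label` and `predict` must have the same length", call. = FALSE)
  }
  if (!is_one_hot(label)) {
    stop("`label` must be one-hot", call. = FALSE)
  }
  check_distribution(predict, "predict")
  -sum(label * log(pmax(predict, .eps_prob)))
}

is_one_hot <- function(v) {
  is.numeric(v) && length(v) >= 2L && all(v %in% c(0, 1)) && sum(v) == 1
}

#' Full dual-teacher supervised-decay loss for one sample or batch
#'
#' Composes the schedule and loss primitives: at progress `x` the temperature
#' `T` and weight `lambda` are read from their sigmoid schedules; the two
#' teachers' logits are softened at `T` and fused via the element-wise
#' maximum; the soft loss is the Jensen-Shannon divergence between the fused
#' teacher label and the student's `T`-softened distribution; the hard loss is
#' the cross-entropy between the one-hot ground truth and the student's
#' ordinary (`T = 1`) softmax; and the total is the convex combination
#' `(1 - lambda) * L_soft + lambda * L_hard`.
#'
#' For matrix inputs (one sample per row, `hard_label` a one-hot matrix) the
#' returned losses are means over the batch.
#'
#' @param student_logits,teacher1_logits,teacher2_logits Logit vectors (or
#'   matrices) over the same label space.
#' @param hard_label One-hot ground-truth vector (or matrix).
#' @param x Scalar training-progress fraction in `[0, 1]`.
#' @param params A [schedule_params()] object.
#' @param renormalize Renormalize the fused teacher label (default `TRUE`).
#' @param t_squared_scaling Multiply the soft loss by `T^2` (the classical
#'   gradient-balancing factor; off by default).
#' @param lambda_override If non-`NULL`, use this constant weight instead of
#'   the schedule (used for hard-only / soft-only endpoints).
#' @return An object of class `"loss_breakdown"`: a list with fields
#'   `T`, `lambda`, `l_soft`, `l_hard`, `total`.
#' @examples
#' compute_distill_loss(c(0, 0, 0), c(2, 1, 0), c(0, 1, 2),
#'                      hard_label = c(1, 0, 0), x = 0.5)
#' @export
compute_distill_loss <- function(student_logits, teacher1_logits,
                                 teacher2_logits, hard_label, x,
                                 params = schedule_params(),
                                 renormalize = TRUE,
                                 t_squared_scaling = FALSE,
                                 lambda_override = NULL) {
  check_progress(x)
  stopifnot(length(x) == 1L)
  temp <- temperature_at(x, params)
  lam <- if (is.null(lambda_override)) lambda_at(x, params) else lambda_override
  stopifnot(is.numeric(lam), length(lam) == 1L, lam >= 0, lam <= 1)

  if (is.matrix(student_logits)) {
    soft_teacher <- combine_teacher_soft_labels(teacher1_logits, teacher2_logits,
                                                temp, renormalize)
    soft_student <- temperature_softmax(student_logits, temp)
    l_soft <- mean(js_rows(soft_teacher, soft_student))
    pred <- temperature_softmax(student_logits, 1)
    l_hard <- mean(-log(pmax(rowSums(hard_label * pred), .eps_prob)))
  } else {
    soft_teacher <- combine_teacher_soft_labels(teacher1_logits, teacher2_logits,
                                                temp, renormalize)
    soft_student <- temperature_softmax(student_logits, temp)
    l_soft <- js_divergence(soft_teacher, soft_student)
    l_hard <- cross_entropy(hard_label, temperature_softmax(student_logits, 1))
  }
  if (t_squared_scaling) l_soft <- l_soft * temp^2
  structure(
    list(T = temp, lambda = lam, l_soft = l_soft, l_hard = l_hard,
         total = (1 - lam) * l_soft + lam * l_hard),
    class = "loss_breakdown"
  )
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "DTSD loss: total %.5f = (1 - %.4f) * soft %.5f + %.4f * hard %.5f  [T = %.4f]\n",
    x$total, x$lambda, x$l_soft, x$lambda, x$l_hard, x$T))
  invisible(x)
}

# row-wise JS divergence between two row-stochastic matrices
js_rows <- function(p1, p2) {
  m <- (p1 + p2) / 2
  kl_rows(p1, m) / 2 + kl_rows(p2, m) / 2
}

kl_rows <- function(p, q) {
  term <- p * (log(pmax(p, .eps_prob)) - log(pmax(q, .eps_prob)))
  term[p <= 0] <- 0
  rowSums(term)
}

# Gradient of the batch DTSD loss w.r.t. the student logits.
# d JS(t, s) / d s_j = log(s_j / m_j) / 2 with m = (t + s)/2, composed with
# the temperature-softmax Jacobian; the hard branch is the usual
# (softmax - onehot). Returns the gradient of the *mean* loss.
distill_loss_grad <- function(student_logits, soft_teacher, hard_label,
                              temp, lam, t_squared_scaling = FALSE) {
  n <- nrow(student_logits)
  s <- temperature_softmax(student_logits, temp)
  m <- (soft_teacher + s) / 2
  g <- 0.5 * (log(pmax(s, .eps_prob)) - log(pmax(m, .eps_prob)))
  # softmax Jacobian at temperature temp: (diag(s) - s s') / temp
  gs <- s * (g - rowSums(g * s)) / temp
  if (t_squared_scaling) gs <- gs * temp^2
  p1 <- temperature_softmax(student_logits, 1)
  gh <- p1 - hard_label
  ((1 - lam) * gs + lam * gh) / n
}
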