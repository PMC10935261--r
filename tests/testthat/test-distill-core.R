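test_that("temperature softmax matches a direct exponentiation oracle", {
  expect_equal(temperature_softmax(c(0, 0), 2), c(0.5, 0.5))
  expect_equal(temperature_softmax(c(log(2), 0), 1), c(2 / 3, 1 / 3))
  expect_equal(temperature_softmax(c(1, 0), 0.5), softmax_oracle(c(1, 0), 0.5),
               tolerance = 1e-12)
  expect_equal(temperature_softmax(c(1, 0), 0.5)[1], 0.8808, tolerance = 1e-4)
  # shift stability: huge logits do not overflow
  expect_equal(sum(temperature_softmax(c(1000, 999, 998), 1)), 1)
  expect_error(temperature_softmax(c(1, 0), -1), "positive")
  expect_error(temperature_softmax(numeric(0), 1))
  # matrix form agrees with row-by-row vector form
  set.seed(1)
  Z <- matrix(rnorm(12), 3, 4)
  expect_equal(temperature_softmax(Z, 1.7),
               t(apply(Z, 1, temperature_softmax, temperature = 1.7)))
})

test_that("max_out is the element-wise maximum and dominates both inputs", {
  p <- c(0.7, 0.2, 0.1); q <- c(0.1, 0.2, 0.7)
  expect_equal(max_out(p, q), c(0.7, 0.2, 0.7))
  expect_equal(max_out(p, p), p)
  expect_equal(max_out(c(1, 0), c(0, 1)), c(1, 1))
  expect_error(max_out(c(0.5, 0.5), c(1, 0, 0)), "length")
  set.seed(2)
  for (i in 1:50) {
    a <- rand_dist(6); b <- rand_dist(6)
    m <- max_out(a, b)
    expect_true(all(m >= a) && all(m >= b))
    expect_gte(sum(m), 1)
  }
})

test_that("fused soft label renormalizes and reduces to one teacher when they agree", {
  # feeding log-probabilities at T = 1 recovers the distributions themselves
  p <- c(0.7, 0.2, 0.1); q <- c(0.1, 0.2, 0.7)
  fused <- combine_teacher_soft_labels(log(p), log(q), 1)
  expect_equal(fused, c(0.4375, 0.125, 0.4375), tolerance = 1e-12)
  expect_equal(sum(fused), 1)
  # identical teachers: fusion equals either teacher's softened output
  z <- c(2.1, -0.3, 0.8, 0)
  for (temp in c(0.5, 1, 2.5)) {
    expect_equal(combine_teacher_soft_labels(z, z, temp),
                 temperature_softmax(z, temp), tolerance = 1e-12)
  }
  # two one-hot teachers on different classes: uniform over those classes
  expect_equal(combine_teacher_soft_labels(c(50, 0, 0), c(0, 50, 0), 1),
               c(0.5, 0.5, 0), tolerance = 1e-12)
  # raw mode keeps the unnormalized maximum
  raw <- combine_teacher_soft_labels(log(p), log(q), 1, renormalize = FALSE)
  expect_equal(sum(raw), 1.6, tolerance = 1e-12)
})

test_that("KL divergence matches the two-term oracle and Gibbs' inequality", {
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), log(2))
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.75)), 0.1438410,
               tolerance = 1e-6)
  set.seed(3)
  for (i in 1:1000) {
    p <- rand_dist(5); q <- rand_dist(5)
    expect_equal(kl_divergence(p, q), kl_oracle(p, q), tolerance = 1e-10)
    expect_gte(kl_divergence(p, q), 0)
    expect_equal(kl_divergence(p, p), 0)
  }
  expect_error(kl_divergence(c(0.5, 0.5), c(1, 0, 0)), "length")
})

test_that("JS divergence is symmetric, bounded, and matches the KL-based oracle", {
  expect_equal(js_divergence(c(1, 0), c(0, 1)), log(2))
  expect_equal(js_divergence(c(0.8, 0.2), c(0.2, 0.8)), 0.1927448,
               tolerance = 1e-6)
  set.seed(4)
  for (i in 1:1000) {
    p <- rand_dist(4); q <- rand_dist(4)
    js <- js_divergence(p, q)
    expect_equal(js, js_divergence(q, p), tolerance = 1e-12)
    expect_equal(js, js_oracle(p, q), tolerance = 1e-10)
    expect_gte(js, 0)
    expect_lte(js, log(2) + 1e-12)
    expect_equal(js_divergence(p, p), 0)
  }
})

test_that("cross-entropy against a one-hot label is -log of the true-class mass", {
  expect_equal(cross_entropy(c(0, 1, 0), c(0.1, 0.8, 0.1)), -log(0.8))
  expect_equal(cross_entropy(c(1, 0), c(0.5, 0.5)), log(2))
  expect_lt(cross_entropy(c(0, 1, 0), c(1e-12, 1 - 2e-12, 1e-12)), 1e-9)
  expect_error(cross_entropy(c(0.5, 0.5), c(0.5, 0.5)), "one-hot")
  expect_error(cross_entropy(c(1, 1, 0), c(0.3, 0.3, 0.4)), "one-hot")
})

test_that("composed loss is the scheduled convex combination of its parts", {
  set.seed(5)
  K <- 6
  for (i in 1:50) {
    sl <- rnorm(K); t1 <- rnorm(K); t2 <- rnorm(K)
    y <- integer(K); y[sample.int(K, 1)] <- 1L
    x <- runif(1)
    lb <- compute_distill_loss(sl, t1, t2, y, x)
    expect_equal(lb$T, temperature_at(x))
    expect_equal(lb$lambda, lambda_at(x))
    expect_equal(lb$total, (1 - lb$lambda) * lb$l_soft + lb$lambda * lb$l_hard,
                 tolerance = 1e-9)
    expect_gte(lb$total, min(lb$l_soft, lb$l_hard) - 1e-12)
    expect_lte(lb$total, max(lb$l_soft, lb$l_hard) + 1e-12)
  }
})

test_that("composed loss endpoints behave like pure soft / pure hard training", {
  z <- c(1.2, -0.4, 0.3)
  y <- c(1, 0, 0)
  # student identical to both teachers, lambda forced to 0: only JS remains, = 0
  lb0 <- compute_distill_loss(z, z, z, y, x = 0.5, lambda_override = 0)
  expect_equal(lb0$total, 0, tolerance = 1e-12)
  # lambda forced to 1: total is the hard loss, teachers irrelevant
  lb1 <- compute_distill_loss(z, rnorm(3), rnorm(3), y, x = 0.2,
                              lambda_override = 1)
  expect_equal(lb1$total, lb1$l_hard)
  expect_equal(lb1$l_hard, cross_entropy(y, temperature_softmax(z, 1)))
})

test_that("hand-composed three-class example reproduces the full loss", {
  # teachers given as log-probability logits; scale 2 puts T = 1 at x = 0.5
  p <- c(0.7, 0.2, 0.1); q <- c(0.1, 0.2, 0.7)
  params <- schedule_params(scale = 2)
  lb <- compute_distill_loss(c(0, 0, 0), log(p), log(q), c(1, 0, 0),
                             x = 0.5, params = params)
  expect_equal(lb$T, 1)
  fused <- c(0.4375, 0.125, 0.4375)
  expected <- 0.5 * js_oracle(fused, rep(1 / 3, 3)) + 0.5 * log(3)
  expect_equal(lb$total, expected, tolerance = 1e-10)
})

test_that("batch (matrix) loss is the mean of the per-sample losses", {
  set.seed(6)
  B <- 7; K <- 4
  Z <- matrix(rnorm(B * K), B, K)
  T1 <- matrix(rnorm(B * K), B, K)
  T2 <- matrix(rnorm(B * K), B, K)
  labs <- sample(0:(K - 1), B, replace = TRUE)
  Y <- matrix(0, B, K); Y[cbind(1:B, labs + 1)] <- 1
  x <- 0.31
  lb <- compute_distill_loss(Z, T1, T2, Y, x)
  per <- sapply(1:B, function(i) {
    l <- compute_distill_loss(Z[i, ], T1[i, ], T2[i, ], Y[i, ], x)
    c(l$l_soft, l$l_hard, l$total)
  })
  expect_equal(lb$l_soft, mean(per[1, ]), tolerance = 1e-10)
  expect_equal(lb$l_hard, mean(per[2, ]), tolerance = 1e-10)
  expect_equal(lb$total, mean(per[3, ]), tolerance = 1e-10)
})

test_that("analytic loss gradient matches central finite differences", {
  set.seed(7)
  B <- 3; K <- 5
  Z <- matrix(rnorm(B * K), B, K)
  T1 <- matrix(rnorm(B * K), B, K)
  T2 <- matrix(rnorm(B * K), B, K)
  Y <- matrix(0, B, K); Y[cbind(1:B, sample.int(K, B, replace = TRUE))] <- 1
  x <- 0.37
  lb <- compute_distill_loss(Z, T1, T2, Y, x)
  fused <- combine_teacher_soft_labels(T1, T2, lb$T)
  g <- dtsdistill:::distill_loss_grad(Z, fused, Y, lb$T, lb$lambda)
  eps <- 1e-6
  for (i in 1:B) for (j in 1:K) {
    Zp <- Z; Zp[i, j] <- Zp[i, j] + eps
    Zm <- Z; Zm[i, j] <- Zm[i, j] - eps
    num <- (compute_distill_loss(Zp, T1, T2, Y, x)$total -
            compute_distill_loss(Zm, T1, T2, Y, x)$total) / (2 * eps)
    expect_equal(g[i, j], num, tolerance = 1e-5)
  }
})
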