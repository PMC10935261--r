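# Brute-force reference implementations used as independent oracles.

kl_oracle <- function(p, q) sum(ifelse(p > 0, p * log(p / q), 0))

js_oracle <- function(p1, p2) {
  m <- (p1 + p2) / 2
  kl_oracle(p1, m) / 2 + kl_oracle(p2, m) / 2
}

softmax_oracle <- function(z, temp = 1) {
  e <- exp(z / temp)
  e / sum(e)
}

# random probability distribution over k classes
rand_dist <- function(k) {
  g <- stats::rgamma(k, shape = 1)
  g / sum(g)
}

# tiny random RGB image
rand_image <- function(h = 16, w = h) array(stats::runif(h * w * 3), c(h, w, 3))

# tiny labeled dataset: n_classes x per_class, sized for fast training tests
tiny_dataset <- function(n_classes = 3, per_class = 12, size = 16, seed = 42,
                         noise_sd = 0.08) {
  generate_synthetic_dataset(
    synthetic_spec(n_classes = n_classes, per_class = per_class, size = size,
                   seed = seed, noise_sd = noise_sd))
}
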