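# Independent brute-force oracle for the effect-size statistics.
# Deliberately written loop-wise from the defining sums (no sd/var/colMeans)
# so it shares no code path with the package implementation.
oracle_effect_sizes <- function(x1, x2) {
  vs <- ncol(x1)
  n1 <- nrow(x1); n2 <- nrow(x2)
  loop_mean <- function(v) { s <- 0; for (u in v) s <- s + u; s / length(v) }
  loop_sd <- function(v) {
    m <- loop_mean(v); s <- 0
    for (u in v) s <- s + (u - m)^2
    sqrt(s / (length(v) - 1))
  }
  d <- numeric(vs)
  m1 <- m2 <- s1 <- s2 <- numeric(vs)
  for (j in seq_len(vs)) {
    m1[j] <- loop_mean(x1[, j]); m2[j] <- loop_mean(x2[, j])
    s1[j] <- loop_sd(x1[, j]);   s2[j] <- loop_sd(x2[, j])
    pooled <- sqrt(((n1 - 1) * s1[j]^2 + (n2 - 1) * s2[j]^2) / (n1 + n2 - 2))
    d[j] <- (m1[j] - m2[j]) / pooled
  }
  d_avg <- loop_mean(abs(d))
  mu_g1 <- loop_mean(m1); mu_g2 <- loop_mean(m2)
  sg1 <- loop_mean(s1); sg2 <- loop_mean(s2)
  pooled_g <- sqrt(((n1 - 1) * sg1^2 + (n2 - 1) * sg2^2) / (n1 + n2 - 2))
  list(per_variable_d = d, d_average = d_avg,
       d_grand = abs(mu_g1 - mu_g2) / pooled_g)
}

# Random small two-class dataset for property tests.
random_small_dataset <- function(seed) {
  set.seed(seed)
  p <- sample(2:10, 1)
  n1 <- sample(4:50, 1); n2 <- sample(4:50, 1)
  x1 <- matrix(rnorm(n1 * p, mean = rnorm(p), sd = runif(p, 0.5, 2)),
               n1, p, byrow = FALSE)
  x2 <- matrix(rnorm(n2 * p, mean = rnorm(p), sd = runif(p, 0.5, 2)),
               n2, p, byrow = FALSE)
  list(x1 = x1, x2 = x2,
       dataset = labeled_dataset(rbind(x1, x2),
                                 rep(c("a", "b"), c(n1, n2))))
}

# Two-class dataset with exact per-variable shifts (class 2 = class 1 + delta).
shifted_dataset <- function(n_per_class, deltas, sd = 1, seed = 1) {
  set.seed(seed)
  p <- length(deltas)
  x1 <- matrix(rnorm(n_per_class * p, 0, sd), n_per_class, p)
  x2 <- matrix(rnorm(n_per_class * p, 0, sd), n_per_class, p)
  x2 <- sweep(x2, 2, deltas, "+")
  labeled_dataset(rbind(x1, x2), rep(c("c1", "c2"), each = n_per_class))
}
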