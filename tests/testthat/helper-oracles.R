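# Monte-Carlo oracle: simulate the per-division recursion X' = U/2 + X/2
# directly, independent of the density machinery.
mc_sample_recursion <- function(i, efficacies, n) {
  draw_u <- function(eff, n) {
    g <- eff$gaussians
    a <- eff$atoms
    w <- c(g$weight, a$weight)
    idx <- sample.int(length(w), n, replace = TRUE, prob = w)
    out <- numeric(n)
    gi <- idx <= nrow(g)
    if (any(gi)) out[gi] <- stats::rnorm(sum(gi), g$mean[idx[gi]],
                                         g$sd[idx[gi]])
    if (any(!gi)) out[!gi] <- a$location[idx[!gi] - nrow(g)]
    out
  }
  x <- numeric(n)
  for (k in seq_along(i)) {
    for (d in seq_len(i[k])) x <- 0.5 * draw_u(efficacies[[k]], n) + 0.5 * x
  }
  x
}

# standard errors of an empirical mean and variance (fourth-moment based)
mc_se <- function(x) {
  n <- length(x)
  s2 <- stats::var(x)
  m4 <- mean((x - mean(x))^4)
  list(mean = sqrt(s2 / n), variance = sqrt(max(m4 - s2^2, 0) / n))
}

noisy_efficacies <- function(sigma = 0.2)
  list(efficacy_normal(1, sigma), efficacy_dirac(0))

spatial_efficacy <- function(sigma = 0.05)
  heterogeneous_efficacy(c(1 / 3, 2 / 3), c(0.5, 1), sigma)
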