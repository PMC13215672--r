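# Exhaustive-enumeration oracle for the latent posterior on short traces.
#
# For a trace of T steps with spike support 0..s_max per step (a wider
# support s1_max at t = 1, where the sampler's initial proposal is an
# untruncated Poisson), enumerates every spike sequence, marginalizes the
# baseline exactly (Gaussian random walk + iid noise => multivariate normal
# likelihood) and marginalizes the firing regime by the forward-backward
# algorithm. Completely independent of the particle code path.
enumerate_posterior <- function(values, dt, theta, s_max = 2L, s1_max = 8L) {
  T_ <- length(values)
  co <- kinetics_to_ar(theta$tau_r, theta$tau_d, theta$a_max, dt)
  supp <- c(list(0:s1_max), rep(list(0:s_max), T_ - 1L))
  grid <- as.matrix(expand.grid(supp))
  colnames(grid) <- NULL
  n <- nrow(grid)

  # deterministic calcium per sequence
  C <- matrix(0, n, T_)
  C[, 1] <- theta$c0 + co$a * grid[, 1]
  C[, 2] <- co$gamma1 * C[, 1] + co$a * grid[, 2]
  if (T_ >= 3) for (t in 3:T_)
    C[, t] <- co$gamma1 * C[, t - 1] + co$gamma2 * C[, t - 2] +
      co$a * grid[, t]

  # exact baseline marginalization: F | s ~ N(c(s), Cov_b + sigma2 I)
  idx <- seq_len(T_)
  Sigma <- 1 + theta$sigma2_b * dt * (outer(idx, idx, pmin) - 1) +
    diag(theta$sigma2, T_)
  U <- chol(Sigma)
  R <- matrix(values, n, T_, byrow = TRUE) - C
  Y <- t(forwardsolve(t(U), t(R)))
  loglik <- -0.5 * rowSums(Y^2) - sum(log(diag(U))) -
    0.5 * T_ * log(2 * pi)

  # regime marginalization by forward-backward with Poisson emissions
  W <- pgbar:::transition_matrix(theta, dt)
  E0 <- matrix(stats::dpois(grid, theta$r0 * dt), n, T_)
  E1 <- matrix(stats::dpois(grid, theta$r1 * dt), n, T_)
  A0 <- matrix(0, n, T_); A1 <- matrix(0, n, T_)
  A0[, 1] <- 0.5 * E0[, 1]
  A1[, 1] <- 0.5 * E1[, 1]
  for (t in 2:T_) {
    A0[, t] <- (A0[, t - 1] * W[1, 1] + A1[, t - 1] * W[2, 1]) * E0[, t]
    A1[, t] <- (A0[, t - 1] * W[1, 2] + A1[, t - 1] * W[2, 2]) * E1[, t]
  }
  log_ps <- log(A0[, T_] + A1[, T_])
  lp <- loglik + log_ps
  post <- exp(lp - max(lp))
  post <- post / sum(post)

  B0 <- matrix(0, n, T_); B1 <- matrix(0, n, T_)
  B0[, T_] <- 1; B1[, T_] <- 1
  if (T_ >= 2) for (t in (T_ - 1):1) {
    B0[, t] <- W[1, 1] * E0[, t + 1] * B0[, t + 1] +
      W[1, 2] * E1[, t + 1] * B1[, t + 1]
    B1[, t] <- W[2, 1] * E0[, t + 1] * B0[, t + 1] +
      W[2, 2] * E1[, t + 1] * B1[, t + 1]
  }
  q1_given_s <- (A1 * B1) / (A0 * B0 + A1 * B1)

  max_s <- max(s1_max, s_max)
  s_marg <- matrix(0, T_, max_s + 1L,
                   dimnames = list(NULL, as.character(0:max_s)))
  for (t in seq_len(T_)) for (k in 0:max(supp[[t]]))
    s_marg[t, k + 1L] <- sum(post[grid[, t] == k])
  list(s_marginals = s_marg,
       s_mean = as.numeric(post %*% grid),
       q1_prob = as.numeric(post %*% q1_given_s))
}

# Empirical single-site marginals from a chained sequence of PGAS sweeps at
# fixed theta (the particle Gibbs Markov chain whose stationary law is the
# latent posterior).
pgas_chain_marginals <- function(trace, theta, n_sweeps, n_particles,
                                 s_max = 2L, burn = 100L, s_levels = 0:2) {
  ref <- bootstrap_trajectory(trace, theta, n_particles)
  T_ <- length(trace$values)
  s_counts <- matrix(0, T_, length(s_levels))
  s_sum <- numeric(T_)
  q_sum <- numeric(T_)
  kept <- 0L
  for (k in seq_len(n_sweeps)) {
    ref <- pgas_sweep(trace, ref, theta, n_particles, s_max)[
      c("q", "s", "c", "b")]
    if (k > burn) {
      kept <- kept + 1L
      q_sum <- q_sum + ref$q
      s_sum <- s_sum + ref$s
      for (j in seq_along(s_levels))
        s_counts[, j] <- s_counts[, j] + (ref$s == s_levels[j])
    }
  }
  list(s_marginals = s_counts / kept, s_mean = s_sum / kept,
       q1_prob = q_sum / kept, n_kept = kept)
}
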