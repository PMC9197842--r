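# 3-state Gaussian hidden Markov model, EM-fit, used to segment the
# directionality index into downstream-bias / none / upstream-bias runs.
# Means are kept ordered (state 1 lowest) via initialization at data
# quantiles; a variance floor guards against collapse on noiseless input.

fit_gaussian_hmm <- function(x, n_states = 3, max_iter = 200, tol = 1e-6,
                             seed = 1) {
  set.seed(seed)
  n <- length(x)
  var_floor <- max(stats::var(x) * 1e-4, 1e-8)
  qs <- stats::quantile(x, probs = seq(0.1, 0.9, length.out = n_states))
  mu <- as.numeric(qs) + stats::rnorm(n_states, 0, 1e-8)
  sig2 <- rep(max(stats::var(x) / n_states, var_floor), n_states)
  pi0 <- rep(1 / n_states, n_states)
  Tr <- matrix(0.1 / (n_states - 1), n_states, n_states)
  diag(Tr) <- 0.9
  loglik_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    B <- vapply(seq_len(n_states), function(k) {
      stats::dnorm(x, mu[k], sqrt(sig2[k]))
    }, numeric(n))
    B <- pmax(B, 1e-300)
    # forward-backward with per-step scaling
    alpha <- matrix(0, n, n_states)
    cscale <- numeric(n)
    alpha[1, ] <- pi0 * B[1, ]
    cscale[1] <- sum(alpha[1, ])
    alpha[1, ] <- alpha[1, ] / cscale[1]
    for (t in 2:n) {
      a <- (alpha[t - 1, ] %*% Tr) * B[t, ]
      cscale[t] <- sum(a)
      alpha[t, ] <- a / cscale[t]
    }
    beta <- matrix(0, n, n_states)
    beta[n, ] <- 1
    for (t in (n - 1):1) {
      beta[t, ] <- (Tr %*% (B[t + 1, ] * beta[t + 1, ])) / cscale[t + 1]
    }
    gamma <- alpha * beta
    gamma <- gamma / rowSums(gamma)
    xi_num <- matrix(0, n_states, n_states)
    for (t in 1:(n - 1)) {
      xi <- (alpha[t, ] %o% (B[t + 1, ] * beta[t + 1, ])) * Tr / cscale[t + 1]
      xi_num <- xi_num + xi
    }
    loglik <- sum(log(cscale))
    pi0 <- gamma[1, ]
    Tr <- xi_num / pmax(rowSums(xi_num), 1e-300)
    w <- colSums(gamma)
    mu <- colSums(gamma * x) / pmax(w, 1e-300)
    sig2 <- vapply(seq_len(n_states), function(k) {
      max(sum(gamma[, k] * (x - mu[k])^2) / max(w[k], 1e-300), var_floor)
    }, 0)
    if (abs(loglik - loglik_old) < tol * (1 + abs(loglik))) {
      converged <- TRUE
      break
    }
    loglik_old <- loglik
  }
  # decode by most-probable path (Viterbi)
  B <- vapply(seq_len(n_states), function(k) {
    stats::dnorm(x, mu[k], sqrt(sig2[k]))
  }, numeric(n))
  B <- log(pmax(B, 1e-300))
  logTr <- log(pmax(Tr, 1e-300))
  delta <- matrix(-Inf, n, n_states)
  psi <- matrix(0L, n, n_states)
  delta[1, ] <- log(pmax(pi0, 1e-300)) + B[1, ]
  for (t in 2:n) {
    for (k in seq_len(n_states)) {
      cand <- delta[t - 1, ] + logTr[, k]
      psi[t, k] <- which.max(cand)
      delta[t, k] <- cand[psi[t, k]] + B[t, k]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  # relabel so state order follows the mean order (1 = lowest mean)
  ord <- order(mu)
  relabel <- match(seq_len(n_states), ord)
  list(states = relabel[path], mu = mu[ord], sigma2 = sig2[ord],
       converged = converged, loglik = loglik)
}
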