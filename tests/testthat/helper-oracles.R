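# Shared helpers: independent oracles the implementation must agree with.
# These deliberately avoid the package's propagators and objective internals.

# closed-form solution of dx/dt = F x + s: x(t) = x_ss + e^{Ft}(x0 - x_ss)
# via eigendecomposition (F assumed invertible, which holds a.s. for the
# random stable draws used in tests)
closed_form_affine <- function(F, s, x0, times) {
  x_ss <- solve(F, -s)
  eg <- eigen(F)
  Vi <- solve(eg$vectors)
  t(vapply(times, function(t) {
    E <- eg$vectors %*% diag(exp(eg$values * t), nrow = length(x0)) %*% Vi
    Re(E %*% (x0 - x_ss) + x_ss)
  }, numeric(length(x0))))
}

# a stable random network drawn with the package's sampling rules but
# assembled independently of sample_random_network
random_stable_net <- function(n, seed) {
  set.seed(seed)
  repeat {
    F <- matrix(runif(n * n, -2, 2), n, n)
    if (max(Re(eigen(F, only.values = TRUE)$values)) < 0) break
  }
  linear_network(F, S_b = runif(n, 0, 2), S_ex = runif(n, 0, 2))
}

# Straight-line re-implementation of the DL-MRA objective (standard and ffl
# variants) using deSolve integration and its own polynomial fit -- no shared
# helpers with the package internals beyond the dataset container.
oracle_phi <- function(theta, ds, variant = "standard", interp_order = 5) {
  n <- ds$n
  Nt <- length(ds$times)
  F <- matrix(theta[1:(n * n)], n, n)
  x0v <- ds$vehicle[1, ]
  if (variant == "standard") {
    S_ex <- theta[n * n + seq_len(n)]
    S_b <- as.numeric(-F %*% x0v)
  } else if (variant == "ffl") {
    S_ex <- c(theta[n * n + 1], rep(0, n - 1))
    S_b <- as.numeric(-F %*% x0v)
    S_b[1] <- 0
  } else stop("oracle supports standard/ffl")
  s <- S_b + S_ex
  phi <- 0
  pred_v <- deSolve::lsoda(x0v, ds$times, function(t, y, p) list(F %*% y + s),
                           NULL, rtol = 1e-10, atol = 1e-12)[, -1, drop = FALSE]
  phi <- phi + sum((ds$vehicle - pred_v)^2)
  ord <- min(interp_order, Nt - 1)
  for (j in seq_len(n)) {
    idx <- setdiff(seq_len(n), j)
    cf <- stats::lm(y ~ poly(t, ord, raw = TRUE),
                    data = data.frame(t = ds$times, y = ds$perturbed[[j]][, j]))
    trace_fn <- function(t) {
      t <- pmin(pmax(t, min(ds$times)), max(ds$times))
      drop(cbind(1, outer(t, seq_len(ord), `^`)) %*% coef(cf))
    }
    rate <- function(t, y, p)
      list(F[idx, idx, drop = FALSE] %*% y + s[idx] + F[idx, j] * trace_fn(t))
    pred <- deSolve::lsoda(ds$perturbed[[j]][1, idx], ds$times, rate, NULL,
                           rtol = 1e-10, atol = 1e-12)[, -1, drop = FALSE]
    phi <- phi + sum((ds$perturbed[[j]][, idx, drop = FALSE] - pred)^2)
  }
  phi
}

# tiny dataset builders used across files
single_activator_dataset <- function(p = 0, timepoints = 11, d = 0, seed = NULL) {
  ds <- perturbation_design(single_activator_network(),
                            times = seq(0, 10, length.out = timepoints), p = p)
  if (d > 0) ds <- add_noise(ds, d, seed = seed)
  ds
}
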