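#' Perturbation time-course dataset
#'
#' The experimental design DL-MRA consumes: a shared time grid, one vehicle
#' (unperturbed control) trajectory, and one perturbation trajectory per node
#' (n + 1 conditions in total).  Objects are normally produced by
#' [perturbation_design()], [cellstate_design()] or [read_dataset()].
#'
#' @param times shared strictly increasing time grid.
#' @param vehicle Nt x n matrix of vehicle activities.
#' @param perturbed list of n Nt x n matrices; element j holds the system
#'   under perturbation of node j.
#' @param p perturbation strength: fraction of unperturbed activity retained
#'   by the perturbed node (0 = complete inhibition, 0.5 = 50% inhibition).
#' @param kind `"activity"` for clamp-type perturbations or `"proportion"`
#'   for mass-conserving initial-condition perturbations of cell states.
#' @param noise_d proportional noise level already applied (0 = clean).
#' @param seed noise seed, if any.
#' @param warnings character vector of quality warnings recorded during
#'   generation (e.g. a failed responsiveness check).
#' @return Object of class `perturbation_dataset`.
#' @export
perturbation_dataset <- function(times, vehicle, perturbed, p = 0,
                                 kind = "activity", noise_d = 0, seed = NULL,
                                 warnings = character()) {
  vehicle <- as.matrix(vehicle)
  n <- ncol(vehicle)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (nrow(vehicle) != length(times))
    stop("vehicle rows must match the time grid")
  if (!is.list(perturbed) || length(perturbed) != n)
    stop(sprintf("'perturbed' must hold exactly one condition per node (%d)", n))
  perturbed <- lapply(perturbed, function(m) {
    m <- as.matrix(m)
    if (!all(dim(m) == dim(vehicle)))
      stop("all conditions must share the vehicle's time grid and node count")
    m
  })
  if (p < 0 || p > 1) stop("'p' must lie in [0, 1]")
  structure(list(n = n, times = as.numeric(times), vehicle = vehicle,
                 perturbed = perturbed, p = p, kind = kind,
                 noise_d = noise_d, seed = seed, warnings = warnings),
            class = "perturbation_dataset")
}

#' @export
print.perturbation_dataset <- function(x, ...) {
  cat(sprintf(
    "Perturbation dataset: %d nodes, %d time points on [%g, %g], %d conditions\n",
    x$n, length(x$times), min(x$times), max(x$times), x$n + 1))
  cat(sprintf("  perturbation strength p = %g (%s), noise d = %g\n",
              x$p, x$kind, x$noise_d))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.perturbation_dataset <- function(x, ...) {
  one <- function(m, cond) {
    data.frame(time = rep(x$times, x$n), condition = cond,
               node = rep(seq_len(x$n), each = length(x$times)),
               value = as.vector(m))
  }
  out <- rbind(one(x$vehicle, "vehicle"),
               do.call(rbind, lapply(seq_len(x$n), function(j)
                 one(x$perturbed[[j]], sprintf("pert_%d", j)))))
  rownames(out) <- NULL
  out
}

#' Number of usable residual equations
#'
#' Per time interval the design supports n equations from the vehicle plus
#' n - 1 from each of the n perturbations (node j's data under perturbation j
#' are never used), i.e. \eqn{n + n^2 - n = n^2} equations -- exactly the
#' number of unknown edge weights.
#'
#' @param ds a [perturbation_dataset].
#' @return Integer count of residual equations per time interval.
#' @export
n_residual_equations <- function(ds) {
  stopifnot(inherits(ds, "perturbation_dataset"))
  as.integer(ds$n + ds$n^2 - ds$n)
}

#' Generate the prescribed perturbation design from a model
#'
#' Implements the two-step protocol used throughout: equilibrate without the
#' external stimulus (from zero activity) to obtain the pre-stimulus steady
#' state, apply the stimulus at t = 0 and record the vehicle time course, then
#' for each node j produce a perturbation condition in which node j's trace is
#' the scaled copy `p * vehicle` and every other node obeys its own rate
#' equation driven by that trace.  No perturbation mechanism is modeled --
#' the scaled trace itself forces the system.
#'
#' For linear networks all trajectories are computed by an exact
#' matrix-exponential propagator of the (coupled) linear system; feedforward
#' models are integrated with a stiff-capable solver, and a responsiveness
#' check (each node responds to the stimulus; each perturbation moves some
#' other node) is recorded as a dataset warning when it fails.
#'
#' @param model a [linear_network] (must be stable) or an [ffl_model].
#' @param times evenly spaced time grid (uneven grids are allowed).
#' @param p perturbation strength in \[0, 1\] (fraction of activity retained).
#' @param ... passed to methods.
#' @return A clean (noise-free) [perturbation_dataset].
#' @export
perturbation_design <- function(model, times = seq(0, 10, length.out = 11),
                                p = 0, ...) {
  UseMethod("perturbation_design")
}

#' @rdname perturbation_design
#' @export
perturbation_design.linear_network <- function(model,
                                               times = seq(0, 10, length.out = 11),
                                               p = 0, ...) {
  fl <- stability_flags(model)
  if (!fl$stable)
    stop(sprintf("model is unstable (max Re eigenvalue = %.4g); refuse to generate data",
                 max(Re(fl$eigenvalues))))
  n <- model$n
  x0 <- basal_steady_state(model)$x_ss
  s <- model$S_b + model$S_ex
  vehicle <- prop_affine_cpp(model$F, s, x0, times)
  perturbed <- lapply(seq_len(n), function(j) {
    idx <- setdiff(seq_len(n), j)
    m <- 2 * n - 1
    # coupled exact system: vehicle states, then the forced remaining nodes
    A <- matrix(0, m, m)
    A[1:n, 1:n] <- model$F
    A[n + seq_along(idx), n + seq_along(idx)] <- model$F[idx, idx]
    A[n + seq_along(idx), j] <- model$F[idx, j] * p
    sv <- c(s, s[idx])
    tr <- prop_affine_cpp(A, sv, c(x0, x0[idx]), times)
    out <- matrix(NA_real_, length(times), n)
    out[, idx] <- tr[, n + seq_along(idx), drop = FALSE]
    out[, j] <- p * tr[, j]
    out
  })
  perturbation_dataset(times, vehicle, perturbed, p = p)
}

#' @rdname perturbation_design
#' @export
perturbation_design.ffl_model <- function(model,
                                          times = seq(0, 10, length.out = 11),
                                          p = 0, ...) {
  n <- 3
  x0 <- basal_steady_state(model)$x_ss
  vehicle <- simulate_network(model, x0, times)$values
  perturbed <- lapply(seq_len(n), function(j) {
    idx <- setdiff(seq_len(n), j)
    # coupled system: the vehicle plus the remaining nodes forced by the
    # scaled vehicle trace of node j
    rate <- function(t, y, parms) {
      xv <- pmax(y[1:n], 0)
      xp <- numeric(n)
      xp[idx] <- pmax(y[n + seq_along(idx)], 0)
      xp[j] <- p * xv[j]
      list(c(ffl_rates(model, xv), ffl_rates(model, xp)[idx]))
    }
    y0 <- c(x0, x0[idx])
    sol <- deSolve::lsoda(y0, times, rate, NULL, rtol = 1e-8, atol = 1e-10)
    out <- matrix(NA_real_, length(times), n)
    out[, idx] <- unname(sol[, n + 1 + seq_along(idx), drop = FALSE])
    out[, j] <- p * unname(sol[, 1 + j])
    out
  })
  ds <- perturbation_dataset(times, vehicle, perturbed, p = p)
  ds$warnings <- ffl_responsiveness_warnings(ds)
  ds
}

# responsiveness of the generated data: every node should respond to the
# stimulus, and every perturbation should move some other node
ffl_responsiveness_warnings <- function(ds) {
  w <- character()
  for (i in seq_len(ds$n)) {
    tr <- ds$vehicle[, i]
    scale <- max(abs(tr), 1e-12)
    if (diff(range(tr)) <= 0.05 * scale)
      w <- c(w, sprintf("node %d barely responds to the stimulus", i))
  }
  # x3 is terminal in a feedforward loop (no outgoing edges), so only the
  # upstream perturbations are informative about the thresholds
  for (j in 1:2) {
    down <- (j + 1):ds$n
    moved <- max(abs(ds$perturbed[[j]][, down] - ds$vehicle[, down]))
    scale <- max(abs(ds$vehicle[, down]), 1e-12)
    if (moved <= 0.01 * scale)
      w <- c(w, sprintf("perturbation of node %d moves no downstream node", j))
  }
  w
}

#' Add proportional Gaussian measurement noise
#'
#' Replaces every data point x by `x + N(0, sd = d * |x|)` independently
#' (a point that is exactly zero stays zero).  Signal-to-noise ratios of
#' 10:1, 5:1 and 2:1 correspond to d = 0.1, 0.2 and 0.5.  The input dataset
#' is not modified; the seed used is recorded on the result.
#'
#' @param ds a [perturbation_dataset].
#' @param d noise level, >= 0.
#' @param seed optional integer seed for the noise draws.
#' @return A new noisy [perturbation_dataset] with `noise_d = d`.
#' @export
add_noise <- function(ds, d, seed = NULL) {
  stopifnot(inherits(ds, "perturbation_dataset"))
  if (d < 0) stop("'d' must be non-negative")
  if (d == 0) return(ds)
  if (!is.null(seed)) set.seed(seed)
  jitter <- function(m) m + rnorm(length(m), 0, d * abs(m))
  out <- ds
  out$vehicle <- jitter(ds$vehicle)
  out$perturbed <- lapply(ds$perturbed, jitter)
  out$noise_d <- d
  out$seed <- seed
  out
}

#' Remove one node from a dataset
#'
#' Drops node j's traces from every condition and removes the perturbation-j
#' condition, giving the design one would have measured for the remaining
#' n - 1 nodes (used to study reconstruction when a node is unobserved).
#'
#' @param ds a [perturbation_dataset] with at least 2 nodes.
#' @param j node index to remove.
#' @return A [perturbation_dataset] with n - 1 nodes and n conditions; the
#'   removed index is recorded in attribute `"dropped"`.
#' @export
drop_node <- function(ds, j) {
  stopifnot(inherits(ds, "perturbation_dataset"))
  if (ds$n < 2) stop("cannot drop a node from a 1-node dataset")
  if (!j %in% seq_len(ds$n)) stop(sprintf("invalid node index %s", j))
  keep <- setdiff(seq_len(ds$n), j)
  out <- perturbation_dataset(ds$times,
                              ds$vehicle[, keep, drop = FALSE],
                              lapply(ds$perturbed[keep], function(m)
                                m[, keep, drop = FALSE]),
                              p = ds$p, kind = ds$kind, noise_d = ds$noise_d,
                              seed = ds$seed, warnings = ds$warnings)
  attr(out, "dropped") <- c(attr(ds, "dropped"), j)
  out
}

#' Cell-state transition design
#'
#' For cell-state networks perturbations need not clamp activities: different
#' starting proportions serve the same purpose.  The vehicle condition starts
#' from equal proportions; the perturbation-j condition starts with state j's
#' proportion set to zero and the removed mass redistributed proportionally
#' over the remaining states.  All trajectories evolve under the
#' continuous-time rate matrix of the Markov model and conserve total
#' proportion.
#'
#' @param m a [markov_model].
#' @param times time grid in days.
#' @return A [perturbation_dataset] of kind `"proportion"`.
#' @export
cellstate_design <- function(m, times = seq(0, 5, length.out = 11)) {
  stopifnot(inherits(m, "markov_model"))
  net <- markov_to_continuous(m)
  n <- m$n
  run <- function(x0) prop_affine_cpp(net$F, rep(0, n), x0, times)
  vehicle <- run(rep(1 / n, n))
  perturbed <- lapply(seq_len(n), function(j) {
    x0 <- rep(1 / n, n)
    x0[j] <- 0
    run(x0 / sum(x0))
  })
  perturbation_dataset(times, vehicle, perturbed, p = 0, kind = "proportion")
}
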