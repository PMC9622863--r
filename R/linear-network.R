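#' Linear network model
#'
#' Constructs the linear ODE network model underlying DL-MRA,
#' \deqn{dx_i/dt = S_{i,b} + S_{i,ex} + \sum_j F_{ij} x_j,}
#' where `F` is the Jacobian of edge weights (entry \eqn{F_{ij}} is the direct
#' effect of node \eqn{j}'s activity on node \eqn{i}'s rate of change), `S_b`
#' the basal production vector (always acting) and `S_ex` the external stimulus
#' vector (acting only while `stimulus_active` is `TRUE`, i.e. after the
#' stimulus is applied at t = 0).
#'
#' @param F n x n numeric matrix of edge weights (per unit time).
#' @param S_b length-n basal production vector; scalar recycled. Default 0.
#' @param S_ex length-n external stimulus vector; scalar recycled. Default 0.
#' @param stimulus_active logical; whether `S_ex` is applied.
#' @return An object of class `linear_network` with fields `n`, `F`, `S_b`,
#'   `S_ex`, `stimulus_active`.
#' @examples
#' net <- linear_network(matrix(c(-1, 1.5, 0, -0.8), 2), S_ex = c(1, 1))
#' network_rates(net, c(0, 0))
#' @export
linear_network <- function(F, S_b = 0, S_ex = 0, stimulus_active = TRUE) {
  F <- as.matrix(F)
  stop_if_not_square(F)
  n <- nrow(F)
  if (length(S_b) == 1) S_b <- rep(S_b, n)
  if (length(S_ex) == 1) S_ex <- rep(S_ex, n)
  check_length(S_b, n, "S_b")
  check_length(S_ex, n, "S_ex")
  structure(list(n = n, F = F, S_b = as.numeric(S_b), S_ex = as.numeric(S_ex),
                 stimulus_active = isTRUE(stimulus_active)),
            class = "linear_network")
}

#' @export
print.linear_network <- function(x, ...) {
  fl <- stability_flags(x)
  cat(sprintf("Linear network: %d nodes (%s%s)\n", x$n,
              if (fl$stable) "stable" else "unstable",
              if (fl$oscillatory) ", damped-oscillatory" else ""))
  cat("Edge weights F:\n")
  print(round(x$F, 4))
  cat("S_b: ", paste(round(x$S_b, 4), collapse = " "), "\n")
  cat("S_ex:", paste(round(x$S_ex, 4), collapse = " "),
      if (x$stimulus_active) "(active)" else "(inactive)", "\n")
  invisible(x)
}

#' Rate of change of node activities
#'
#' Evaluates \eqn{dx/dt = S_b + S_{ex} + F x} for a [linear_network] (the
#' stimulus term is included only when the network's stimulus is active).
#'
#' @param net a `linear_network`.
#' @param x activity vector of length `net$n`.
#' @return Numeric rate vector of length `net$n`.
#' @export
network_rates <- function(net, x) {
  stopifnot(inherits(net, "linear_network"))
  check_length(x, net$n, "x")
  drv <- net$S_b + net$F %*% x
  if (net$stimulus_active) drv <- drv + net$S_ex
  as.numeric(drv)
}

#' Time-course container
#'
#' A trajectory pairs a strictly increasing time grid with the matrix of node
#' activities sampled on it (one row per time point, one column per node).
#'
#' @param times strictly increasing numeric vector.
#' @param values numeric matrix, `length(times)` rows.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(times, values) {
  times <- as.numeric(times)
  values <- as.matrix(values)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (nrow(values) != length(times))
    stop("row count of 'values' must equal length of 'times'")
  if (!all(is.finite(values))) stop("'values' contains non-finite entries")
  structure(list(times = times, values = values), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d time points x %d nodes on [%g, %g]\n",
              length(x$times), ncol(x$values), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  n <- ncol(x$values)
  data.frame(time = rep(x$times, n),
             node = rep(seq_len(n), each = length(x$times)),
             value = as.vector(x$values))
}

#' Simulate a network model
#'
#' Integrates the initial-value problem for a network model on a time grid.
#' For [linear_network] objects a stiff-capable adaptive integrator
#' (`deSolve::lsoda`) is used with tight default tolerances; an unstable
#' network that diverges is reported together with its eigenvalues.
#'
#' @param model a network model (`linear_network` or [ffl_model]).
#' @param x0 initial activity vector at `times[1]`.
#' @param times strictly increasing time grid; the first entry is the
#'   initial-condition time.
#' @param rtol,atol relative / absolute solver tolerances.
#' @param ... passed to methods.
#' @return A [trajectory].
#' @export
simulate_network <- function(model, x0, times, rtol = 1e-8, atol = 1e-10, ...) {
  UseMethod("simulate_network")
}

#' @rdname simulate_network
#' @export
simulate_network.linear_network <- function(model, x0, times, rtol = 1e-8,
                                            atol = 1e-10, ...) {
  check_length(x0, model$n, "x0")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  s <- net_input(model)
  sol <- suppressWarnings(
    deSolve::lsoda(y = x0, times = times,
                   func = function(t, y, p) list(model$F %*% y + s),
                   parms = NULL, rtol = rtol, atol = atol))
  vals <- unname(sol[, -1, drop = FALSE])
  if (nrow(vals) < length(times) || !all(is.finite(vals)) ||
      max(abs(vals)) > 1e100) {
    ev <- eigen(model$F, only.values = TRUE)$values
    stop(sprintf(
      "integration failed (diverging trajectory?); eigenvalues of F: %s",
      paste(format(ev, digits = 3), collapse = ", ")))
  }
  trajectory(times, vals)
}

# total constant input currently driving the network
net_input <- function(net) {
  net$S_b + if (net$stimulus_active) net$S_ex else 0
}

#' Pre-stimulus steady state
#'
#' Steady state of the network driven by basal production only (stimulus
#' switched off).  For a stable linear network the direct linear solve
#' \eqn{F x = -S_b} is used by default; the long-integration route (from zero
#' initial activity until \eqn{\max|dx/dt|} falls below `tol` or `t_max` is
#' reached) is available for cross-checking and for nonlinear models.
#'
#' @param model network model.
#' @param method `"solve"` (linear algebra) or `"integrate"`.
#' @param tol steady-state criterion on \eqn{\max|dx/dt|}.
#' @param t_max integration horizon for the `"integrate"` route.
#' @param ... passed to methods.
#' @return A list of class `steady_state` with `x_ss` and `residual`
#'   (max absolute rate at `x_ss`).
#' @export
basal_steady_state <- function(model, ...) UseMethod("basal_steady_state")

#' @rdname basal_steady_state
#' @export
basal_steady_state.linear_network <- function(model,
                                              method = c("solve", "integrate"),
                                              tol = 1e-9, t_max = 1000, ...) {
  method <- match.arg(method)
  fl <- stability_flags(model)
  if (!fl$stable)
    stop(sprintf("network is not stable (max Re eigenvalue = %.4g); no basal steady state",
                 max(Re(fl$eigenvalues))))
  off <- model
  off$stimulus_active <- FALSE
  if (method == "solve") {
    x <- as.numeric(solve(model$F, -model$S_b))
  } else {
    x <- integrate_to_steady(function(y) as.numeric(off$F %*% y + off$S_b),
                             rep(0, model$n), tol, t_max)
  }
  res <- max(abs(off$F %*% x + off$S_b))
  structure(list(x_ss = x, residual = res), class = "steady_state")
}

# shared long-integration steady-state search
integrate_to_steady <- function(rate_fn, x0, tol, t_max) {
  t_now <- 0; x <- x0; chunk <- 50
  while (t_now < t_max) {
    sol <- deSolve::lsoda(y = x, times = c(0, chunk),
                          func = function(t, y, p) list(rate_fn(y)),
                          parms = NULL, rtol = 1e-10, atol = 1e-12)
    x <- unname(sol[nrow(sol), -1])
    t_now <- t_now + chunk
    if (max(abs(rate_fn(x))) < tol) break
  }
  x
}

#' Stability and oscillation diagnostics
#'
#' A network is stable iff every eigenvalue of its edge-weight matrix has a
#' negative real part; it has damped-oscillatory potential iff any eigenvalue
#' has an imaginary part exceeding `imag_tol` in magnitude.
#'
#' @param model a `linear_network` or a bare edge-weight matrix.
#' @param imag_tol tolerance below which imaginary parts count as zero.
#' @return List with logicals `stable`, `oscillatory` and the complex
#'   `eigenvalues`.
#' @export
stability_flags <- function(model, imag_tol = 1e-9) {
  F <- if (inherits(model, "linear_network")) model$F else as.matrix(model)
  stop_if_not_square(F)
  ev <- eigen(F, only.values = TRUE)$values
  list(stable = max(Re(ev)) < 0,
       oscillatory = any(abs(Im(ev)) > imag_tol),
       eigenvalues = ev)
}

#' Total stimulus implied by a steady state
#'
#' At steady state the rate equations give \eqn{S_b + S_{ex} = -F x_{ss}}
#' per node; given an edge-weight estimate and a (near-)steady activity
#' vector this recovers the total constant input.
#'
#' @param F_hat n x n edge-weight matrix estimate.
#' @param x_ss steady-state activity vector.
#' @return Length-n vector of total per-node input \eqn{S_b + S_{ex}}.
#' @export
stimulus_from_steady_state <- function(F_hat, x_ss) {
  F_hat <- as.matrix(F_hat)
  stop_if_not_square(F_hat, "F_hat")
  check_length(x_ss, nrow(F_hat), "x_ss")
  as.numeric(-F_hat %*% x_ss)
}

#' Basal production implied by a pre-stimulus steady state
#'
#' When t = 0 is a steady state reached without the external stimulus, the
#' basal production vector satisfies \eqn{S_b = -F x(0)}.  This is the
#' elimination used by the estimator at every objective evaluation.
#'
#' @param F_hat n x n edge-weight matrix estimate.
#' @param x0 pre-stimulus steady-state activity vector.
#' @return Length-n basal production estimate.
#' @export
basal_from_initial_state <- function(F_hat, x0) {
  F_hat <- as.matrix(F_hat)
  stop_if_not_square(F_hat, "F_hat")
  check_length(x0, nrow(F_hat), "x0")
  as.numeric(-F_hat %*% x0)
}

#' Serialize / restore a linear network as JSON
#'
#' The document stores `n`, row-major `F`, `S_b` and `S_ex`.
#'
#' @param net a `linear_network`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @export
network_to_json <- function(net, path = NULL) {
  stopifnot(inherits(net, "linear_network"))
  doc <- list(n = net$n, F = as.vector(t(net$F)), S_b = net$S_b,
              S_ex = net$S_ex, stimulus_active = net$stimulus_active)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' @param json JSON string or path to a JSON file written by
#'   [network_to_json()].
#' @rdname network_to_json
#' @export
network_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json)
  linear_network(matrix(doc$F, doc$n, doc$n, byrow = TRUE),
                 S_b = doc$S_b, S_ex = doc$S_ex,
                 stimulus_active = isTRUE(doc$stimulus_active))
}
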