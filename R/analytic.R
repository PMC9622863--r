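#' First-difference tables for the analytic route
#'
#' Builds the Taylor-difference quantities the direct per-time-point solver
#' consumes: time differences of the vehicle
#' \eqn{\Delta_t x_i(k+1) = x_i(k+1) - x_i(k)}, perturbation differences
#' \eqn{\Delta_{p,j} x_i(k) = x_i(k, p_j) - x_i(k)}, and the first-difference
#' rate estimates \eqn{y_i(k+1) = f_i(k+1) - f_i(k)},
#' \eqn{y_{i,j}(k) = f_{i,j}(k) - f_i(k)}.  With only sampled data the rates
#' \eqn{f_i(k)} must be estimated; the default differentiates a least-squares
#' polynomial through each trace (accurate for smooth trajectories at the
#' default grid spacing), with plain forward or central differences as
#' options.  The difference schemes are first-order accurate only: at
#' spacing \eqn{\Delta t} a decaying mode \eqn{e^{-\lambda t}} has its rate
#' estimates -- and hence the recovered edge weights -- shrunk by the factor
#' \eqn{(1 - e^{-\lambda \Delta t})/(\lambda \Delta t)}, a ~37% bias at
#' \eqn{\lambda \Delta t = 1}.
#'
#' @param ds a [perturbation_dataset] with at least 2 time points.
#' @param diff rate-estimation scheme: `"poly"` (default), `"forward"` or
#'   `"central"`.
#' @param poly_order order of the differentiated polynomial under the
#'   `"poly"` scheme (reduced automatically when points are few).
#' @return List of class `difference_tables`: `dt_x` ((Nt-1) x n), `dp_x`
#'   (list over perturbations of (Nt-1) x n), `y_t` (rate differences of the
#'   vehicle, rows aligned to time index k+1), `y_p` (list, rate differences
#'   under each perturbation), `f_hat` (per-condition rate estimates), and
#'   `valid_k` (time indices with complete rows).
#' @export
difference_tables <- function(ds, diff = c("poly", "forward", "central"),
                              poly_order = 6) {
  stopifnot(inherits(ds, "perturbation_dataset"))
  scheme <- match.arg(diff)
  Nt <- length(ds$times)
  if (Nt < 2) stop("need at least 2 time points")
  n <- ds$n
  rate_est <- function(x) {
    # rows 1..Nt, NA where the stencil is unavailable
    f <- matrix(NA_real_, Nt, n)
    dt <- diff(ds$times)
    if (scheme == "poly") {
      ord <- min(poly_order, Nt - 1)
      for (i in seq_len(n)) {
        pc <- rev(pracma::polyfit(ds$times, x[, i], ord))  # ascending
        dpc <- pc[-1] * seq_len(ord)                       # derivative coefs
        f[, i] <- drop(outer(ds$times, 0:(ord - 1), `^`) %*% dpc)
      }
    } else if (scheme == "forward") {
      f[1:(Nt - 1), ] <- (x[2:Nt, , drop = FALSE] - x[1:(Nt - 1), , drop = FALSE]) / dt
    } else {
      if (Nt >= 3)
        f[2:(Nt - 1), ] <- (x[3:Nt, , drop = FALSE] - x[1:(Nt - 2), , drop = FALSE]) /
          (ds$times[3:Nt] - ds$times[1:(Nt - 2)])
    }
    f
  }
  f_veh <- rate_est(ds$vehicle)
  f_pert <- lapply(ds$perturbed, rate_est)
  dt_x <- ds$vehicle[2:Nt, , drop = FALSE] - ds$vehicle[1:(Nt - 1), , drop = FALSE]
  dp_x <- lapply(ds$perturbed, function(m)
    (m - ds$vehicle)[1:(Nt - 1), , drop = FALSE])
  y_t <- f_veh[2:Nt, , drop = FALSE] - f_veh[1:(Nt - 1), , drop = FALSE]
  y_p <- lapply(f_pert, function(f) (f - f_veh)[1:(Nt - 1), , drop = FALSE])
  valid_k <- which(apply(!is.na(y_t), 1, all))
  structure(list(dt_x = dt_x, dp_x = dp_x, y_t = y_t, y_p = y_p,
                 f_hat = c(list(vehicle = f_veh), f_pert),
                 valid_k = valid_k, diff = scheme, n = n, times = ds$times),
            class = "difference_tables")
}

#' Direct per-time-point Jacobian estimates
#'
#' Solves, for every node i and usable time index k, the n x n linear system
#' whose first row comes from the vehicle time difference and whose remaining
#' rows come from the perturbations of the other nodes (data from
#' perturbation i are never used for row i).  This is the fast analytic route:
#' exact in the small-step limit on clean data, but fragile under noise --
#' which is why the least-squares estimator [dlmra()] exists.
#'
#' @param ds a [perturbation_dataset].
#' @param diff rate-estimation scheme passed to [difference_tables()].
#' @param rcond_min reciprocal-condition-number threshold below which a
#'   per-time-point system is flagged singular and excluded from the median.
#' @param poly_order polynomial order for the `"poly"` rate scheme.
#' @return Object of class `jacobian_series`: `estimates` (n x n x Nt-1 array,
#'   NA where flagged), `median` (element-wise median over non-flagged
#'   estimates), `spread` (element-wise IQR), `rcond` (n x (Nt-1) matrix of
#'   reciprocal condition numbers) and `flagged` (logical matrix).
#' @export
jacobian_series <- function(ds, diff = c("poly", "forward", "central"),
                            rcond_min = 1e-10, poly_order = 6) {
  tab <- difference_tables(ds, diff, poly_order = poly_order)
  n <- ds$n
  Nt <- length(ds$times)
  est <- array(NA_real_, c(n, n, Nt - 1))
  rc <- matrix(NA_real_, n, Nt - 1)
  flagged <- matrix(TRUE, n, Nt - 1)
  for (k in tab$valid_k) {
    for (i in seq_len(n)) {
      others <- setdiff(seq_len(n), i)
      A <- rbind(tab$dt_x[k, ],
                 do.call(rbind, lapply(others, function(j) tab$dp_x[[j]][k, ])))
      b <- c(tab$y_t[k, i], vapply(others, function(j) tab$y_p[[j]][k, i], 0))
      if (any(is.na(A)) || any(is.na(b))) next
      rc[i, k] <- rcond(A)
      if (is.finite(rc[i, k]) && rc[i, k] > rcond_min) {
        est[i, , k] <- solve(A, b)
        flagged[i, k] <- FALSE
      }
    }
  }
  if (any(rowSums(!flagged) == 0))
    stop(sprintf("all time points singular for node(s) %s",
                 paste(which(rowSums(!flagged) == 0), collapse = ", ")))
  med <- apply(est, c(1, 2), median, na.rm = TRUE)
  spr <- apply(est, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else diff(quantile(v, c(0.25, 0.75), na.rm = TRUE)))
  structure(list(estimates = est, median = med, spread = spr, rcond = rc,
                 flagged = flagged, diff = tab$diff, times = ds$times),
            class = "jacobian_series")
}

#' @export
print.jacobian_series <- function(x, ...) {
  cat(sprintf("Per-time-point Jacobian estimates (%s differences, %d usable solves)\n",
              x$diff, sum(!x$flagged)))
  cat("Median estimate:\n")
  print(round(x$median, 4))
  invisible(x)
}

#' @export
as.data.frame.jacobian_series <- function(x, ...) {
  n <- nrow(x$median)
  Nk <- dim(x$estimates)[3]
  grid <- expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(Nk))
  data.frame(time = x$times[grid$k], i = grid$i, j = grid$j,
             estimate = x$estimates[as.matrix(grid)],
             rcond = x$rcond[cbind(grid$i, grid$k)])
}

#' Stimulus recovery from the analytic estimates
#'
#' Applies the steady-state relation \eqn{S_b + S_{ex} = -F x} with the median
#' edge-weight estimate and the final measured time point (assumed near steady
#' state); when t = 0 was a pre-stimulus steady state the basal contribution
#' \eqn{S_b = -F x(0)} is separated out so the external stimulus alone is
#' also reported.  The final-point rate residual is attached as a quality
#' flag.
#'
#' @param series a [jacobian_series].
#' @param ds the dataset the series came from.
#' @return List with `S_total`, `S_b`, `S_ex` and `residual`.
#' @export
series_stimuli <- function(series, ds) {
  stopifnot(inherits(series, "jacobian_series"),
            inherits(ds, "perturbation_dataset"))
  Fm <- series$median
  x_end <- ds$vehicle[nrow(ds$vehicle), ]
  x0 <- ds$vehicle[1, ]
  S_total <- stimulus_from_steady_state(Fm, x_end)
  S_b <- basal_from_initial_state(Fm, x0)
  Nt <- length(ds$times)
  resid <- max(abs((ds$vehicle[Nt, ] - ds$vehicle[Nt - 1, ]) /
                     (ds$times[Nt] - ds$times[Nt - 1])))
  list(S_total = S_total, S_b = S_b, S_ex = S_total - S_b, residual = resid)
}
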