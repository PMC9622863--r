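#' Polynomial interpolant of a sampled trace
#'
#' Least-squares polynomial of the requested order through the sampled values,
#' returned as a callable; evaluation outside the sampled range clamps to the
#' endpoints.  Used to force the measured trace of the perturbed node through
#' the surrogate ODE during estimation.  If fewer than `order + 1` points are
#' available the order is reduced with a warning.
#'
#' @param times sample times.
#' @param values sampled values.
#' @param order polynomial order (default 5, balancing fidelity against
#'   overfitting of noisy traces).
#' @return A function of time; the ascending coefficient vector is attached
#'   as attribute `"coef"` and the order as `"order"`.
#' @export
poly_interpolant <- function(times, values, order = 5) {
  if (length(times) != length(values)) stop("times/values length mismatch")
  if (order >= length(times)) {
    order <- length(times) - 1
    warning(sprintf("too few points; interpolation order reduced to %d", order))
  }
  pc <- rev(pracma::polyfit(times, values, order))  # ascending powers
  lo <- min(times); hi <- max(times)
  f <- function(t) {
    t <- pmin(pmax(t, lo), hi)
    drop(outer(t, 0:order, `^`) %*% pc)
  }
  attr(f, "coef") <- pc
  attr(f, "order") <- order
  f
}

# internal: per-variant theta layout
variant_code <- function(variant) {
  match(variant, c("standard", "zero_basal", "ffl", "cellstate")) - 1L
}

free_param_names <- function(n, variant) {
  fn <- as.vector(outer(seq_len(n), seq_len(n),
                        function(i, j) sprintf("F%d%d", i, j)))
  switch(variant,
         standard = ,
         zero_basal = c(fn, sprintf("S%dex", seq_len(n))),
         ffl = c(fn, "S1ex"),
         cellstate = {
           keep <- as.vector(outer(seq_len(n), seq_len(n), `!=`))
           fn[keep]
         })
}

# analytic warm start: the per-time-point median Jacobian and the
# steady-state stimulus algebra, clipped into the box
analytic_start <- function(ds, variant, bounds) {
  js <- jacobian_series(ds)
  F0 <- js$median
  clip <- function(x) pmin(pmax(x, bounds[1] + 1e-6), bounds[2] - 1e-6)
  if (variant == "cellstate") {
    # column-major off-diagonal order, rates clipped non-negative
    theta <- numeric(0)
    for (j in seq_len(ds$n)) theta <- c(theta, F0[-j, j])
    return(pmin(pmax(theta, 0), bounds[2] - 1e-6))
  }
  st <- series_stimuli(js, ds)
  if (variant == "ffl") c(clip(as.vector(F0)), clip(st$S_ex[1]))
  else c(clip(as.vector(F0)), clip(st$S_ex))
}

# map a free-parameter vector to the full (F, S_b, S_ex) set, mirroring the
# compiled objective
theta_to_params <- function(theta, n, variant, x0) {
  if (variant == "cellstate") {
    F <- matrix(0, n, n)
    idx <- 1
    for (j in seq_len(n)) for (i in seq_len(n)) if (i != j) {
      F[i, j] <- theta[idx]; idx <- idx + 1
    }
    diag(F) <- -colSums(F)
    return(list(F = F, S_b = rep(0, n), S_ex = rep(0, n)))
  }
  F <- matrix(theta[seq_len(n * n)], n, n)
  if (variant == "standard") {
    list(F = F, S_b = as.numeric(-F %*% x0),
         S_ex = theta[n * n + seq_len(n)])
  } else if (variant == "zero_basal") {
    list(F = F, S_b = rep(0, n), S_ex = theta[n * n + seq_len(n)])
  } else {  # ffl
    S_b <- as.numeric(-F %*% x0)
    S_b[1] <- 0
    list(F = F, S_b = S_b, S_ex = c(theta[n * n + 1], rep(0, n - 1)))
  }
}

# assemble the constant problem description handed to the compiled objective
build_phi_spec <- function(ds, variant, interp_order) {
  Nt <- length(ds$times)
  order <- min(interp_order, Nt - 1)
  pcs <- lapply(seq_len(ds$n), function(j) {
    f <- suppressWarnings(
      poly_interpolant(ds$times, ds$perturbed[[j]][, j], order))
    attr(f, "coef")
  })
  list(n = ds$n, variant = variant_code(variant), times = ds$times,
       vehicle = ds$vehicle, perturbed = ds$perturbed, pc = pcs)
}

#' DL-MRA objective function
#'
#' The sum of squared errors \eqn{\Phi} between measured trajectories and the
#' trajectories of the candidate linear model: the vehicle condition is
#' propagated from the measured initial state, and each perturbation-j
#' condition replaces node j's equation by the polynomial interpolant of its
#' measured trace; residuals of node j under perturbation j are never counted.
#' Basal production is eliminated per variant from the measured t = 0 state.
#' A candidate whose trajectories blow up numerically receives a large finite
#' penalty (1e12) rather than an exception so that multistart survives wild
#' guesses.
#'
#' @param theta free-parameter vector; layout per variant:
#'   column-major edge weights then stimulus terms
#'   (`standard` / `zero_basal`), edge weights then `S1ex` (`ffl`), or
#'   column-major off-diagonal rates (`cellstate`).
#' @param data a [perturbation_dataset].
#' @param variant estimator variant.
#' @param interp_order polynomial order for the perturbed-trace interpolant.
#' @return The scalar objective \eqn{\Phi}.
#' @export
dlmra_objective <- function(theta, data,
                            variant = c("standard", "cellstate", "ffl",
                                        "zero_basal"),
                            interp_order = 5) {
  variant <- match.arg(variant)
  spec <- build_phi_spec(data, variant, interp_order)
  dlmra_phi_cpp(theta, spec)
}

#' Fit a dynamic network model by multistart least squares (DL-MRA)
#'
#' The core estimator: fits the linear network model
#' \eqn{dx/dt = S_b + S_{ex} + F x} to a perturbation time-course dataset by
#' bounded multistart least squares.  Perturbations enter without any
#' mechanistic model: the measured trace of the perturbed node, interpolated
#' by a polynomial, forces the remaining equations, and the perturbed node's
#' own residuals are excluded.  Basal production is not a free parameter --
#' it is eliminated at every objective evaluation from the measured t = 0
#' state (a pre-stimulus steady state), per variant:
#'
#' * `standard`: free parameters are the n^2 edge weights and n external
#'   stimuli; \eqn{S_b = -F x(0)}.
#' * `zero_basal`: as standard with \eqn{S_b \equiv 0} (for systems known to
#'   rest at zero without stimulus).
#' * `ffl`: three-node gene-circuit prior -- \eqn{S_{1,b} = 0},
#'   \eqn{S_{2,ex} = S_{3,ex} = 0}; free parameters are the 9 edge weights
#'   and \eqn{S_{1,ex}}; \eqn{S_{2,b}, S_{3,b}} eliminated from rows 2-3 of
#'   \eqn{-F x(0)}.
#' * `cellstate`: mass-conserving transition network -- off-diagonal rates
#'   are non-negative free parameters, each diagonal is minus its column sum,
#'   and \eqn{S_b = S_{ex} = 0}.
#'
#' Each start draws edge weights uniform on `init_edge` and stimulus terms
#' uniform on `init_input`, then runs a bounded damped least-squares
#' (Levenberg-Marquardt) minimization within `bounds` -- residual magnitudes
#' can span many decades when a clamped node leaves an unstable complement
#' subsystem, which damped least squares handles where plain quasi-Newton
#' descent stalls (L-BFGS-B remains as a fallback).  The best final
#' objective wins (ties break to the lowest start index).  When
#' `warm_start = TRUE` (default) the first start is seeded by the direct
#' per-time-point analytic solution ([jacobian_series()]) instead of a random
#' draw: on clean data from weakly damped oscillatory networks the random
#' multistart alone can miss the global basin, and the analytic estimates --
#' however noise-fragile on their own -- make an excellent initializer.
#'
#' @param data a [perturbation_dataset] (complete: vehicle plus one
#'   perturbation per node).
#' @param variant estimator variant, see Details.
#' @param n_starts number of multistart runs (default 10).
#' @param bounds length-2 box for every free parameter (default c(-10, 10);
#'   the cellstate lower bound is raised to 0).
#' @param init_edge,init_input sampling intervals for initial guesses.
#' @param interp_order polynomial order for perturbed-trace interpolation.
#' @param seed optional seed for the initial-guess draws.
#' @param warm_start seed the first start from the analytic per-time-point
#'   solution (see Details).
#' @param control optimizer settings: `maxit` (iteration cap), `ftol`/`ptol`
#'   (Levenberg-Marquardt convergence tolerances), `factr` (fallback
#'   L-BFGS-B tolerance).
#' @return An object of class `dlmra`: list with `coefficients` (full named
#'   parameter vector: edge weights, basal production, external stimuli),
#'   `F`, `S_b`, `S_ex`, `sse` (best objective), `starts` (per-start table
#'   with the free-parameter matrix in attribute `"par"`), `variant`,
#'   `options`, `data` and `call`.
#' @seealso [predict.dlmra()], [multistart_cv()]
#' @examples
#' \donttest{
#' ds <- perturbation_design(single_activator_network(), p = 0)
#' fit <- dlmra(ds, n_starts = 4, seed = 1)
#' coef(fit)
#' }
#' @export
dlmra <- function(data,
                  variant = c("standard", "cellstate", "ffl", "zero_basal"),
                  n_starts = 10, bounds = c(-10, 10),
                  init_edge = c(-2, 2), init_input = c(0, 2),
                  interp_order = 5, seed = NULL, warm_start = TRUE,
                  control = list()) {
  stopifnot(inherits(data, "perturbation_dataset"))
  variant <- match.arg(variant)
  if (n_starts < 1) stop("'n_starts' must be >= 1")
  if (variant == "cellstate") {
    dev <- max(abs(rowSums(data$vehicle) - 1),
               vapply(data$perturbed, function(m) max(abs(rowSums(m) - 1)), 0))
    if (dev > 1e-3)
      warning(sprintf("dataset is not mass-conserving (max deviation %.3g)", dev))
  }
  spec <- build_phi_spec(data, variant, interp_order)
  pn <- free_param_names(data$n, variant)
  npar <- length(pn)
  n_edge <- if (variant == "cellstate") npar else data$n^2
  lower <- rep(if (variant == "cellstate") max(0, bounds[1]) else bounds[1], npar)
  upper <- rep(bounds[2], npar)
  ctl <- modifyList(list(maxit = 300, factr = 1e7, ftol = 1e-10,
                         ptol = 1e-10), control)

  warm <- if (isTRUE(warm_start))
    tryCatch(analytic_start(data, variant, bounds), error = function(e) NULL)
  if (!is.null(seed)) set.seed(seed)
  draw_init <- function() {
    init <- numeric(npar)
    lo_e <- if (variant == "cellstate") max(0, init_edge[1]) else init_edge[1]
    init[seq_len(n_edge)] <- runif(n_edge, lo_e, init_edge[2])
    if (npar > n_edge)
      init[(n_edge + 1):npar] <- runif(npar - n_edge, init_input[1], init_input[2])
    init
  }
  fn <- function(th) {
    v <- dlmra_phi_cpp(th, spec)
    if (!is.finite(v)) 1e12 else v
  }
  one_start <- function(init) {
    res <- tryCatch({
      o <- minpack.lm::nls.lm(
        par = init, lower = lower, upper = upper,
        fn = function(th) dlmra_resid_cpp(th, spec),
        control = minpack.lm::nls.lm.control(maxiter = ctl$maxit,
                                             ftol = ctl$ftol,
                                             ptol = ctl$ptol))
      list(par = o$par, value = o$deviance,
           convergence = if (o$info %in% 1:4) 0L else 1L,
           message = o$message)
    }, error = function(e) e)
    if (!inherits(res, "error")) return(res)
    # damped least squares failed outright: quasi-Newton fallback
    res <- tryCatch(
      optim(init, fn, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = ctl$maxit, factr = ctl$factr)),
      error = function(e) e)
    if (inherits(res, "error")) return(res)
    list(par = res$par, value = res$value, convergence = res$convergence,
         message = if (is.null(res$message)) "" else res$message)
  }

  par_mat <- matrix(NA_real_, n_starts, npar, dimnames = list(NULL, pn))
  init_mat <- matrix(NA_real_, n_starts, npar, dimnames = list(NULL, pn))
  value <- rep(NA_real_, n_starts)
  convergence <- rep(NA_integer_, n_starts)
  msg <- character(n_starts)
  for (s in seq_len(n_starts)) {
    init <- if (s == 1 && !is.null(warm)) warm else draw_init()
    res <- one_start(init)
    init_mat[s, ] <- init
    if (inherits(res, "error")) {
      msg[s] <- conditionMessage(res)
      next
    }
    par_mat[s, ] <- res$par
    value[s] <- res$value
    convergence[s] <- res$convergence
    msg[s] <- res$message
  }
  if (all(is.na(value)))
    stop(paste0("all starts failed to converge:\n  ",
                paste(unique(msg), collapse = "\n  ")))
  best <- which.min(replace(value, is.na(value), Inf))  # ties -> lowest index
  pars <- theta_to_params(par_mat[best, ], data$n, variant, data$vehicle[1, ])

  cf <- setNames(c(as.vector(pars$F), pars$S_b, pars$S_ex),
                 param_names(data$n))
  starts <- data.frame(start = seq_len(n_starts), value = value,
                       convergence = convergence, message = msg)
  attr(starts, "par") <- par_mat
  attr(starts, "init") <- init_mat
  structure(list(coefficients = cf, F = pars$F, S_b = pars$S_b,
                 S_ex = pars$S_ex, sse = value[best], best_start = best,
                 starts = starts, variant = variant,
                 options = list(n_starts = n_starts, bounds = bounds,
                                init_edge = init_edge, init_input = init_input,
                                interp_order = interp_order, seed = seed,
                                control = ctl),
                 data = data, call = match.call()),
            class = "dlmra")
}

#' @export
print.dlmra <- function(x, digits = 4, ...) {
  cat(sprintf("DL-MRA fit (%s variant), %d nodes\n", x$variant, x$data$n))
  cat(sprintf("  Phi = %.6g over %d starts (best = start %d, %d converged)\n",
              x$sse, nrow(x$starts), x$best_start,
              sum(x$starts$convergence == 0, na.rm = TRUE)))
  cat("Edge weights F:\n")
  print(round(x$F, digits))
  cat("S_b: ", paste(round(x$S_b, digits), collapse = " "), "\n")
  cat("S_ex:", paste(round(x$S_ex, digits), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.dlmra <- function(object, ...) object$coefficients

#' @export
summary.dlmra <- function(object, ...) {
  cv <- tryCatch(multistart_cv(object), error = function(e) NULL)
  structure(list(fit = object, cv = cv,
                 flags = stability_flags(object$F)),
            class = "summary.dlmra")
}

#' @export
print.summary.dlmra <- function(x, ...) {
  print(x$fit)
  cat(sprintf("Fitted network: %s%s\n",
              if (x$flags$stable) "stable" else "unstable",
              if (x$flags$oscillatory) ", damped-oscillatory" else ""))
  if (!is.null(x$cv) && length(x$cv)) {
    cat("Multistart coefficient of variation (starts with Phi < 2 min Phi):\n")
    print(round(x$cv, 4))
  }
  invisible(x)
}

#' Predicted trajectories of a fitted model
#'
#' Recomputes the model trajectories exactly as the objective does: the
#' vehicle condition propagated from the measured initial state, and each
#' perturbation condition with the perturbed node forced by its polynomial
#' interpolant.  For node j under perturbation j the fitted value is the
#' interpolant itself (those points carry no residual).
#'
#' @param object a fitted `dlmra` object.
#' @param newdata optional [perturbation_dataset] to predict for (defaults to
#'   the training data).
#' @param ... unused.
#' @return Tidy data.frame: `condition`, `time`, `node`, `observed`,
#'   `fitted`, `residual`, `used` (whether the point enters the objective).
#' @export
predict.dlmra <- function(object, newdata = NULL, ...) {
  ds <- if (is.null(newdata)) object$data else newdata
  n <- ds$n
  Nt <- length(ds$times)
  order <- min(object$options$interp_order, Nt - 1)
  s <- object$S_b + object$S_ex
  rows <- list()
  pred_v <- prop_affine_cpp(object$F, s, ds$vehicle[1, ], ds$times)
  rows[["vehicle"]] <- data.frame(
    condition = "vehicle", time = rep(ds$times, n),
    node = rep(seq_len(n), each = Nt),
    observed = as.vector(ds$vehicle), fitted = as.vector(pred_v),
    used = TRUE)
  for (j in seq_len(n)) {
    idx <- setdiff(seq_len(n), j)
    f <- suppressWarnings(
      poly_interpolant(ds$times, ds$perturbed[[j]][, j], order))
    pred <- matrix(NA_real_, Nt, n)
    pred[, idx] <- prop_forced_cpp(object$F[idx, idx, drop = FALSE], s[idx],
                                   object$F[idx, j], attr(f, "coef"),
                                   ds$perturbed[[j]][1, idx], ds$times)
    pred[, j] <- f(ds$times)
    used <- matrix(TRUE, Nt, n); used[, j] <- FALSE
    rows[[sprintf("pert_%d", j)]] <- data.frame(
      condition = sprintf("pert_%d", j), time = rep(ds$times, n),
      node = rep(seq_len(n), each = Nt),
      observed = as.vector(ds$perturbed[[j]]), fitted = as.vector(pred),
      used = as.vector(used))
  }
  out <- do.call(rbind, rows)
  out$residual <- out$observed - out$fitted
  rownames(out) <- NULL
  out
}

#' @export
fitted.dlmra <- function(object, ...) predict(object)$fitted

#' @export
residuals.dlmra <- function(object, ...) {
  pr <- predict(object)
  ifelse(pr$used, pr$residual, NA_real_)
}

#' @export
plot.dlmra <- function(x, ...) {
  pr <- predict(x)
  conds <- unique(pr$condition)
  old <- par(mfrow = c(1, length(conds)), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  for (cond in conds) {
    sub <- pr[pr$condition == cond, ]
    obs <- matrix(sub$observed, ncol = x$data$n)
    fit <- matrix(sub$fitted, ncol = x$data$n)
    matplot(unique(sub$time), obs, pch = 1, xlab = "time", ylab = "activity",
            main = cond, ...)
    matplot(unique(sub$time), fit, type = "l", lty = 1, add = TRUE)
  }
  invisible(x)
}

#' Simulate datasets from a fitted network
#'
#' Regenerates the experimental design from the fitted linear network (same
#' time grid and perturbation strength as the training data), optionally with
#' proportional noise -- useful for posterior predictive checks.
#'
#' @param object a fitted `dlmra` object.
#' @param nsim number of datasets.
#' @param seed optional seed.
#' @param d proportional noise level for the simulated data.
#' @param ... unused.
#' @return A list of [perturbation_dataset] objects (length `nsim`).
#' @export
simulate.dlmra <- function(object, nsim = 1, seed = NULL, d = 0, ...) {
  if (!is.null(seed)) set.seed(seed)
  net <- linear_network(object$F, S_b = object$S_b, S_ex = object$S_ex)
  clean <- perturbation_design(net, times = object$data$times, p = object$data$p)
  lapply(seq_len(nsim), function(i) {
    if (d > 0) add_noise(clean, d) else clean
  })
}

#' Serialize a fit with its provenance as JSON
#'
#' Exports the full parameter set, the best objective value, the per-start
#' table (initial guesses, final free parameters, final objective,
#' convergence flags) and the options/seed that produced them, so a fit can
#' be archived or compared across runs.
#'
#' @param fit a fitted `dlmra` object.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "dlmra"))
  doc <- list(
    variant = fit$variant,
    n = fit$data$n,
    coefficients = as.list(coef(fit)),
    sse = fit$sse,
    best_start = fit$best_start,
    starts = list(value = fit$starts$value,
                  convergence = fit$starts$convergence,
                  par = apply(attr(fit$starts, "par"), 1, as.list),
                  init = apply(attr(fit$starts, "init"), 1, as.list)),
    options = fit$options)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Multistart convergence diagnostics
#'
#' Coefficient of variation (sample sd over absolute mean) of every free
#' parameter across the qualifying multistart runs: those whose final
#' objective is below 1e-4 (`"low_sse"`) or below twice the minimum
#' (`"twice_min"`).  Tightly peaked CVs near zero indicate the multistart
#' converged to one basin.
#'
#' @param fit a fitted `dlmra` object.
#' @param mode qualification rule.
#' @param low_sse_tol threshold for `"low_sse"`.
#' @return Named numeric vector of per-parameter CVs; when fewer than two
#'   starts qualify, an empty vector flagged with attribute
#'   `"reason" = "insufficient_starts"`.
#' @export
multistart_cv <- function(fit, mode = c("twice_min", "low_sse"),
                          low_sse_tol = 1e-4) {
  stopifnot(inherits(fit, "dlmra"))
  mode <- match.arg(mode)
  par <- attr(fit$starts, "par")
  val <- fit$starts$value
  ok <- !is.na(val) & if (mode == "low_sse") val < low_sse_tol else
    val < 2 * min(val, na.rm = TRUE) + .Machine$double.eps
  if (sum(ok) < 2)
    return(structure(setNames(numeric(0), character(0)),
                     reason = "insufficient_starts"))
  sub <- par[ok, , drop = FALSE]
  apply(sub, 2, function(v) sd(v) / max(abs(mean(v)), .Machine$double.eps))
}
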