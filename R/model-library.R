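#' The two-node single-activator model
#'
#' The small benchmark network in which node 1 activates node 2
#' (\eqn{F_{21} = 1.5}), node 1 decays first-order (\eqn{F_{11} = -1}), node 2
#' self-regulates negatively (\eqn{F_{22} = -0.8}), both nodes receive a unit
#' external stimulus at t = 0 and basal production is zero:
#' \deqn{dx_1/dt = 1 - x_1, \quad dx_2/dt = 1 + 1.5 x_1 - 0.8 x_2.}
#'
#' @return A [linear_network].
#' @export
single_activator_network <- function() {
  linear_network(matrix(c(-1, 1.5, 0, -0.8), 2, 2),
                 S_b = c(0, 0), S_ex = c(1, 1))
}

#' Sample a random stable linear network
#'
#' Edge weights are drawn i.i.d. uniform on `edge_range` and the basal and
#' external stimulus strengths i.i.d. uniform on `input_range`; draws are
#' rejected until the edge-weight matrix is stable (all eigenvalues with
#' negative real part).  Uses the current RNG state, so results are
#' reproducible under `set.seed()`.
#'
#' @param n node count (2 and 3 are the benchmarked sizes; larger is allowed).
#' @param edge_range,input_range sampling intervals for edge weights and for
#'   the basal/stimulus strengths.
#' @param max_attempts rejection-sampling cap.
#' @return A stable [linear_network]; the number of draws needed is attached
#'   as attribute `"attempts"`.
#' @export
sample_random_network <- function(n, edge_range = c(-2, 2),
                                  input_range = c(0, 2),
                                  max_attempts = 10000) {
  for (attempt in seq_len(max_attempts)) {
    F <- matrix(runif(n * n, edge_range[1], edge_range[2]), n, n)
    if (max(Re(eigen(F, only.values = TRUE)$values)) < 0) {
      net <- linear_network(F,
                            S_b = runif(n, input_range[1], input_range[2]),
                            S_ex = runif(n, input_range[1], input_range[2]))
      attr(net, "attempts") <- attempt
      return(net)
    }
  }
  stop(sprintf("no stable network found in %d attempts", max_attempts))
}

## ---- feedforward-loop gene circuit models -------------------------------

#' The 16 feedforward-loop model structures
#'
#' Enumerates every combination of activating/repressing regulation for the
#' three existing edges (x1 to x2, x1 to x3, x2 to x3) and AND/OR integration
#' of the two inputs of x3.  Models 1-8 have an activating x1-to-x2 edge,
#' 9-16 a repressing one; within each half the gate alternates in blocks of 4
#' and the (x1-to-x3, x2-to-x3) signs cycle through
#' (act, act), (act, rep), (rep, act), (rep, rep).
#'
#' @return data.frame with columns `model_id`, `sign_21`, `gate`, `sign_31`,
#'   `sign_32`.
#' @export
ffl_model_table <- function() {
  signs <- c("activator", "repressor")
  grid <- expand.grid(sign_32 = signs, sign_31 = signs,
                      gate = c("AND", "OR"), sign_21 = signs,
                      stringsAsFactors = FALSE)
  data.frame(model_id = seq_len(16),
             sign_21 = grid$sign_21, gate = grid$gate,
             sign_31 = grid$sign_31, sign_32 = grid$sign_32,
             stringsAsFactors = FALSE)
}

#' Feedforward-loop model specification
#'
#' A three-node gene circuit in which x1 (stimulus-driven) regulates x2 and,
#' together with x2, regulates x3 through an AND or OR gate; every node decays
#' first-order.  Regulation uses Hill functions with exponent 2 and thresholds
#' `K` (activity units).  Either give a `model_id` (1-16, see
#' [ffl_model_table()]) or the three signs and the gate explicitly.
#'
#' @param model_id integer 1-16 selecting a row of [ffl_model_table()].
#' @param sign_21,sign_31,sign_32 `"activator"` or `"repressor"`.
#' @param gate `"AND"` or `"OR"`.
#' @param K named or positional numeric vector of the three Hill thresholds
#'   (x1-to-x2, x1-to-x3, x2-to-x3), all positive.  The default 0.5 keeps the
#'   circuit responsive to a unit stimulus and to partial perturbations.
#' @return An object of class `ffl_model`.
#' @export
ffl_model <- function(model_id = NULL, sign_21 = "activator", gate = "AND",
                      sign_31 = "activator", sign_32 = "activator",
                      K = c(0.5, 0.5, 0.5)) {
  if (!is.null(model_id)) {
    tab <- ffl_model_table()
    if (!model_id %in% tab$model_id) stop("'model_id' must be in 1..16")
    row <- tab[tab$model_id == model_id, ]
    sign_21 <- row$sign_21; gate <- row$gate
    sign_31 <- row$sign_31; sign_32 <- row$sign_32
  }
  sign_21 <- match.arg(sign_21, c("activator", "repressor"))
  sign_31 <- match.arg(sign_31, c("activator", "repressor"))
  sign_32 <- match.arg(sign_32, c("activator", "repressor"))
  gate <- match.arg(gate, c("AND", "OR"))
  K <- as.numeric(K)
  if (length(K) != 3 || any(K <= 0)) stop("'K' must be 3 positive thresholds")
  if (is.null(model_id)) {
    tab <- ffl_model_table()
    model_id <- tab$model_id[tab$sign_21 == sign_21 & tab$gate == gate &
                               tab$sign_31 == sign_31 & tab$sign_32 == sign_32]
  }
  structure(list(model_id = model_id, sign_21 = sign_21, gate = gate,
                 sign_31 = sign_31, sign_32 = sign_32,
                 K = c(x1x2 = K[1], x1x3 = K[2], x2x3 = K[3]), n = 3L),
            class = "ffl_model")
}

#' @export
print.ffl_model <- function(x, ...) {
  cat(sprintf("FFL model #%d: x1-%s->x2, x1-%s->x3, x2-%s->x3, %s gate\n",
              x$model_id, substr(x$sign_21, 1, 3), substr(x$sign_31, 1, 3),
              substr(x$sign_32, 1, 3), x$gate))
  cat("Hill thresholds K:", paste(sprintf("%s=%g", names(x$K), x$K),
                                  collapse = ", "), "\n")
  invisible(x)
}

# Hill regulation with exponent 2: activator (u/K)^2/(1+(u/K)^2),
# repressor 1/(1+(u/K)^2)
hill_reg <- function(u, K, sign) {
  r2 <- (u / K)^2
  if (sign == "activator") r2 / (1 + r2) else 1 / (1 + r2)
}

# competitive form used by the OR gate: the two regulators share the
# denominator 1 + (u/Ku)^2 + (v/Kv)^2
hill_comp <- function(u, K_u, K_v, v, sign) {
  den <- 1 + (u / K_u)^2 + (v / K_v)^2
  if (sign == "activator") (u / K_u)^2 / den else 1 / den
}

#' Rate function of a feedforward-loop model
#'
#' \eqn{dx_1/dt = S_{1,ex} - x_1} (unit stimulus when active),
#' \eqn{dx_2/dt = f(x_1) - x_2} and \eqn{dx_3/dt = G(x_1, x_2) - x_3} where
#' `G` multiplies the two Hill terms (AND gate) or sums the two competitive
#' forms (OR gate).
#'
#' @param spec an [ffl_model].
#' @param x non-negative activity 3-vector.
#' @param stimulus_active whether the unit stimulus on node 1 is applied.
#' @return Rate 3-vector.
#' @export
ffl_rates <- function(spec, x, stimulus_active = TRUE) {
  stopifnot(inherits(spec, "ffl_model"))
  check_length(x, 3, "x")
  if (any(x < 0)) stop("negative activities are outside the Hill model domain")
  K <- spec$K
  G <- if (spec$gate == "AND") {
    hill_reg(x[1], K["x1x3"], spec$sign_31) *
      hill_reg(x[2], K["x2x3"], spec$sign_32)
  } else {
    hill_comp(x[1], K["x1x3"], K["x2x3"], x[2], spec$sign_31) +
      hill_comp(x[2], K["x2x3"], K["x1x3"], x[1], spec$sign_32)
  }
  unname(c((if (stimulus_active) 1 else 0) - x[1],
           hill_reg(x[1], K[["x1x2"]], spec$sign_21) - x[2],
           G - x[3]))
}

#' @rdname simulate_network
#' @export
simulate_network.ffl_model <- function(model, x0, times, rtol = 1e-8,
                                       atol = 1e-10, stimulus_active = TRUE,
                                       ...) {
  check_length(x0, 3, "x0")
  sol <- deSolve::lsoda(y = pmax(x0, 0), times = times,
                        func = function(t, y, p)
                          list(ffl_rates(model, pmax(y, 0), stimulus_active)),
                        parms = NULL, rtol = rtol, atol = atol)
  trajectory(times, unname(sol[, -1, drop = FALSE]))
}

#' @rdname basal_steady_state
#' @export
basal_steady_state.ffl_model <- function(model, tol = 1e-9, t_max = 1000, ...) {
  x <- integrate_to_steady(function(y) ffl_rates(model, pmax(y, 0), FALSE),
                           c(0, 0, 0), tol, t_max)
  structure(list(x_ss = x, residual = max(abs(ffl_rates(model, x, FALSE)))),
            class = "steady_state")
}

## ---- Markov cell-state transition models --------------------------------

#' Markov cell-state transition model
#'
#' A column-stochastic matrix `M` of per-step transition probabilities (entry
#' \eqn{M_{ij}} = probability that a cell in state j is in state i one step
#' later) together with the step length in days.
#'
#' @param M n x n column-stochastic matrix; entries in \[0, 1\], columns
#'   summing to 1 (tolerance 1e-12).
#' @param step time difference of one Markov step, in days.
#' @return An object of class `markov_model`.
#' @export
markov_model <- function(M, step = 1) {
  M <- as.matrix(M)
  stop_if_not_square(M, "M")
  if (any(M < 0 | M > 1)) stop("'M' entries must lie in [0, 1]")
  if (any(abs(colSums(M) - 1) > 1e-12))
    stop("columns of 'M' must each sum to 1 (transition probabilities)")
  if (step <= 0) stop("'step' must be positive")
  structure(list(M = M, step = step, n = nrow(M)), class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("Markov cell-state model: %d states, step = %g day(s)\n",
              x$n, x$step))
  print(round(x$M, 4))
  invisible(x)
}

#' Random cell-state transition model
#'
#' Samples a column-stochastic daily transition matrix in which cells mostly
#' retain their state: each diagonal entry is uniform on `stay_range` and the
#' remaining column mass is split over the other states by a uniform
#' (symmetric Dirichlet) split.  Draws are rejected until the matrix
#' logarithm is a valid continuous-time generator (non-negative off-diagonal
#' rates), so the sampled chain always has an exact rate-matrix counterpart.
#'
#' @param n number of cell states.
#' @param step Markov step length in days.
#' @param stay_range interval for the per-state retention probability.
#' @param max_attempts rejection cap.
#' @return A [markov_model].
#' @export
random_markov_model <- function(n = 3, step = 1, stay_range = c(0.6, 0.9),
                                max_attempts = 1000) {
  for (attempt in seq_len(max_attempts)) {
    M <- matrix(0, n, n)
    for (j in seq_len(n)) {
      stay <- runif(1, stay_range[1], stay_range[2])
      w <- rexp(n - 1)
      M[-j, j] <- (1 - stay) * w / sum(w)
      M[j, j] <- stay
    }
    m <- markov_model(M, step = step)
    net <- suppressWarnings(markov_to_continuous(m))
    off <- row(net$F) != col(net$F)
    if (attr(net, "conversion") == "logm" && all(net$F[off] > -1e-9))
      return(m)
  }
  stop(sprintf("no embeddable transition matrix found in %d attempts",
               max_attempts))
}

#' Convert a Markov transition model to continuous time
#'
#' Finds the rate matrix `F` (columns summing to zero, so total proportion is
#' conserved) whose flow reproduces the Markov chain: exactly via
#' \eqn{F = \log(M)/\Delta t} when the real matrix logarithm exists, else by
#' the first-order expansion \eqn{F = (M - I)/\Delta t} with a warning.  The
#' returned network has zero basal production and stimulus, since cell-state
#' proportions are driven purely by interconversion.
#'
#' @param m a [markov_model].
#' @param method `"auto"` (logarithm with first-order fallback), `"logm"`, or
#'   `"first_order"`.
#' @return A [linear_network] with attribute `"conversion"` (`"logm"` or
#'   `"first_order"`).
#' @export
markov_to_continuous <- function(m, method = c("auto", "logm", "first_order")) {
  stopifnot(inherits(m, "markov_model"))
  method <- match.arg(method)
  F <- NULL
  conv <- "first_order"
  if (method != "first_order") {
    L <- tryCatch(suppressWarnings(pracma::logm(m$M)), error = function(e) NULL)
    ok <- !is.null(L) && all(is.finite(L)) && all(abs(Im(L)) < 1e-10) &&
      max(abs(pracma::expm(Re(L)) - m$M)) < 1e-6
    if (ok) L <- Re(L)
    if (ok) {
      F <- L / m$step
      conv <- "logm"
    } else if (method == "logm") {
      stop("real matrix logarithm of 'M' does not exist or did not converge")
    } else {
      warning("matrix logarithm unavailable; falling back to first-order (M - I)/step")
    }
  }
  if (is.null(F)) F <- (m$M - diag(m$n)) / m$step
  # columns of log(M) sum to zero analytically; tidy up roundoff so that
  # simulated proportions conserve mass exactly
  F <- sweep(F, 2, colSums(F) / m$n)
  net <- linear_network(F, S_b = rep(0, m$n), S_ex = rep(0, m$n),
                        stimulus_active = FALSE)
  attr(net, "conversion") <- conv
  net
}
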