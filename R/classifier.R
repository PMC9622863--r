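#' Ground-truth sign classes of a generating model
#'
#' Maps each parameter of the generating model to its true class: `"null"`
#' for an exact zero, otherwise the sign.  For feedforward-loop models the
#' basal-production truths are the pre-stimulus steady-state production rates
#' (node activity times unit decay), so e.g. a repressed node 2 has positive
#' basal production while an activated one has none.
#'
#' @param model a [linear_network], [ffl_model] or [markov_model].
#' @param ... passed to methods.
#' @return Named character vector over the model's full parameter set
#'   (edge weights, basal production, external stimuli), values in
#'   `positive`, `negative`, `null`.
#' @export
sign_truth <- function(model, ...) UseMethod("sign_truth")

sign_class <- function(v, tol = 0) {
  ifelse(abs(v) <= tol, "null", ifelse(v > 0, "positive", "negative"))
}

#' @export
sign_truth.linear_network <- function(model, ...) {
  setNames(sign_class(c(as.vector(model$F), model$S_b, model$S_ex)),
           param_names(model$n))
}

#' @export
sign_truth.ffl_model <- function(model, ...) {
  edge <- function(sign) if (sign == "activator") "positive" else "negative"
  x0 <- basal_steady_state(model)$x_ss
  cls <- c(F11 = "negative", F21 = edge(model$sign_21), F31 = edge(model$sign_31),
           F12 = "null", F22 = "negative", F32 = edge(model$sign_32),
           F13 = "null", F23 = "null", F33 = "negative",
           S1b = "null", S2b = sign_class(x0[2], 1e-6),
           S3b = sign_class(x0[3], 1e-6),
           S1ex = "positive", S2ex = "null", S3ex = "null")
  cls[param_names(3)]
}

#' @export
sign_truth.markov_model <- function(model, ...) {
  sign_truth.linear_network(markov_to_continuous(model))
}

#' The 12 reported parameters of a feedforward-loop fit
#'
#' The gene-circuit estimator fixes `S1b`, `S2ex` and `S3ex` at zero by prior
#' knowledge; the remaining 12 parameters (9 edge weights, the stimulus on
#' node 1, and the two basal productions) are what classification is scored
#' on.
#'
#' @return Character vector of parameter names.
#' @export
ffl_reported_params <- function() {
  c(as.vector(outer(1:3, 1:3, function(i, j) sprintf("F%d%d", i, j))),
    "S1ex", "S2b", "S3b")
}

#' Classify point estimates into signed edge calls
#'
#' Thresholded sign rule for a single estimate vector: parameters smaller in
#' magnitude than `null_frac` of the reference scale (by default 1/100 of the
#' largest-magnitude estimate) are called `null`, the rest by sign.
#'
#' @param values named numeric vector of estimates.
#' @param scale reference scale; defaults to `max(abs(values))`.
#' @param null_frac fraction of `scale` below which an estimate is negligible.
#' @return Character vector of classes aligned with `values`.
#' @export
classify_signs <- function(values, scale = NULL, null_frac = 0.01) {
  if (is.null(scale)) scale <- max(abs(values))
  if (scale <= 0) return(setNames(rep("null", length(values)), names(values)))
  setNames(sign_class(values, tol = scale * null_frac), names(values))
}

#' Bootstrap ensemble of parameter estimates
#'
#' Generates `B` noisy replicates of a clean dataset (the simulated data act
#' as the mean, proportional Gaussian noise as the measurement error), fits
#' each with the multistart estimator, and collects the full parameter
#' vectors.  The per-replicate estimate distributions feed the
#' percentile-window classifier.
#'
#' @param ds_clean a clean [perturbation_dataset].
#' @param d noise level for the replicates.
#' @param B number of bootstrap datasets (default 50).
#' @param n_starts multistart count per replicate.
#' @param seed master seed; per-replicate seeds are derived deterministically.
#' @param variant,interp_order passed to [dlmra()].
#' @return Object of class `bootstrap_ensemble`: `estimates` (B x n_params
#'   named matrix), `d`, `seeds`, `variant`.
#' @export
bootstrap_ensemble <- function(ds_clean, d, B = 50, n_starts = 10, seed = 1,
                               variant = "standard", interp_order = 5) {
  stopifnot(inherits(ds_clean, "perturbation_dataset"))
  est <- NULL
  seeds <- integer(B)
  for (b in seq_len(B)) {
    seeds[b] <- derive_seed(seed, b)
    noisy <- add_noise(ds_clean, d, seed = seeds[b])
    fit <- dlmra(noisy, variant = variant, n_starts = n_starts,
                 interp_order = interp_order, seed = derive_seed(seed, B + b))
    if (is.null(est))
      est <- matrix(NA_real_, B, length(coef(fit)),
                    dimnames = list(NULL, names(coef(fit))))
    est[b, ] <- coef(fit)
  }
  structure(list(estimates = est, d = d, B = B, seeds = seeds,
                 variant = variant),
            class = "bootstrap_ensemble")
}

#' @export
print.bootstrap_ensemble <- function(x, ...) {
  cat(sprintf("Bootstrap ensemble: B = %d replicates at d = %g (%s variant)\n",
              x$B, x$d, x$variant))
  invisible(x)
}

#' Percentile-window classification of bootstrap ensembles
#'
#' For each parameter, takes the symmetric percentile window
#' \[100 - w, w\] around the median of its bootstrap estimates: if all values
#' in the window are positive the parameter is called `positive`, if all
#' negative `negative`, and if the window spans zero `null`.  At `width = 50`
#' the window is the median alone, so the call is the median's sign and
#' `null` only arises from an exactly zero median.  Percentiles use linear
#' interpolation between order statistics (`stats::quantile` type 7).
#'
#' @param ens a [bootstrap_ensemble] or a numeric matrix (rows = replicates)
#'   or a single numeric vector of estimates.
#' @param width upper percentile w in \[50, 100\].
#' @return Named character vector of classes, one per parameter.
#' @export
classify_window <- function(ens, width) {
  if (width < 50 || width > 100) stop("'width' must lie in [50, 100]")
  est <- if (inherits(ens, "bootstrap_ensemble")) ens$estimates
         else if (is.matrix(ens)) ens else matrix(ens, ncol = 1)
  apply(est, 2, function(v) {
    if (width == 50) {
      m <- median(v)
      return(if (m > 0) "positive" else if (m < 0) "negative" else "null")
    }
    q <- quantile(v, c(100 - width, width) / 100, names = FALSE, type = 7)
    if (q[1] > 0) "positive" else if (q[2] < 0) "negative" else "null"
  })
}

#' Classification accuracy
#'
#' Exact-match fraction between predicted and ground-truth classes.
#'
#' @param pred,truth equal-length class vectors.
#' @return Fraction correct in \[0, 1\].
#' @export
classification_accuracy <- function(pred, truth) {
  if (length(pred) == 0) stop("empty classification")
  if (length(pred) != length(truth)) stop("length mismatch")
  mean(pred == truth)
}

#' ROC over percentile windows
#'
#' Sweeps the symmetric percentile window from the median only (w = 50) to
#' the full estimate range (w = 100) and scores the null-vs-non-null decision
#' across all parameters of all supplied ensembles: a positive event is a
#' non-null call, so TPR is the fraction of truly non-null parameters called
#' non-null (the fraction also carrying the correct sign is reported
#' separately as `tpr_signed`) and FPR the fraction of truly null parameters
#' called non-null.  AUC is the trapezoidal area with the (0,0) and (1,1)
#' endpoints appended; the selected window is the smallest w whose FPR is at
#' or below `fpr_target` (FPR is non-increasing in w).
#'
#' @param ensembles list of [bootstrap_ensemble] objects (or estimate
#'   matrices).
#' @param truths list of named truth-class vectors aligned with the ensemble
#'   parameters.
#' @param widths window sweep (default 50 to 100 in 0.5-percentile steps).
#' @param fpr_target false-positive-rate budget for window selection.
#' @param params optional character vector restricting which parameters are
#'   scored (e.g. [ffl_reported_params()]).
#' @return Object of class `window_roc`: `curve` (data.frame width, tpr,
#'   tpr_signed, fpr), `auc`, `selected_width`.
#' @export
window_roc <- function(ensembles, truths, widths = seq(50, 100, by = 0.5),
                       fpr_target = 0.05, params = NULL) {
  if (length(ensembles) != length(truths))
    stop("'ensembles' and 'truths' must be aligned")
  mats <- lapply(ensembles, function(e)
    if (inherits(e, "bootstrap_ensemble")) e$estimates else as.matrix(e))
  if (!is.null(params)) {
    mats <- lapply(mats, function(m) m[, params, drop = FALSE])
    truths <- lapply(truths, function(tr) tr[params])
  }
  truth_all <- unlist(lapply(truths, unname))
  is_null <- truth_all == "null"
  if (!any(is_null)) stop("no null parameters in truth; FPR undefined")
  n_nonnull <- sum(!is_null)
  curve <- data.frame(width = widths, tpr = NA_real_, tpr_signed = NA_real_,
                      fpr = NA_real_)
  for (r in seq_along(widths)) {
    calls <- unlist(lapply(mats, classify_window, width = widths[r]))
    called_nonnull <- calls != "null"
    curve$tpr[r] <- sum(called_nonnull & !is_null) / n_nonnull
    curve$tpr_signed[r] <- sum(!is_null & calls == truth_all) / n_nonnull
    curve$fpr[r] <- sum(called_nonnull & is_null) / sum(is_null)
  }
  pts <- unique(rbind(data.frame(fpr = 0, tpr = 0),
                      curve[order(curve$fpr, curve$tpr), c("fpr", "tpr")],
                      data.frame(fpr = 1, tpr = 1)))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  ok <- curve$fpr <= fpr_target
  selected <- if (any(ok)) min(curve$width[ok]) else NA_real_
  structure(list(curve = curve, auc = auc, selected_width = selected,
                 fpr_target = fpr_target),
            class = "window_roc")
}

#' @export
print.window_roc <- function(x, ...) {
  cat(sprintf("Percentile-window ROC: AUC = %.3f; window [%g, %g] gives FPR <= %g\n",
              x$auc, 100 - x$selected_width, x$selected_width, x$fpr_target))
  invisible(x)
}

#' @export
plot.window_roc <- function(x, ...) {
  plot(x$curve$fpr, x$curve$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "False positive rate", ylab = "True positive rate", ...)
  abline(0, 1, lty = 3)
  invisible(x)
}
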