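test_that("polynomial interpolants reproduce polynomials and smooth curves", {
  tt <- seq(0, 10, length.out = 11)
  f_const <- poly_interpolant(tt, rep(3, 11))
  expect_equal(f_const(c(-5, 0, 2.5, 10, 20)), rep(3, 5), tolerance = 1e-9)

  f_sq <- poly_interpolant(tt, tt^2)
  expect_lt(max(abs(f_sq(tt) - tt^2)), 1e-10)  # degree <= order: exact

  f_exp <- poly_interpolant(tt, exp(-tt))
  dense <- seq(0, 10, length.out = 201)
  expect_lt(max(abs(f_exp(dense) - exp(-dense))), 0.025)

  # evaluation clamps outside the sampled range
  expect_equal(f_exp(-1), f_exp(0))
  expect_equal(f_exp(11), f_exp(10))

  expect_warning(f3 <- poly_interpolant(c(0, 1, 2), c(0, 1, 4), order = 5),
                 "order reduced")
  expect_equal(attr(f3, "order"), 2)
})

test_that("the objective is zero at the generating parameters and positive off them", {
  ds <- single_activator_dataset(p = 0)
  net <- single_activator_network()
  theta <- c(as.vector(net$F), net$S_ex)
  expect_lt(dlmra_objective(theta, ds), 1e-6)
  bump <- theta; bump[2] <- bump[2] + 1
  expect_gt(dlmra_objective(bump, ds), 1e-3)
})

test_that("the objective agrees with an independent re-implementation", {
  # nontrivial forcing: partial inhibition, random net, wrong candidate
  net <- random_stable_net(2, seed = 19)
  ds <- perturbation_design(net, p = 0.5)
  set.seed(4)
  for (k in 1:5) {
    theta <- c(runif(4, -2, 2), runif(2, 0, 2))
    a <- dlmra_objective(theta, ds)
    b <- oracle_phi(theta, ds)
    expect_equal(a, b, tolerance = 1e-6)  # 6 significant digits
  }
  # ffl variant too
  m <- ffl_model(5)
  dsf <- perturbation_design(m, p = 0.5)
  thetaf <- c(runif(9, -1, 1), 1)
  expect_equal(dlmra_objective(thetaf, dsf, variant = "ffl"),
               oracle_phi(thetaf, dsf, variant = "ffl"), tolerance = 1e-6)
})

test_that("wild candidates receive a finite penalty, not an exception", {
  ds <- single_activator_dataset(p = 0)
  wild <- c(10, 10, 10, 10, 10, 10)  # strongly unstable candidate
  v <- dlmra_objective(wild, ds)
  expect_true(is.finite(v))
  expect_gte(v, 1e10)
})

test_that("the objective responds to the perturbed node's sampled trace", {
  net <- random_stable_net(2, seed = 23)
  ds <- perturbation_design(net, p = 0.5)
  theta <- c(as.vector(net$F), net$S_ex)
  phi0 <- dlmra_objective(theta, ds)
  # the node-j trace under perturbation j carries no residuals, but it forces
  # the surrogate ODE: changing its sampled values must change Phi
  mod <- ds
  mod$perturbed[[1]][, 1] <- mod$perturbed[[1]][, 1] * 1.3
  expect_gt(abs(dlmra_objective(theta, mod) - phi0), 1e-6)
})

test_that("excluded residuals are exactly the perturbed node's own points", {
  ds <- single_activator_dataset(p = 0.5)
  fit <- dlmra(ds, n_starts = 2, seed = 1)
  pr <- predict(fit)
  excl <- pr[!pr$used, ]
  expect_true(all(grepl("^pert_", excl$condition)))
  expect_true(all(as.integer(sub("pert_", "", excl$condition)) == excl$node))
  expect_true(all(is.na(residuals(fit)[!pr$used])))
})

test_that("the single-activator network is recovered from clean data", {
  ds <- single_activator_dataset(p = 0)
  fit <- dlmra(ds, n_starts = 6, seed = 2)
  truth <- c(F11 = -1, F21 = 1.5, F12 = 0, F22 = -0.8,
             S1b = 0, S2b = 0, S1ex = 1, S2ex = 1)
  expect_lt(max(abs(coef(fit) - truth[names(coef(fit))])), 0.05)
  expect_equal(fit$sse, min(fit$starts$value, na.rm = TRUE))
})

test_that("10:1 noise still yields the correct sign pattern", {
  ds <- single_activator_dataset(p = 0, d = 0.1, seed = 14)
  fit <- dlmra(ds, n_starts = 10, seed = 3)
  truth_sign <- c(F11 = -1, F21 = 1, F12 = 0, F22 = -1,
                  S1b = 0, S2b = 0, S1ex = 1, S2ex = 1)
  est <- coef(fit)
  # signs of the six structurally nonzero parameters
  nz <- names(truth_sign)[truth_sign != 0]
  expect_equal(sign(est[nz]), truth_sign[nz])
})

test_that("random stable 2-node networks are recovered within 0.05", {
  worst <- 0
  for (k in 1:20) {
    net <- random_stable_net(2, seed = 1300 + k)
    ds <- perturbation_design(net, p = 0)
    fit <- dlmra(ds, n_starts = 6, seed = 1400 + k)
    truth <- c(as.vector(net$F), net$S_b, net$S_ex)
    worst <- max(worst, max(abs(coef(fit) - truth)))
  }
  expect_lt(worst, 0.05)
})

test_that("a clean 3-node network is recovered accurately", {
  net <- random_stable_net(3, seed = 77)
  ds <- perturbation_design(net, p = 0)
  fit <- dlmra(ds, n_starts = 8, seed = 9)
  truth <- c(as.vector(net$F), net$S_b, net$S_ex)
  expect_lt(max(abs(coef(fit) - truth)), 0.1)
})

test_that("more time points do not worsen recovery under a fixed noise scheme", {
  net <- random_stable_net(2, seed = 55)
  err <- function(np, rep) {
    ds <- add_noise(perturbation_design(net, times = seq(0, 10, length.out = np),
                                        p = 0), 0.2, seed = 5000 + rep)
    fit <- dlmra(ds, n_starts = 5, seed = 6000 + rep)
    truth <- c(as.vector(net$F), net$S_b, net$S_ex)
    median(abs(coef(fit) - truth))
  }
  e3 <- median(vapply(1:5, function(r) err(3, r), 0))
  e21 <- median(vapply(1:5, function(r) err(21, r), 0))
  expect_lte(e21, e3)
})

test_that("the cell-state variant recovers transition rates under its constraints", {
  set.seed(17)
  m <- random_markov_model(3)
  cs <- cellstate_design(m, times = seq(0, 5, length.out = 11))
  fit <- dlmra(cs, variant = "cellstate", n_starts = 6, seed = 4)
  truthF <- markov_to_continuous(m)$F
  off <- row(truthF) != col(truthF)
  expect_lt(max(abs(fit$F[off] - truthF[off])) / max(abs(truthF[off])), 0.05)
  expect_equal(colSums(fit$F), rep(0, 3), tolerance = 1e-12)  # by construction
  expect_true(all(fit$F[off] >= 0))
  expect_equal(fit$S_b, rep(0, 3))
  expect_equal(fit$S_ex, rep(0, 3))

  ident <- cellstate_design(markov_model(diag(3)))
  fit0 <- dlmra(ident, variant = "cellstate", n_starts = 3, seed = 5)
  expect_lt(max(abs(fit0$F)), 1e-3)
})

test_that("a non-mass-conserving dataset triggers the cell-state warning", {
  ds <- single_activator_dataset(p = 0)
  expect_warning(dlmra(ds, variant = "cellstate", n_starts = 1, seed = 1),
                 "mass-conserving")
})

test_that("the ffl variant honors its fixed-zero priors and basal elimination", {
  m4 <- ffl_model(4)  # repressor inputs to x3: nonzero pre-stimulus state
  ds <- perturbation_design(m4, p = 0.5)
  fit <- dlmra(ds, variant = "ffl", n_starts = 6, seed = 6)
  cf <- coef(fit)
  expect_equal(unname(cf[c("S1b", "S2ex", "S3ex")]), c(0, 0, 0))
  x0 <- ds$vehicle[1, ]
  expect_equal(unname(cf["S3b"]),
               -sum(fit$F[3, ] * x0), tolerance = 1e-10)
  # models 1-8 start at x1(0) = x2(0) = 0, so S3b reduces to -F33 x3(0)
  expect_equal(unname(cf["S3b"]), -fit$F[3, 3] * x0[3], tolerance = 1e-10)
})

test_that("complete inhibition hides F31 of FFL model 1 from the estimator", {
  m1 <- ffl_model(1)
  fit0 <- dlmra(perturbation_design(m1, p = 0), variant = "ffl",
                n_starts = 6, seed = 7)
  calls0 <- classify_signs(coef(fit0)[ffl_reported_params()])
  expect_equal(unname(calls0["F31"]), "null")
  # the other existing edges and the stimulus are still found
  expect_equal(unname(calls0[c("F11", "F21", "F22", "F33", "S1ex")]),
               c("negative", "positive", "negative", "negative", "positive"))
  # partial inhibition restores identifiability of F31
  fit5 <- dlmra(perturbation_design(m1, p = 0.5), variant = "ffl",
                n_starts = 6, seed = 8)
  expect_equal(unname(classify_signs(coef(fit5)[ffl_reported_params()])["F31"]),
               "positive")
})

test_that("the zero-basal variant matches the standard fit when S_b is truly zero", {
  ds <- single_activator_dataset(p = 0)
  fit <- dlmra(ds, variant = "zero_basal", n_starts = 6, seed = 10)
  truth <- c(F11 = -1, F21 = 1.5, F12 = 0, F22 = -0.8,
             S1b = 0, S2b = 0, S1ex = 1, S2ex = 1)
  expect_lt(max(abs(coef(fit) - truth[names(coef(fit))])), 0.05)
  expect_equal(fit$S_b, c(0, 0))
})

test_that("zero-basal fits flag structurally absent cascade edges as negligible", {
  # x1 -> x2 -> x3 cascade resting at zero: F13 = F31 = 0 in truth
  F <- matrix(c(-1, 1.2, 0,  0, -1, 0.9,  0, 0, -0.8), 3, 3)
  net <- linear_network(F, S_b = 0, S_ex = c(1, 0, 0))
  ds <- perturbation_design(net, p = 0)
  fit <- dlmra(ds, variant = "zero_basal", n_starts = 8, seed = 11)
  calls <- classify_signs(coef(fit))
  expect_equal(unname(calls[c("F13", "F31")]), c("null", "null"))
  expect_equal(unname(calls[c("F21", "F32")]), c("positive", "positive"))
})

test_that("multistart bookkeeping: best start wins, CV is computed over good starts", {
  ds <- single_activator_dataset(p = 0)
  fit <- dlmra(ds, n_starts = 6, seed = 12)
  expect_equal(fit$sse, min(fit$starts$value, na.rm = TRUE))
  cv <- multistart_cv(fit)
  expect_true(length(cv) > 0)
  expect_lt(median(cv), 0.05)  # converged starts agree tightly

  # hand-crafted start table: CV of (1.0, 1.1) with sample sd
  fake <- fit
  par <- attr(fit$starts, "par")[1:2, , drop = FALSE]
  par[, 1] <- c(1.0, 1.1)
  attr(fake$starts, "par") <- par
  fake$starts <- fake$starts[1:2, ]
  attr(fake$starts, "par") <- par
  fake$starts$value <- c(1e-9, 1.5e-9)
  cv2 <- multistart_cv(fake, mode = "twice_min")
  expect_equal(unname(cv2[1]), sd(c(1, 1.1)) / mean(c(1, 1.1)),
               tolerance = 1e-10)

  # fewer than two qualifying starts -> flagged empty result
  fake$starts$value <- c(1e-9, 10)
  expect_equal(length(multistart_cv(fake)), 0)
  expect_equal(attr(multistart_cv(fake), "reason"), "insufficient_starts")
})

test_that("a fit serializes to JSON with full provenance", {
  fit <- dlmra(single_activator_dataset(p = 0), n_starts = 3, seed = 31)
  path <- tempfile(fileext = ".json")
  fit_to_json(fit, path)
  doc <- jsonlite::fromJSON(path)
  expect_equal(doc$variant, "standard")
  expect_equal(doc$sse, fit$sse)
  expect_equal(unlist(doc$coefficients), coef(fit))
  expect_length(doc$starts$value, 3)
  expect_equal(doc$options$seed, 31)
})

test_that("fits are reproducible given a seed and expose standard methods", {
  ds <- single_activator_dataset(p = 0)
  f1 <- dlmra(ds, n_starts = 3, seed = 21)
  f2 <- dlmra(ds, n_starts = 3, seed = 21)
  expect_identical(coef(f1), coef(f2))
  expect_s3_class(f1, "dlmra")
  expect_output(print(f1), "DL-MRA fit")
  expect_output(print(summary(f1)), "stable")
  pr <- predict(f1)
  expect_true(all(c("condition", "time", "node", "observed", "fitted",
                    "residual", "used") %in% names(pr)))
  expect_lt(max(abs(pr$residual[pr$used])), 0.05)
  sims <- simulate(f1, nsim = 2, seed = 1, d = 0.1)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "perturbation_dataset")
})
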