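test_that("point classification applies the 1/100 negligibility rule", {
  vals <- c(a = 1.5, b = -0.8, c = 0.001)
  expect_equal(unname(classify_signs(vals)),
               c("positive", "negative", "null"))
  expect_equal(unname(classify_signs(rep(0, 4))), rep("null", 4))
  # explicit scale: max |param| = 2 flags |v| < 0.02
  got <- classify_signs(c(0.019, 0.021, -2), scale = 2)
  expect_equal(unname(got), c("null", "positive", "negative"))
})

test_that("ground-truth classes follow the generating model", {
  net <- linear_network(matrix(c(-1, 0, 2, -3), 2), S_b = c(0, 1),
                        S_ex = c(1, 0))
  tr <- sign_truth(net)
  expect_equal(unname(tr[c("F11", "F21", "F12", "F22")]),
               c("negative", "null", "positive", "negative"))
  expect_equal(unname(tr[c("S1b", "S2b", "S1ex", "S2ex")]),
               c("null", "positive", "positive", "null"))

  # FFL: repressed node 2 rests high -> positive basal production truth
  tr9 <- sign_truth(ffl_model(9))
  expect_equal(unname(tr9[c("F21", "F31", "F32")]),
               c("negative", "positive", "positive"))
  expect_equal(unname(tr9[c("F12", "F13", "F23")]), rep("null", 3))
  expect_equal(unname(tr9["S2b"]), "positive")
  expect_equal(unname(tr9["S3b"]), "null")   # AND gate with x1 absent
  tr1 <- sign_truth(ffl_model(1))
  expect_equal(unname(tr1[c("S2b", "S3b")]), c("null", "null"))
  tr16 <- sign_truth(ffl_model(16))
  expect_equal(unname(tr16[c("S2b", "S3b")]), c("positive", "positive"))
})

test_that("window classification reads the percentile interval", {
  ones <- matrix(1, 20, 1)
  for (w in c(50, 75, 100))
    expect_equal(unname(classify_window(ones, w)), "positive")
  sym <- matrix(c(seq(-1, -0.1, length.out = 10),
                  seq(0.1, 1, length.out = 10)), ncol = 1)
  expect_equal(unname(classify_window(sym, 90)), "null")
  neg <- matrix(rnorm(30, -5, 0.1), ncol = 1)
  expect_equal(unname(classify_window(neg, 95)), "negative")
  expect_error(classify_window(ones, 45), "50, 100")
})

test_that("the median-only window never calls a nonzero median null", {
  set.seed(2)
  for (k in 1:50) {
    v <- rnorm(11, mean = runif(1, -1, 1))
    call <- classify_window(matrix(v, ncol = 1), 50)
    m <- median(v)
    expect_equal(unname(call),
                 if (m > 0) "positive" else if (m < 0) "negative" else "null")
  }
})

test_that("widening the window only grows the null set (FPR monotone)", {
  set.seed(3)
  est <- matrix(rnorm(50 * 12, mean = rep(runif(12, -0.5, 0.5), each = 50),
                      sd = 0.4), 50, 12)
  prev_null <- rep(FALSE, 12)
  for (w in seq(50, 100, by = 2.5)) {
    is_null <- classify_window(est, w) == "null"
    expect_true(all(is_null | !prev_null))  # nulls never un-null
    prev_null <- is_null
  }
})

test_that("accuracy is the exact-match fraction", {
  expect_equal(classification_accuracy(c("positive", "null"),
                                       c("positive", "null")), 1)
  pred <- rep("positive", 12); truth <- pred; truth[5] <- "null"
  expect_equal(classification_accuracy(pred, truth), 11 / 12,
               tolerance = 1e-10)
  expect_error(classification_accuracy(character(), character()), "empty")
  expect_error(classification_accuracy("null", c("null", "null")), "mismatch")
})

test_that("random guessing on balanced 3-class truth sits near 1/3", {
  set.seed(8)
  classes <- c("positive", "negative", "null")
  truth <- rep(classes, each = 400)
  guess <- sample(classes, 1200, replace = TRUE)
  expect_equal(classification_accuracy(guess, truth), 1 / 3, tolerance = 0.05)
})

test_that("ROC endpoints and AUC behave on constructed ensembles", {
  # perfectly separated: non-null ensembles far from zero, null ensembles
  # straddling zero symmetrically
  set.seed(5)
  mk <- function(mu, sd) matrix(rnorm(40 * 3, rep(mu, each = 40), sd), 40, 3)
  ens <- list(mk(c(5, -5, 0), c(0.2, 0.2, 1)))
  truths <- list(c(a = "positive", b = "negative", c = "null"))
  colnames(ens[[1]]) <- names(truths[[1]])
  roc <- window_roc(ens, truths)
  expect_equal(roc$auc, 1, tolerance = 1e-6)
  expect_false(is.na(roc$selected_width))

  # w = 100 with both signs present in every column -> everything null
  both <- matrix(c(rnorm(20, 2), rnorm(20, -2)), 40, 3)
  colnames(both) <- c("a", "b", "c")
  roc2 <- window_roc(list(both), truths)
  last <- roc2$curve[roc2$curve$width == 100, ]
  expect_equal(last$tpr, 0)
  expect_equal(last$fpr, 0)
  # FPR is non-increasing in the width
  expect_true(all(diff(roc2$curve$fpr) <= 1e-12))

  expect_error(window_roc(list(both), list(c(a = "positive", b = "negative",
                                             c = "negative"))), "no null")
})

test_that("bootstrap ensembles are reproducible and correctly shaped", {
  ds <- single_activator_dataset(p = 0)
  e1 <- bootstrap_ensemble(ds, d = 0.2, B = 4, n_starts = 2, seed = 9)
  e2 <- bootstrap_ensemble(ds, d = 0.2, B = 4, n_starts = 2, seed = 9)
  expect_identical(e1$estimates, e2$estimates)
  expect_equal(dim(e1$estimates), c(4, 8))
  expect_named(as.data.frame(e1$estimates),
               c("F11", "F21", "F12", "F22", "S1b", "S2b", "S1ex", "S2ex"))
  # clean replicates at d -> 0 concentrate on the true parameters
  e0 <- bootstrap_ensemble(ds, d = 1e-6, B = 3, n_starts = 2, seed = 10)
  expect_lt(max(abs(sweep(e0$estimates, 2,
                          c(-1, 1.5, 0, -0.8, 0, 0, 1, 1)))), 0.05)
})
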