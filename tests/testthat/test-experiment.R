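test_that("the design holds n+1 conditions and n^2 residual equations", {
  for (n in 2:3) {
    net <- random_stable_net(n, seed = 600 + n)
    ds <- perturbation_design(net, p = 0)
    expect_equal(ds$n, n)
    expect_length(ds$perturbed, n)           # + vehicle = n + 1 conditions
    expect_equal(n_residual_equations(ds), n^2)
  }
  unstable <- linear_network(diag(c(1, -1)), S_b = c(1, 1))
  expect_error(perturbation_design(unstable), "unstable")
})

test_that("perturbed traces are scaled copies of the vehicle before noise", {
  net <- random_stable_net(3, seed = 33)
  for (p in c(0, 0.5, 1)) {
    ds <- perturbation_design(net, p = p)
    for (j in 1:3)
      expect_equal(ds$perturbed[[j]][, j], p * ds$vehicle[, j],
                   tolerance = 1e-9)
  }
  # p = 1 leaves every condition identical to vehicle
  ds1 <- perturbation_design(net, p = 1)
  for (j in 1:3)
    expect_equal(ds1$perturbed[[j]], ds1$vehicle, tolerance = 1e-7)
  # p = 0 zeroes the perturbed node exactly
  ds0 <- perturbation_design(single_activator_network(), p = 0)
  expect_true(all(ds0$perturbed[[1]][, 1] == 0))
})

test_that("vehicle starts from the pre-stimulus basal steady state", {
  net <- random_stable_net(2, seed = 64)
  ds <- perturbation_design(net, p = 0)
  expect_equal(ds$vehicle[1, ], basal_steady_state(net)$x_ss, tolerance = 1e-9)
})

test_that("complete inhibition hides the direct x1->x3 edge in FFL model 1", {
  m1 <- ffl_model(1)
  d0 <- perturbation_design(m1, p = 0)
  # node 3 never leaves zero under either upstream perturbation (AND gate)
  expect_equal(max(abs(d0$perturbed[[1]][, 3])), 0, tolerance = 1e-9)
  expect_equal(max(abs(d0$perturbed[[2]][, 3])), 0, tolerance = 1e-9)
  expect_equal(d0$vehicle[1, 3], 0, tolerance = 1e-9)
  # 50% inhibition separates the three node-3 responses
  d5 <- perturbation_design(m1, p = 0.5)
  spread <- max(abs(d5$perturbed[[1]][, 3] - d5$perturbed[[2]][, 3]))
  expect_gt(spread, 0.01)
})

test_that("proportional noise has the stated scale, zeros stay zero, d=0 is identity", {
  ds <- single_activator_dataset(p = 0)
  expect_identical(add_noise(ds, 0), ds)
  expect_error(add_noise(ds, -0.1), "non-negative")

  noisy <- add_noise(ds, 0.5, seed = 1)
  expect_true(all(noisy$perturbed[[1]][, 1] == 0))  # sd = d * 0
  expect_identical(ds$noise_d, 0)                   # input unmodified

  # Monte-Carlo check of the scale: x = 2, d = 0.5 -> sd = 1
  tiny <- perturbation_dataset(c(0, 1), matrix(2, 2, 1),
                               list(matrix(2, 2, 1)), p = 1)
  set.seed(8)
  draws <- replicate(2e4, add_noise(tiny, 0.5)$vehicle[1, 1])
  expect_equal(sd(draws - 2), 1, tolerance = 0.02)
  expect_equal(mean(draws), 2, tolerance = 3 * 1 / sqrt(2e4))  # unbiased, 3 sigma
})

test_that("noise draws are seed-reproducible", {
  ds <- single_activator_dataset(p = 0)
  a <- add_noise(ds, 0.2, seed = 42)
  b <- add_noise(ds, 0.2, seed = 42)
  expect_identical(a$vehicle, b$vehicle)
  expect_identical(a$perturbed, b$perturbed)
})

test_that("dropping a node removes its traces and its condition", {
  net <- random_stable_net(3, seed = 71)
  ds <- perturbation_design(net, p = 0)
  rd <- drop_node(ds, 3)
  expect_equal(rd$n, 2)
  expect_length(rd$perturbed, 2)          # vehicle + 2 perturbations
  expect_equal(rd$vehicle, ds$vehicle[, 1:2])
  expect_equal(rd$perturbed[[1]], ds$perturbed[[1]][, 1:2])
  expect_error(drop_node(rd, 3), "invalid")
  expect_error(drop_node(drop_node(rd, 2), 1), "1-node")
})

test_that("cell-state designs conserve mass and forget their initial condition", {
  ident <- markov_model(diag(3))
  cs <- cellstate_design(ident)
  for (m in c(list(cs$vehicle), cs$perturbed))
    expect_equal(m, matrix(rep(m[1, ], each = nrow(m)), nrow(m)))  # constant

  set.seed(13)
  m <- random_markov_model(3)
  cs <- cellstate_design(m, times = seq(0, 5, length.out = 11))
  expect_equal(cs$kind, "proportion")
  for (mat in c(list(cs$vehicle), cs$perturbed)) {
    expect_lt(max(abs(rowSums(mat) - 1)), 1e-8)
    expect_true(all(abs(mat[1, ]) < 1e-12 | mat[1, ] > 0))
  }
  # perturbation j zeroes state j at t = 0 and renormalizes the rest
  expect_equal(cs$perturbed[[2]][1, ], c(0.5, 0, 0.5))

  # all conditions converge to the stationary distribution of M
  ev <- eigen(m$M)
  pi_vec <- Re(ev$vectors[, which.max(Re(ev$values))])
  pi_vec <- pi_vec / sum(pi_vec)
  far <- seq(0, 50 * m$step, length.out = 3)
  ends <- vapply(c(list(rep(1/3, 3)), lapply(1:3, function(j) {
    x <- rep(1/3, 3); x[j] <- 0; x / sum(x)
  })), function(x0)
    simulate_network(markov_to_continuous(m), x0, far)$values[3, ],
    numeric(3))
  expect_lt(max(abs(ends - pi_vec)), 1e-3)
})

test_that("datasets survive the CSV + metadata round trip and validate cleanly", {
  ds <- add_noise(perturbation_design(random_stable_net(2, seed = 88),
                                      times = seq(0, 10, length.out = 5), p = 0.5),
                  0.1, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_dataset(ds, path)
  expect_equal(nrow(validate_dataset(path)), 0)
  back <- read_dataset(path)
  expect_equal(back$vehicle, ds$vehicle, tolerance = 1e-12)
  expect_equal(back$perturbed, ds$perturbed, tolerance = 1e-12)
  expect_equal(back$p, 0.5)
  expect_equal(back$noise_d, 0.1)

  # corrupt: remove one condition
  df <- read.csv(path)
  write.csv(df[df$condition != "pert_2", ], path, row.names = FALSE)
  expect_true("missing_condition" %in% validate_dataset(path)$code)

  # corrupt: shuffle times within one trace
  df$time[df$condition == "vehicle" & df$node == 1] <-
    rev(df$time[df$condition == "vehicle" & df$node == 1])
  write.csv(df, path, row.names = FALSE)
  expect_true("time_ordering" %in% validate_dataset(path)$code)
})
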