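# quotient matrices, DDE integration, lifting

test_that("singleton partition gives the identity quotient", {
  net <- random_quantized_network(5, L = 2, seed = 2)
  p <- as_partition(1:5)
  qnet <- quotient_network(net, p)
  for (k in 1:2) expect_equal(qnet$layers[[k]]$A, net$layers[[k]]$A)
})

test_that("quotient of a planted lift recovers the planted quotient", {
  R1 <- matrix(c(0, 2, 1, 1), 2, 2)
  R2 <- matrix(c(1, 0, 2, 0), 2, 2)
  pl <- plant_partition(list(R1, R2), sizes = c(3, 2), seed = 9)
  qnet <- quotient_network(pl$net, pl$partition)
  expect_equal(qnet$layers[[1]]$A, R1)
  expect_equal(qnet$layers[[2]]$A, R2)
  expect_equal(qnet$sizes, c(3, 2))
  # a non-equitable partition is rejected
  bad <- as_partition(c(1, 1, 2, 2, 2))
  if (!is_equitable(pl$net, bad)$equitable)
    expect_error(quotient_network(pl$net, bad), "not equitable")
})

test_that("undelayed linear DDE reproduces the exponential", {
  tr <- integrate_dde(function(t, y, yd) -yd[[1]], 1, c(0, 1), 1e-3,
                      delays = 0)
  expect_equal(tr$Y[nrow(tr$Y), 1], exp(-1), tolerance = 1e-6)
})

test_that("delayed linear DDE matches the method-of-steps closed form", {
  delta <- 0.5
  tr <- integrate_dde(function(t, y, yd) -yd[[1]], 1, c(0, 2 * delta), 1e-3,
                      delays = delta)
  expect_equal(tr$Y[, 1], dde_steps_solution(tr$times, delta),
               tolerance = 1e-8)
})

test_that("integrator converges at fourth order on the smooth test", {
  err <- vapply(c(2e-2, 1e-2), function(h) {
    tr <- integrate_dde(function(t, y, yd) -y, 1, c(0, 1), h)
    abs(tr$Y[nrow(tr$Y), 1] - exp(-1))
  }, numeric(1))
  expect_gt(err[1] / err[2], 2^4 * 0.7)       # halving the step: ~2^4
})

test_that("integrator agrees with an independent DDE solver", {
  skip_if_not_installed("deSolve")
  # scalar delayed logistic-type test problem
  f <- function(t, y, yd) 0.8 * yd[[1]] * (1 - y)
  tr <- integrate_dde(f, 0.5, c(0, 10), 0.01, delays = 1)
  sol <- deSolve::dede(
    y = 0.5, times = seq(0, 10, 0.1),
    func = function(t, y, parms) {
      ylag <- if (t <= 1) 0.5 else deSolve::lagvalue(t - 1)
      list(0.8 * ylag * (1 - y))
    }, parms = NULL)
  ours <- interp_trajectory(tr, sol[, 1])[, 1]
  expect_equal(ours, unname(sol[, 2]), tolerance = 1e-5)
})

test_that("blow-up is reported with the time of failure", {
  expect_error(integrate_dde(function(t, y, yd) y^2, 2, c(0, 5), 1e-3),
               "blew up at t")
})

test_that("compiled network integrator agrees with the R reference rhs path", {
  pl <- plant_partition(list(matrix(c(0, 1, 1, 0), 2, 2)), sizes = c(2, 2),
                        seed = 4, kind = "electrical", sigma = 0.3,
                        models = "hr")
  net <- pl$net
  n <- 3
  x0 <- initial_state(net, jitter = 0.1, seed = 2)
  # R route: generic rhs through integrate_dde
  rhs <- assemble_quotient_rhs(net)
  trR <- integrate_dde(function(t, y, yd) rhs(t, y, yd),
                       as.vector(t(x0)), c(0, 50), 0.01, delays = 0)
  # compiled route
  trC <- integrate_network(net, x0, c(0, 50), 0.01)
  expect_equal(trC$Y[nrow(trC$Y), ], trR$Y[nrow(trR$Y), ], tolerance = 1e-9)
})

test_that("compiled network integrator handles delays like the R route", {
  net <- linear_pair(a = 0.1, sigma = 0.4, delta = 0.5, kind = "direct")
  x0 <- matrix(c(1, 0.3), 2, 1)
  rhs <- assemble_quotient_rhs(net)
  trR <- integrate_dde(function(t, y, yd) rhs(t, y, yd),
                       c(1, 0.3), c(0, 10), 0.01, delays = c(0.5))
  trC <- integrate_network(net, x0, c(0, 10), 0.01)
  expect_equal(trC$Y[nrow(trC$Y), ], trR$Y[nrow(trR$Y), ], tolerance = 1e-8)
})

test_that("diffusive coupling vanishes on the synchronous state", {
  net <- linear_pair(a = -0.3, sigma = 2)
  rhs <- assemble_quotient_rhs(net)
  y <- c(0.7, 0.7)
  expect_equal(rhs(0, y, list(y)), -0.3 * y)   # reduces to isolated field
})

test_that("lifting copies cluster states to all members", {
  pl <- plant_partition(list(matrix(c(0, 1, 2, 0), 2, 2)), sizes = c(2, 3),
                        seed = 5, models = "hr", sigma = 0.1)
  p <- pl$partition
  qnet <- quotient_network(pl$net, p)
  trq <- integrate_network(qnet, initial_state(qnet, jitter = 0.2, seed = 3),
                           c(0, 20), 0.05)
  full <- lift_trajectory(trq, p)
  expect_equal(ncol(full$Y), 5 * 3)
  for (i in 1:5) {
    q <- p$color[i]
    expect_equal(node_states(full, i), node_states(trq, q))
  }
  # identity on the singleton partition
  ps <- as_partition(seq_len(qnet$N))
  expect_equal(lift_trajectory(trq, ps)$Y, trq$Y)
})

test_that("synchronous manifold is flow invariant (quotient/lift consistency)", {
  set.seed(8)
  for (seed in c(1, 2, 3)) {
    pl <- random_planted_network(N = 6, L = 2, seed = seed)
    net <- pl$net
    net$models <- "hr"
    for (k in seq_along(net$layers)) {
      net$layers[[k]]$sigma <- 0.2
      net$layers[[k]]$kind <- c("electrical", "ftm")[k]
      net$layers[[k]]$kparams <- synapse_kinds()[[net$layers[[k]]$kind]]$kparams
    }
    p <- refine_equitable(net)
    qnet <- quotient_network(net, p)
    x0q <- initial_state(qnet, jitter = 0.3, seed = seed)
    trq <- integrate_network(qnet, x0q, c(0, 100), 0.02)
    trf <- integrate_network(net, lift_state(p, x0q), c(0, 100), 0.02)
    lifted <- lift_trajectory(trq, p)
    expect_lt(max(abs(trf$Y - lifted$Y)), 1e-7)
  }
})

test_that("trajectory interpolation is consistent with stored samples", {
  net1 <- mlnetwork(list(), N = 1, models = "hr")
  tr <- integrate_network(net1, initial_state(net1), c(0, 100), 0.05,
                          save_every = 4)
  # interpolation at stored times returns stored values
  expect_equal(interp_trajectory(tr, tr$times[10]), tr$Y[10, , drop = FALSE])
  # interpolation between samples close to a finer reference
  tr2 <- integrate_network(net1, initial_state(net1), c(0, 100), 0.05,
                           save_every = 1)
  tq <- tr$times[5] + tr$dt * 0.37
  ref <- interp_trajectory(tr2, tq)
  expect_equal(interp_trajectory(tr, tq), ref, tolerance = 1e-5)
})
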