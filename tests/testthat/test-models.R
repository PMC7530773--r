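# neuron and synapse model library

test_that("swim gating functions evaluate to their hand-computed values", {
  g <- clustersync:::.swim_gating(0)
  # m_inf at V = 0 mV (Vs = 8265/105): direct evaluation of alpha_m/beta_m
  expect_equal(g$m_inf, 0.9377, tolerance = 1e-4)
  # chi time constant is state independent
  p <- swim_params()
  expect_equal(p$tau_chi, 9400)
  # synaptic gate: zero at and below threshold
  expect_equal(clustersync:::.swim_sinf(-30, p), 0)
  expect_equal(clustersync:::.swim_sinf(-55, p), 0)
  expect_gt(clustersync:::.swim_sinf(-20, p), 0)
})

test_that("swim synapse activations follow the three kinds", {
  xj <- c(-40, 0, 0, 0, 0, 0.3, 0.5)
  expect_equal(swim_synapse_activation(3, -50, xj), 10)   # V_j - V_i
  expect_equal(swim_synapse_activation(3, -40, xj), 0)    # equal potentials
  expect_equal(swim_synapse_activation(1, -80, xj), 0)    # at reversal
  expect_equal(swim_synapse_activation(1, -40, xj), (-80 + 40) * 0.3)
  expect_equal(swim_synapse_activation(2, -40, xj), 40 * 0.5)
  expect_error(swim_synapse_activation(9, 0, xj), "unknown")
})

test_that("hindmarsh-rose vector field and equilibria", {
  p <- hr_params(I = 0)
  d <- hr_rhs(c(0, 1, 0), p)
  expect_equal(d, c(1, 0, p$mu * p$s * 1.6))
  expect_equal(hr_params(3)$I - hr_params(2)$I, 1)
  # an equilibrium found numerically has a tiny residual
  p2 <- hr_params(I = 2)
  eq <- function(V) {
    y <- 1 - 5 * V^2
    z <- p2$s * (V - p2$x_rest)
    y - V^3 + p2$b * V^2 - z + p2$I
  }
  Vstar <- uniroot(eq, c(-3, 0), tol = 1e-14)$root
  x <- c(Vstar, 1 - 5 * Vstar^2, p2$s * (Vstar - p2$x_rest))
  expect_lt(max(abs(hr_rhs(x, p2))), 1e-10)
})

test_that("ftm activation saturates and vanishes at reversal", {
  expect_equal(ftm_activation(-1, -0.6), (2 - (-1)) / 2)   # logistic midpoint
  expect_equal(ftm_activation(-1, 1e3), 0)
  expect_equal(ftm_activation(-1, -1e3), 3)
  expect_equal(ftm_activation(2, 0.5), 0)                  # V_i at E
})

test_that("numeric jacobian is exact on linear maps", {
  A <- matrix(c(2, -1, 0.5, 3), 2, 2)
  J <- numeric_jacobian(function(x) A %*% x, c(1, -2))
  expect_equal(J, A, tolerance = 1e-8)
})

test_that("compiled model RHS agree with the R reference implementations", {
  models <- neuron_models()
  set.seed(5)
  for (i in 1:20) {
    xs <- c(runif(1, -70, 20), runif(4, 0, 1), runif(2, 0, 0.9))
    ps <- swim_params()
    expect_equal(model_rhs_cpp(1L, xs, clustersync:::.swim_param_vec(ps)),
                 swim_rhs(xs, ps), tolerance = 1e-12)
    xh <- runif(3, -2, 2)
    ph <- hr_params(I = sample(2:3, 1))
    expect_equal(model_rhs_cpp(2L, xh, clustersync:::.hr_param_vec(ph)),
                 hr_rhs(xh, ph), tolerance = 1e-12)
  }
})

test_that("analytic jacobians match central differences on random states", {
  models <- neuron_models()
  set.seed(11)
  ps <- swim_params(); pv <- clustersync:::.swim_param_vec(ps)
  for (i in 1:25) {
    x <- c(runif(1, -70, 20), runif(4, 0.05, 0.9), runif(2, 0, 0.9))
    Ja <- model_jac_cpp(1L, x, pv)
    Jn <- numeric_jacobian(function(y) swim_rhs(y, ps), x, rel_step = 1e-6)
    expect_lt(max(abs(Ja - Jn)) / max(1, max(abs(Jn))), 1e-4)
  }
  ph <- hr_params(); pvh <- clustersync:::.hr_param_vec(ph)
  for (i in 1:10) {
    x <- runif(3, -2, 2)
    Ja <- model_jac_cpp(2L, x, pvh)
    Jn <- numeric_jacobian(function(y) hr_rhs(y, ph), x)
    expect_lt(max(abs(Ja - Jn)), 1e-5)
    expect_equal(models$hr$Df(x, ph), Ja, tolerance = 1e-12)
  }
})

test_that("compiled coupling derivatives match the R registry", {
  kinds <- synapse_kinds()
  set.seed(3)
  for (nm in names(kinds)) {
    kd <- kinds[[nm]]
    for (i in 1:10) {
      xi <- c(runif(1, -70, 30), runif(6, 0, 1))
      xj <- c(runif(1, -70, 30), runif(6, 0, 1))
      out <- coupling_eval_cpp(kd$cpp_id, as.numeric(kd$kparams), xi, xj)
      expect_equal(out[1], kd$a(xi, xj, kd$kparams), tolerance = 1e-12)
      expect_equal(out[2], kd$D1a(xi, xj, kd$kparams), tolerance = 1e-12)
      d2 <- kd$D2a(xi, xj, kd$kparams)
      expect_equal(out[3], d2$value, tolerance = 1e-12)
      expect_equal(out[4], as.numeric(d2$index))
      # cross-check D1/D2 against numeric differentiation of the activation
      d1n <- numeric_jacobian(function(v) kd$a(c(v, xi[-1]), xj, kd$kparams),
                              xi[1])[1, 1]
      expect_equal(out[2], d1n, tolerance = 1e-6)
      d2n <- numeric_jacobian(function(v) {
        y <- xj; y[d2$index] <- v
        kd$a(xi, y, kd$kparams)
      }, xj[d2$index])[1, 1]
      expect_equal(out[3], d2n, tolerance = 1e-6)
    }
  }
})

test_that("isolated swim neuron stays bounded and oscillates", {
  net1 <- mlnetwork(list(), N = 1, models = "swim", node_type = 1L)
  tr <- integrate_network(net1, initial_state(net1), c(0, 20000), 0.02,
                          save_every = 50)
  V <- tr$Y[, 1]
  expect_true(all(is.finite(tr$Y)))
  expect_gt(max(V), -30)                       # reaches spike heights
  expect_lt(min(V), -50)                       # and repolarizes
  expect_gt(sum(V[-length(V)] < -20 & V[-1] >= -20), 3)  # several spikes
})

test_that("isolated hindmarsh-rose neuron has a bounded attractor", {
  net1 <- mlnetwork(list(), N = 1, models = "hr", node_type = 1L)
  tr <- integrate_network(net1, initial_state(net1), c(0, 2000), 0.05,
                          save_every = 10)
  expect_true(all(is.finite(tr$Y)))
  expect_true(all(abs(tr$Y[, 1]) < 5))
  expect_gt(diff(range(tr$Y[, 1])), 1)        # genuinely oscillating
})
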