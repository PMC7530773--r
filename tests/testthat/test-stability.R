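# variational assembly, Lyapunov estimation, verdicts, direct checks

# vsys for the two-linear-node diffusive toy: transverse eq eta' = (a-2s)eta
toy_vsys <- function(a, sigma, t_end = 60, kind = "electrical", delta = 0) {
  net <- linear_pair(a = a, sigma = sigma, delta = delta, kind = kind)
  p <- refine_equitable(net)
  qnet <- quotient_network(net, p)
  traj <- integrate_network(qnet, matrix(0, 1, 1), c(0, t_end), 0.01)
  tr <- build_transform(net, p)
  assemble_variational(net, p, tr, traj)
}

test_that("uncoupled pair reduces to the isolated jacobian equation", {
  # one 2-cluster, a coupling layer with zero weights: eta' = Df(s) eta
  A0 <- matrix(0, 2, 2)
  net <- mlnetwork(list(sync_layer(A0, sigma = 1)), models = "linear",
                   model_params = list(list(a = -0.7)))
  p <- as_partition(c(1, 1))
  qnet <- quotient_network(net, p)
  traj <- integrate_network(qnet, matrix(1, 1, 1), c(0, 40), 0.01)
  tr <- build_transform(net, p)
  vs <- assemble_variational(net, p, tr, traj)
  r <- block_mle(vs, 1, t_max = 30, seed = 1, repeats = 1)
  expect_equal(r$Lambda, -0.7, tolerance = 0.01)
  expect_equal(r$method, "threshold")          # hits the lower threshold
  expect_true(r$stable)
})

test_that("linear diffusive toy matches the closed-form exponent", {
  for (cfg in list(c(-1, 0.5), c(0.5, 0.1), c(0.5, 0.35))) {
    a <- cfg[1]; sigma <- cfg[2]
    vs <- toy_vsys(a, sigma)
    r <- block_mle(vs, 1, t_max = 50, seed = 2, repeats = 1)
    expect_equal(r$Lambda, a - 2 * sigma, tolerance = 0.01,
                 info = sprintf("a=%g sigma=%g", a, sigma))
    expect_equal(r$stable, a - 2 * sigma < 0)
  }
})

test_that("scalar decay hits the lower threshold with the right exponent", {
  vs <- toy_vsys(-1, 0)                        # eta' = -eta
  r <- block_mle(vs, 1, t_max = 50, seed = 1, repeats = 2)
  expect_equal(r$Lambda, -1, tolerance = 0.01)
  expect_equal(r$method, "threshold")
})

test_that("delayed scalar feedback changes stability at the known boundary", {
  # through the 'direct' coupling kind the transverse equation is the pure
  # delayed feedback eta'(t) = -a eta(t - 1)
  lam <- function(a) {
    vs <- toy_vsys(0, a, t_end = 320, kind = "direct", delta = 1)
    block_mle(vs, 1, t_max = 300, seed = 3, repeats = 1)$Lambda
  }
  expect_lt(lam(pi / 2 - 0.3), 0)
  expect_gt(lam(pi / 2 + 0.3), 0)
})

test_that("verdicts take the maximum over touching blocks", {
  mk <- function(L, marginal = FALSE)
    list(Lambda = L, stable = L < 0, marginal = marginal, method = "slope")
  rep1 <- cluster_stability(list(mk(-0.2), mk(0.1)),
                            list(c(1, 2), c(1)))
  expect_equal(unname(rep1$Lambda_cluster), c(0.1, -0.2))
  expect_equal(unname(rep1$stable), c(FALSE, TRUE))
  rep2 <- cluster_stability(list(mk(-0.2), mk(-0.05)), list(1, 2))
  expect_true(all(rep2$stable))
  # isolated desynchronization pattern: a cluster with its own positive
  # block breaks alone when the shared block stays negative
  rep3 <- cluster_stability(list(mk(0.3), mk(-0.1)),
                            list(3, c(1, 2, 3)))
  expect_equal(unname(rep3$stable), c(TRUE, TRUE, FALSE))
  expect_equal(rep3$intertwined, list(1:3))
})

test_that("block exponents are independent of evaluation order", {
  b <- build_swim_cpg(sigma1 = 0, sigma2 = 0)
  p <- refine_equitable(b$net)
  qnet <- quotient_network(b$net, p)
  traj <- integrate_network(qnet, initial_state(qnet), c(0, 3000), 0.02,
                            save_every = 5)
  tr <- build_transform(b$net, p)
  # per-layer transforms give three separable sub-problems for layer 1 only
  net1 <- mlnetwork(b$net$layers[1], node_type = b$net$node_type,
                    models = "swim")
  t1 <- build_transform(net1, p, dclass = "classA")
  vs <- assemble_variational(net1, p, t1, traj)
  L_fwd <- vapply(1:3, function(m)
    block_mle(vs, m, t_max = 2000, seed = 10 + m, repeats = 1)$Lambda,
    numeric(1))
  L_rev <- vapply(3:1, function(m)
    block_mle(vs, m, t_max = 2000, seed = 10 + m, repeats = 1)$Lambda,
    numeric(1))
  expect_equal(L_fwd, rev(L_rev), tolerance = 1e-12)
})

test_that("padded state components stay exactly zero and are excluded", {
  # mixed dimensions: hr (n = 3) and linear (n = 1) nodes; the pair of
  # linear nodes is a cluster, padded to dimension 3
  A <- matrix(0, 4, 4)
  A[3, 1] <- 1; A[4, 1] <- 1                  # hr source drives the pair
  A[3, 4] <- 1; A[4, 3] <- 1                  # mutual diffusive link
  net <- mlnetwork(list(sync_layer(A, sigma = 0.2, kind = "electrical")),
                   node_type = c(1L, 1L, 2L, 2L),
                   models = c("hr", "linear"),
                   model_params = list(NULL, list(a = 0.1)))
  p <- refine_equitable(net)
  expect_equal(max(p$sizes), 2)
  q_pair <- p$color[3]
  qnet <- quotient_network(net, p)
  traj <- integrate_network(qnet, initial_state(qnet), c(0, 300), 0.02)
  tr <- build_transform(net, p)
  vs <- assemble_variational(net, p, tr, traj)
  m <- which(vapply(vs$block_clusters, function(cl) q_pair %in% cl, logical(1)))
  r <- block_mle(vs, m, t_max = 250, seed = 4, repeats = 1)
  # transverse exponent of the pair: a - 2 sigma (mutual link) - sigma
  # (common diffusive drive from the source) = -0.5
  expect_equal(r$Lambda, 0.1 - 3 * 0.2, tolerance = 0.02)
})

test_that("direct full-network checks agree with the linear verdicts", {
  stable <- linear_pair(a = -1, sigma = 0.5)      # a - 2 sigma = -2
  p <- refine_equitable(stable)
  r1 <- direct_check(stable, p, 1, amplitude = 1e-3, step = 0.01,
                     transient = 5, t_max = 30)
  expect_equal(r1$outcome, "resync")
  unstable <- linear_pair(a = 0.5, sigma = 0.1)   # a - 2 sigma = +0.3
  p2 <- refine_equitable(unstable)
  r2 <- direct_check(unstable, p2, 1, amplitude = 1e-3, step = 0.01,
                     transient = 5, t_max = 60)
  expect_equal(r2$outcome, "diverge")
})

test_that("stability maps run per grid point and collect errors", {
  grid <- expand.grid(a = c(-1, 0.5), sigma = c(0.1, 0.5))
  df <- stability_map(function(a, sigma) linear_pair(a = a, sigma = sigma),
                      grid, step = 0.01, transient = 5, window = 60,
                      repeats = 1)
  expect_equal(nrow(df), 4)
  expect_true(all(is.na(df$error)))
  expect_equal(df$stable_C1, df$a - 2 * df$sigma < 0)
})
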