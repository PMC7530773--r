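# equitable partition refinement, certification, classification, planting

test_that("edgeless and singleton networks refine trivially", {
  net <- mlnetwork(list(), N = 5, models = "linear")
  p <- refine_equitable(net)
  expect_equal(p$Q, 1)                        # no input constraint at all
  expect_equal(p$sizes, 5)
  net1 <- mlnetwork(list(), N = 1, models = "linear")
  expect_equal(refine_equitable(net1)$Q, 1)
})

test_that("refinement output is equitable and respects node types", {
  for (seed in 1:10) {
    pl <- random_planted_network(N = 8, L = 2, seed = seed)
    p <- refine_equitable(pl$net)
    expect_true(is_equitable(pl$net, p)$equitable)
  }
  # two node types are never merged even with identical inputs
  net <- mlnetwork(list(sync_layer(matrix(0, 4, 4))),
                   node_type = c(1, 1, 2, 2), models = c("linear", "linear"))
  p <- refine_equitable(net)
  expect_equal(p$Q, 2)
  expect_true(all(vapply(p$clusters, function(cl)
    length(unique(net$node_type[cl])) == 1, logical(1))))
})

test_that("refinement never splits a planted cluster", {
  for (seed in 1:25) {
    pl <- random_planted_network(N = sample(5:9, 1), L = sample(1:3, 1),
                                 seed = seed)
    p <- refine_equitable(pl$net)
    # found partition is at least as coarse as planted: each found cluster is
    # a union of planted clusters (equivalently, planted refines found)
    expect_true(all(tapply(p$color, pl$partition$color,
                           function(x) length(unique(x))) == 1),
                info = sprintf("seed %d", seed))
  }
})

test_that("refinement matches the exhaustive-search oracle on small networks", {
  for (seed in 1:20) {
    net <- if (seed %% 2 == 0)
      random_planted_network(N = 7, L = 2, seed = seed)$net
    else random_quantized_network(N = 6, L = 2, seed = seed)
    p <- refine_equitable(net)
    expect_same_partition(p, brute_force_coarsest(net))
  }
})

test_that("equitability certificates report a violation witness", {
  b <- build_swim_cpg()
  # the all-in-one-cluster partition of the swim CPG is not equitable
  r <- is_equitable(b$net, rep(1, 6))
  expect_false(r$equitable)
  expect_true(!is.null(r$witness))
  expect_true(r$witness$layer %in% 1:3)
  # singleton partition is vacuously equitable
  expect_true(is_equitable(b$net, 1:6)$equitable)
  # output of refine_equitable certifies equitable
  p <- refine_equitable(b$net)
  expect_true(is_equitable(b$net, p)$equitable)
  expect_error(is_equitable(b$net, c(1, 1, 2)), "cover")
})

test_that("directed-class dispatch covers the four regimes", {
  # fully symmetric toy
  net <- mlnetwork(list(sync_layer(matrix(c(0, 1, 1, 0), 2, 2))), models = "linear")
  expect_equal(classify_network(net, refine_equitable(net)), "undirected")
  # swim CPG: directed, all clusters of size two, asymmetric link between
  # two non-trivial clusters -> class A
  b <- build_swim_cpg()
  expect_equal(classify_network(b$net, refine_equitable(b$net)), "classA")
  # macaque: asymmetric links touch trivial clusters only -> class B
  m <- build_macaque()
  pm <- refine_equitable(m$net, force_singleton = m$isolated)
  expect_equal(classify_network(m$net, pm), "classB")
  # directed with a 3-cluster and an asymmetric link inside -> unsupported
  A <- matrix(0, 6, 6)
  A[1, 2] <- 1; A[2, 3] <- 1; A[3, 1] <- 1    # directed 3-cycle
  A[4, 5] <- 1; A[5, 6] <- 1; A[6, 4] <- 1
  A[1, 4] <- 1; A[2, 5] <- 1; A[3, 6] <- 1
  A[4, 1] <- 1; A[5, 2] <- 1; A[6, 3] <- 1
  net3 <- mlnetwork(list(sync_layer(A)), models = "linear")
  p3 <- refine_equitable(net3)
  if (max(p3$sizes) > 2)
    expect_equal(classify_network(net3, p3), "unsupported")
})

test_that("planting lifts a quotient exactly", {
  # sizes all 1: the lift is the quotient itself
  R <- matrix(c(0, 2, 1, 0), 2, 2)
  pl <- plant_partition(list(R), sizes = c(1, 1), seed = 1)
  expect_equal(pl$net$layers[[1]]$A, R)
  # row sums: every node receives quotient weight from each cluster
  pl <- plant_partition(list(matrix(c(0, 2, 2, 0), 2, 2)), sizes = c(3, 3),
                        seed = 7)
  A <- pl$net$layers[[1]]$A
  Z <- matrix(0, 6, 2); Z[cbind(1:6, pl$partition$color)] <- 1
  G <- A %*% Z
  for (i in 1:6) {
    q <- pl$partition$color[i]
    expect_equal(unname(G[i, ]), if (q == 1) c(0, 2) else c(2, 0))
  }
  # infeasible row sum
  expect_error(plant_partition(list(matrix(c(0, 5, 5, 0), 2, 2)),
                               sizes = c(3, 3)), "not achievable")
})

test_that("symmetric planting produces symmetric layers with exact sums", {
  for (seed in 1:10) {
    pl <- random_planted_network(N = 8, L = 2, seed = seed, symmetric = TRUE)
    for (l in pl$net$layers) expect_equal(l$A, t(l$A))
    expect_true(is_equitable(pl$net, pl$partition)$equitable)
  }
})

test_that("refining a quotient built from planted structure yields singletons", {
  # the quotient of the coarsest partition has no coarser equitable merge
  # (unless planted); its own refinement is all singletons
  pl <- random_planted_network(N = 8, L = 2, seed = 3)
  p <- refine_equitable(pl$net)
  qnet <- quotient_network(pl$net, p)
  pq <- refine_equitable(qnet)
  expect_equal(pq$Q, p$Q)
})
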