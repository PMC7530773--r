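# IRR transform: orthonormality, projector diagonality, block structure

check_transform_invariants <- function(tr, net) {
  N <- tr$N
  expect_lt(max(abs(tr$T %*% t(tr$T) - diag(N))), 1e-10)
  # first Q rows are normalized cluster indicators
  for (q in seq_len(tr$Q)) {
    members <- tr$partition$clusters[[q]]
    expect_equal(unname(tr$T[q, members]),
                 rep(1 / sqrt(length(members)), length(members)))
    expect_equal(unname(tr$T[q, -members]), rep(0, N - length(members)))
  }
  # J_q diagonal, PSD, summing to the identity
  S <- Reduce(`+`, tr$J)
  expect_lt(max(abs(S - diag(N))), 1e-10)
  for (J in tr$J) expect_lt(max(abs(J - diag(diag(J)))), 1e-10)
  # declared blocks cover the transverse rows exactly once
  if (N > tr$Q)
    expect_setequal(unlist(tr$blocks), (tr$Q + 1):N)
  # off-block residual of every B^k below threshold
  det2 <- detect_blocks(tr)
  expect_equal(lapply(det2$blocks, sort), lapply(tr$blocks, sort))
}

test_that("a 2-node cluster forces the antisymmetric transverse row", {
  net <- linear_pair(a = -1, sigma = 1)
  p <- refine_equitable(net)
  tr <- build_transform(net, p)
  expect_equal(tr$Q, 1)
  v <- tr$T[2, ]
  expect_equal(sort(abs(v)), rep(1 / sqrt(2), 2))
  expect_equal(sum(v), 0)
  check_transform_invariants(tr, net)
})

test_that("swim CPG transform reproduces the published block patterns", {
  b <- build_swim_cpg()
  p <- refine_equitable(b$net)
  tr <- build_transform(b$net, p)
  check_transform_invariants(tr, b$net)
  # all three layers together: one 3x3 transverse block, all clusters
  expect_equal(lengths(tr$blocks), 3L)
  expect_equal(tr$block_clusters[[1]], 1:3)
  # zero coupling between synchronous and transverse rows in each B^k is
  # not guaranteed for directed networks in general, but the per-layer
  # transverse patterns are: {1,1,1}, {1,2}, {3}
  pats <- lapply(1:3, function(k) {
    net1 <- mlnetwork(b$net$layers[k], node_type = b$net$node_type,
                      models = "swim")
    t1 <- build_transform(net1, p, dclass = "classA")
    list(sizes = sort(lengths(t1$blocks)),
         clusters = t1$block_clusters)
  })
  expect_equal(pats[[1]]$sizes, c(1L, 1L, 1L))
  expect_equal(pats[[2]]$sizes, c(1L, 2L))
  expect_equal(sort(unlist(pats[[2]]$clusters[lengths(pats[[2]]$clusters) == 2])),
               c(2, 3))                      # the 2x2 couples C2 and C3
  expect_equal(pats[[3]]$sizes, 3L)
  expect_equal(pats[[3]]$clusters[[1]], 1:3)
})

test_that("undirected planted networks get block-diagonal B^k", {
  for (seed in c(2, 5, 11)) {
    pl <- random_planted_network(N = 9, L = 2, seed = seed, symmetric = TRUE)
    p <- refine_equitable(pl$net)
    tr <- build_transform(pl$net, p, seed = 1)
    check_transform_invariants(tr, pl$net)
    # undirected: no coupling between synchronous and transverse rows
    trows <- setdiff(seq_len(tr$N), seq_len(tr$Q))
    for (Bk in tr$B) {
      thr <- 1e-10 * max(1, max(abs(Bk)))
      expect_lt(max(abs(Bk[seq_len(tr$Q), trows])), thr * 10)
      expect_lt(max(abs(Bk[trows, seq_len(tr$Q)])), thr * 10)
    }
    # block pattern is seed independent
    tr2 <- build_transform(pl$net, p, seed = 97)
    sig <- function(tr) {
      o <- order(vapply(tr$block_clusters, min, numeric(1)),
                 lengths(tr$blocks))
      list(lengths(tr$blocks)[o], tr$block_clusters[o])
    }
    expect_equal(sig(tr2), sig(tr))
  }
})

test_that("intertwined sets take the transitive closure over shared blocks", {
  # explicit block -> cluster maps
  expect_equal(intertwined_sets(list(1, 2, 3),
                                list(1, 2, 3)), list(1, 2, 3))
  expect_equal(intertwined_sets(list(1, 2), list(c(1, 2), c(2, 3))),
               list(1:3))
  expect_equal(intertwined_sets(list(1, 2, 3), list(c(1, 2), 3, c(3, 4))),
               list(c(1, 2), c(3, 4)))
  # all-1x1 blocks: singletons
  m <- build_macaque()
  pm <- refine_equitable(m$net, force_singleton = m$isolated)
  trm <- build_transform(m$net, pm)
  expect_equal(lengths(trm$blocks), rep(1L, 3))
  expect_equal(intertwined_sets(trm), as.list(sort(which(pm$sizes > 1))))
})

test_that("unsupported directed networks are rejected", {
  A <- matrix(0, 6, 6)
  A[1, 2] <- 1; A[2, 3] <- 1; A[3, 1] <- 1
  A[4, 5] <- 1; A[5, 6] <- 1; A[6, 4] <- 1
  A[1, 4] <- 1; A[2, 5] <- 1; A[3, 6] <- 1
  A[4, 1] <- 1; A[5, 2] <- 1; A[6, 3] <- 1
  net <- mlnetwork(list(sync_layer(A)), models = "linear")
  p <- refine_equitable(net)
  if (classify_network(net, p) == "unsupported")
    expect_error(build_transform(net, p), "does not apply")
})

test_that("transform exports round trip", {
  b <- build_swim_cpg()
  p <- refine_equitable(b$net)
  tr <- build_transform(b$net, p)
  dir <- withr::local_tempdir()
  export_transform(tr, dir)
  expect_equal(load_adjacency(file.path(dir, "T.csv")), tr$T)
  js <- jsonlite::read_json(file.path(dir, "blocks.json"),
                            simplifyVector = FALSE)
  expect_equal(length(js$blocks), length(tr$blocks))
  expect_equal(unlist(js$blocks[[1]]), tr$blocks[[1]])
})
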