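# Shared toy fixtures.

# two identical linear nodes x' = a x coupled diffusively (h = x_j - x_i)
linear_pair <- function(a, sigma, delta = 0, kind = "electrical") {
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  mlnetwork(list(sync_layer(A, sigma = sigma, delta = delta, kind = kind)),
            node_type = c(1L, 1L), models = "linear",
            model_params = list(list(a = a)))
}

# random small multi-layer network with quantized weights (0, 1, 2) and no
# planted structure
random_quantized_network <- function(N, L = 2, seed = 1, p_edge = 0.4) {
  set.seed(seed)
  layers <- lapply(seq_len(L), function(k) {
    A <- matrix(sample(0:2, N * N, replace = TRUE,
                       prob = c(1 - p_edge, p_edge * 0.7, p_edge * 0.3)), N, N)
    diag(A) <- 0
    sync_layer(A, sigma = 1, delta = 0, kind = "electrical")
  })
  mlnetwork(layers, node_type = rep(1L, N), models = "linear")
}

expect_same_partition <- function(p1, color2) {
  testthat::expect_equal(canon_colors(p1$color), canon_colors(color2))
}
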