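# Independent oracles used across the test suite.

# ---- set-partition enumeration (restricted growth strings) ----------------
.partition_cache <- new.env(parent = emptyenv())

all_set_partitions <- function(n) {
  key <- as.character(n)
  if (!is.null(.partition_cache[[key]])) return(.partition_cache[[key]])
  out <- list()
  rec <- function(color, k) {
    i <- length(color) + 1
    if (i > n) { out[[length(out) + 1]] <<- color; return(invisible()) }
    for (c in seq_len(k + 1)) rec(c(color, c), max(k, c))
  }
  rec(integer(0), 0L)
  # precompute indicator matrices
  parts <- lapply(out, function(color) {
    Q <- max(color)
    Z <- matrix(0, n, Q)
    Z[cbind(seq_len(n), color)] <- 1
    list(color = color, Z = Z, Q = Q, sizes = tabulate(color, Q))
  })
  .partition_cache[[key]] <- parts
  parts
}

# is a partition (indicator Z, color) equitable for all layers? vectorized:
# received sums G = A Z must equal the cluster-wise average row
.oracle_equitable <- function(As, part, tol = 1e-9) {
  for (A in As) {
    G <- A %*% part$Z
    Rbar <- rowsum(G, part$color) / part$sizes
    if (max(abs(G - Rbar[part$color, , drop = FALSE])) > tol) return(FALSE)
  }
  TRUE
}

# exhaustive-search coarsest equitable partition (N <= 8); assumes one node
# type; returns a color vector
brute_force_coarsest <- function(net, tol = 1e-9) {
  As <- lapply(net$layers, `[[`, "A")
  parts <- all_set_partitions(net$N)
  bestQ <- net$N + 1L; best <- NULL; ties <- 0L
  for (p in parts) {
    if (p$Q >= bestQ) next
    if (.oracle_equitable(As, p, tol)) { best <- p; bestQ <- p$Q }
  }
  # uniqueness of the minimum (the coarsest equitable partition is unique;
  # a tie would indicate an oracle bug)
  for (p in parts)
    if (p$Q == bestQ && .oracle_equitable(As, p, tol)) ties <- ties + 1L
  stopifnot(ties == 1L)
  best$color
}

# canonical form of a color vector (clusters numbered by first appearance)
canon_colors <- function(color) as.integer(factor(color, levels = unique(color)))

# ---- DDE closed forms ------------------------------------------------------
# x' = -x(t - delta), x == 1 on history; valid on [0, 2 delta]
dde_steps_solution <- function(t, delta) {
  ifelse(t <= delta, 1 - t, 1 - t + (t - delta)^2 / 2)
}

# rightmost characteristic root real part for y' = -a y(t-1):
# lambda = -a e^{-lambda}; for a in (0, pi/2) the rightmost root is real or a
# complex pair; stability boundary at a = pi/2 (root +/- i pi/2)
delayed_scalar_stable <- function(a) a < pi / 2
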