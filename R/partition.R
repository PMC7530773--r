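# Equitable partitions (step S1).
#
# A partition of the node set is equitable when all nodes of a cluster
# receive, in every layer, the same total weight from every cluster
# (including their own).  The coarsest such partition refining the node-type
# partition is found by iterated color refinement on received-weight
# signatures; the fixpoint of that refinement is the coarsest equitable
# partition.  Only incoming weights enter the definition; directedness is
# handled downstream by the network classification.

.partition_from_color <- function(color) {
  # renumber clusters by smallest contained node index
  first <- tapply(seq_along(color), color, min)
  ord <- order(first)
  remap <- integer(length(first))
  remap[ord] <- seq_along(ord)
  color <- remap[color]
  clusters <- split(seq_along(color), color)
  names(clusters) <- NULL
  structure(list(color = as.integer(color), clusters = clusters,
                 sizes = lengths(clusters), Q = length(clusters)),
            class = "ml_partition")
}

#' Construct a partition object from a cluster-id vector
#'
#' @param color length-N vector of cluster ids.
#' @return object of class `ml_partition` with clusters renumbered by
#'   smallest member.
#' @export
as_partition <- function(color) .partition_from_color(as.integer(factor(color)))

#' @export
print.ml_partition <- function(x, ...) {
  cat(sprintf("partition: %d cluster(s) over %d node(s)\n", x$Q, length(x$color)))
  for (q in seq_len(x$Q))
    cat(sprintf("  C%d (%d): %s\n", q, x$sizes[q],
                paste(x$clusters[[q]], collapse = ", ")))
  invisible(x)
}

# group rows of a numeric matrix into identical-signature classes, with
# absolute tolerance; rows are sorted lexicographically and split where any
# column differs by more than tol
.group_rows <- function(S, tol) {
  N <- nrow(S)
  if (N == 1) return(1L)
  ord <- do.call(order, as.data.frame(S))
  grp <- integer(N)
  g <- 1L
  grp[ord[1]] <- g
  for (r in 2:N) {
    if (max(abs(S[ord[r], ] - S[ord[r - 1], ])) > tol) g <- g + 1L
    grp[ord[r]] <- g
  }
  grp
}

#' Coarsest equitable partition of a multi-layer network
#'
#' Iterative color refinement: starting from the node-type partition, each
#' node's signature is the vector of total weights received from every
#' current color in every layer; nodes are re-colored by signature until a
#' fixpoint.  The fixpoint is the coarsest equitable partition refining the
#' node-type partition.
#'
#' @param net an [mlnetwork()].
#' @param tol absolute tolerance for comparing received weight sums.
#' @param force_singleton optional vector of node indices forced into
#'   singleton clusters before refinement (used by pipelines that treat
#'   fully disconnected nodes as trivial).
#' @return an `ml_partition`.
#' @export
refine_equitable <- function(net, tol = 1e-9, force_singleton = integer(0)) {
  N <- net$N
  color <- as.integer(factor(net$node_type))
  if (length(force_singleton) > 0) {
    mx <- max(color)
    color[force_singleton] <- mx + seq_along(force_singleton)
    color <- as.integer(factor(color))
  }
  if (length(net$layers) == 0 || N == 1)
    return(.partition_from_color(color))
  repeat {
    Q <- max(color)
    Z <- matrix(0, N, Q)
    Z[cbind(seq_len(N), color)] <- 1
    S <- do.call(cbind, c(list(color),
                          lapply(net$layers, function(l) l$A %*% Z)))
    newcol <- .group_rows(S, tol)
    if (max(newcol) == Q) break
    color <- newcol
  }
  .partition_from_color(color)
}

#' Certify equitability of a partition
#'
#' @param net an [mlnetwork()].
#' @param partition an `ml_partition` (or cluster-id vector).
#' @param tol absolute tolerance.
#' @return list with `equitable` (logical) and, when false, `witness`
#'   (layer, cluster, from_cluster, nodes) describing the first violation.
#' @export
is_equitable <- function(net, partition, tol = 1e-9) {
  if (!inherits(partition, "ml_partition")) partition <- as_partition(partition)
  if (length(partition$color) != net$N || anyNA(partition$color))
    stop("partition does not cover the node set")
  Q <- partition$Q
  Z <- matrix(0, net$N, Q)
  Z[cbind(seq_len(net$N), partition$color)] <- 1
  for (k in seq_along(net$layers)) {
    G <- net$layers[[k]]$A %*% Z   # received weight from each cluster
    for (q in seq_len(Q)) {
      members <- partition$clusters[[q]]
      if (length(members) < 2) next
      ref <- G[members[1], ]
      for (i in members[-1]) {
        d <- abs(G[i, ] - ref)
        if (max(d) > tol) {
          p <- which.max(d)
          return(list(equitable = FALSE,
                      witness = list(layer = k, cluster = q, from_cluster = p,
                                     nodes = c(members[1], i))))
        }
      }
    }
  }
  # clusters must not mix node types
  for (q in seq_len(Q))
    if (length(unique(net$node_type[partition$clusters[[q]]])) > 1)
      return(list(equitable = FALSE,
                  witness = list(layer = NA, cluster = q, from_cluster = NA,
                                 nodes = partition$clusters[[q]])))
  list(equitable = TRUE, witness = NULL)
}

#' Classify a network into the regimes supported by the transverse analysis
#'
#' `undirected` when every layer is symmetric; class `A` when every cluster
#' has at most two nodes; class `B` when every asymmetric link touches a
#' trivial (singleton) cluster; `unsupported` otherwise.
#'
#' @param net an [mlnetwork()].
#' @param partition an equitable `ml_partition`.
#' @param tol absolute tolerance for symmetry of weights.
#' @return one of "undirected", "classA", "classB", "unsupported".
#' @export
classify_network <- function(net, partition, tol = 1e-9) {
  if (all(is_undirected(net, tol))) return("undirected")
  # class B is checked first: when all asymmetric links touch trivial
  # clusters the transverse algebra reduces to the undirected one on the
  # non-trivial clusters, which is the stronger structural statement; a
  # network of size-<=2 clusters that fails that test is class A
  classB <- TRUE
  trivial <- partition$sizes[partition$color] == 1
  for (l in net$layers) {
    D <- abs(l$A - t(l$A)) > tol
    idx <- which(D, arr.ind = TRUE)
    if (nrow(idx) > 0 && any(!trivial[idx[, 1]] & !trivial[idx[, 2]])) {
      classB <- FALSE
      break
    }
  }
  if (classB) return("classB")
  if (max(partition$sizes) <= 2) return("classA")
  "unsupported"
}

# fill one rectangular block (mq x mp) with entries 0/unit and constant row
# sums count*unit; directed version: random columns per row
.fill_block_directed <- function(mq, mp, count, unit, diag_block) {
  B <- matrix(0, mq, mp)
  if (count == 0) return(B)
  for (i in seq_len(mq)) {
    avail <- seq_len(mp)
    if (diag_block && mq > 1) avail <- setdiff(avail, i)
    if (count > length(avail)) {
      # a singleton source cluster carries the full quotient weight (the
      # all-singleton case is the identity lift)
      if (length(avail) == 1) { B[i, avail] <- count * unit; next }
      stop("plant_partition: requested row sum not achievable")
    }
    B[i, sample(avail, count)] <- unit
  }
  B
}

# symmetric fill via cyclic stub assignment (off-diagonal pair of blocks)
.fill_block_cyclic <- function(mq, mp, count, unit) {
  B <- matrix(0, mq, mp)
  if (count == 0) return(B)
  if (mp == 1) { B[, 1] <- count * unit; return(B) }
  if (count > mp) stop("plant_partition: requested row sum not achievable")
  if ((mq * count) %% mp != 0)
    stop("plant_partition: infeasible symmetric block (stub count)")
  for (i in seq_len(mq))
    B[i, ((i - 1) * count + seq_len(count) - 1) %% mp + 1] <- unit
  B
}

# symmetric hollow diagonal block via circulant offsets
.fill_block_sym_diag <- function(m, count, unit) {
  B <- matrix(0, m, m)
  if (count == 0) return(B)
  if (m == 1) { B[1, 1] <- count * unit; return(B) }
  if (count > m - 1) stop("plant_partition: requested row sum not achievable")
  offs <- integer(0)
  half <- count %/% 2
  if (half > 0) offs <- c(offs, seq_len(half), m - seq_len(half))
  if (count %% 2 == 1) {
    if (m %% 2 != 0)
      stop("plant_partition: infeasible symmetric diagonal block (odd degree, odd size)")
    offs <- c(offs, m %/% 2)
  }
  for (i in seq_len(m)) B[i, (i - 1 + offs) %% m + 1] <- unit
  B
}

#' Lift a quotient specification to a full network with a planted partition
#'
#' Builds an N-node multi-layer network whose cluster-wise received weight
#' sums reproduce the given quotient matrices exactly, with link placement
#' randomized inside each cluster-pair block.  The planted partition is
#' therefore equitable by construction.
#'
#' @param R_list list (one per layer) of Q x Q quotient weight matrices;
#'   entries must be multiples of `unit`.
#' @param sizes cluster sizes (length Q).
#' @param seed RNG seed.
#' @param unit elementary link weight (entries of the lifted matrices are 0
#'   or `unit`); single value or one per layer.
#' @param symmetric logical per layer: build a symmetric (undirected) layer
#'   (requires R^k and the stub counts to be consistent).
#' @param sigma,delta,kind per-layer coupling strength, delay, kind name.
#' @param node_type optional per-cluster node type (lifted to members).
#' @param models model names per type.
#' @return list with `net` (the [mlnetwork()]) and `partition` (the planted
#'   `ml_partition`).
#' @export
plant_partition <- function(R_list, sizes, seed = 1, unit = 1,
                            symmetric = FALSE, sigma = 1, delta = 0,
                            kind = "electrical", node_type = NULL,
                            models = NULL) {
  Q <- length(sizes)
  L <- length(R_list)
  unit <- rep_len(unit, L); symmetric <- rep_len(symmetric, L)
  sigma <- rep_len(sigma, L); delta <- rep_len(delta, L)
  kind <- rep_len(kind, L)
  N <- sum(sizes)
  starts <- cumsum(c(0, sizes[-Q]))
  idx <- lapply(seq_len(Q), function(q) starts[q] + seq_len(sizes[q]))
  set.seed(seed)
  # one random within-cluster permutation shared by all layers
  perm <- unlist(lapply(seq_len(Q), function(q) starts[q] + sample(sizes[q])))
  layers <- vector("list", L)
  for (k in seq_len(L)) {
    R <- as.matrix(R_list[[k]])
    if (!all(dim(R) == Q)) stop("quotient matrix dimension mismatch")
    counts <- R / unit[k]
    if (max(abs(counts - round(counts))) > 1e-9)
      stop("plant_partition: quotient weights are not multiples of the unit")
    counts <- round(counts)
    A <- matrix(0, N, N)
    if (symmetric[k]) {
      # stub consistency: sizes[q] * counts[q, p] == sizes[p] * counts[p, q]
      SC <- diag(sizes, nrow = Q) %*% counts
      if (max(abs(SC - t(SC))) > 1e-9)
        stop("plant_partition: symmetric layer needs consistent stub counts")
      for (q in seq_len(Q)) {
        A[idx[[q]], idx[[q]]] <- .fill_block_sym_diag(sizes[q], counts[q, q], unit[k])
        if (q < Q) for (p in seq((q + 1), Q)) {
          B <- .fill_block_cyclic(sizes[q], sizes[p], counts[q, p], unit[k])
          A[idx[[q]], idx[[p]]] <- B
          A[idx[[p]], idx[[q]]] <- t(B)
        }
      }
    } else {
      for (q in seq_len(Q)) for (p in seq_len(Q))
        A[idx[[q]], idx[[p]]] <- .fill_block_directed(sizes[q], sizes[p],
                                                      counts[q, p], unit[k],
                                                      diag_block = (q == p))
    }
    A <- A[perm, perm, drop = FALSE]
    layers[[k]] <- sync_layer(A, sigma = sigma[k], delta = delta[k], kind = kind[k])
  }
  color_final <- integer(N)
  color_final[perm] <- rep(seq_len(Q), sizes)
  if (is.null(node_type)) node_type <- rep(1L, Q)
  nt <- node_type[color_final]
  net <- mlnetwork(layers, node_type = nt, models = models)
  list(net = net, partition = as_partition(color_final))
}

#' Random multi-layer test network with a planted equitable partition
#'
#' Fixture generator: draws a random cluster structure (sizes, small
#' integer quotient weights), lifts it with [plant_partition()], and
#' optionally perturbs nothing further (weights stay quantized, as in the
#' case studies, so equitability comparisons are exact).
#'
#' @param N total node count.
#' @param L number of layers.
#' @param seed RNG seed.
#' @param symmetric build symmetric layers.
#' @param Q number of planted clusters (default random in 2..min(4, N)).
#' @return list with `net` and planted `partition`.
#' @export
random_planted_network <- function(N = 8, L = 2, seed = 1, symmetric = FALSE,
                                   Q = NULL) {
  set.seed(seed)
  if (is.null(Q)) Q <- sample(2:min(4, N - 1), 1)
  # random composition of N into Q parts
  cuts <- sort(sample(seq_len(N - 1), Q - 1))
  sizes <- diff(c(0, cuts, N))
  R_list <- lapply(seq_len(L), function(k) {
    R <- matrix(0, Q, Q)
    for (q in seq_len(Q)) for (p in seq_len(Q)) {
      mx <- if (symmetric) {
        if (q == p) sizes[q] - 1 else sizes[p]
      } else {
        if (q == p) max(sizes[q] - 1, as.integer(sizes[q] == 1)) else sizes[p]
      }
      R[q, p] <- sample(0:min(2, mx), 1)
    }
    if (symmetric) {
      # make degree counts consistent: c_pq = m_q c_qp / m_p must be integral;
      # enforce by zeroing inconsistent off-diagonal entries and symmetrizing
      for (q in seq_len(Q)) {
        if (R[q, q] %% 2 == 1 && sizes[q] %% 2 == 1 && sizes[q] > 1)
          R[q, q] <- R[q, q] - 1
        if (q < Q) for (p in seq(q + 1, Q)) {
          if ((sizes[q] * R[q, p]) %% sizes[p] != 0) R[q, p] <- 0
          R[p, q] <- sizes[q] * R[q, p] / sizes[p]
          if (R[p, q] > sizes[q]) { R[q, p] <- 0; R[p, q] <- 0 }
        }
      }
    }
    R
  })
  plant_partition(R_list, sizes, seed = seed + 1000L,
                  symmetric = symmetric)
}
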