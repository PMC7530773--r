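# Irreducible-representation (IRR) perturbation coordinates (step S3,
# algebraic part).
#
# The orthonormal matrix T has Q "synchronous" rows (normalized cluster
# indicators) followed by N - Q "transverse" rows spanning, per cluster, the
# orthogonal complement of the indicator inside the cluster's coordinate
# support.  In these coordinates B^k = T A^k T^T reveals which transverse
# perturbation components are coupled: the connected components of the
# nonzero pattern of the transverse sub-blocks (union over layers) are the
# independent stability sub-problems, and clusters sharing a sub-block are
# intertwined.
#
# Transverse rows are refined by a randomized simultaneous block
# diagonalization step restricted to per-cluster rotations, which keeps
# every J_q = T E_q T^T exactly diagonal (a requirement of the variational
# equation).  Size-2 clusters leave no freedom, so no refinement is needed
# for directed class-A networks.

# orthonormal basis of the complement of the all-ones vector in R^m (m >= 2):
# columns 2..m of the Q factor of a QR decomposition seeded with 1s
.complement_basis <- function(m) {
  Qm <- qr.Q(qr(cbind(rep(1, m), diag(m)[, -m, drop = FALSE])))
  t(Qm[, -1, drop = FALSE])  # (m-1) x m, rows orthonormal, orthogonal to 1
}

#' Build the IRR coordinate transform
#'
#' @param net an [mlnetwork()].
#' @param partition an equitable `ml_partition`.
#' @param dclass network class from [classify_network()]; `"unsupported"`
#'   is rejected.
#' @param seed seed for the randomized block-refinement step.
#' @param tol relative threshold below which a B^k entry counts as zero.
#' @return object of class `irr_transform` with fields `T` (N x N
#'   orthonormal), `B` (per-layer transformed matrices), `J` (per-cluster
#'   diagonal projectors), `blocks` (transverse row-index sets),
#'   `block_clusters` (clusters touching each block), `row_cluster`
#'   (cluster of each transverse row), `Q`, `dclass`.
#' @export
build_transform <- function(net, partition, dclass = NULL, seed = 1,
                            tol = 1e-8) {
  if (is.null(dclass)) dclass <- classify_network(net, partition)
  if (identical(dclass, "unsupported"))
    stop("network is neither undirected nor of directed class A or B; ",
         "the IRR construction does not apply")
  N <- net$N; Q <- partition$Q
  Tm <- matrix(0, N, N)
  for (q in seq_len(Q)) {
    members <- partition$clusters[[q]]
    Tm[q, members] <- 1 / sqrt(length(members))
  }
  row_cluster <- integer(0)
  r <- Q
  for (q in seq_len(Q)) {
    members <- partition$clusters[[q]]
    m <- length(members)
    if (m < 2) next
    Tm[r + seq_len(m - 1), members] <- .complement_basis(m)
    row_cluster <- c(row_cluster, rep(q, m - 1))
    r <- r + m - 1
  }
  trows <- if (N > Q) (Q + 1):N else integer(0)

  # per-cluster refinement of the transverse basis
  nt <- length(trows)
  if (nt > 1 && any(table(row_cluster) > 1)) {
    set.seed(seed)
    for (sweep in 1:2) {
      Bt <- lapply(net$layers, function(l) {
        Tt <- Tm[trows, , drop = FALSE]
        Tt %*% l$A %*% t(Tt)
      })
      if (length(Bt) == 0) break
      co <- stats::rnorm(length(Bt))
      M <- Reduce(`+`, Map(function(B, c) c * (B + t(B)) / 2, Bt, co))
      for (q in unique(row_cluster[duplicated(row_cluster)])) {
        sel <- which(row_cluster == q)
        K <- M[sel, sel, drop = FALSE]
        ev <- eigen((K + t(K)) / 2, symmetric = TRUE)
        Tm[trows[sel], ] <- t(ev$vectors) %*% Tm[trows[sel], , drop = FALSE]
      }
    }
  }

  B <- lapply(net$layers, function(l) Tm %*% l$A %*% t(Tm))
  det <- .detect_blocks_raw(B, trows, row_cluster, tol)

  # reorder transverse rows: blocks by smallest touched cluster, rows inside
  # a block by (cluster, original position)
  if (length(det$blocks) > 0) {
    block_min <- vapply(det$block_clusters, min, numeric(1))
    bord <- order(block_min, vapply(det$blocks, min, numeric(1)))
    neworder <- unlist(lapply(det$blocks[bord], function(rs)
      rs[order(row_cluster[rs - Q], rs)]))
    Tm[trows, ] <- Tm[neworder, , drop = FALSE]
    row_cluster <- row_cluster[neworder - Q]
    B <- lapply(net$layers, function(l) Tm %*% l$A %*% t(Tm))
    det <- .detect_blocks_raw(B, trows, row_cluster, tol)
  }

  J <- lapply(seq_len(Q), function(q) {
    members <- partition$clusters[[q]]
    E <- diag(0, N); diag(E)[members] <- 1
    Tm %*% E %*% t(Tm)
  })

  structure(list(T = Tm, B = B, J = J,
                 blocks = det$blocks, block_clusters = det$block_clusters,
                 row_cluster = row_cluster, Q = Q, N = N,
                 dclass = dclass, partition = partition, tol = tol),
            class = "irr_transform")
}

#' @export
print.irr_transform <- function(x, ...) {
  cat(sprintf("IRR transform: N = %d, Q = %d, class %s\n", x$N, x$Q, x$dclass))
  for (m in seq_along(x$blocks))
    cat(sprintf("  transverse block %d: rows {%s} ~ clusters {%s}\n", m,
                paste(x$blocks[[m]], collapse = ","),
                paste(sort(x$block_clusters[[m]]), collapse = ",")))
  invisible(x)
}

# connected components of the union (over layers) of the symmetrized nonzero
# pattern of the transverse sub-blocks
.detect_blocks_raw <- function(B, trows, row_cluster, tol) {
  nt <- length(trows)
  if (nt == 0) return(list(blocks = list(), block_clusters = list()))
  Adj <- matrix(FALSE, nt, nt)
  for (Bk in B) {
    thr <- tol * max(abs(Bk), 1e-300)
    P <- abs(Bk[trows, trows, drop = FALSE]) > thr
    Adj <- Adj | P | t(P)
  }
  diag(Adj) <- TRUE
  comp <- integer(nt); cid <- 0
  for (s in seq_len(nt)) {
    if (comp[s] != 0) next
    cid <- cid + 1
    frontier <- s
    comp[s] <- cid
    while (length(frontier) > 0) {
      nb <- which(Adj[frontier[1], ] & comp == 0)
      comp[nb] <- cid
      frontier <- c(frontier[-1], nb)
    }
  }
  blocks <- split(trows, comp)
  names(blocks) <- NULL
  block_clusters <- lapply(blocks, function(rs)
    sort(unique(row_cluster[rs - (trows[1] - 1)])))
  list(blocks = blocks, block_clusters = block_clusters)
}

#' Detect transverse sub-blocks of an IRR transform
#'
#' @param transform an `irr_transform`.
#' @param tol relative zero threshold (defaults to the transform's).
#' @return list with `blocks` (transverse row-index sets) and
#'   `block_clusters` (sorted cluster ids touching each block).
#' @export
detect_blocks <- function(transform, tol = transform$tol) {
  trows <- if (transform$N > transform$Q) (transform$Q + 1):transform$N else integer(0)
  .detect_blocks_raw(transform$B, trows, transform$row_cluster, tol)
}

#' Intertwined cluster sets
#'
#' Clusters sharing any transverse sub-block have coupled variational
#' equations; the transitive closure of that relation partitions the
#' non-trivial clusters into intertwined sets.
#'
#' @param blocks,block_clusters as returned by [detect_blocks()] (defaults
#'   taken from an `irr_transform` passed as `blocks`).
#' @return list of sorted integer vectors of cluster ids.
#' @export
intertwined_sets <- function(blocks, block_clusters = NULL) {
  if (inherits(blocks, "irr_transform")) {
    block_clusters <- blocks$block_clusters
    blocks <- blocks$blocks
  }
  if (length(block_clusters) == 0) return(list())
  ids <- sort(unique(unlist(block_clusters)))
  parent <- stats::setNames(ids, ids)
  find <- function(x) { while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]; x }
  for (cl in block_clusters) {
    r <- find(cl[1])
    for (c2 in cl[-1]) parent[[as.character(find(c2))]] <- r
  }
  roots <- vapply(ids, find, numeric(1))
  out <- split(ids, roots)
  names(out) <- NULL
  out <- lapply(out, sort)
  out[order(vapply(out, min, numeric(1)))]
}

#' Export an IRR transform to files
#'
#' Writes `T.csv`, one `B<k>.csv` per layer, and `blocks.json`.
#'
#' @param transform an `irr_transform`.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
export_transform <- function(transform, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_adjacency(transform$T, file.path(dir, "T.csv"))
  for (k in seq_along(transform$B))
    write_adjacency(transform$B[[k]], file.path(dir, sprintf("B%d.csv", k)))
  jsonlite::write_json(
    list(blocks = transform$blocks,
         clusters_per_block = transform$block_clusters,
         intertwined_sets = intertwined_sets(transform)),
    file.path(dir, "blocks.json"), auto_unbox = FALSE, pretty = TRUE)
  invisible(dir)
}
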