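# Quotient network and trajectory machinery (step S2).
#
# Collapsing each equitable cluster to a single node yields the quotient
# network with per-layer weight matrices R^k, R^k[q, p] = total weight any
# member of cluster q receives from cluster p.  Integrating the quotient
# yields the synchronous trajectory s(t) = (s_1(t), ..., s_Q(t)), which
# lifts to an exact solution of the full network.

#' Quotient network of an equitable partition
#'
#' @param net an [mlnetwork()].
#' @param partition an equitable `ml_partition`.
#' @param tol tolerance used to verify representative independence.
#' @return an [mlnetwork()] over the Q cluster nodes with extra fields
#'   `sizes` (cluster sizes) and `parent_partition`.
#' @export
quotient_network <- function(net, partition, tol = 1e-9) {
  Q <- partition$Q
  Z <- matrix(0, net$N, Q)
  Z[cbind(seq_len(net$N), partition$color)] <- 1
  reps <- vapply(partition$clusters, `[`, integer(1), 1)
  layers <- lapply(net$layers, function(l) {
    G <- l$A %*% Z
    for (q in seq_len(Q)) {
      members <- partition$clusters[[q]]
      if (length(members) > 1 &&
          max(abs(sweep(G[members, , drop = FALSE], 2, G[members[1], ]))) > tol)
        stop("partition is not equitable: representative rows disagree")
    }
    sync_layer(G[reps, , drop = FALSE], sigma = l$sigma, delta = l$delta,
               kind = l$kind, kparams = l$kparams)
  })
  qnet <- mlnetwork(layers, node_type = net$node_type[reps],
                    models = net$models, model_params = net$model_params,
                    labels = if (!is.null(net$labels)) net$labels[reps] else NULL,
                    N = Q)
  qnet$sizes <- partition$sizes
  qnet$parent_partition <- partition
  class(qnet) <- c("quotient_network", "mlnetwork")
  qnet
}

# generic multi-layer network right-hand side evaluated in R (oracle for the
# compiled core and building block for assemble_quotient_rhs)
.network_rhs_r <- function(net, y, ydel_list, models = neuron_models(),
                           kinds = synapse_kinds()) {
  n <- .net_state_dim(net, models)
  N <- net$N
  dy <- numeric(N * n)
  for (i in seq_len(N)) {
    md <- .get_model(net$models[[net$node_type[i]]], models)
    p <- md$params
    ov <- net$model_params[[net$node_type[i]]]
    if (!is.null(ov)) p[names(ov)] <- ov
    xi <- y[(i - 1) * n + seq_len(n)]
    d <- numeric(n)
    d[seq_len(md$n)] <- md$f(xi[seq_len(md$n)], p)
    dy[(i - 1) * n + seq_len(n)] <- d
  }
  for (k in seq_along(net$layers)) {
    l <- net$layers[[k]]
    kd <- .get_kind(l$kind, kinds)
    yk <- ydel_list[[k]]
    for (i in seq_len(N)) {
      xi <- y[(i - 1) * n + seq_len(n)]
      acc <- 0
      for (j in seq_len(N)) {
        w <- l$A[i, j]
        if (w != 0)
          acc <- acc + w * kd$a(xi, yk[(j - 1) * n + seq_len(n)], l$kparams)
      }
      dy[(i - 1) * n + 1] <- dy[(i - 1) * n + 1] + l$sigma * acc
    }
  }
  dy
}

#' Delayed right-hand side of a quotient (or full) network
#'
#' Returns a callable `f(t, y, ydel_list)` where `y` is the stacked padded
#' state and `ydel_list` holds, per layer, the stacked state at `t -
#' delta_k`.  Suitable for [integrate_dde()].
#'
#' @param net an [mlnetwork()] (typically a [quotient_network()]).
#' @param models model registry.
#' @return function of (t, y, ydel_list).
#' @export
assemble_quotient_rhs <- function(net, models = neuron_models()) {
  force(net); force(models)
  function(t, y, ydel_list) .network_rhs_r(net, y, ydel_list, models)
}

# greatest common divisor of a set of positive reals on a 1e-9 grid
.float_gcd <- function(x, tol = 1e-9) {
  g2 <- function(a, b) {
    while (b > tol) { r <- a %% b; a <- b; b <- r }
    a
  }
  Reduce(g2, x)
}

# largest step <= step that divides every positive delay
.adjust_step <- function(step, deltas) {
  pos <- deltas[deltas > 0]
  if (length(pos) == 0) return(step)
  g <- .float_gcd(pos)
  g / ceiling(g / step - 1e-9)
}

.make_trajectory <- function(times, Y, F_, N, n, labels = NULL) {
  structure(list(times = times, dt = if (length(times) > 1) times[2] - times[1] else NA_real_,
                 Y = Y, F = F_, N = N, n = n, labels = labels),
            class = "ml_trajectory")
}

#' @export
print.ml_trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d nodes x %d components, t in [%g, %g], %d samples\n",
              x$N, x$n, x$times[1], x$times[length(x$times)], length(x$times)))
  invisible(x)
}

#' Interpolate a stored trajectory
#'
#' Cubic Hermite interpolation on the stored uniform grid (states and
#' derivatives are both stored, so the interpolant matches the integrator's
#' order on the grid).
#'
#' @param traj an `ml_trajectory`.
#' @param t vector of query times inside the stored span.
#' @return matrix length(t) x (N*n).
#' @export
interp_trajectory <- function(traj, t) {
  ts <- traj$times; dt <- traj$dt
  s <- (t - ts[1]) / dt
  i <- pmin(pmax(floor(s + 1e-9), 0), length(ts) - 2)
  th <- s - i
  out <- matrix(0, length(t), ncol(traj$Y))
  for (r in seq_along(t)) {
    ii <- i[r] + 1
    u <- th[r]
    if (u < 1e-12) { out[r, ] <- traj$Y[ii, ]; next }
    h00 <- 2 * u^3 - 3 * u^2 + 1; h10 <- u^3 - 2 * u^2 + u
    h01 <- -2 * u^3 + 3 * u^2; h11 <- u^3 - u^2
    out[r, ] <- h00 * traj$Y[ii, ] + h10 * dt * traj$F[ii, ] +
      h01 * traj$Y[ii + 1, ] + h11 * dt * traj$F[ii + 1, ]
  }
  out
}

#' Extract the state matrix of one node from a trajectory
#'
#' @param traj an `ml_trajectory`.
#' @param node node index.
#' @return matrix length(times) x n.
#' @export
node_states <- function(traj, node) {
  traj$Y[, (node - 1) * traj$n + seq_len(traj$n), drop = FALSE]
}

#' Fixed-step method-of-steps integrator for delay differential equations
#'
#' Classical RK4 with the method of steps: the step is reduced so that every
#' positive delay is an integer multiple of it, and delayed states are
#' evaluated by cubic Hermite interpolation on the already-computed grid.
#' Zero delays are evaluated at the current RK4 stage (ordinary RK4).
#'
#' @param rhs function `f(t, y, ydel_list)`; `ydel_list[[j]]` is the state
#'   at `t - delays[j]`.
#' @param history initial data: a numeric vector (constant history) or a
#'   function of t defined on `[t0 - max(delays), t0]`.
#' @param t_span c(t0, t1).
#' @param step nominal step size (> 0), possibly reduced to fit delays.
#' @param delays vector of delays (>= 0), one per entry of `ydel_list`.
#' @return an `ml_trajectory` with N = 1, n = state length (plus attribute
#'   `step` holding the step actually used).
#' @export
integrate_dde <- function(rhs, history, t_span, step, delays = numeric(0)) {
  if (step <= 0) stop("step must be positive")
  h <- .adjust_step(step, delays)
  t0 <- t_span[1]; t1 <- t_span[2]
  nsteps <- round((t1 - t0) / h)
  if (nsteps < 1) stop("empty time span")
  histfun <- if (is.function(history)) history else function(t) history
  y0 <- histfun(t0)
  D <- length(y0)
  Y <- matrix(0, nsteps + 1, D)
  F_ <- matrix(0, nsteps + 1, D)
  Y[1, ] <- y0
  dsteps <- round(delays / h)
  lookup <- function(tq, stage_y, completed) {
    lapply(seq_along(delays), function(j) {
      if (dsteps[j] == 0) return(stage_y)
      tt <- tq - delays[j]
      if (tt <= t0 + 1e-12) return(histfun(tt))
      s <- (tt - t0) / h
      i <- floor(s + 1e-9); u <- s - i
      if (i + 1 > completed) stop("delayed lookup beyond computed history")
      if (u < 1e-9) return(Y[i + 1, ])
      h00 <- 2 * u^3 - 3 * u^2 + 1; h10 <- u^3 - 2 * u^2 + u
      h01 <- -2 * u^3 + 3 * u^2; h11 <- u^3 - u^2
      h00 * Y[i + 1, ] + h10 * h * F_[i + 1, ] +
        h01 * Y[i + 2, ] + h11 * h * F_[i + 2, ]
    })
  }
  y <- y0
  for (s in seq_len(nsteps)) {
    t <- t0 + (s - 1) * h
    k1 <- rhs(t, y, lookup(t, y, s))
    F_[s, ] <- k1
    yt <- y + h / 2 * k1
    k2 <- rhs(t + h / 2, yt, lookup(t + h / 2, yt, s))
    yt <- y + h / 2 * k2
    k3 <- rhs(t + h / 2, yt, lookup(t + h / 2, yt, s))
    yt <- y + h * k3
    k4 <- rhs(t + h, yt, lookup(t + h, yt, s))
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(y)))
      stop(sprintf("integration blew up at t = %g", t + h))
    Y[s + 1, ] <- y
  }
  tend <- t0 + nsteps * h
  F_[nsteps + 1, ] <- rhs(tend, y, lookup(tend, y, nsteps))
  tr <- .make_trajectory(t0 + h * (0:nsteps), Y, F_, N = 1L, n = D)
  attr(tr, "step") <- h
  tr
}

#' Integrate a multi-layer network with the compiled core
#'
#' @param net an [mlnetwork()] (full or quotient).
#' @param x0 initial state: N x n matrix, list of per-node vectors, or
#'   stacked vector (padded dimension n).
#' @param t_span c(t0, t1).
#' @param step nominal step (reduced to divide all delays).
#' @param save_every store every `save_every`-th grid point (the trajectory
#'   grid spacing is `step * save_every`).
#' @param store_from only store output from this time on (the integration
#'   still starts at t0; earlier samples are discarded, which keeps long
#'   transients memory-free).
#' @param models model registry.
#' @param pulse optional list(node, onset, duration, amplitude): square
#'   current pulse added to the membrane-potential derivative of one node.
#' @return an `ml_trajectory`.
#' @export
integrate_network <- function(net, x0, t_span, step, save_every = 1L,
                              store_from = t_span[1],
                              models = neuron_models(), pulse = NULL) {
  n <- .net_state_dim(net, models)
  y0 <- .pack_state(net, x0, n)
  deltas <- vapply(net$layers, `[[`, numeric(1), "delta")
  h <- .adjust_step(step, deltas)
  spec <- .net_cpp_spec(net, models, pulse = pulse)
  # align store_from on the grid
  k0 <- max(0, floor((store_from - t_span[1]) / h + 1e-9))
  res <- net_integrate_cpp(spec, y0, t_span[1], t_span[2], h,
                           as.integer(save_every), t_span[1] + k0 * h)
  if (res$status != 0)
    stop(sprintf("network integration blew up at t = %g", res$blow_time))
  tr <- .make_trajectory(res$times, res$Y, res$F, N = net$N, n = n,
                         labels = net$labels)
  attr(tr, "step") <- h
  tr
}

.pack_state <- function(net, x0, n) {
  if (is.list(x0)) {
    y0 <- numeric(net$N * n)
    for (i in seq_len(net$N)) y0[(i - 1) * n + seq_along(x0[[i]])] <- x0[[i]]
    y0
  } else if (is.matrix(x0)) {
    if (nrow(x0) != net$N) stop("x0 must have one row per node")
    y0 <- numeric(net$N * n)
    for (i in seq_len(net$N)) y0[(i - 1) * n + seq_len(ncol(x0))] <- x0[i, ]
    y0
  } else {
    if (length(x0) != net$N * n) stop("stacked state length mismatch")
    as.numeric(x0)
  }
}

#' Default initial state for a network
#'
#' Model-specific resting-like initial conditions, optionally jittered
#' per node (to start off the synchronous manifold).
#'
#' @param net an [mlnetwork()].
#' @param jitter amplitude of uniform per-component jitter (default 0).
#' @param seed RNG seed used when `jitter > 0`.
#' @param models model registry.
#' @return N x n matrix of initial states.
#' @export
initial_state <- function(net, jitter = 0, seed = 1, models = neuron_models()) {
  n <- .net_state_dim(net, models)
  X <- matrix(0, net$N, n)
  for (i in seq_len(net$N)) {
    md <- .get_model(net$models[[net$node_type[i]]], models)
    x <- switch(md$name,
                swim = c(-45, 0.5, 0.3, 0.05, 0.3, 0, 0),
                hr = c(-1.3, -7, 1),
                linear = 1,
                rep(0, md$n))
    X[i, seq_along(x)] <- x
  }
  if (jitter > 0) {
    set.seed(seed)
    X <- X + matrix(stats::runif(length(X), -jitter, jitter), nrow(X), ncol(X))
  }
  X
}

#' Lift a quotient trajectory to the full node space
#'
#' Every node copies the trajectory of its cluster: x_i(t) = s_{q(i)}(t).
#'
#' @param quotient_traj trajectory of the Q cluster states.
#' @param partition the `ml_partition` mapping nodes to clusters.
#' @return an `ml_trajectory` over all N nodes.
#' @export
lift_trajectory <- function(quotient_traj, partition) {
  n <- quotient_traj$n
  N <- length(partition$color)
  cols <- unlist(lapply(partition$color, function(q) (q - 1) * n + seq_len(n)))
  .make_trajectory(quotient_traj$times,
                   quotient_traj$Y[, cols, drop = FALSE],
                   quotient_traj$F[, cols, drop = FALSE],
                   N = N, n = n)
}

#' Synchronous initial state of a full network from per-cluster states
#'
#' @param partition an `ml_partition`.
#' @param cluster_states Q x n matrix of per-cluster initial states.
#' @return N x n matrix with identical rows inside each cluster.
#' @export
lift_state <- function(partition, cluster_states) {
  cluster_states[partition$color, , drop = FALSE]
}
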