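# Transverse stability analysis (step S3, dynamical part).
#
# The variational equation for perturbations transverse to the synchronous
# manifold, written in IRR coordinates, splits into independent sub-blocks.
# Each block is a linear, possibly delayed system driven by the quotient
# trajectory s(t):
#
#   eta_dot_r = [ Df_q(s_q) + sum_k sigma^k sum_p R^k[q,p] D1h^k(s_q, s_p(t-d_k)) ] eta_r
#             + sum_k sigma^k sum_r' B^k[r,r'] D2h^k(s_q, s_{q'}(t-d_k)) eta_r'(t-d_k)
#
# with q = q(r) the cluster of transverse row r.  The maximum Lyapunov
# exponent of a block decides stability: integration from a random unit
# perturbation stops when its norm crosses an upper threshold (unstable) or
# a lower threshold (stable); if neither triggers, the exponent is the
# least-squares slope of the log-norm over the last half of the run and the
# block is flagged marginal.

#' Assemble the transverse variational system
#'
#' @param net an [mlnetwork()].
#' @param partition equitable `ml_partition`.
#' @param transform `irr_transform` from [build_transform()].
#' @param quotient_traj quotient trajectory (from [integrate_network()] on
#'   the [quotient_network()]); must cover the Lyapunov window plus the
#'   longest delay.
#' @param models model registry.
#' @param step integration step for the variational system (defaults to the
#'   step used for the trajectory).
#' @return object of class `variational_system`.
#' @export
assemble_variational <- function(net, partition, transform, quotient_traj,
                                 models = neuron_models(),
                                 step = attr(quotient_traj, "step")) {
  Q <- partition$Q
  n <- .net_state_dim(net, models)
  if (ncol(quotient_traj$Y) != Q * n)
    stop("trajectory does not match the quotient dimension")
  qnet <- quotient_network(net, partition)
  kinds <- synapse_kinds()
  cluster_model <- integer(Q); cluster_params <- vector("list", Q)
  cluster_dim <- integer(Q)
  for (q in seq_len(Q)) {
    ty <- qnet$node_type[q]
    md <- .get_model(net$models[[ty]], models)
    p <- md$params
    ov <- net$model_params[[ty]]
    if (!is.null(ov)) p[names(ov)] <- ov
    cluster_model[q] <- md$cpp_id
    cluster_params[[q]] <- md$pack(p)
    cluster_dim[q] <- md$n
  }
  trows <- if (net$N > Q) (Q + 1):net$N else integer(0)
  layers <- lapply(seq_along(net$layers), function(k) {
    l <- net$layers[[k]]
    kd <- .get_kind(l$kind, kinds)
    list(tau = transform$B[[k]][trows, trows, drop = FALSE],
         R = qnet$layers[[k]]$A,
         sigma = l$sigma, delta = l$delta,
         kind = kd$cpp_id, kparams = as.numeric(l$kparams))
  })
  maxdelay <- if (length(net$layers)) max(vapply(net$layers, `[[`, numeric(1), "delta")) else 0
  structure(list(Q = Q, n = n, nt = length(trows),
                 row_cluster = transform$row_cluster,
                 cluster_model = cluster_model,
                 cluster_params = cluster_params,
                 cluster_dim = cluster_dim,
                 layers = layers, blocks = transform$blocks,
                 block_clusters = transform$block_clusters,
                 traj = quotient_traj, step = step, maxdelay = maxdelay),
            class = "variational_system")
}

#' @export
print.variational_system <- function(x, ...) {
  cat(sprintf("variational system: %d transverse row(s) x %d components, %d block(s)\n",
              x$nt, x$n, length(x$blocks)))
  invisible(x)
}

# slice the variational system to one block and build the compiled-core spec
.block_vspec <- function(vsys, rows) {
  sel <- rows - vsys$Q   # transverse-row indices
  list(nb = length(sel), n = vsys$n, Q = vsys$Q,
       row_cluster = as.integer(vsys$row_cluster[sel]),
       cluster_model = as.integer(vsys$cluster_model),
       cluster_params = vsys$cluster_params,
       cluster_dim = as.integer(vsys$cluster_dim),
       layers = lapply(vsys$layers, function(l) {
         l$tau <- l$tau[sel, sel, drop = FALSE]
         l
       }))
}

.traj_cpp <- function(traj) {
  list(t_start = traj$times[1], dt = traj$dt, Y = traj$Y, F = traj$F)
}

#' Maximum Lyapunov exponent of one transverse block
#'
#' Integrates the block's perturbation along the stored synchronous
#' trajectory from random unit initial conditions.  Stops early when the
#' perturbation norm crosses `eps_hi` (diverging, positive exponent) or
#' `eps_lo` (converging, negative exponent); otherwise reports the
#' least-squares slope of the log-norm over the last half of the run,
#' flagged marginal when inside `marginal_band`.
#'
#' @param vsys a `variational_system`.
#' @param block block index (into `vsys$blocks`) or a vector of transverse
#'   row indices.
#' @param eps_hi,eps_lo stopping thresholds on the perturbation norm.
#' @param t_max maximal integration time (model time units).
#' @param seed RNG seed for the initial perturbations.
#' @param step integration step.
#' @param repeats number of random initial conditions; the reported
#'   exponent is the maximum over repeats.
#' @param marginal_band half-width of the band around zero flagged marginal.
#' @return list with `Lambda`, `stable`, `marginal`, `method`
#'   ("threshold" or "slope"), `t_end`, `repeats` (per-repeat detail).
#' @export
block_mle <- function(vsys, block, eps_hi = 1e4, eps_lo = 1e-4,
                      t_max = 2e4, seed = 1, step = vsys$step, repeats = 3,
                      marginal_band = 0.01) {
  rows <- if (length(block) == 1 && block <= length(vsys$blocks))
    vsys$blocks[[block]] else block
  spec <- .block_vspec(vsys, rows)
  h <- .adjust_step(step, vapply(vsys$layers, `[[`, numeric(1), "delta"))
  traj <- vsys$traj
  t0 <- traj$times[1] + vsys$maxdelay
  t1 <- min(t0 + t_max, traj$times[length(traj$times)])
  nsteps <- floor((t1 - t0) / h)
  if (nsteps < 10) stop("trajectory too short for the requested window")
  t1 <- t0 + nsteps * h
  sample_every <- max(1L, as.integer(round(nsteps / 2000)))
  # active components (padding masked out)
  D <- spec$nb * spec$n
  active <- unlist(lapply(seq_len(spec$nb), function(r)
    (r - 1) * spec$n + seq_len(spec$cluster_dim[spec$row_cluster[r]])))
  set.seed(seed)
  out <- vector("list", repeats)
  for (rep_i in seq_len(repeats)) {
    eta0 <- numeric(D)
    v <- stats::rnorm(length(active))
    eta0[active] <- v / sqrt(sum(v^2))
    res <- var_integrate_cpp(spec, .traj_cpp(traj), eta0, t0, t1, h,
                             eps_hi, eps_lo, sample_every)
    if (res$stop_code == 3)
      stop(sprintf("variational integration blew up at t = %g", res$stop_time))
    ts <- res$sample_t; ln <- res$sample_ln
    ns <- length(ts)
    fitsel <- if (ns >= 8) seq.int(ceiling(ns / 2), ns) else seq_len(ns)
    slope <- if (length(fitsel) >= 2)
      stats::coef(stats::lm.fit(cbind(1, ts[fitsel]), ln[fitsel]))[2]
    else (ln[ns] - ln[1]) / max(ts[ns] - ts[1], h)
    method <- if (res$stop_code %in% c(1L, 2L)) "threshold" else "slope"
    Lam <- if (method == "threshold") {
      # growth-rate estimate from the full run; the sign is fixed by the rule
      gr <- (ln[ns] - ln[1]) / max(ts[ns] - ts[1], h)
      if (res$stop_code == 1L) max(gr, .Machine$double.eps) else min(gr, -.Machine$double.eps)
    } else slope
    out[[rep_i]] <- list(Lambda = unname(Lam), method = method,
                         stop_code = res$stop_code, t_end = res$stop_time,
                         slope = unname(slope))
  }
  Lams <- vapply(out, `[[`, numeric(1), "Lambda")
  best <- which.max(Lams)
  Lam <- Lams[best]
  method <- out[[best]]$method
  list(Lambda = Lam, stable = Lam < 0,
       marginal = (method == "slope") && abs(Lam) < marginal_band,
       method = method, t_end = out[[best]]$t_end, repeats = out)
}

#' Per-cluster stability verdicts from per-block exponents
#'
#' The exponent of a cluster is the maximum over all blocks whose cluster
#' set contains it; a cluster is stable iff that maximum is negative.
#'
#' @param block_reports list of [block_mle()] results (one per block).
#' @param block_clusters cluster sets per block (from the transform).
#' @param intertwined optional precomputed intertwined sets.
#' @return object of class `stability_report` with `Lambda_block`,
#'   `Lambda_cluster` (named by cluster id), `stable`, `marginal`,
#'   `intertwined`.
#' @export
cluster_stability <- function(block_reports, block_clusters,
                              intertwined = NULL) {
  stopifnot(length(block_reports) == length(block_clusters))
  ids <- sort(unique(unlist(block_clusters)))
  Lb <- vapply(block_reports, `[[`, numeric(1), "Lambda")
  Lc <- vapply(ids, function(q) {
    max(Lb[vapply(block_clusters, function(cl) q %in% cl, logical(1))])
  }, numeric(1))
  marg <- vapply(ids, function(q) {
    touch <- which(vapply(block_clusters, function(cl) q %in% cl, logical(1)))
    m <- touch[which.max(Lb[touch])]
    isTRUE(block_reports[[m]]$marginal)
  }, logical(1))
  names(Lc) <- names(marg) <- ids
  if (is.null(intertwined))
    intertwined <- intertwined_sets(vector("list", length(block_clusters)),
                                    block_clusters)
  structure(list(Lambda_block = Lb, block_clusters = block_clusters,
                 Lambda_cluster = Lc, stable = Lc < 0, marginal = marg,
                 intertwined = intertwined),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  for (q in names(x$Lambda_cluster))
    cat(sprintf("  cluster %s: Lambda = %+.5f -> %s%s\n", q,
                x$Lambda_cluster[[q]],
                if (x$stable[[q]]) "stable" else "unstable",
                if (x$marginal[[q]]) " (marginal)" else ""))
  cat("  intertwined sets:",
      paste(vapply(x$intertwined, function(s) paste0("{", paste(s, collapse = ","), "}"),
                   character(1)), collapse = " "), "\n")
  invisible(x)
}

#' Full stability analysis of one network
#'
#' Convenience pipeline: coarsest equitable partition, classification,
#' quotient integration (transient discarded, then a stored window),
#' IRR transform, per-block Lyapunov exponents, per-cluster verdicts.
#'
#' @param net an [mlnetwork()].
#' @param step integration step for the quotient trajectory.
#' @param transient model time discarded before the stored window.
#' @param window length of the stored synchronous-trajectory window; the
#'   Lyapunov integration runs inside it.
#' @param t_max maximal Lyapunov integration time (<= window - max delay).
#' @param x0 initial state for the quotient (default [initial_state()]).
#' @param save_every trajectory decimation factor for the stored window.
#' @param mle_step variational integration step (defaults to `step`).
#' @param seed RNG seed (transform refinement and initial perturbations).
#' @param repeats random initial perturbations per block.
#' @param models model registry.
#' @param force_singleton node indices forced trivial (see
#'   [refine_equitable()]).
#' @param eps_hi,eps_lo,marginal_band passed to [block_mle()].
#' @return list (class `stability_pipeline`) with partition, dclass,
#'   quotient, trajectory, transform, block reports and `report`.
#' @export
analyze_stability <- function(net, step, transient, window, t_max = window,
                              x0 = NULL, save_every = 1L, mle_step = step,
                              seed = 1, repeats = 3,
                              models = neuron_models(),
                              force_singleton = integer(0),
                              eps_hi = 1e4, eps_lo = 1e-4,
                              marginal_band = 0.01) {
  partition <- refine_equitable(net, force_singleton = force_singleton)
  dclass <- classify_network(net, partition)
  qnet <- quotient_network(net, partition)
  if (is.null(x0)) x0 <- initial_state(qnet, models = models)
  maxdelay <- if (length(net$layers))
    max(vapply(net$layers, `[[`, numeric(1), "delta")) else 0
  t_end <- transient + window + 2 * step * save_every
  traj <- integrate_network(qnet, x0, c(0, t_end), step,
                            save_every = save_every,
                            store_from = max(0, transient - maxdelay - 2 * step * save_every),
                            models = models)
  vb <- analyze_stability_from_traj(net, partition, dclass, traj,
                                    t_max = t_max, mle_step = mle_step,
                                    seed = seed, repeats = repeats,
                                    models = models, eps_hi = eps_hi,
                                    eps_lo = eps_lo,
                                    marginal_band = marginal_band)
  vb$quotient <- qnet
  vb
}

#' @rdname analyze_stability
#' @param partition,dclass,traj precomputed pipeline stages (the trajectory
#'   must cover the Lyapunov window plus the longest delay).
#' @export
analyze_stability_from_traj <- function(net, partition, dclass, traj,
                                        t_max, mle_step, seed = 1,
                                        repeats = 3,
                                        models = neuron_models(),
                                        eps_hi = 1e4, eps_lo = 1e-4,
                                        marginal_band = 0.01) {
  transform <- build_transform(net, partition, dclass, seed = seed)
  vsys <- assemble_variational(net, partition, transform, traj,
                               models = models, step = mle_step)
  reports <- lapply(seq_along(vsys$blocks), function(m)
    block_mle(vsys, m, eps_hi = eps_hi, eps_lo = eps_lo, t_max = t_max,
              seed = seed + m, step = mle_step, repeats = repeats,
              marginal_band = marginal_band))
  report <- cluster_stability(reports, vsys$block_clusters,
                              intertwined = intertwined_sets(transform))
  structure(list(net = net, partition = partition, dclass = dclass,
                 trajectory = traj, transform = transform, vsys = vsys,
                 block_reports = reports, report = report),
            class = "stability_pipeline")
}

#' @export
print.stability_pipeline <- function(x, ...) {
  cat(sprintf("stability pipeline: N = %d, Q = %d (%s)\n",
              x$net$N, x$partition$Q, x$dclass))
  print(x$report)
  invisible(x)
}

#' Stability map over a parameter grid
#'
#' @param net_builder function taking one row of `param_grid` (as a list)
#'   and returning an [mlnetwork()].
#' @param param_grid data frame of parameter combinations.
#' @param ... further arguments passed to [analyze_stability()].
#' @return data frame: the grid columns plus, per non-trivial cluster,
#'   `Lambda_C<q>` and `stable_C<q>`, and an `error` column (NA on
#'   success).
#' @export
stability_map <- function(net_builder, param_grid, ...) {
  rows <- lapply(seq_len(nrow(param_grid)), function(i) {
    pars <- as.list(param_grid[i, , drop = FALSE])
    res <- tryCatch({
      pl <- analyze_stability(do.call(net_builder, pars), ...)
      Lc <- pl$report$Lambda_cluster
      out <- c(as.list(stats::setNames(Lc, paste0("Lambda_C", names(Lc)))),
               as.list(stats::setNames(pl$report$stable,
                                       paste0("stable_C", names(Lc)))))
      c(pars, out, list(error = NA_character_))
    }, error = function(e) c(pars, list(error = conditionMessage(e))))
    res
  })
  nms <- unique(unlist(lapply(rows, names)))
  df <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(nms, names(r))] <- NA
    as.data.frame(r[nms], stringsAsFactors = FALSE)
  }))
  df
}

#' Direct full-network validation of a cluster verdict
#'
#' Integrates the full network from the lifted synchronous state plus a
#' small perturbation transverse to one cluster and watches the
#' intra-cluster state spread: returns `"resync"` when the spread falls
#' below `resync_tol`, `"diverge"` when it exceeds `diverge_tol`, else
#' `"inconclusive"`.
#'
#' @param net an [mlnetwork()].
#' @param partition equitable partition.
#' @param cluster cluster id to perturb.
#' @param amplitude perturbation amplitude applied (+/-) to the membrane
#'   potential of the cluster members.
#' @param seed RNG seed (sign pattern randomization).
#' @param step integration step.
#' @param transient quotient pre-integration time to land on the attractor.
#' @param t_max observation horizon after the perturbation.
#' @param resync_tol,diverge_tol spread thresholds.
#' @param models model registry.
#' @return list with `outcome`, `spread` (time series), `times`.
#' @export
direct_check <- function(net, partition, cluster, amplitude = 1e-3, seed = 1,
                         step, transient, t_max, resync_tol = 1e-6,
                         diverge_tol = 1, models = neuron_models()) {
  qnet <- quotient_network(net, partition)
  n <- .net_state_dim(net, models)
  x0q <- initial_state(qnet, models = models)
  trq <- integrate_network(qnet, x0q, c(0, transient), step,
                           save_every = max(1L, as.integer(round(transient / step / 4))),
                           models = models)
  sQ <- matrix(trq$Y[nrow(trq$Y), ], qnet$N, n, byrow = TRUE)
  X0 <- lift_state(partition, sQ)
  members <- partition$clusters[[cluster]]
  if (length(members) < 2) stop("cluster is trivial; nothing to perturb")
  set.seed(seed)
  pat <- stats::rnorm(length(members))
  pat <- pat - mean(pat)                       # transverse to the indicator
  pat <- pat / sqrt(sum(pat^2)) * amplitude
  X0[members, 1] <- X0[members, 1] + pat
  se <- max(1L, as.integer(round(1 / step)))   # sample spread roughly per ms
  tr <- integrate_network(net, X0, c(0, t_max), step, save_every = se,
                          models = models)
  spread <- rep(0, nrow(tr$Y))
  for (q in seq_len(partition$Q)) {
    mem <- partition$clusters[[q]]
    if (length(mem) < 2) next
    cols <- lapply(mem, function(i) (i - 1) * n + seq_len(n))
    ref <- tr$Y[, cols[[1]], drop = FALSE]
    for (j in seq_along(mem)[-1]) {
      d <- abs(tr$Y[, cols[[j]], drop = FALSE] - ref)
      spread <- pmax(spread, apply(d, 1, max))
    }
  }
  hit_div <- which(spread > diverge_tol)
  hit_res <- which(spread < resync_tol)
  outcome <- if (length(hit_div) > 0) "diverge"
  else if (length(hit_res) > 0 && max(hit_res) == length(spread)) "resync"
  else "inconclusive"
  list(outcome = outcome, spread = spread, times = tr$times)
}
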