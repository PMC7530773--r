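# End-to-end case studies.
#
# Case study 1: the swim central pattern generator of the nudibranch
# Dendronotus iris -- six conductance-based neurons (three contralateral
# pairs Si1, Si2, Si3), coupled by dynamical inhibitory chemical synapses
# (layer 1), dynamical excitatory chemical synapses (layer 2) and electrical
# gap junctions (layer 3), all undelayed.
#
# Case study 2: a 29-area cortical connectivity network with Hindmarsh-Rose
# area dynamics and fast-threshold-modulation excitatory coupling, split
# into an undelayed short-range layer and a delayed long-range layer.
#
# The shipped coupling matrices are synthetic reconstructions: the original
# supplementary datasets are not redistributed here, so matrices were
# constructed to match every published structural property of the two
# circuits (cluster counts and sizes, directedness class, transverse block
# patterns, intertwining, disconnected nodes, quantized weight levels).
# See inst/extdata/README.md.

.extdata <- function(...) {
  p <- system.file("extdata", ..., package = "clustersync")
  if (p == "") stop("fixture not found: ", file.path(...))
  p
}

#' Coupling matrices of the swim CPG fixture
#'
#' @return list of three 6 x 6 matrices (inhibitory, excitatory,
#'   electrical), orientation `A[i, j]` = weight of j -> i.
#' @export
swim_cpg_matrices <- function() {
  lapply(c("swim_cpg_synthetic_A1.csv", "swim_cpg_synthetic_A2.csv",
           "swim_cpg_synthetic_A3.csv"),
         function(f) load_adjacency(.extdata(f)))
}

#' Build the swim CPG network
#'
#' @param sigma1 inhibitory coupling strength (nS; physiological 120).
#' @param sigma2 excitatory coupling strength (nS; physiological 100).
#' @param sigma3 electrical coupling strength (nS; default 0.1).
#' @param g_KCa calcium-activated potassium conductance of the neuron model
#'   (no established published value; default chosen so the isolated neuron
#'   oscillates).
#' @return a case-study bundle (list with `net`, `defaults` for the
#'   pipeline, `provenance`).
#' @export
build_swim_cpg <- function(sigma1 = 120, sigma2 = 100, sigma3 = 0.1,
                           g_KCa = NULL) {
  A <- swim_cpg_matrices()
  labels <- c("Si1L", "Si2L", "Si3L", "Si1R", "Si2R", "Si3R")
  mp <- if (is.null(g_KCa)) NULL else list(list(g_KCa = g_KCa))
  net <- mlnetwork(
    list(sync_layer(A[[1]], sigma = sigma1, delta = 0, kind = "inhibitory"),
         sync_layer(A[[2]], sigma = sigma2, delta = 0, kind = "excitatory"),
         sync_layer(A[[3]], sigma = sigma3, delta = 0, kind = "electrical")),
    node_type = rep(1L, 6), models = "swim", model_params = mp,
    labels = labels)
  structure(list(
    net = net,
    defaults = list(step = 0.01, transient = 10000, window = 20000,
                    mle_step = 0.01, save_every = 10L,
                    force_singleton = integer(0)),
    provenance = list(case = "swim_cpg",
                      sigma = c(sigma1, sigma2, sigma3),
                      fixtures = "swim_cpg_synthetic_A{1,2,3}.csv")),
    class = "case_study_bundle")
}

#' Area table of the cortical-network fixture
#'
#' @return data frame with `label` and `kind` (2 marks the visually driven
#'   area V1).
#' @export
macaque_areas <- function() {
  utils::read.csv(.extdata("macaque_synthetic_areas.csv"),
                  stringsAsFactors = FALSE)
}

#' Coupling matrices of the cortical-network fixture
#'
#' @return list of two 29 x 29 quantized matrices (undelayed short-range,
#'   delayed long-range), orientation `A[i, j]` = weight of j -> i.
#' @export
macaque_matrices <- function() {
  lapply(c("macaque_synthetic_A1.csv", "macaque_synthetic_A2.csv"),
         function(f) load_adjacency(.extdata(f)))
}

#' Build the cortical network
#'
#' @param delta2 delay of the long-range layer (ms, >= 0).
#' @param sigma coupling strength of both layers (the published analysis
#'   does not state it; the default reproduces the reported
#'   delay-dependent synchronization of the inferotemporal pair).
#' @return a case-study bundle; `isolated` lists the fully disconnected
#'   nodes (forced into trivial clusters by the pipeline), `roles` names
#'   the expected clusters (C1 input-free, C2 prefrontal pair, C3
#'   inferotemporal pair).
#' @export
build_macaque <- function(delta2 = 5, sigma = 0.25) {
  if (delta2 < 0) stop("negative delay")
  A <- macaque_matrices()
  ar <- macaque_areas()
  net <- mlnetwork(
    list(sync_layer(A[[1]], sigma = sigma, delta = 0, kind = "ftm"),
         sync_layer(A[[2]], sigma = sigma, delta = delta2, kind = "ftm")),
    node_type = ar$kind,
    models = c("hr", "hr"),
    model_params = list(hr_params(I = 2), hr_params(I = 3)),
    labels = ar$label)
  deg <- rowSums(abs(A[[1]])) + colSums(abs(A[[1]])) +
    rowSums(abs(A[[2]])) + colSums(abs(A[[2]]))
  isolated <- which(deg == 0)
  structure(list(
    net = net,
    isolated = isolated,
    defaults = list(step = 0.05, transient = 19500, window = 20000,
                    mle_step = 0.05, save_every = 5L,
                    force_singleton = isolated),
    provenance = list(case = "macaque", delta2 = delta2, sigma = sigma,
                      fixtures = "macaque_synthetic_A{1,2}.csv")),
    class = "case_study_bundle")
}

#' @export
print.case_study_bundle <- function(x, ...) {
  cat(sprintf("case study '%s'\n", x$provenance$case))
  print(x$net)
  invisible(x)
}

#' Run the full stability pipeline on a case-study bundle
#'
#' @param bundle from [build_swim_cpg()] or [build_macaque()].
#' @param transient,window,t_max,step,mle_step,save_every overrides of the
#'   bundle defaults.
#' @param seed RNG seed.
#' @param repeats random perturbations per block.
#' @return the bundle with `pipeline` (see [analyze_stability()]) and
#'   convenience fields `partition`, `dclass`, `report` filled in.
#' @export
run_case_study <- function(bundle, transient = NULL, window = NULL,
                           t_max = NULL, step = NULL, mle_step = NULL,
                           save_every = NULL, seed = 1, repeats = 3) {
  d <- bundle$defaults
  g <- function(x, dflt) if (is.null(x)) dflt else x
  pl <- analyze_stability(
    bundle$net,
    step = g(step, d$step),
    transient = g(transient, d$transient),
    window = g(window, d$window),
    t_max = g(t_max, g(window, d$window)),
    save_every = g(save_every, d$save_every),
    mle_step = g(mle_step, d$mle_step),
    seed = seed, repeats = repeats,
    force_singleton = d$force_singleton)
  bundle$pipeline <- pl
  bundle$partition <- pl$partition
  bundle$dclass <- pl$dclass
  bundle$report <- pl$report
  bundle
}

#' Identify the published cluster roles in a macaque partition
#'
#' C1 is the input-free pair, C2 the prefrontal pair (contains 8l), C3 the
#' inferotemporal pair (contains TEO).
#'
#' @param bundle a macaque bundle.
#' @param partition an `ml_partition` of its network.
#' @return named integer vector mapping role -> cluster id (NA when a role
#'   has no matching non-trivial cluster).
#' @export
macaque_cluster_roles <- function(bundle, partition) {
  labels <- bundle$net$labels
  nontrivial <- which(partition$sizes > 1)
  find_with <- function(lbl) {
    q <- partition$color[match(lbl, labels)]
    if (q %in% nontrivial) q else NA_integer_
  }
  indeg <- Reduce(`+`, lapply(bundle$net$layers, function(l) rowSums(abs(l$A))))
  c1 <- NA_integer_
  for (q in nontrivial)
    if (all(indeg[partition$clusters[[q]]] == 0)) { c1 <- q; break }
  c(C1 = c1, C2 = find_with("8l"), C3 = find_with("TEO"))
}

#' Quantize weights onto a fixed set of levels
#'
#' Each entry is replaced by the closest level (Euclidean distance); ties
#' go to the lower level by default.
#'
#' @param W non-negative weight matrix.
#' @param levels sorted ascending vector of levels.
#' @param tie_rule `"lower"` (default) or `"upper"`.
#' @return matrix of the same shape with entries drawn from `levels`.
#' @export
quantize_weights <- function(W, levels = c(0, 0.1, 0.5, 1),
                             tie_rule = c("lower", "upper")) {
  tie_rule <- match.arg(tie_rule)
  if (length(levels) == 0) stop("empty level set")
  levels <- sort(levels)
  idx <- vapply(as.vector(W), function(w) {
    d <- abs(w - levels)
    hits <- which(d <= min(d) + 1e-12)      # exact ties despite rounding
    if (tie_rule == "lower") hits[1] else hits[length(hits)]
  }, integer(1))
  matrix(levels[idx], nrow(W), ncol(W))
}

#' Split a weight matrix by connection length
#'
#' Connections shorter than the threshold go to the instantaneous layer,
#' the others to the delayed layer; the two parts sum to the input.
#'
#' @param W weight matrix.
#' @param D pairwise connection length matrix (same shape, mm).
#' @param threshold length threshold (default 20 mm); strictly shorter
#'   connections are instantaneous.
#' @return list with `A1` (short/undelayed) and `A2` (long/delayed).
#' @export
split_by_length <- function(W, D, threshold = 20) {
  if (!all(dim(W) == dim(D))) stop("weight and length matrices differ in shape")
  list(A1 = W * (D < threshold), A2 = W * (D >= threshold))
}

#' Firing-rate response to a current pulse
#'
#' Integrates the full network from the lifted synchronous state (after a
#' quotient transient), adds a square current pulse to one node, detects
#' spikes as upward threshold crossings of the membrane potential, and
#' returns per-node sliding-window firing rates.
#'
#' @param bundle a case-study bundle.
#' @param target_node node index (or label) receiving the pulse.
#' @param pulse list(onset, duration, amplitude) relative to the start of
#'   the observation window.
#' @param rate_window sliding window length for the rate estimate.
#' @param t_max observation horizon.
#' @param step,save_every integration step and storage decimation.
#' @param spike_threshold upward crossing level (default 1 for
#'   Hindmarsh-Rose, 0 mV for the swim model).
#' @param transient quotient pre-integration time.
#' @return list with `times` (rate grid), `rates` (grid x N matrix, spikes
#'   per time unit), `spikes` (per-node spike times).
#' @export
pulse_response <- function(bundle, target_node, pulse = list(onset = 500, duration = 50, amplitude = 1),
                           rate_window = 100, t_max = 3000, step = NULL,
                           save_every = NULL, spike_threshold = NULL,
                           transient = NULL) {
  d <- bundle$defaults
  g <- function(x, dflt) if (is.null(x)) dflt else x
  step <- g(step, d$step); save_every <- g(save_every, d$save_every)
  transient <- g(transient, d$transient)
  net <- bundle$net
  if (is.character(target_node)) target_node <- match(target_node, net$labels)
  if (is.na(target_node)) stop("unknown target node")
  if (is.null(spike_threshold))
    spike_threshold <- if ("swim" %in% net$models) 0 else 1
  partition <- refine_equitable(net, force_singleton = d$force_singleton)
  qnet <- quotient_network(net, partition)
  n <- .net_state_dim(net)
  trq <- integrate_network(qnet, initial_state(qnet), c(0, transient), step,
                           save_every = max(1L, as.integer(transient / step / 4)))
  X0 <- lift_state(partition, matrix(trq$Y[nrow(trq$Y), ], qnet$N, n, byrow = TRUE))
  tr <- integrate_network(net, X0, c(0, t_max), step, save_every = save_every,
                          pulse = list(node = target_node,
                                       onset = pulse$onset,
                                       duration = pulse$duration,
                                       amplitude = pulse$amplitude))
  V <- tr$Y[, (seq_len(net$N) - 1) * n + 1, drop = FALSE]
  spikes <- lapply(seq_len(net$N), function(i) {
    v <- V[, i]
    up <- which(v[-length(v)] < spike_threshold & v[-1] >= spike_threshold)
    tr$times[up + 1]
  })
  grid <- seq(tr$times[1] + rate_window, tr$times[length(tr$times)],
              by = rate_window / 5)
  rates <- vapply(spikes, function(sp)
    vapply(grid, function(tt) sum(sp > tt - rate_window & sp <= tt) / rate_window,
           numeric(1)),
    numeric(length(grid)))
  if (all(lengths(spikes) == 0)) warning("no spikes detected anywhere")
  list(times = grid, rates = rates, spikes = spikes)
}
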