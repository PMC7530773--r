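# Multi-layer network data model and I/O.
#
# Orientation convention: A[i, j] is the weight of the link j -> i, i.e. the
# row index is the postsynaptic (receiving) node.  This matches the equitable
# cluster condition, which constrains received inputs.  Node indices are
# 1-based and contiguous.

#' Construct a connection layer
#'
#' @param A N x N weight matrix, `A[i, j]` = weight of link j -> i.
#' @param sigma coupling strength multiplying the whole layer.
#' @param delta transmission delay (>= 0; same time unit as the models, ms).
#' @param kind coupling kind name (see [synapse_kinds()]).
#' @param kparams optional named overrides of the kind parameters.
#' @return object of class `sync_layer`.
#' @export
sync_layer <- function(A, sigma = 1, delta = 0, kind = "electrical",
                       kparams = NULL) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("layer matrix must be square")
  if (any(!is.finite(A))) stop("layer matrix contains non-finite weights")
  if (!is.finite(delta) || delta < 0) stop("negative or non-finite delay")
  kd <- .get_kind(kind)
  kp <- kd$kparams
  if (!is.null(kparams)) kp[names(kparams)] <- kparams
  structure(list(A = A, sigma = sigma, delta = delta, kind = kind,
                 kparams = kp),
            class = "sync_layer")
}

#' Construct a multi-layer network
#'
#' @param layers list of [sync_layer()] objects sharing one node count.
#' @param node_type integer vector of node types in 1..M (one model per
#'   type); defaults to all nodes of type 1.
#' @param models character vector mapping type -> neuron model name
#'   (defaults to "hr" for every type).
#' @param model_params optional list mapping type -> parameter list
#'   overriding the model defaults.
#' @param labels optional node names.
#' @param N node count, required when `layers` is empty.
#' @return object of class `mlnetwork`.
#' @export
mlnetwork <- function(layers, node_type = NULL, models = NULL,
                      model_params = NULL, labels = NULL, N = NULL) {
  if (length(layers) > 0) {
    Ns <- vapply(layers, function(l) nrow(l$A), integer(1))
    if (length(unique(Ns)) != 1) stop("layers disagree on node count")
    N <- Ns[1]
  } else if (is.null(N)) stop("N required for a network with no layers")
  if (is.null(node_type)) node_type <- rep(1L, N)
  node_type <- as.integer(node_type)
  if (length(node_type) != N) stop("node_type length mismatch")
  M <- max(node_type)
  if (!setequal(unique(node_type), seq_len(M)))
    stop("node types must be contiguous 1..M")
  if (is.null(models)) models <- rep("hr", M)
  if (length(models) != M) stop("need one model name per node type")
  for (m in models) .get_model(m)
  if (is.null(model_params)) model_params <- vector("list", M)
  if (!is.null(labels) && length(labels) != N) stop("labels length mismatch")
  structure(list(N = N, M = M, node_type = node_type, layers = layers,
                 models = models, model_params = model_params,
                 labels = labels),
            class = "mlnetwork")
}

#' @export
print.mlnetwork <- function(x, ...) {
  cat(sprintf("multi-layer network: N = %d nodes, M = %d type(s), L = %d layer(s)\n",
              x$N, x$M, length(x$layers)))
  for (k in seq_along(x$layers)) {
    l <- x$layers[[k]]
    cat(sprintf("  layer %d: kind = %s, sigma = %g, delta = %g, %d links\n",
                k, l$kind, l$sigma, l$delta, sum(l$A != 0)))
  }
  invisible(x)
}

#' Read an adjacency matrix from a headerless CSV file
#'
#' @param path CSV file with N rows x N columns of reals.
#' @param orientation `"targets"` (default) when file rows are receiving
#'   nodes, `"sources"` when file rows are sending nodes (the matrix is then
#'   transposed into the package convention).
#' @return N x N numeric matrix with `A[i, j]` = weight of j -> i.
#' @export
load_adjacency <- function(path, orientation = c("targets", "sources")) {
  orientation <- match.arg(orientation)
  df <- utils::read.csv(path, header = FALSE)
  A <- as.matrix(df)
  dimnames(A) <- NULL
  if (!is.numeric(A)) stop("non-numeric cell in adjacency file: ", path)
  if (nrow(A) != ncol(A)) stop("adjacency file is not square: ", path)
  if (orientation == "sources") A <- t(A)
  A
}

#' Write an adjacency matrix as headerless CSV
#'
#' Values are written with 17 significant digits so that a write/load round
#' trip reproduces every entry exactly.
#'
#' @param A square numeric matrix.
#' @param path output path.
#' @param orientation as in [load_adjacency()].
#' @export
write_adjacency <- function(A, path, orientation = c("targets", "sources")) {
  orientation <- match.arg(orientation)
  if (orientation == "sources") A <- t(A)
  lines <- apply(A, 1, function(r) paste(format(r, digits = 17, scientific = TRUE,
                                                trim = TRUE), collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Build a network from a configuration document
#'
#' The configuration is a list (or a JSON/YAML file parsing to one) with
#' fields `layers` (each with `file` or `A`, `sigma`, `delta`, `kind`),
#' `node_types`, `models`, `labels`.
#'
#' @param config list or path to a JSON/YAML file.
#' @param base_dir directory against which relative layer files are
#'   resolved (defaults to the config file's directory).
#' @return an [mlnetwork()].
#' @export
build_network <- function(config, base_dir = NULL) {
  if (is.character(config)) {
    path <- config
    if (is.null(base_dir)) base_dir <- dirname(path)
    config <- if (grepl("\\.ya?ml$", path)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("yaml package required for YAML configs")
      yaml::read_yaml(path)
    } else jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(base_dir)) base_dir <- "."
  if (is.data.frame(config$layers))
    config$layers <- lapply(seq_len(nrow(config$layers)),
                            function(i) as.list(config$layers[i, ]))
  layers <- lapply(config$layers, function(lc) {
    A <- if (!is.null(lc$A)) as.matrix(lc$A) else {
      f <- lc$file
      if (!file.exists(f)) f <- file.path(base_dir, lc$file)
      load_adjacency(f, orientation = if (is.null(lc$orientation)) "targets" else lc$orientation)
    }
    sync_layer(A, sigma = if (is.null(lc$sigma)) 1 else lc$sigma,
               delta = if (is.null(lc$delta)) 0 else lc$delta,
               kind = if (is.null(lc$kind)) "electrical" else lc$kind)
  })
  mlnetwork(layers,
            node_type = config$node_types,
            models = config$models,
            labels = config$labels,
            N = config$N)
}

#' Read a multi-layer edge list
#'
#' Tab-separated file with columns `src`, `dst`, `weight`, `layer` (header
#' optional); returns one adjacency matrix per layer in the package
#' orientation (`A[i, j]` = weight of j -> i).
#'
#' @param path TSV file.
#' @param N node count (defaults to the largest node index present).
#' @return named list of N x N matrices, one per layer id.
#' @export
load_edgelist <- function(path, N = NULL) {
  first <- readLines(path, n = 1)
  header <- grepl("src", first, fixed = TRUE)
  df <- utils::read.delim(path, header = header,
                          col.names = c("src", "dst", "weight", "layer"))
  if (is.null(N)) N <- max(df$src, df$dst)
  out <- lapply(split(df, df$layer), function(d) {
    A <- matrix(0, N, N)
    A[cbind(d$dst, d$src)] <- d$weight
    A
  })
  out
}

#' Per-layer symmetry test
#'
#' @param net an [mlnetwork()].
#' @param tol absolute tolerance on `max |A - t(A)|` (default 1e-9).
#' @return logical vector, one entry per layer.
#' @export
is_undirected <- function(net, tol = 1e-9) {
  vapply(net$layers, function(l) max(abs(l$A - t(l$A))) <= tol, logical(1))
}

# padded state dimension over the models present in a network
.net_state_dim <- function(net, models = neuron_models()) {
  max(vapply(net$models, function(m) .get_model(m, models)$n, integer(1)))
}

# per-node packed parameter vectors + model ids for the compiled core
.net_cpp_spec <- function(net, models = neuron_models(), kinds = synapse_kinds(),
                          pulse = NULL) {
  n <- .net_state_dim(net, models)
  mod_ids <- integer(net$N)
  params <- vector("list", net$N)
  for (i in seq_len(net$N)) {
    ty <- net$node_type[i]
    md <- .get_model(net$models[[ty]], models)
    p <- md$params
    ov <- net$model_params[[ty]]
    if (!is.null(ov)) p[names(ov)] <- ov
    mod_ids[i] <- md$cpp_id
    params[[i]] <- md$pack(p)
  }
  layers <- lapply(net$layers, function(l) {
    kd <- .get_kind(l$kind, kinds)
    list(A = l$A, sigma = l$sigma, delta = l$delta,
         kind = kd$cpp_id, kparams = as.numeric(l$kparams))
  })
  list(N = net$N, n = n, model = mod_ids, params = params, layers = layers,
       pulse = pulse)
}
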