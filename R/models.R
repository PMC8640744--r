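# The four regression architectures: linear, fully connected, sequence
# convolutional and graph convolutional. All take the L x (21+d) per-residue
# encoding, end in a single output node, and use leaky ReLU activations with
# 20% dropout ahead of the output. Convolutions are valid (no padding); the
# graph convolution is the order-independent operator in which all neighbor
# nodes share one weight matrix and their incoming signal is averaged.

#' Order-independent graph convolution at every node
#'
#' Computes, for each node i with feature vector `x_i` and neighbor set `N_i`,
#' `z_i = sigma(W_C' x_i + (1/|N_i|) * sum_{j in N_i} W_N' x_j + b)`,
#' where `W_C` is the center-node weight matrix, `W_N` the weight matrix
#' shared by all neighbor nodes, and the neighbor term is zero for isolated
#' nodes. This is the single-layer building block of the graph convolutional
#' network, exposed directly so it can be checked against a naive per-node
#' implementation.
#'
#' @param X `L x F` numeric matrix of node features.
#' @param g igraph structure graph with `L` nodes.
#' @param params List with `W_C` (`F x filters`), `W_N` (`F x filters`), `b`
#'   (length `filters`) and optionally `activation` (`"identity"` or
#'   `"leaky_relu"`, default identity) and `slope` (default 0.2).
#' @return `L x filters` matrix of node outputs.
#' @export
graph_conv_apply <- function(X, g, params) {
  stopifnot(is.matrix(X), nrow(X) == igraph::vcount(g),
            is.matrix(params$W_C), is.matrix(params$W_N))
  if (!identical(dim(params$W_C), dim(params$W_N)))
    stop("W_C and W_N must have the same shape")
  if (ncol(X) != nrow(params$W_C))
    stop("feature width ", ncol(X), " does not match W_C rows ",
         nrow(params$W_C))
  if (length(params$b) != ncol(params$W_C))
    stop("bias length must equal the number of filters")
  A <- graph_neighbor_weights(g)
  Z <- X %*% params$W_C + (A %*% X) %*% params$W_N
  Z <- sweep(Z, 2L, params$b, "+")
  act <- if (is.null(params$activation)) "identity" else params$activation
  if (act == "leaky_relu") {
    slope <- if (is.null(params$slope)) 0.2 else params$slope
    Z[Z < 0] <- slope * Z[Z < 0]
  } else if (act != "identity") stop("unknown activation: ", act)
  Z
}

#' Specify a model architecture
#'
#' @param architecture One of `"linear"`, `"fully_connected"`, `"seq_conv"`,
#'   `"graph_conv"`.
#' @param hidden Integer vector of hidden-layer widths for the fully
#'   connected network (default 100).
#' @param filters Filters per convolutional layer (default 16).
#' @param kernel Kernel width for the sequence convolution (default 5;
#'   convolutions are valid, so each layer shortens the sequence by
#'   `kernel - 1`).
#' @param n_conv_layers Number of convolutional layers (default 1). Graph
#'   layers all reuse the same graph topology.
#' @param include_final_dense Whether convolutional models get the final
#'   100-unit dense layer before the output node (default `TRUE`).
#' @param final_dense_width Width of that layer (default 100).
#' @param dropout Dropout probability before the output node (default 0.2).
#' @param leaky_slope Negative slope of the leaky ReLU (default 0.2).
#' @param graph igraph structure graph, required for `"graph_conv"`.
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(architecture = c("linear", "fully_connected",
                                        "seq_conv", "graph_conv"),
                       hidden = 100L, filters = 16L, kernel = 5L,
                       n_conv_layers = 1L, include_final_dense = TRUE,
                       final_dense_width = 100L, dropout = 0.2,
                       leaky_slope = 0.2, graph = NULL, seed = 1L) {
  architecture <- match.arg(architecture)
  if (architecture == "graph_conv" && is.null(graph))
    stop("graph_conv architecture requires a structure graph")
  stopifnot(dropout >= 0, dropout < 1)
  structure(list(architecture = architecture, hidden = as.integer(hidden),
                 filters = as.integer(filters), kernel = as.integer(kernel),
                 n_conv_layers = as.integer(n_conv_layers),
                 include_final_dense = isTRUE(include_final_dense),
                 final_dense_width = as.integer(final_dense_width),
                 dropout = dropout, leaky_slope = leaky_slope,
                 graph = graph, seed = as.integer(seed)),
            class = "model_spec")
}

.assemble_layers <- function(spec, L, in_features) {
  act <- function() layer_leaky_relu(spec$leaky_slope)
  layers <- list()
  cur_L <- L
  cur_F <- in_features
  flat <- FALSE
  if (spec$architecture == "linear") {
    layers <- list(layer_flatten(), layer_dense(L * in_features, 1L))
    return(layers)
  }
  if (spec$architecture == "fully_connected") {
    layers <- list(layer_flatten())
    width <- L * in_features
    for (h in spec$hidden) {
      layers <- c(layers, list(layer_dense(width, h), act(),
                               layer_dropout(spec$dropout)))
      width <- h
    }
    layers <- c(layers, list(layer_dense(width, 1L)))
    return(layers)
  }
  for (i in seq_len(spec$n_conv_layers)) {
    if (spec$architecture == "seq_conv") {
      if (cur_L < spec$kernel)
        stop("sequence too short for ", spec$n_conv_layers,
             " valid convolution layer(s) of kernel ", spec$kernel)
      layers <- c(layers, list(layer_seq_conv(spec$kernel, cur_F,
                                              spec$filters), act()))
      cur_L <- cur_L - spec$kernel + 1L
    } else {
      if (igraph::vcount(spec$graph) != L)
        stop("graph has ", igraph::vcount(spec$graph),
             " nodes but sequence length is ", L)
      A <- graph_neighbor_weights(spec$graph)
      layers <- c(layers, list(layer_graph_conv(cur_F, spec$filters, A),
                               act()))
    }
    cur_F <- spec$filters
  }
  layers <- c(layers, list(layer_flatten()))
  width <- cur_L * cur_F
  if (spec$include_final_dense) {
    layers <- c(layers, list(layer_dense(width, spec$final_dense_width),
                             act(), layer_dropout(spec$dropout)))
    width <- spec$final_dense_width
  }
  c(layers, list(layer_dense(width, 1L)))
}

#' Build an untrained model
#'
#' Parameters are drawn from a seeded uniform fan-in initializer, so two
#' builds with the same spec are identical.
#'
#' @param spec A [model_spec()].
#' @param L Sequence length.
#' @param in_features Encoding width per residue (21 + d).
#' @return An object of class `dms_model` with fields `spec`, `L`,
#'   `in_features`, `layers`, `n_params` and `trained`.
#' @export
build_model <- function(spec, L, in_features) {
  stopifnot(inherits(spec, "model_spec"))
  layers <- withr::with_seed(spec$seed, .assemble_layers(spec, L, in_features))
  n_params <- sum(vapply(layers, function(l)
    sum(vapply(.param_names(l), function(p) length(l[[p]]), numeric(1))),
    numeric(1)))
  structure(list(spec = spec, L = as.integer(L),
                 in_features = as.integer(in_features),
                 layers = layers, n_params = n_params, trained = FALSE,
                 history = NULL),
            class = "dms_model")
}

#' @export
print.dms_model <- function(x, ...) {
  cat(sprintf("<dms_model> %s, L = %d, %d input features/residue, %s params%s\n",
              x$spec$architecture, x$L, x$in_features,
              format(x$n_params, big.mark = ","),
              if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

#' Describe a model's layers
#'
#' @param m A `dms_model`.
#' @return A data.frame with one row per layer: kind and parameter count.
#' @export
model_describe <- function(m) {
  stopifnot(inherits(m, "dms_model"))
  data.frame(
    layer = seq_along(m$layers),
    kind = vapply(m$layers, `[[`, character(1), "kind"),
    n_params = vapply(m$layers, function(l)
      sum(vapply(.param_names(l), function(p) length(l[[p]]), numeric(1))),
      numeric(1)))
}

# Coerce prediction input: accept an encoding array (n,L,F), a single L x F
# matrix, or raw variant strings plus wt/proj attached to the call.
.as_batch <- function(X, m) {
  if (is.matrix(X)) {
    stopifnot(nrow(X) == m$L, ncol(X) == m$in_features)
    X <- array(X, dim = c(1L, nrow(X), ncol(X)))
  }
  d <- dim(X)
  if (length(d) != 3L || d[2] != m$L || d[3] != m$in_features)
    stop("input of dim (", paste(d, collapse = ","),
         ") does not match model (L = ", m$L, ", F = ", m$in_features, ")")
  X
}

#' Predict functional scores
#'
#' Dropout is disabled at prediction time; repeated calls give identical
#' results. Untrained models may be used (e.g. for testing) and predict from
#' their initial parameters.
#'
#' @param object A `dms_model`.
#' @param newdata Encoded batch array `(n, L, 21+d)` from [encode_variants()],
#'   or a single `L x (21+d)` matrix.
#' @param ... Unused.
#' @return Numeric vector of predicted scores (one per variant).
#' @export
predict.dms_model <- function(object, newdata, ...) {
  X <- .as_batch(newdata, object)
  nn_forward(object$layers, X)$pred
}

#' Save / load a model as portable JSON
#'
#' Serializes the architecture spec (graph as an edge list) and all layer
#' parameters to a single JSON file at full double precision.
#'
#' @param m A `dms_model`.
#' @param path JSON file path.
#' @return For `load_model`, the restored `dms_model`.
#' @export
save_model <- function(m, path) {
  stopifnot(inherits(m, "dms_model"))
  spec <- m$spec
  graph_edges <- NULL
  graph_kind <- NULL
  if (!is.null(spec$graph)) {
    e <- igraph::as_edgelist(spec$graph)
    mode(e) <- "integer"
    graph_edges <- e
    graph_kind <- igraph::graph_attr(spec$graph, "kind")
    spec$graph <- NULL
  }
  payload <- list(
    spec = unclass(spec), L = m$L, in_features = m$in_features,
    graph = if (is.null(graph_edges)) NULL else
      list(n = m$L, kind = graph_kind, edges = graph_edges),
    trained = m$trained,
    layers = lapply(m$layers, function(l) {
      keep <- setdiff(names(l), "A")
      l[keep]
    }))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  spec <- p$spec
  graph <- NULL
  if (!is.null(p$graph) && length(p$graph) > 0L) {
    edges <- matrix(as.integer(p$graph$edges), ncol = 2L)
    graph <- .new_structure_graph(
      igraph::make_graph(t(edges), n = p$graph$n, directed = FALSE),
      p$graph$kind)
  }
  spec <- model_spec(architecture = spec$architecture, hidden = spec$hidden,
                     filters = spec$filters, kernel = spec$kernel,
                     n_conv_layers = spec$n_conv_layers,
                     include_final_dense = spec$include_final_dense,
                     final_dense_width = spec$final_dense_width,
                     dropout = spec$dropout, leaky_slope = spec$leaky_slope,
                     graph = graph, seed = spec$seed)
  m <- build_model(spec, p$L, p$in_features)
  for (i in seq_along(m$layers)) {
    for (nm in .param_names(m$layers[[i]])) {
      v <- p$layers[[i]][[nm]]
      tmpl <- m$layers[[i]][[nm]]
      if (is.matrix(tmpl)) v <- matrix(as.numeric(v), nrow(tmpl), ncol(tmpl))
      else v <- as.numeric(v)
      m$layers[[i]][[nm]] <- v
    }
  }
  m$trained <- isTRUE(p$trained)
  m
}
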