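#' Steep sigmoid squashing function
#'
#' The activation function used throughout the package,
#' \eqn{\phi(x) = 2/(1 + e^{-kx}) - 1} with a steep default slope
#' \eqn{k = 32}, so that \eqn{\phi} behaves almost like a step function
#' while remaining differentiable.  Odd, bounded in \eqn{(-1, 1)}.
#'
#' @param x numeric vector.
#' @param slope positive slope constant \eqn{k} (default 32).
#' @return numeric vector of the same length, values in \eqn{(-1, 1)}.
#' @examples
#' steep_sigmoid(0)      # 0
#' steep_sigmoid(0.1)    # ~0.92167
#' @export
steep_sigmoid <- function(x, slope = 32) {
  # identical to 2/(1+exp(-slope*x)) - 1, but saturates without overflow
  tanh(0.5 * slope * x)
}

#' Network configuration
#'
#' Describes the fixed geometry of a spatially embedded, layered,
#' feed-forward network.  Defaults give the 33-node, five-layer topology
#' used in all experiments: layer sizes 5, 12, 8, 6, 2, layers placed at
#' y = 4 (input) down to y = 0 (output), and nodes within a layer centred
#' on x = 0 at unit spacing.
#'
#' @param layer_sizes integer vector of at least two positive layer sizes.
#' @param sigmoid_slope positive slope of [steep_sigmoid()].
#' @param layer_y y-coordinate per layer; must be strictly monotone.
#'   Default: input at the top, descending by 1 per layer to the output.
#' @param node_spacing horizontal distance between neighbouring nodes.
#' @return an object of class `network_config`.
#' @export
network_config <- function(layer_sizes = c(5L, 12L, 8L, 6L, 2L),
                           sigmoid_slope = 32,
                           layer_y = NULL,
                           node_spacing = 1) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L || any(is.na(layer_sizes)) || any(layer_sizes < 1L))
    stop("layer_sizes must contain at least two positive integers")
  if (!is.numeric(sigmoid_slope) || length(sigmoid_slope) != 1L || sigmoid_slope <= 0)
    stop("sigmoid_slope must be a single positive number")
  if (is.null(layer_y)) layer_y <- seq(length(layer_sizes) - 1, 0)
  if (length(layer_y) != length(layer_sizes))
    stop("layer_y must have one entry per layer")
  d <- diff(layer_y)
  if (any(d == 0) || !(all(d > 0) || all(d < 0)))
    stop("layer_y must be strictly monotone")
  if (!is.numeric(node_spacing) || node_spacing <= 0)
    stop("node_spacing must be positive")
  structure(
    list(layer_sizes = layer_sizes,
         sigmoid_slope = sigmoid_slope,
         layer_y = as.numeric(layer_y),
         node_spacing = as.numeric(node_spacing)),
    class = "network_config")
}

#' Node table implied by a network configuration
#'
#' Nodes are numbered layer by layer (input layer first) and left to right
#' within each layer.  Within a layer of k nodes the x-coordinates are
#' \code{(-(k-1)/2, ..., +(k-1)/2) * node_spacing}.
#'
#' @param config a [network_config()].
#' @return data.frame with columns `id`, `layer`, `x`, `y`.
#' @export
node_geometry <- function(config) {
  sizes <- config$layer_sizes
  layer <- rep(seq_along(sizes), sizes)
  x <- unlist(lapply(sizes, function(k) (seq_len(k) - 1 - (k - 1) / 2) * config$node_spacing))
  data.frame(id = seq_len(sum(sizes)),
             layer = layer,
             x = x,
             y = config$layer_y[layer])
}

#' Build a spatial feed-forward network
#'
#' Creates a network with biases drawn uniformly from \[-1, 1\], per-node
#' `modul` parameters drawn uniformly from \[0, 1\] and, with
#' `init = "full_adjacent"`, every adjacent-layer pair of nodes connected
#' with a weight drawn uniformly from \[-1, 1\] (216 connections at the
#' default topology).  Uses the R random number stream; call `set.seed()`
#' beforehand for reproducible builds.
#'
#' @param config a [network_config()].
#' @param init `"full_adjacent"` (adjacent layers fully connected) or
#'   `"empty"` (no connections).
#' @return an object of class `forage_network`: a list with elements
#'   `config`, `nodes` (data.frame `id`, `layer`, `x`, `y`, `bias`,
#'   `modul`) and `connections` (data.frame `source`, `target`, `weight`).
#' @export
build_network <- function(config = network_config(),
                          init = c("full_adjacent", "empty")) {
  init <- match.arg(init)
  nodes <- node_geometry(config)
  n <- nrow(nodes)
  nodes$bias <- runif(n, -1, 1)
  nodes$modul <- runif(n, 0, 1)
  if (init == "full_adjacent") {
    L <- length(config$layer_sizes)
    pairs <- do.call(rbind, lapply(seq_len(L - 1), function(l) {
      from <- nodes$id[nodes$layer == l]
      to <- nodes$id[nodes$layer == l + 1]
      expand.grid(source = from, target = to)
    }))
    conns <- data.frame(source = pairs$source, target = pairs$target,
                        weight = runif(nrow(pairs), -1, 1))
  } else {
    conns <- data.frame(source = integer(0), target = integer(0),
                        weight = numeric(0))
  }
  new_network(config, nodes, conns)
}

#' @noRd
new_network <- function(config, nodes, connections) {
  net <- structure(list(config = config, nodes = nodes,
                        connections = connections),
                   class = "forage_network")
  validate_network(net)
  net
}

#' Validate the feed-forward invariants of a network
#'
#' Checks that every connection runs from a lower to a strictly higher
#' layer, that no target is an input node, and that no (source, target)
#' pair is duplicated.
#'
#' @param net a `forage_network`.
#' @return `net`, invisibly; errors on violation.
#' @export
validate_network <- function(net) {
  nodes <- net$nodes
  cn <- net$connections
  if (nrow(cn)) {
    ls <- nodes$layer[match(cn$source, nodes$id)]
    lt <- nodes$layer[match(cn$target, nodes$id)]
    if (anyNA(ls) || anyNA(lt)) stop("connection refers to unknown node")
    if (any(ls >= lt)) stop("connections must be strictly feed-forward")
    if (any(lt == 1L)) stop("input nodes cannot receive connections")
    if (anyDuplicated(cn[c("source", "target")]))
      stop("duplicate connection")
  }
  if (any(nodes$modul < 0 | nodes$modul > 1)) stop("modul must lie in [0, 1]")
  invisible(net)
}

#' @export
print.forage_network <- function(x, ...) {
  cat(sprintf("<forage_network> %d nodes in %d layers (%s), %d connections\n",
              nrow(x$nodes), length(x$config$layer_sizes),
              paste(x$config$layer_sizes, collapse = "-"),
              nrow(x$connections)))
  invisible(x)
}

#' Which nodes act as modulatory nodes?
#'
#' Under standard (non-diffusion) neuromodulation a hidden node is
#' modulatory when its evolved `modul` parameter lies below the threshold
#' (default 0.4).  Input and output nodes never act as modulatory nodes,
#' and under diffusion-based neuromodulation the `modul` parameter is
#' inert, so no node is modulatory.
#'
#' @param net a `forage_network`.
#' @param treatment `"diffusion"` or `"standard"`.
#' @param modul_threshold threshold below which `modul` marks a hidden
#'   node as modulatory (default 0.4).
#' @return logical vector over nodes (in `net$nodes` order).
#' @export
is_modulatory <- function(net, treatment = c("diffusion", "standard"),
                          modul_threshold = 0.4) {
  treatment <- match.arg(treatment)
  if (treatment == "diffusion") return(rep(FALSE, nrow(net$nodes)))
  hidden <- net$nodes$layer > 1L &
    net$nodes$layer < length(net$config$layer_sizes)
  hidden & net$nodes$modul < modul_threshold
}

#' Node ids of the input layer / output layer
#' @param net a `forage_network`.
#' @return integer vector of node ids, in left-to-right order.
#' @export
input_ids <- function(net) net$nodes$id[net$nodes$layer == 1L]

#' @rdname input_ids
#' @export
output_ids <- function(net) {
  net$nodes$id[net$nodes$layer == length(net$config$layer_sizes)]
}

#' Single forward pass through a network
#'
#' Input nodes take the input values verbatim (no sigmoid, no bias).
#' Every other node i computes
#' \eqn{a_i = \phi(\sum_{j \in C_n} w_{ij} a_j + b_i)} layer by layer,
#' where \eqn{C_n} are its non-modulatory in-neighbours; activations of
#' modulatory nodes never enter these sums.
#'
#' @param net a `forage_network`.
#' @param input numeric vector, one value per input node.
#' @param treatment `"diffusion"` or `"standard"` (determines which nodes
#'   count as modulatory).
#' @param modul_threshold see [is_modulatory()].
#' @return numeric vector of per-node activations, in node-id order.
#' @export
forward_pass <- function(net, input, treatment = c("diffusion", "standard"),
                         modul_threshold = 0.4) {
  treatment <- match.arg(treatment)
  n_in <- net$config$layer_sizes[1]
  if (length(input) != n_in)
    stop(sprintf("input must have length %d", n_in))
  if (any(!is.finite(input))) stop("input contains non-finite values")
  mod <- is_modulatory(net, treatment, modul_threshold)
  cpp_forward(net$nodes$layer, net$nodes$bias, mod,
              net$connections$source, net$connections$target,
              net$connections$weight, as.numeric(input),
              net$config$sigmoid_slope)
}

# Plain-R reference forward pass, used as the independent oracle for the
# C++ engine in the test suite.
forward_pass_ref <- function(net, input, treatment = "diffusion",
                             modul_threshold = 0.4) {
  nodes <- net$nodes
  mod <- is_modulatory(net, treatment, modul_threshold)
  a <- numeric(nrow(nodes))
  a[nodes$layer == 1L] <- input
  cn <- net$connections
  for (l in seq(2L, length(net$config$layer_sizes))) {
    for (i in nodes$id[nodes$layer == l]) {
      inc <- cn[cn$target == i, , drop = FALSE]
      keep <- !mod[match(inc$source, nodes$id)]
      s <- sum(inc$weight[keep] * a[match(inc$source[keep], nodes$id)]) +
        nodes$bias[nodes$id == i]
      a[nodes$id == i] <- steep_sigmoid(s, net$config$sigmoid_slope)
    }
  }
  a
}

# Internal: nodes must be ordered by id == (layer, x) order; all package
# constructors guarantee this, deserialisation re-sorts.
assert_canonical <- function(net) {
  if (!identical(net$nodes$id, seq_len(nrow(net$nodes))))
    stop("network nodes are not in canonical id order")
  invisible(net)
}
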