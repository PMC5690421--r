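#' Serialize a network to JSON
#'
#' The canonical on-disk form of a network: configuration, node records
#' and connection records.  Round-trips losslessly through
#' [network_from_json()] (full double precision).
#'
#' @param net a `forage_network`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return the JSON string (invisibly when written to `path`).
#' @export
network_to_json <- function(net, path = NULL) {
  obj <- list(
    config = list(layer_sizes = net$config$layer_sizes,
                  sigmoid_slope = net$config$sigmoid_slope,
                  layer_y = net$config$layer_y,
                  node_spacing = net$config$node_spacing),
    nodes = net$nodes,
    connections = net$connections)
  js <- jsonlite::toJSON(obj, digits = NA, dataframe = "columns",
                         auto_unbox = FALSE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname network_to_json
#' @param json a JSON string or file path produced by [network_to_json()].
#' @export
network_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  config <- network_config(layer_sizes = obj$config$layer_sizes,
                           sigmoid_slope = obj$config$sigmoid_slope,
                           layer_y = obj$config$layer_y,
                           node_spacing = obj$config$node_spacing)
  nodes <- as.data.frame(obj$nodes)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  conns <- as.data.frame(obj$connections)
  if (!nrow(conns))
    conns <- data.frame(source = integer(0), target = integer(0),
                        weight = numeric(0))
  new_network(config, nodes, conns)
}

#' Convert a network (or CFN) to an igraph graph
#'
#' Node attributes `x`, `y`, `layer`, `bias`, `modul` and the edge
#' attribute `weight` are carried over; CFN edges additionally carry their
#' functional-module `label`.
#'
#' @param x a `forage_network` or `cfn` object.
#' @param directed logical; keep edge direction (default `TRUE`).
#' @param ... unused.
#' @return an [igraph::graph] object.
#' @export
as_igraph <- function(x, ...) UseMethod("as_igraph")

#' @rdname as_igraph
#' @export
as_igraph.forage_network <- function(x, directed = TRUE, ...) {
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = x$connections$source, to = x$connections$target,
                   weight = x$connections$weight),
    directed = directed,
    vertices = data.frame(name = x$nodes$id, layer = x$nodes$layer,
                          x = x$nodes$x, y = x$nodes$y,
                          bias = x$nodes$bias, modul = x$nodes$modul))
  g
}

#' Export a network to GraphML
#'
#' @param net a `forage_network` or `cfn`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
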