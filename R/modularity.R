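#' Newman modularity (Q-score)
#'
#' Scores the community structure of a network on its undirected,
#' unweighted projection.  With an explicit `partition` the Q of that
#' partition is returned; otherwise Q is maximized by greedy
#' agglomerative search (fast-greedy community detection) and the best
#' partition found is returned alongside its score.  Applied to a core
#' functional network this is the \emph{functional modularity} of the
#' underlying ANN.
#'
#' @param x a `forage_network`, `cfn`, or [igraph::graph] object.
#' @param partition optional membership: a named vector, or a vector in
#'   vertex order, mapping each node to a community id.
#' @return list with `q` (numeric; 0 for an edgeless graph by
#'   convention) and `partition` (integer membership named by node id).
#' @export
q_score <- function(x, partition = NULL) {
  g <- if (inherits(x, "igraph")) x else as_igraph(x)
  g <- igraph::as_undirected(g, mode = "collapse")
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if ("weight" %in% igraph::edge_attr_names(g))
    g <- igraph::delete_edge_attr(g, "weight")   # unweighted projection
  if (igraph::gsize(g) == 0L) {
    memb <- rep(1L, igraph::gorder(g))
    names(memb) <- igraph::V(g)$name
    return(list(q = 0, partition = memb))
  }
  if (!is.null(partition)) {
    if (!is.null(names(partition)))
      partition <- partition[igraph::V(g)$name]
    if (anyNA(partition) || length(partition) != igraph::gorder(g))
      stop("partition must assign every node of the scored graph")
    memb <- as.integer(factor(partition))
    q <- igraph::modularity(g, memb, weights = NULL)
  } else {
    cl <- igraph::cluster_fast_greedy(g, weights = NULL)
    memb <- igraph::membership(cl)
    q <- igraph::modularity(g, memb, weights = NULL)
  }
  memb <- as.integer(memb)
  names(memb) <- igraph::V(g)$name
  list(q = q, partition = memb)
}
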