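#' Standard error of regression between two activation series
#'
#' The knockout score: the root of the mean squared deviation between a
#' node's recorded activation and its recomputed (knockout) activation,
#' \eqn{\sqrt{\sum_i (y_i - \hat y_i)^2 / n}}.  Set `root = FALSE` for
#' the plain mean-squared reading.
#'
#' @param y,yhat equal-length numeric series.
#' @param root apply the square root (default `TRUE`).
#' @return a non-negative scalar.
#' @export
ser <- function(y, yhat, root = TRUE) {
  if (length(y) != length(yhat)) stop("series lengths differ")
  if (!length(y)) stop("zero-length activation record")
  m <- mean((y - yhat)^2)
  if (root) sqrt(m) else m
}

#' Bias-node detection
#'
#' Any node whose recorded activation has variance strictly below
#' `tol` (default 1e-9) is deemed to act as a bias node: its output is
#' effectively constant over the whole testing phase.
#'
#' @param record activation record matrix (rows = nodes, columns = steps).
#' @param tol variance threshold (strict `<`).
#' @return integer vector of node ids (row indices).
#' @export
detect_bias_nodes <- function(record, tol = 1e-9) {
  if (!nrow(record) || !ncol(record)) stop("empty activation record")
  v <- apply(record, 1, var)
  which(v < tol)
}

#' Knockout table for one node
#'
#' Enumerates all \eqn{2^p} kept-subsets of the p connections feeding
#' into a node.  For each subset the node's activation is recomputed at
#' every recorded step from the \emph{recorded} activations of its
#' in-neighbours (frozen-input semantics: knockouts do not propagate),
#' and scored by [ser()] against the node's recorded activation.
#' Contributions of modulatory in-neighbours are zero, as in the forward
#' pass.  Rows are sorted by SER ascending, ties broken by larger subset
#' first.
#'
#' @param net a `forage_network` (typically with learned weights).
#' @param record the testing-phase activation record for `net`.
#' @param node_id the node to analyse (non-input).
#' @param treatment,modul_threshold see [is_modulatory()].
#' @param cap maximum admissible in-degree (default 20); beyond it the
#'   \eqn{2^p} enumeration is refused with an error.
#' @param root see [ser()].
#' @return list with `table` (data.frame `mask`, `size`, `ser`, sorted),
#'   `incoming` (connection row indices in `net$connections`, the bit
#'   order of `mask`), and `node_id`.
#' @export
knockout_table <- function(net, record, node_id,
                           treatment = c("diffusion", "standard"),
                           modul_threshold = 0.4, cap = 20L, root = TRUE) {
  treatment <- match.arg(treatment)
  if (net$nodes$layer[node_id] == 1L)
    stop("input nodes have no incoming connections to knock out")
  inc <- which(net$connections$target == node_id)
  p <- length(inc)
  if (p > cap)
    stop(sprintf(
      "in-degree %d of node %d exceeds the knockout cap of %d (2^p blow-up)",
      p, node_id, cap))
  mod <- is_modulatory(net, treatment, modul_threshold)
  y <- record[node_id, ]
  contrib <- matrix(0, nrow = max(p, 0), ncol = ncol(record))
  for (k in seq_len(p)) {
    src <- net$connections$source[inc[k]]
    if (!mod[src])
      contrib[k, ] <- net$connections$weight[inc[k]] * record[src, ]
  }
  mse <- cpp_knockout_mse(contrib, y, net$nodes$bias[node_id],
                          net$config$sigmoid_slope)
  masks <- seq_len(2^p) - 1L
  sizes <- integer(length(masks))
  for (b in seq_len(p))
    sizes <- sizes + as.integer(bitwAnd(masks, bitwShiftL(1L, b - 1L)) > 0)
  s <- if (root) sqrt(mse) else mse
  tab <- data.frame(mask = masks, size = as.integer(sizes), ser = s)
  tab <- tab[order(tab$ser, -tab$size, tab$mask), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, incoming = inc, node_id = node_id)
}

# Select the smallest combination (fewest kept connections) whose SER is at
# or below the threshold; ties resolved by lower SER, then lower mask.
select_combination <- function(kt, threshold) {
  ok <- kt$table[kt$table$ser <= threshold, , drop = FALSE]
  if (!nrow(ok))
    stop("no knockout combination at or below the error threshold")
  ok <- ok[order(ok$size, ok$ser, ok$mask), , drop = FALSE]
  ok$mask[1]
}

# connection row indices kept by a mask, in incoming-bit order
mask_to_kept <- function(kt, mask) {
  p <- length(kt$incoming)
  if (!p) return(integer(0))
  bits <- bitwAnd(mask, bitwShiftL(1L, 0:(p - 1))) > 0
  kt$incoming[bits]
}

#' Extract one season's functional subnetwork
#'
#' Breadth-first traversal from the season's output node.  At each
#' visited node the smallest knockout combination with SER at or below
#' the error threshold is selected; its connections are kept and their
#' source nodes (in ascending id order) are enqueued.  Nodes never
#' reached, or whose selection is the empty combination, contribute no
#' incoming connections.
#'
#' @inheritParams knockout_table
#' @param season `"summer"` (left output) or `"winter"` (right output).
#' @param threshold non-negative error threshold.
#' @param cache optional environment used to memoise knockout tables
#'   across calls (as in the [build_cfn()] threshold search).
#' @return list with `kept` (connection row indices into
#'   `net$connections`), `nodes` (visited node ids), `season`,
#'   `threshold`.
#' @export
extract_subnetwork <- function(net, record, season = c("summer", "winter"),
                               threshold,
                               treatment = c("diffusion", "standard"),
                               modul_threshold = 0.4, cap = 20L,
                               root = TRUE, cache = NULL) {
  season <- match.arg(season)
  treatment <- match.arg(treatment)
  if (threshold < 0) stop("threshold must be non-negative")
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  start <- output_ids(net)[if (season == "summer") 1L else 2L]
  queue <- start
  visited <- integer(0)
  kept <- integer(0)
  while (length(queue)) {
    cur <- queue[1]
    queue <- queue[-1]
    if (cur %in% visited) next
    visited <- c(visited, cur)
    if (net$nodes$layer[cur] == 1L) next   # input nodes: nothing incoming
    key <- as.character(cur)
    kt <- cache[[key]]
    if (is.null(kt)) {
      kt <- knockout_table(net, record, cur, treatment, modul_threshold,
                           cap, root)
      cache[[key]] <- kt
    }
    sel <- mask_to_kept(kt, select_combination(kt, threshold))
    kept <- c(kept, sel)
    nxt <- sort(unique(net$connections$source[sel]))
    queue <- c(queue, nxt[!(nxt %in% visited)])
  }
  list(kept = sort(unique(kept)), nodes = sort(visited), season = season,
       threshold = threshold)
}

# all-kept recomputation error per non-input node (no 2^p enumeration);
# sets the lower bound of the threshold search
all_kept_ser <- function(net, record, treatment, modul_threshold, root = TRUE) {
  mod <- is_modulatory(net, treatment, modul_threshold)
  ids <- net$nodes$id[net$nodes$layer > 1L]
  vapply(ids, function(i) {
    inc <- which(net$connections$target == i)
    s <- rep(net$nodes$bias[i], ncol(record))
    for (k in inc) {
      src <- net$connections$source[k]
      if (!mod[src]) s <- s + net$connections$weight[k] * record[src, ]
    }
    ser(record[i, ], steep_sigmoid(s, net$config$sigmoid_slope), root)
  }, numeric(1))
}

#' Build the core functional network (CFN)
#'
#' Runs the full ARK procedure: starting from the smallest usable error
#' threshold (the largest all-kept recomputation error across nodes,
#' plus 1e-12), extract the summer and winter functional subnetworks,
#' union them into a pruned network, and evaluate its testing fitness on
#' the same environment.  The threshold is raised in steps of
#' `threshold_step` (default 0.01) and the last CFN found before fitness
#' first drops below the original testing fitness is returned, so the
#' CFN always possesses at least the fitness of the original network.
#' Connections present in both subnetworks form the common functional
#' module; the others are labeled by their season.
#'
#' @param net the learned `forage_network` (end of a training phase).
#' @param record the testing-phase activation record of `net`.
#' @param env the `forage_environment` shared by both phases.
#' @inheritParams simulate_lifetime
#' @inheritParams knockout_table
#' @param threshold_step increment of the threshold search (default 0.01).
#' @param max_threshold safety bound of the search (default 4.1, above
#'   the largest possible SER for activations in (-1, 1)).
#' @return an object of class `cfn`: `connections` (data.frame `source`,
#'   `target`, `weight`, `label` in summer/winter/common),
#'   `error_threshold`, `cfn_fitness`, `original_fitness`, `bias_nodes`,
#'   `summer_kept`/`winter_kept` (row indices into `net$connections`)
#'   and `network` (the pruned `forage_network`).
#' @export
build_cfn <- function(net, record, env,
                      treatment = c("diffusion", "standard"),
                      plasticity = plasticity_config(),
                      sources = point_sources(),
                      modul_threshold = 0.4, cap = 20L, root = TRUE,
                      threshold_step = 0.01, max_threshold = 4.1) {
  treatment <- match.arg(treatment)
  original <- simulate_lifetime(net, env, learning_on = FALSE,
                                treatment = treatment,
                                plasticity = plasticity, sources = sources,
                                modul_threshold = modul_threshold)$fitness
  cache <- new.env(parent = emptyenv())
  th <- max(all_kept_ser(net, record, treatment, modul_threshold, root)) + 1e-12
  best <- NULL
  repeat {
    su <- extract_subnetwork(net, record, "summer", th, treatment,
                             modul_threshold, cap, root, cache)
    wi <- extract_subnetwork(net, record, "winter", th, treatment,
                             modul_threshold, cap, root, cache)
    kept <- sort(unique(c(su$kept, wi$kept)))
    pruned <- net
    pruned$connections <- net$connections[kept, , drop = FALSE]
    rownames(pruned$connections) <- NULL
    fit <- simulate_lifetime(pruned, env, learning_on = FALSE,
                             treatment = treatment, plasticity = plasticity,
                             sources = sources,
                             modul_threshold = modul_threshold)$fitness
    if (fit >= original) {
      label <- ifelse(kept %in% su$kept & kept %in% wi$kept, "common",
                      ifelse(kept %in% su$kept, "summer", "winter"))
      best <- list(threshold = th, kept = kept, label = label,
                   summer_kept = su$kept, winter_kept = wi$kept,
                   fitness = fit, pruned = pruned)
    } else {
      break
    }
    if (!length(kept)) break           # nothing left to prune away
    th <- th + threshold_step
    if (th > max_threshold) break
  }
  if (is.null(best)) {
    # even the least aggressive simplification lost fitness: fall back to
    # the unpruned network (every connection common to both seasons)
    kept <- seq_len(nrow(net$connections))
    best <- list(threshold = NA_real_, kept = kept,
                 label = rep("common", length(kept)),
                 summer_kept = kept, winter_kept = kept,
                 fitness = original, pruned = net)
    warning("ARK could not simplify without losing fitness; returning the full network")
  }
  conns <- net$connections[best$kept, , drop = FALSE]
  conns$label <- best$label
  rownames(conns) <- NULL
  structure(list(connections = conns,
                 error_threshold = best$threshold,
                 cfn_fitness = best$fitness,
                 original_fitness = original,
                 bias_nodes = detect_bias_nodes(record),
                 summer_kept = best$summer_kept,
                 winter_kept = best$winter_kept,
                 network = best$pruned),
            class = "cfn")
}

#' @export
print.cfn <- function(x, ...) {
  cat(sprintf(
    "<cfn> %d connections (%d summer, %d winter, %d common) at threshold %.4g; fitness %.4f (original %.4f)\n",
    nrow(x$connections), sum(x$connections$label == "summer"),
    sum(x$connections$label == "winter"),
    sum(x$connections$label == "common"),
    x$error_threshold, x$cfn_fitness, x$original_fitness))
  invisible(x)
}

#' @rdname as_igraph
#' @export
as_igraph.cfn <- function(x, directed = TRUE, ...) {
  ids <- sort(unique(c(x$connections$source, x$connections$target)))
  nodes <- x$network$nodes[x$network$nodes$id %in% ids, , drop = FALSE]
  igraph::graph_from_data_frame(
    d = data.frame(from = x$connections$source, to = x$connections$target,
                   weight = x$connections$weight,
                   label = x$connections$label),
    directed = directed,
    vertices = data.frame(name = nodes$id, layer = nodes$layer,
                          x = nodes$x, y = nodes$y, bias = nodes$bias))
}

#' One-connection knockout validation of the functional modules
#'
#' For each functional-module label (plus a `random` class drawn from
#' all CFN connections) one uniformly chosen connection is removed from
#' the CFN and the testing phase is re-run; the per-season fitness shows
#' whether removing a summer (winter) connection hurts only the summer
#' (winter) task, while removing a common connection hurts both.
#'
#' @param cfn a [build_cfn()] result.
#' @param env the environment of the CFN's testing phase.
#' @inheritParams simulate_lifetime
#' @return data.frame with one row per class (`none` baseline, `random`,
#'   `common`, `summer`, `winter`): the removed connection and the
#'   resulting summer and winter fitness.  Empty classes are skipped
#'   with a message.
#' @export
knockout_validation <- function(cfn, env,
                                treatment = c("diffusion", "standard"),
                                plasticity = plasticity_config(),
                                sources = point_sources(),
                                modul_threshold = 0.4) {
  treatment <- match.arg(treatment)
  run <- function(netx) {
    r <- simulate_lifetime(netx, env, learning_on = FALSE,
                           treatment = treatment, plasticity = plasticity,
                           sources = sources,
                           modul_threshold = modul_threshold)
    c(summer = r$summer_fitness, winter = r$winter_fitness)
  }
  base <- run(cfn$network)
  rows <- list(data.frame(class = "none", source = NA_integer_,
                          target = NA_integer_, summer_fitness = base["summer"],
                          winter_fitness = base["winter"]))
  for (cls in c("random", "common", "summer", "winter")) {
    pool <- if (cls == "random") seq_len(nrow(cfn$connections))
            else which(cfn$connections$label == cls)
    if (!length(pool)) {
      message(sprintf("no %s-labeled connection to knock out; skipped", cls))
      next
    }
    j <- pool[sample.int(length(pool), 1L)]
    netx <- cfn$network
    key <- paste(netx$connections$source, netx$connections$target)
    drop <- which(key == paste(cfn$connections$source[j],
                               cfn$connections$target[j]))
    netx$connections <- netx$connections[-drop, , drop = FALSE]
    f <- run(netx)
    rows[[length(rows) + 1L]] <- data.frame(
      class = cls, source = cfn$connections$source[j],
      target = cfn$connections$target[j],
      summer_fitness = f["summer"], winter_fitness = f["winter"])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
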