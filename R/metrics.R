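#' Summarize seasonal-association probes
#'
#' Aggregates the end-of-season probes of one or more environments into
#' the forgetting metrics:
#' \itemize{
#'   \item \strong{Perfect}: number of season ends at which both the
#'     summer and the winter association were Known.
#'   \item \strong{Retained / Forgotten}: for each pair of consecutive
#'     season ends, an association Known at the earlier end is Retained
#'     if still Known at the later end, otherwise Forgotten (at most two
#'     per transition).
#'   \item \strong{Retained Percent}: 100 x Retained / Known, where
#'     Known counts the associations at risk of a transition (those
#'     Known at season ends 1 to 5), so Retained + Forgotten = Known.
#'     Defined as 0 when nothing was ever Known.
#' }
#'
#' @param probes a data.frame of probes for one environment (columns
#'   `knows_summer`, `knows_winter`, one row per season end, in order),
#'   or a list of such data.frames (one per environment).
#' @param n_envs optional expected number of environments (checked).
#' @return an object of class `assessment_summary` with fields
#'   `perfect_count`, `known_count`, `retained_count`, `forgotten_count`,
#'   `retained_percent`.
#' @export
summarize_assessments <- function(probes, n_envs = NULL) {
  if (is.data.frame(probes)) probes <- list(probes)
  if (!is.null(n_envs) && length(probes) != n_envs)
    stop(sprintf("expected %d environments, got %d", n_envs, length(probes)))
  perfect <- known <- retained <- forgotten <- 0L
  for (pr in probes) {
    ks <- pr$knows_summer
    kw <- pr$knows_winter
    perfect <- perfect + sum(ks & kw)
    s <- length(ks)
    if (s > 1L) {
      for (assoc in list(ks, kw)) {
        at_risk <- assoc[-s]
        still <- assoc[-1L]
        known <- known + sum(at_risk)
        retained <- retained + sum(at_risk & still)
        forgotten <- forgotten + sum(at_risk & !still)
      }
    }
  }
  structure(list(perfect_count = perfect,
                 known_count = known,
                 retained_count = retained,
                 forgotten_count = forgotten,
                 retained_percent =
                   if (known == 0L) 0 else 100 * retained / known),
            class = "assessment_summary")
}

#' @export
print.assessment_summary <- function(x, ...) {
  cat(sprintf(
    "<assessment_summary> Perfect %d | Known %d | Retained %d | Forgotten %d | Retained %% %.1f\n",
    x$perfect_count, x$known_count, x$retained_count, x$forgotten_count,
    x$retained_percent))
  invisible(x)
}

#' Seasonal weight change by functional module
#'
#' Joins the training-phase per-connection |dw| trace with the
#' functional-module labels of a core functional network from the same
#' environment, and reports, for each season type, the median summed
#' |dw| over the connections of each module.  Under diffusion this is
#' the task-specific localized-learning signature: summer-module
#' connections change in summer, winter-module connections in winter.
#'
#' @param weight_trace matrix of summed |dw|, one row per connection of
#'   the original network (in its connection order), one column per
#'   season block (as produced by [run_training_then_testing()]).
#' @param net the original `forage_network` the trace belongs to.
#' @param cfn a [build_cfn()] result for the same environment.
#' @return data.frame with columns `label`, `season`, `median_dw`,
#'   `n_connections`; the per-connection table is attached as attribute
#'   `"per_connection"`.
#' @export
weight_change_by_module <- function(weight_trace, net, cfn) {
  cn <- net$connections
  if (nrow(cn) != nrow(weight_trace))
    stop("weight_trace rows do not match the network's connections")
  key <- paste(cn$source, cn$target)
  ckey <- paste(cfn$connections$source, cfn$connections$target)
  if (!all(ckey %in% key))
    stop("CFN contains connections unknown to the traced network")
  label <- cfn$connections$label[match(key, ckey)]
  parity <- (seq_len(ncol(weight_trace)) - 1L) %% 2L
  per_conn <- data.frame(
    source = cn$source, target = cn$target, label = label,
    summer_dw = rowSums(weight_trace[, parity == 0L, drop = FALSE]),
    winter_dw = rowSums(weight_trace[, parity == 1L, drop = FALSE]))
  keep <- !is.na(per_conn$label)
  out <- do.call(rbind, lapply(c("summer", "winter", "common"), function(lb) {
    sub <- per_conn[keep & per_conn$label == lb, , drop = FALSE]
    data.frame(label = lb, season = c("summer", "winter"),
               median_dw = if (nrow(sub)) c(median(sub$summer_dw),
                                            median(sub$winter_dw)) else c(NA_real_, NA_real_),
               n_connections = nrow(sub))
  }))
  rownames(out) <- NULL
  attr(out, "per_connection") <- per_conn
  out
}
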