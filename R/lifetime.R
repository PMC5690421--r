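#' Simulate one foraging lifetime
#'
#' Runs a network through every presentation step of an environment.  At
#' each step the three food bits are placed on inputs 1-3 and the
#' one-step-delayed seasonal feedback on inputs 4 (summer) and 5
#' (winter); the off-season feedback input is 0, as is the first step of
#' each season.  The agent eats iff the current season's output
#' activation is strictly positive (left output in summer, right in
#' winter).  With `learning_on`, one neuromodulated Hebbian step follows
#' each forward pass; under the diffusion treatment the point-source
#' activations mirror the seasonal feedback inputs.  Fitness is
#' \deqn{0.5 + (nutritiousEaten - poisonousEaten) / totalFood.}
#'
#' @param net a `forage_network` with a 5-node input and 2-node output layer.
#' @param env a `forage_environment`.
#' @param learning_on logical; apply plasticity after each step.
#' @param treatment `"diffusion"` or `"standard"` neuromodulation.
#' @param plasticity a [plasticity_config()].
#' @param sources a [point_sources()] table (positions; activations are
#'   driven by the seasonal feedback during the run).
#' @param modul_threshold see [is_modulatory()].
#' @param record capture the per-node activation record (needed for ARK).
#' @param trace accumulate per-connection, per-season |dw| sums.
#' @return an object of class `lifetime_result`: fitness, eaten counts,
#'   behavior vector, per-season fitness, aggregate summer/winter
#'   fitness, the (possibly learned) network, and optional
#'   `activation_record` / `weight_trace`.
#' @export
simulate_lifetime <- function(net, env, learning_on = TRUE,
                              treatment = c("diffusion", "standard"),
                              plasticity = plasticity_config(),
                              sources = point_sources(),
                              modul_threshold = 0.4,
                              record = FALSE, trace = FALSE) {
  treatment <- match.arg(treatment)
  check_task_shape(net)
  steps <- env_steps(env)
  run_steps(net, steps, learning_on, treatment, plasticity, sources,
            modul_threshold, record, trace)
}

check_task_shape <- function(net) {
  sizes <- net$config$layer_sizes
  if (sizes[1] != 5L || sizes[length(sizes)] != 2L)
    stop("the foraging task needs a 5-input, 2-output network")
  assert_canonical(net)
  invisible(net)
}

# Run a (possibly partial) step table through the C++ engine.
run_steps <- function(net, steps, learning_on, treatment, plasticity,
                      sources, modul_threshold, record, trace) {
  nodes <- net$nodes
  mod <- is_modulatory(net, treatment, modul_threshold)
  foods <- steps$foods
  storage.mode(foods) <- "integer"
  outs <- output_ids(net)
  res <- cpp_lifetime(
    nodes$layer, nodes$x, nodes$y, nodes$bias, mod,
    net$connections$source, net$connections$target, net$connections$weight,
    foods, steps$season, steps$new_season, steps$block, steps$nutritious,
    steps$n_blocks,
    learning_on, treatment == "diffusion",
    plasticity$update_pairing == "eligibility",
    plasticity$learning_rate, plasticity$sigma, plasticity$radius_cutoff,
    falloff_prefactor(plasticity),
    ifelse(is.null(plasticity$weight_clamp), 0, plasticity$weight_clamp),
    !is.null(plasticity$weight_clamp),
    sources$x, sources$y, outs[1], outs[2],
    record, trace, net$config$sigmoid_slope)

  out_net <- net
  out_net$connections$weight <- res$weights
  blk_fit <- 0.5 + (res$block_nutritious - res$block_poisonous) / res$block_length
  parity <- (seq_len(steps$n_blocks) - 1L) %% 2L
  agg <- function(p) {
    sel <- parity == p
    0.5 + (sum(res$block_nutritious[sel]) - sum(res$block_poisonous[sel])) /
      sum(res$block_length[sel])
  }
  structure(list(
    fitness = res$fitness,
    nutritious_eaten = res$nutritious_eaten,
    poisonous_eaten = res$poisonous_eaten,
    total_food = res$total_food,
    behavior = res$behavior,
    per_season_fitness = blk_fit,
    summer_fitness = agg(0L),
    winter_fitness = agg(1L),
    network = out_net,
    activation_record = if (record) res$record else NULL,
    weight_trace = if (trace) res$trace else NULL),
    class = "lifetime_result")
}

#' @export
print.lifetime_result <- function(x, ...) {
  cat(sprintf(
    "<lifetime_result> fitness %.4f (%d nutritious, %d poisonous of %d)\n",
    x$fitness, x$nutritious_eaten, x$poisonous_eaten, x$total_food))
  invisible(x)
}

#' Probe whether a network knows a seasonal association
#'
#' With learning off and both feedback inputs at 0, each of the eight
#' food items is presented once and the season-appropriate output is
#' read.  The association is Known iff the network eats all four
#' nutritious items and none of the four poisonous ones under `rule`.
#'
#' @param net a `forage_network`.
#' @param rule the [season_rule()] to check against.
#' @param season `"summer"` (left output) or `"winter"` (right output).
#' @inheritParams simulate_lifetime
#' @return list with `knows` (logical) and `eats` (logical over the 8 items).
#' @export
probe_association <- function(net, rule, season = c("summer", "winter"),
                              treatment = c("diffusion", "standard"),
                              modul_threshold = 0.4) {
  season <- match.arg(season)
  treatment <- match.arg(treatment)
  items <- food_items()
  out_id <- output_ids(net)[if (season == "summer") 1L else 2L]
  eats <- vapply(seq_len(8), function(i) {
    a <- forward_pass(net, c(items[i, ], 0, 0), treatment, modul_threshold)
    a[out_id] > 0
  }, logical(1))
  list(knows = all(eats == is_nutritious(items, rule)), eats = eats)
}

#' Training phase followed by testing phase
#'
#' The training phase runs a full lifetime from the network's evolved
#' weights with learning on; at the end of each of the six seasons the
#' network is probed (learning off, feedback inputs 0) for both seasonal
#' associations.  The testing phase then replays the same environment on
#' the learned weights with learning off, capturing the activation
#' record that the ARK analysis operates on.
#'
#' @inheritParams simulate_lifetime
#' @param trace accumulate the per-connection, per-season |dw| trace
#'   during training (used by [weight_change_by_module()]).
#' @return list with elements `train` and `test` (both
#'   `lifetime_result`), `learned_network`, and `probes` (data.frame
#'   `season_index` 0-5, `season`, `knows_summer`, `knows_winter`).
#' @export
run_training_then_testing <- function(net, env,
                                      treatment = c("diffusion", "standard"),
                                      plasticity = plasticity_config(),
                                      sources = point_sources(),
                                      modul_threshold = 0.4,
                                      trace = TRUE) {
  treatment <- match.arg(treatment)
  check_task_shape(net)
  steps <- env_steps(env)
  nb <- steps$n_blocks
  cur <- net
  probes <- vector("list", nb)
  seg_counts <- matrix(0L, nb, 3)
  behavior <- integer(0)
  tr <- if (trace) matrix(0, nrow(net$connections), nb) else NULL
  for (b in seq_len(nb) - 1L) {
    sel <- steps$block == b
    seg <- list(foods = steps$foods[sel, , drop = FALSE],
                season = steps$season[sel],
                new_season = steps$new_season[sel],
                block = rep(0L, sum(sel)),
                nutritious = steps$nutritious[sel],
                n_steps = sum(sel), n_blocks = 1L)
    res <- run_steps(cur, seg, TRUE, treatment, plasticity, sources,
                     modul_threshold, record = FALSE, trace = trace)
    cur <- res$network
    seg_counts[b + 1L, ] <- c(res$nutritious_eaten, res$poisonous_eaten,
                              res$total_food)
    behavior <- c(behavior, res$behavior)
    if (trace) tr[, b + 1L] <- res$weight_trace[, 1L]
    probes[[b + 1L]] <- data.frame(
      season_index = b,
      season = if (b %% 2L == 0L) "summer" else "winter",
      knows_summer = probe_association(cur, env$summer_rule, "summer",
                                       treatment, modul_threshold)$knows,
      knows_winter = probe_association(cur, env$winter_rule, "winter",
                                       treatment, modul_threshold)$knows)
  }
  nut <- sum(seg_counts[, 1]); poi <- sum(seg_counts[, 2])
  total <- sum(seg_counts[, 3])
  parity <- (seq_len(nb) - 1L) %% 2L
  agg <- function(p) {
    sel <- parity == p
    0.5 + (sum(seg_counts[sel, 1]) - sum(seg_counts[sel, 2])) /
      sum(seg_counts[sel, 3])
  }
  train <- structure(list(
    fitness = 0.5 + (nut - poi) / total,
    nutritious_eaten = nut, poisonous_eaten = poi, total_food = total,
    behavior = behavior,
    per_season_fitness = 0.5 + (seg_counts[, 1] - seg_counts[, 2]) / seg_counts[, 3],
    summer_fitness = agg(0L), winter_fitness = agg(1L),
    network = cur,
    activation_record = NULL,
    weight_trace = tr), class = "lifetime_result")
  test <- simulate_lifetime(cur, env, learning_on = FALSE,
                            treatment = treatment, plasticity = plasticity,
                            sources = sources,
                            modul_threshold = modul_threshold, record = TRUE)
  list(train = train, test = test, learned_network = cur,
       probes = do.call(rbind, probes))
}
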