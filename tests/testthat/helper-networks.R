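# Hand-built fixture networks, all constructed in code at test time.

# a network that never eats: zero weights, -1 bias on both outputs
never_eat_network <- function() {
  net <- build_network(init = "empty")
  net$nodes$bias[] <- 0
  net$nodes$modul[] <- 1
  net$nodes$bias[output_ids(net)] <- -1
  net
}

# a network that eats every item: +1 bias on both outputs
eat_all_network <- function() {
  net <- never_eat_network()
  net$nodes$bias[output_ids(net)] <- 1
  net
}

# fixed policy implementing both seasonal rules: each output wired
# directly to its season's decision-bit input with the rule's polarity
dual_rule_network <- function(summer_rule, winter_rule) {
  net <- build_network(init = "empty")
  net$nodes$bias[] <- 0
  net$nodes$modul[] <- 1
  outs <- output_ids(net)
  net$connections <- data.frame(
    source = c(summer_rule$decision_bit + 1L, winter_rule$decision_bit + 1L),
    target = outs,
    weight = c(summer_rule$nutritious_value, winter_rule$nutritious_value))
  validate_network(net)
}

# fixed policy applying one rule on both outputs (eats iff the item
# matches `rule`, in either season)
single_rule_network <- function(rule) {
  net <- build_network(init = "empty")
  net$nodes$bias[] <- 0
  net$nodes$modul[] <- 1
  net$connections <- data.frame(
    source = rep(rule$decision_bit + 1L, 2),
    target = output_ids(net),
    weight = rep(rule$nutritious_value, 2))
  validate_network(net)
}

# random sparse network on the default geometry
random_sparse_network <- function(n_conn = 10) {
  net <- build_network(init = "empty")
  lp <- neuroforage:::legal_pairs(net$nodes)
  pick <- lp[sample.int(nrow(lp), n_conn), ]
  net$connections <- data.frame(source = pick$source, target = pick$target,
                                weight = runif(n_conn, -1, 1))
  validate_network(net)
}

# Plain-R reference lifetime simulation built from the exported per-step
# operations; the independent oracle for the C++ engine.
simulate_lifetime_ref <- function(net, env, learning_on = TRUE,
                                  treatment = "diffusion",
                                  plasticity = plasticity_config(),
                                  modul_threshold = 0.4) {
  steps <- neuroforage:::env_steps(env)
  eligibility <- plasticity$update_pairing == "eligibility"
  outs <- output_ids(net)
  fb <- 0
  prev_a <- NULL
  nut <- 0L
  poi <- 0L
  behavior <- integer(steps$n_steps)
  for (t in seq_len(steps$n_steps)) {
    if (steps$new_season[t]) {
      fb <- 0
      prev_a <- NULL
    }
    sfb <- if (steps$season[t] == 0L) fb else 0
    wfb <- if (steps$season[t] == 1L) fb else 0
    input <- c(steps$foods[t, ], sfb, wfb)
    a <- forward_pass(net, input, treatment, modul_threshold)
    eat <- if (steps$season[t] == 0L) a[outs[1]] > 0 else a[outs[2]] > 0
    behavior[t] <- as.integer(eat)
    if (eat) {
      if (steps$nutritious[t]) nut <- nut + 1L else poi <- poi + 1L
    }
    if (learning_on && (!eligibility || !is.null(prev_a))) {
      m <- if (treatment == "diffusion") {
        diffusion_modulation(net, point_sources(summer_activation = sfb,
                                                winter_activation = wfb),
                             plasticity)
      } else {
        standard_modulation(net, a, modul_threshold)
      }
      hebb_a <- if (eligibility) prev_a else a
      net <- apply_learning_step(net, m, hebb_a, plasticity, treatment,
                                 modul_threshold)
    }
    fb <- if (eat) (if (steps$nutritious[t]) 1 else -1) else 0
    prev_a <- a
  }
  list(fitness = 0.5 + (nut - poi) / steps$n_steps,
       nutritious_eaten = nut, poisonous_eaten = poi,
       behavior = behavior, network = net)
}
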