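test_that("seasonal rules classify the 3-bit foods as stated", {
  rule <- season_rule(0, -1)
  expect_true(is_nutritious(c(-1, 1, 1), rule))
  expect_false(is_nutritious(c(1, 1, 1), rule))
  # every rule splits the eight items 4/4
  for (bit in 0:2) {
    for (val in c(-1, 1)) {
      expect_equal(sum(is_nutritious(food_items(), season_rule(bit, val))), 4)
    }
  }
})

test_that("environment generation is uniform over rules and day orders", {
  set.seed(17)
  env <- generate_environment()
  expect_equal(nrow(env$order), 30)                  # 3 years x 2 x 5 days
  expect_true(all(apply(env$order, 1, function(r) setequal(r, 1:8))))
  # probability both seasons share the same rule: exhaustive count over
  # the 6 x 6 equally likely rule pairs gives 6/36 = 1/6
  rules <- expand.grid(bit = 0:2, val = c(-1, 1))
  same <- outer(seq_len(6), seq_len(6), Vectorize(function(i, j)
    rules$bit[i] == rules$bit[j] && rules$val[i] == rules$val[j]))
  expect_equal(mean(same), 1 / 6)
  # and empirically the generator matches that rate
  set.seed(18)
  hits <- mean(replicate(2000, {
    e <- generate_environment(years = 1, days_per_season = 1)
    e$summer_rule$decision_bit == e$winter_rule$decision_bit &&
      e$summer_rule$nutritious_value == e$winter_rule$nutritious_value
  }))
  expect_lt(abs(hits - 1 / 6), 0.03)
})

test_that("environment JSON round-trips exactly", {
  set.seed(19)
  env <- generate_environment()
  back <- environment_from_json(environment_to_json(env))
  expect_equal(back$order, env$order)
  expect_equal(back$summer_rule, env$summer_rule)
  expect_equal(back$winter_rule, env$winter_rule)
})

test_that("lifetime fitness anchors: never eat, eat all, oracle", {
  set.seed(20)
  env <- generate_environment()
  # base fitness: an agent that never eats scores exactly 0.5
  expect_identical(simulate_lifetime(never_eat_network(), env)$fitness, 0.5)
  # eating every item nets 4 nutritious - 4 poisonous per day: still 0.5
  expect_identical(simulate_lifetime(eat_all_network(), env)$fitness, 0.5)
  # a policy implementing both rules scores exactly 1
  oracle <- dual_rule_network(env$summer_rule, env$winter_rule)
  r <- simulate_lifetime(oracle, env, learning_on = FALSE)
  expect_identical(r$fitness, 1)
  expect_equal(r$nutritious_eaten, 120)
  expect_equal(r$poisonous_eaten, 0)
  expect_equal(r$total_food, 240)
})

test_that("single-season policy scores exactly 0.75 whenever decision bits differ", {
  # exhaustive over all rule pairs with distinct decision bits
  for (sb in 0:2) for (sv in c(-1, 1)) for (wb in setdiff(0:2, sb)) {
    for (wv in c(-1, 1)) {
      set.seed(21)
      env <- make_environment(season_rule(sb, sv), season_rule(wb, wv))
      pol <- single_rule_network(env$winter_rule)
      r <- simulate_lifetime(pol, env, learning_on = FALSE)
      expect_identical(r$fitness, 0.75)
      expect_identical(r$winter_fitness, 1)
      expect_identical(r$summer_fitness, 0.5)
    }
  }
})

test_that("identical (network, environment) gives identical results", {
  set.seed(22)
  net <- build_network()
  env <- generate_environment()
  r1 <- simulate_lifetime(net, env, TRUE, "diffusion")
  r2 <- simulate_lifetime(net, env, TRUE, "diffusion")
  expect_identical(r1$behavior, r2$behavior)
  expect_identical(r1$network$connections$weight,
                   r2$network$connections$weight)
})

test_that("off-season feedback and rule changes cannot affect summer behavior", {
  set.seed(23)
  net <- build_network()
  env1 <- generate_environment()
  env2 <- env1
  env2$winter_rule <- season_rule(
    (env1$winter_rule$decision_bit + 1) %% 3, -env1$winter_rule$nutritious_value)
  r1 <- simulate_lifetime(net, env1, TRUE, "diffusion")
  r2 <- simulate_lifetime(net, env2, TRUE, "diffusion")
  steps <- neuroforage:::env_steps(env1)
  first_summer <- steps$block == 0L
  expect_identical(r1$behavior[first_summer], r2$behavior[first_summer])
})

test_that("feedback inputs carry the previous item's outcome with a season reset", {
  set.seed(24)
  env <- generate_environment()
  steps <- neuroforage:::env_steps(env)
  r <- simulate_lifetime(eat_all_network(), env, learning_on = FALSE,
                         record = TRUE)
  rec <- r$activation_record
  expected_fb <- numeric(steps$n_steps)
  for (t in seq_len(steps$n_steps)) {
    expected_fb[t] <- if (steps$new_season[t]) 0 else
      ifelse(steps$nutritious[t - 1], 1, -1)   # it always eats
  }
  summer_row <- rec[4, ]
  winter_row <- rec[5, ]
  expect_equal(summer_row[steps$season == 0L],
               expected_fb[steps$season == 0L])
  expect_equal(winter_row[steps$season == 1L],
               expected_fb[steps$season == 1L])
  # off-season feedback inputs are silent
  expect_identical(summer_row[steps$season == 1L],
                   rep(0, sum(steps$season == 1L)))
  expect_identical(winter_row[steps$season == 0L],
                   rep(0, sum(steps$season == 0L)))
})

test_that("probes read stored knowledge with silent feedback", {
  set.seed(25)
  env <- make_environment(season_rule(0, -1), season_rule(1, 1))
  oracle <- dual_rule_network(env$summer_rule, env$winter_rule)
  expect_true(probe_association(oracle, env$summer_rule, "summer")$knows)
  expect_true(probe_association(oracle, env$winter_rule, "winter")$knows)
  expect_false(probe_association(oracle, season_rule(2, 1), "summer")$knows)
  ne <- never_eat_network()
  expect_false(probe_association(ne, env$summer_rule, "summer")$knows)
})

test_that("training-then-testing wires the phases together", {
  set.seed(26)
  env <- make_environment(season_rule(0, -1), season_rule(1, 1))
  oracle <- dual_rule_network(env$summer_rule, env$winter_rule)
  res <- run_training_then_testing(oracle, env, "diffusion")
  # a dual-rule policy is already perfect: training == testing == 1
  expect_identical(res$test$fitness, 1)
  expect_identical(res$train$fitness, 1)
  expect_true(all(res$probes$knows_summer))
  expect_true(all(res$probes$knows_winter))
  expect_equal(res$probes$season_index, 0:5)
  # the testing phase captured a full activation record
  expect_equal(dim(res$test$activation_record), c(33, 240))
  expect_true(all(abs(res$test$activation_record) <= 1))
  # weight trace exists, one column per season
  expect_equal(dim(res$train$weight_trace), c(2, 6))
  # training equals testing for a static network: learned weights unchanged
  expect_identical(res$learned_network$connections$weight,
                   oracle$connections$weight)
})
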