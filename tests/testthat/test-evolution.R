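test_that("mutation with all rates zero leaves the genome unchanged", {
  set.seed(29)
  net <- build_network()
  cfg <- evolution_config(p_add = 0, p_remove = 0, p_reassign = 0,
                          weight_rate_numerator = 0, p_bias = 0, p_modul = 0)
  expect_identical(mutate_genome(net, cfg), net)
})

test_that("weight mutations occur 2/n per connection on average", {
  set.seed(30)
  net <- build_network()
  cfg <- evolution_config(p_add = 0, p_remove = 0, p_reassign = 0,
                          p_bias = 0, p_modul = 0)
  counts <- replicate(2000, {
    m <- mutate_genome(net, cfg)
    sum(m$connections$weight != net$connections$weight)
  })
  # expected count is n * (2/n) = 2; MC tolerance ~5 sd of the mean
  expect_lt(abs(mean(counts) - 2), 0.17)
})

test_that("mutation preserves the feed-forward invariants and bounds", {
  set.seed(31)
  net <- build_network()
  cfg <- evolution_config()
  for (i in 1:300) {
    net <- mutate_genome(net, cfg)
  }
  expect_silent(validate_network(net))
  expect_true(all(net$connections$weight >= -1 & net$connections$weight <= 1))
  expect_true(all(net$nodes$bias >= -1 & net$nodes$bias <= 1))
  expect_true(all(net$nodes$modul >= 0 & net$nodes$modul <= 1))
  expect_true(nrow(net$connections) <=
                nrow(neuroforage:::legal_pairs(net$nodes)))
})

test_that("add-connection skips silently on a saturated network", {
  set.seed(32)
  net <- build_network(init = "empty")
  lp <- neuroforage:::legal_pairs(net$nodes)
  net$connections <- data.frame(source = lp$source, target = lp$target,
                                weight = runif(nrow(lp), -1, 1))
  cfg <- evolution_config(p_add = 1, p_remove = 0, p_reassign = 0,
                          weight_rate_numerator = 0, p_bias = 0, p_modul = 0)
  m <- mutate_genome(net, cfg)
  expect_equal(nrow(m$connections), nrow(lp))
  # and on an empty network, add with probability 1 adds exactly one
  e <- build_network(init = "empty")
  m2 <- mutate_genome(e, cfg)
  expect_equal(nrow(m2$connections), 1)
})

test_that("crossing the modul threshold flips a hidden node's role", {
  set.seed(33)
  net <- build_network()
  net$nodes$modul[] <- 1
  net$nodes$modul[10] <- 0.39
  expect_true(is_modulatory(net, "standard")[10])
  net$nodes$modul[10] <- 0.41
  expect_false(is_modulatory(net, "standard")[10])
})

test_that("behavioral diversity is the mean normalised Hamming distance", {
  b <- matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE)  # identical rows
  b <- rbind(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(behavioral_diversity(b), c(0, 0))
  comp <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))     # complementary pair
  expect_equal(behavioral_diversity(comp), c(1, 1))
  set.seed(34)
  m <- matrix(rbinom(60, 1, 0.5), 6, 10)
  d <- behavioral_diversity(m)
  p <- sample.int(6)
  expect_equal(behavioral_diversity(m[p, ]), d[p])  # permutation equivariant
})

test_that("non-dominated sorting ranks Pareto fronts correctly", {
  obj <- rbind(c(2, 2), c(1, 3), c(3, 1),   # front 1 (mutually non-dominated)
               c(1, 1), c(2, 0),            # front 2
               c(0, 0))                     # front 3
  ns <- nondominated_sort(obj)
  expect_equal(ns$rank, c(1, 1, 1, 2, 2, 3))
  # brute-force check: nobody in front 1 is dominated
  for (i in ns$fronts[[1]]) {
    for (j in seq_len(nrow(obj))) {
      expect_false(all(obj[j, ] >= obj[i, ]) && any(obj[j, ] > obj[i, ]))
    }
  }
})

test_that("selection is elitist: a dominating genome outlives the dominated", {
  set.seed(35)
  for (i in 1:20) {
    obj <- matrix(runif(40), 20, 2)
    sel <- neuroforage:::pnsga_select(obj, 10)$indices
    out <- setdiff(seq_len(20), sel)
    for (o in out) {
      dominates_survivor <- vapply(sel, function(s)
        all(obj[o, ] >= obj[s, ]) && any(obj[o, ] > obj[s, ]), logical(1))
      expect_false(any(dominates_survivor))
    }
  }
})

test_that("with one informative objective selection is fitness truncation", {
  obj <- cbind(performance = c(0.9, 0.1, 0.5, 0.7, 0.3),
               diversity = rep(0.5, 5))
  sel <- neuroforage:::pnsga_select(obj, 2)$indices
  expect_setequal(sel, c(1, 4))
})

test_that("the cost objective enters selection 75% of the time", {
  set.seed(36)
  pop <- lapply(1:4, function(i) build_network(init = "empty"))
  obj <- cbind(performance = runif(4), diversity = runif(4), cost = 1:4)
  cfg <- evolution_config(population_size = 4)
  freq <- mean(replicate(10000,
    pnsga_generation(pop, obj, cfg, "PCC", n_offspring = 0)$cost_included))
  expect_lt(abs(freq - 0.75), 0.015)
  # PA treatments never include it
  expect_false(any(replicate(50,
    pnsga_generation(pop, obj, cfg, "PA", n_offspring = 0)$cost_included)))
})

test_that("inclusion probability one reduces PNSGA to plain NSGA-II", {
  set.seed(37)
  pop <- lapply(1:6, function(i) build_network(init = "empty"))
  obj <- cbind(performance = runif(6), diversity = runif(6),
               cost = sample(1:6))
  cfg <- evolution_config(population_size = 3, cost_probability = 1)
  g1 <- pnsga_generation(pop, obj, cfg, "PCC", n_offspring = 0)
  expect_true(g1$cost_included)
  # deterministic NSGA-II on the same objectives selects the same set
  sel <- neuroforage:::pnsga_select(
    cbind(obj[, 1:2], cost = -obj[, 3]), 3)$indices
  expect_equal(g1$indices, sel)
})

test_that("evolution is reproducible and archives its champion", {
  cfg <- evolution_config(population_size = 8, generations = 3,
                          n_lifetimes = 2)
  set.seed(38)
  a1 <- evolve("PA_D", cfg)
  set.seed(38)
  a2 <- evolve("PA_D", cfg)
  expect_identical(a1$history, a2$history)
  expect_identical(a1$champion$connections$weight,
                   a2$champion$connections$weight)
  expect_equal(nrow(a1$history), 3)
  expect_true(a1$champion_fitness >= 0 && a1$champion_fitness <= 1)
  # zero generations: archive holds the untouched random population
  set.seed(39)
  a0 <- evolve("PA", evolution_config(population_size = 5, generations = 0))
  expect_equal(length(a0$population), 5)
  expect_equal(nrow(a0$history), 0)
  expect_null(a0$champion)
})
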