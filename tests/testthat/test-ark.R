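# A hand-built network reproducing the canonical knockout walkthrough
# structurally: the season output keeps a constant-output helper (acting
# as a bias node) plus a varying signal node; the helper's own selection
# is the empty combination; a deeper relay keeps its strong input and
# sheds two near-zero spurious connections.
walkthrough_network <- function() {
  net <- build_network(init = "empty")
  net$nodes$bias[] <- 0
  net$nodes$modul[] <- 1
  net$nodes$bias[21] <- 0.04    # constant-output helper
  net$nodes$bias[22] <- 0.04    # asymmetric relay: activations 0.97/0.83/0.1/-0.66
  net$connections <- data.frame(
    source = c(1L, 2L, 3L, 2L, 12L, 13L, 3L, 21L, 22L),
    target = c(12L, 12L, 12L, 13L, 22L, 22L, 21L, 32L, 32L),
    weight = c(0.5, 0.001, 0.001, 0.5, 0.0637, 0.03, 1e-6, -0.885, 1))
  validate_network(net)
}

walkthrough_record <- function(net) {
  set.seed(424)
  env <- generate_environment()
  simulate_lifetime(net, env, learning_on = FALSE,
                    record = TRUE)$activation_record
}

test_that("SER is the root mean squared deviation", {
  expect_equal(ser(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ser(c(1, -1, 1, -1), c(0, 0, 0, 0)), 1)   # sqrt(4/4)
  y <- runif(10)
  yh <- runif(10)
  expect_equal(ser(y, yh), ser(yh, y))                    # symmetric
  expect_equal(ser(c(1, -1), c(0, 0), root = FALSE), 1)
  expect_error(ser(numeric(0), numeric(0)), "zero-length")
  expect_error(ser(1:3, 1:2), "lengths differ")
})

test_that("knockout tables enumerate 2^p combinations, sorted by SER", {
  net <- walkthrough_network()
  rec <- walkthrough_record(net)
  kt <- knockout_table(net, rec, 22L)
  expect_equal(nrow(kt$table), 4)              # in-degree 2
  expect_equal(sort(kt$table$mask), 0:3)
  # the no-knockout combination has (near-)zero SER and sorts first
  expect_lt(kt$table$ser[kt$table$mask == 3][1], 1e-9)
  expect_equal(kt$table$mask[1], 3)
  expect_false(is.unsorted(kt$table$ser))
  # ties are reverse-sorted by combination size
  tied <- kt$table[duplicated(kt$table$ser) |
                     duplicated(kt$table$ser, fromLast = TRUE), ]
  if (nrow(tied) > 1) expect_false(is.unsorted(-tied$size))
  kt12 <- knockout_table(net, rec, 12L)
  expect_equal(nrow(kt12$table), 8)
  expect_error(knockout_table(net, rec, 12L, cap = 2), "exceeds the knockout cap")
  expect_error(knockout_table(net, rec, 1L), "input nodes")
})

test_that("a true bias node selects the empty combination", {
  net <- walkthrough_network()
  rec <- walkthrough_record(net)
  kt <- knockout_table(net, rec, 21L)
  expect_lt(kt$table$ser[kt$table$mask == 0], 1e-3)
  expect_equal(neuroforage:::select_combination(kt, 0.7), 0L)
  expect_true(21L %in% detect_bias_nodes(rec))
})

test_that("the error threshold selects monotonically smaller combinations", {
  net <- walkthrough_network()
  rec <- walkthrough_record(net)
  for (node in c(12L, 22L, 32L)) {
    kt <- knockout_table(net, rec, node)
    sizes <- vapply(c(1e-10, 0.05, 0.3, 0.7, 1.5, 4),
                    function(th) {
                      sel <- neuroforage:::select_combination(kt, th)
                      sum(bitwAnd(sel, bitwShiftL(1L, 0:10)) > 0)
                    }, numeric(1))
    expect_false(is.unsorted(rev(sizes)))
  }
})

test_that("the knockout walkthrough reproduces the canonical selections", {
  net <- walkthrough_network()
  rec <- walkthrough_record(net)
  th <- 0.70
  # output: keep both incoming connections
  kt_o <- knockout_table(net, rec, 32L)
  expect_equal(neuroforage:::select_combination(kt_o, th), 3L)
  # helper node: empty combination (bias role)
  kt_b <- knockout_table(net, rec, 21L)
  expect_equal(neuroforage:::select_combination(kt_b, th), 0L)
  # relay keeps its strong input, sheds the weak one
  kt_r <- knockout_table(net, rec, 22L)
  keep_r <- neuroforage:::mask_to_kept(
    kt_r, neuroforage:::select_combination(kt_r, th))
  expect_equal(net$connections$source[keep_r], 12L)
  # deep node drops its two spurious connections
  kt_d <- knockout_table(net, rec, 12L)
  keep_d <- neuroforage:::mask_to_kept(
    kt_d, neuroforage:::select_combination(kt_d, th))
  expect_equal(net$connections$source[keep_d], 1L)
  # and the full BFS extraction keeps exactly that subnetwork
  sub <- extract_subnetwork(net, rec, "summer", th)
  kept <- net$connections[sub$kept, ]
  expect_setequal(paste(kept$source, kept$target),
                  c("21 32", "22 32", "12 22", "1 12"))
})

test_that("extraction limits: huge threshold empties, tiny threshold preserves", {
  net <- walkthrough_network()
  rec <- walkthrough_record(net)
  sub <- extract_subnetwork(net, rec, "summer", threshold = 10)
  expect_equal(length(sub$kept), 0)
  sub0 <- extract_subnetwork(net, rec, "summer", threshold = 1e-10)
  # nothing with recorded influence may be dropped at threshold ~0
  expect_true(all(c("21 32", "22 32") %in%
                    paste(net$connections$source[sub0$kept],
                          net$connections$target[sub0$kept])))
  expect_error(extract_subnetwork(net, rec, "summer", threshold = -1),
               "non-negative")
})

test_that("CFNs never lose fitness and label connections consistently", {
  set.seed(40)
  for (i in 1:4) {
    net <- build_network()
    env <- generate_environment()
    res <- run_training_then_testing(net, env, "diffusion", trace = FALSE)
    cfn <- build_cfn(res$learned_network, res$test$activation_record, env,
                     "diffusion")
    expect_gte(cfn$cfn_fitness, cfn$original_fitness)
    expect_true(all(cfn$connections$label %in% c("summer", "winter", "common")))
    # common is exactly the intersection of the two subnetworks
    s <- cfn$summer_kept
    w <- cfn$winter_kept
    expect_setequal(which(cfn$connections$label == "common"),
                    match(intersect(s, w), sort(unique(c(s, w)))))
    expect_equal(nrow(cfn$connections), length(unique(c(s, w))))
  }
})

test_that("disjoint subnetworks yield no common labels; identical all common", {
  set.seed(41)
  env <- make_environment(season_rule(0, -1), season_rule(1, 1))
  oracle <- dual_rule_network(env$summer_rule, env$winter_rule)
  res <- run_training_then_testing(oracle, env, "diffusion")
  cfn <- build_cfn(res$learned_network, res$test$activation_record, env,
                   "diffusion")
  expect_equal(sort(cfn$connections$label), c("summer", "winter"))
  # identical rules served through one shared hidden relay: the shared
  # input connection becomes the common functional module
  env2 <- make_environment(season_rule(1, 1), season_rule(1, 1))
  shared <- build_network(init = "empty")
  shared$nodes$bias[] <- 0
  shared$nodes$modul[] <- 1
  outs <- output_ids(shared)
  shared$connections <- data.frame(source = c(2L, 10L, 10L),
                                   target = c(10L, outs[1], outs[2]),
                                   weight = c(1, 1, 1))
  res2 <- run_training_then_testing(shared, env2, "diffusion")
  cfn2 <- build_cfn(res2$learned_network, res2$test$activation_record, env2,
                    "diffusion")
  expect_equal(cfn2$cfn_fitness, 1)
  expect_equal(sort(cfn2$connections$label), c("common", "summer", "winter"))
  expect_equal(cfn2$connections$label[cfn2$connections$target == 10L],
               "common")
})

test_that("CFN fitness agrees with brute-force subset enumeration on small nets", {
  set.seed(42)
  for (i in 1:3) {
    net <- random_sparse_network(n_conn = 8)
    env <- generate_environment()
    res <- run_training_then_testing(net, env, "diffusion", trace = FALSE)
    learned <- res$learned_network
    cfn <- build_cfn(learned, res$test$activation_record, env, "diffusion")
    m <- nrow(learned$connections)
    subset_fitness <- vapply(seq_len(2^m) - 1L, function(mask) {
      keep <- bitwAnd(mask, bitwShiftL(1L, 0:(m - 1))) > 0
      pruned <- learned
      pruned$connections <- learned$connections[keep, , drop = FALSE]
      simulate_lifetime(pruned, env, learning_on = FALSE)$fitness
    }, numeric(1))
    sizes <- vapply(seq_len(2^m) - 1L, function(mask)
      sum(bitwAnd(mask, bitwShiftL(1L, 0:(m - 1))) > 0), numeric(1))
    best_small <- max(subset_fitness[sizes <= nrow(cfn$connections)])
    expect_equal(cfn$cfn_fitness, best_small)
    expect_gte(cfn$cfn_fitness, cfn$original_fitness)
  }
})

test_that("bias-node variance threshold is strict", {
  rec <- rbind(rep(0.5, 10), seq(-1, 1, length.out = 10))
  expect_equal(detect_bias_nodes(rec), 1L)
  v <- var(rec[2, ])
  expect_length(detect_bias_nodes(rec, tol = v), 1L)        # strict <
  expect_length(detect_bias_nodes(rec, tol = v * 1.001), 2L)
  expect_error(detect_bias_nodes(rec[, 0]), "empty")
})

test_that("single-connection knockouts hit only their own season", {
  set.seed(43)
  for (i in 1:5) {
    sb <- sample(0:2, 1)
    wb <- sample(setdiff(0:2, sb), 1)
    env <- make_environment(season_rule(sb, sample(c(-1, 1), 1)),
                            season_rule(wb, sample(c(-1, 1), 1)))
    oracle <- dual_rule_network(env$summer_rule, env$winter_rule)
    res <- run_training_then_testing(oracle, env, "diffusion")
    cfn <- build_cfn(res$learned_network, res$test$activation_record, env,
                     "diffusion")
    kv <- knockout_validation(cfn, env, "diffusion")
    base <- kv[kv$class == "none", ]
    sm <- kv[kv$class == "summer", ]
    wi <- kv[kv$class == "winter", ]
    # removing a winter connection leaves summer fitness exactly unchanged
    expect_identical(wi$summer_fitness, base$summer_fitness)
    expect_lt(wi$winter_fitness, base$winter_fitness)
    expect_identical(sm$winter_fitness, base$winter_fitness)
    expect_lt(sm$summer_fitness, base$summer_fitness)
  }
})
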