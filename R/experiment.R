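#' Deterministic seed derivation
#'
#' Derives a child seed from a master seed and any number of indices
#' (run number, environment number, ...), so that any single run or
#' environment can be replayed in isolation.  Stays within the 32-bit
#' integer range.
#'
#' @param master integer master seed.
#' @param ... integer indices.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (i in idx) s <- (s * 48271 + as.double(i) + 1) %% 2147483647
  as.integer(s)
}

#' Experiment configuration
#'
#' Bundles every sub-configuration of a full experiment: evolution, then
#' a post-evolution analysis of each run's champion in fresh
#' environments (training + testing phase, seasonal-association metrics,
#' ARK and functional modularity).
#'
#' @param treatment `"PA"`, `"PCC"`, `"PA_D"` or `"PCC_D"`.
#' @param n_runs number of independent evolutionary runs.
#' @param master_seed master seed; per-run seeds are derived via
#'   [derive_seed()].
#' @param evolution an [evolution_config()].
#' @param plasticity a [plasticity_config()].
#' @param network a [network_config()].
#' @param n_post_envs environments in the post-evolution analysis
#'   (80 at full scale).
#' @param ark_envs how many of those environments also get the ARK /
#'   modularity analysis (defaults to all of them).
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(treatment = "PA_D", n_runs = 1L,
                              master_seed = 1L,
                              evolution = evolution_config(),
                              plasticity = plasticity_config(),
                              network = network_config(),
                              n_post_envs = 80L, ark_envs = NULL,
                              out_dir = NULL) {
  treatment_info(treatment)   # validates
  if (is.null(ark_envs)) ark_envs <- n_post_envs
  structure(list(treatment = treatment, n_runs = as.integer(n_runs),
                 master_seed = as.integer(master_seed),
                 evolution = evolution, plasticity = plasticity,
                 network = network,
                 n_post_envs = as.integer(n_post_envs),
                 ark_envs = as.integer(min(ark_envs, n_post_envs)),
                 out_dir = out_dir),
            class = "experiment_config")
}

#' Read an experiment configuration from a YAML or JSON file
#'
#' Top-level keys mirror the arguments of [experiment_config()];
#' `evolution`, `plasticity` and `network` are nested maps passed to
#' their respective constructors.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  args <- obj
  if (!is.null(obj$evolution))
    args$evolution <- do.call(evolution_config, obj$evolution)
  if (!is.null(obj$plasticity))
    args$plasticity <- do.call(plasticity_config, obj$plasticity)
  if (!is.null(obj$network))
    args$network <- do.call(network_config, obj$network)
  do.call(experiment_config, args)
}

#' Post-evolution analysis of one individual
#'
#' Re-evaluates a (typically evolved) network in `n_envs` fresh
#' environments.  Each environment gets a training phase (learning on,
#' seasonal probes at the six season ends, weight trace) and a testing
#' phase (learning off, activation record); for the first `ark_envs`
#' environments the ARK core functional network and its functional
#' modularity are computed as well.
#'
#' @param net a `forage_network`.
#' @param treatment see [treatment_info()].
#' @param n_envs number of fresh environments.
#' @param ark_envs environments that also get ARK (default: all).
#' @inheritParams simulate_lifetime
#' @param cap ARK in-degree cap, see [knockout_table()].
#' @return list with `per_env` (one row per environment: fitnesses,
#'   per-environment Perfect/Known/Retained/Forgotten counts, CFN
#'   fitness/threshold/size and functional modularity where computed),
#'   `summary` (pooled [summarize_assessments()]), `probes` and `cfns`.
#' @export
analyze_champion <- function(net, treatment, n_envs = 80L, ark_envs = n_envs,
                             plasticity = plasticity_config(),
                             sources = point_sources(),
                             modul_threshold = 0.4, cap = 20L) {
  info <- treatment_info(treatment)
  sim_treatment <- if (info$diffusion) "diffusion" else "standard"
  probes <- vector("list", n_envs)
  cfns <- vector("list", n_envs)
  rows <- vector("list", n_envs)
  for (e in seq_len(n_envs)) {
    env <- generate_environment()
    rtt <- run_training_then_testing(net, env, sim_treatment, plasticity,
                                     sources, modul_threshold, trace = TRUE)
    probes[[e]] <- rtt$probes
    m <- summarize_assessments(rtt$probes)
    q <- NA_real_
    cfn_fit <- NA_real_
    cfn_thr <- NA_real_
    cfn_size <- NA_integer_
    if (e <= ark_envs) {
      cfn <- tryCatch(
        build_cfn(rtt$learned_network, rtt$test$activation_record, env,
                  sim_treatment, plasticity, sources, modul_threshold, cap),
        error = function(err) NULL)
      if (!is.null(cfn)) {
        cfns[[e]] <- cfn
        q <- q_score(cfn)$q
        cfn_fit <- cfn$cfn_fitness
        cfn_thr <- cfn$error_threshold
        cfn_size <- nrow(cfn$connections)
      }
    }
    rows[[e]] <- data.frame(
      env = e,
      train_fitness = rtt$train$fitness,
      test_fitness = rtt$test$fitness,
      test_summer_fitness = rtt$test$summer_fitness,
      test_winter_fitness = rtt$test$winter_fitness,
      perfect = m$perfect_count, known = m$known_count,
      retained = m$retained_count, forgotten = m$forgotten_count,
      cfn_fitness = cfn_fit, cfn_threshold = cfn_thr,
      cfn_size = cfn_size, functional_modularity = q)
  }
  list(per_env = do.call(rbind, rows),
       summary = summarize_assessments(probes),
       probes = probes,
       cfns = cfns)
}

#' Run a full experiment
#'
#' For each run: seed, evolve, take the highest-fitness individual of
#' the final generation, and run the post-evolution analysis.  Results
#' (and champion genomes) are written under `out_dir` when configured;
#' a run whose summary CSV already exists is loaded instead of re-run,
#' so interrupted experiments resume where they stopped.
#'
#' @param config an [experiment_config()].
#' @param verbose passed to [evolve()].
#' @return an object of class `experiment_result`: `runs` (one row per
#'   run: champion fitness, median post-analysis metrics), `per_env`
#'   (all runs' per-environment rows) and `config`.
#' @export
run_experiment <- function(config, verbose = 0) {
  if (!is.null(config$out_dir) &&
      !dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  runs <- vector("list", config$n_runs)
  envs <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    run_csv <- if (!is.null(config$out_dir))
      file.path(config$out_dir, sprintf("%s_run%03d_envs.csv",
                                        config$treatment, r)) else NULL
    if (!is.null(run_csv) && file.exists(run_csv)) {
      per_env <- utils::read.csv(run_csv)
      runs[[r]] <- summarize_run(config, r, NA_real_, per_env)
      envs[[r]] <- cbind(run = r, per_env)
      next
    }
    seed <- derive_seed(config$master_seed, r)
    set.seed(seed)
    archive <- evolve(config$treatment, config$evolution, config$plasticity,
                      config$network, verbose = verbose)
    set.seed(derive_seed(config$master_seed, r, 1L))
    post <- analyze_champion(archive$champion, config$treatment,
                             config$n_post_envs, config$ark_envs,
                             config$plasticity,
                             modul_threshold = config$evolution$modul_threshold)
    runs[[r]] <- summarize_run(config, r, archive$champion_fitness,
                               post$per_env, seed)
    envs[[r]] <- cbind(run = r, post$per_env)
    if (!is.null(config$out_dir)) {
      write.csv(post$per_env, run_csv, row.names = FALSE)
      network_to_json(archive$champion,
                      file.path(config$out_dir,
                                sprintf("%s_run%03d_champion.json",
                                        config$treatment, r)))
    }
  }
  out <- structure(list(runs = do.call(rbind, runs),
                        per_env = do.call(rbind, envs),
                        config = config),
                   class = "experiment_result")
  if (!is.null(config$out_dir)) {
    write.csv(out$runs, file.path(config$out_dir,
                                  paste0(config$treatment, "_runs.csv")),
              row.names = FALSE)
  }
  out
}

summarize_run <- function(config, r, champion_fitness, per_env,
                          seed = NA_integer_) {
  retained_pct <- if (sum(per_env$known) == 0) 0 else
    100 * sum(per_env$retained) / sum(per_env$known)
  data.frame(
    run = r, treatment = config$treatment, seed = seed,
    champion_fitness = champion_fitness,
    median_train_fitness = median(per_env$train_fitness),
    median_test_fitness = median(per_env$test_fitness),
    perfect = sum(per_env$perfect),
    retained_percent = retained_pct,
    median_functional_modularity =
      median(per_env$functional_modularity, na.rm = TRUE))
}

#' Compare two treatments on a per-run metric
#'
#' Convenience wrapper around the Mann-Whitney U test
#' ([stats::wilcox.test()]) for per-run summary metrics.
#'
#' @param runs per-run data.frame(s) as produced by [run_experiment()],
#'   row-bound across treatments.
#' @param metric column to compare (default `"retained_percent"`).
#' @param treatments length-2 character vector; the alternative is that
#'   the first stochastically dominates the second.
#' @return the `htest` object.
#' @export
compare_treatments <- function(runs, metric = "retained_percent",
                               treatments = c("PA_D", "PA")) {
  x <- runs[[metric]][runs$treatment == treatments[1]]
  y <- runs[[metric]][runs$treatment == treatments[2]]
  if (!length(x) || !length(y))
    stop("both treatments need at least one run")
  stats::wilcox.test(x, y, alternative = "greater", exact = FALSE)
}

#' Summary tables of an experiment archive
#'
#' Medians with 25th/75th percentiles per treatment for the headline
#' metrics.
#'
#' @param x an `experiment_result`, or a data.frame of per-run rows
#'   (possibly from several experiments row-bound together).
#' @return data.frame, one row per (treatment, metric).
#' @export
report <- function(x) {
  runs <- if (inherits(x, "experiment_result")) x$runs else x
  if (is.null(runs) || !nrow(runs)) stop("empty archive")
  metrics <- c("champion_fitness", "median_train_fitness",
               "median_test_fitness", "perfect", "retained_percent",
               "median_functional_modularity")
  out <- do.call(rbind, lapply(split(runs, runs$treatment), function(d) {
    do.call(rbind, lapply(metrics, function(m) {
      v <- d[[m]]
      data.frame(treatment = d$treatment[1], metric = m,
                 median = median(v, na.rm = TRUE),
                 q25 = unname(quantile(v, 0.25, na.rm = TRUE)),
                 q75 = unname(quantile(v, 0.75, na.rm = TRUE)),
                 n = sum(!is.na(v)))
    }))
  }))
  rownames(out) <- NULL
  out
}
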