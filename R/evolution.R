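#' Evolution configuration
#'
#' Parameters of the PNSGA neuroevolution loop.  The full-scale profile
#' (population 400, 20000 generations) is the default; see
#' [desk_evolution_config()] for a scaled-down profile suitable for
#' interactive work.
#'
#' @param population_size number of individuals (default 400).
#' @param generations number of generations (default 20000).
#' @param n_lifetimes lifetimes (fresh environments) averaged into the
#'   performance objective each generation (default 4).
#' @param modul_threshold `modul` value below which a hidden node is
#'   modulatory under non-diffusion treatments (default 0.4).
#' @param p_add,p_remove per-genome probability of one add- / one
#'   remove-connection attempt (default 0.20 each).
#' @param p_reassign per-connection probability of reassigning one
#'   endpoint (default 0.15).
#' @param weight_rate_numerator per-connection weight-mutation
#'   probability is `weight_rate_numerator / n_connections` (default 2).
#' @param p_bias,p_modul per-node mutation probabilities (default 0.10).
#' @param eta_m polynomial-mutation distribution index (default 15).
#' @param cost_probability probability that the connection-cost
#'   objective enters the non-dominated sort in a given generation
#'   (default 0.75; performance and diversity always enter).
#' @return an object of class `evolution_config`.
#' @export
evolution_config <- function(population_size = 400L, generations = 20000L,
                             n_lifetimes = 4L, modul_threshold = 0.4,
                             p_add = 0.2, p_remove = 0.2, p_reassign = 0.15,
                             weight_rate_numerator = 2, p_bias = 0.1,
                             p_modul = 0.1, eta_m = 15,
                             cost_probability = 0.75) {
  rates <- c(p_add, p_remove, p_reassign, p_bias, p_modul, cost_probability)
  stopifnot(all(rates >= 0 & rates <= 1), population_size >= 2,
            generations >= 0, n_lifetimes >= 1, eta_m > 0)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 n_lifetimes = as.integer(n_lifetimes),
                 modul_threshold = modul_threshold,
                 p_add = p_add, p_remove = p_remove,
                 p_reassign = p_reassign,
                 weight_rate_numerator = weight_rate_numerator,
                 p_bias = p_bias, p_modul = p_modul, eta_m = eta_m,
                 cost_probability = cost_probability),
            class = "evolution_config")
}

#' @rdname evolution_config
#' @param ... overrides passed to [evolution_config()].
#' @export
desk_evolution_config <- function(...) {
  args <- list(population_size = 100L, generations = 1000L)
  args[names(list(...))] <- list(...)
  do.call(evolution_config, args)
}

#' Treatment properties
#'
#' The four treatments: `PA` (performance alone), `PCC` (performance +
#' connection cost), and their diffusion counterparts `PA_D` and
#' `PCC_D`.  Diffusion treatments use point-source neuromodulation (the
#' `modul` parameter is inert but still evolved); `PCC*` treatments add
#' a minimized connection-count objective.
#'
#' @param treatment one of `"PA"`, `"PCC"`, `"PA_D"`, `"PCC_D"`.
#' @return list with logical fields `diffusion` and `cost`.
#' @export
treatment_info <- function(treatment) {
  treatment <- match.arg(treatment, c("PA", "PCC", "PA_D", "PCC_D"))
  list(treatment = treatment,
       diffusion = grepl("_D$", treatment),
       cost = grepl("^PCC", treatment))
}

# all legal strictly-forward (source, target) pairs for a geometry
legal_pairs <- function(nodes) {
  pairs <- expand.grid(source = nodes$id, target = nodes$id)
  ls <- nodes$layer[pairs$source]
  lt <- nodes$layer[pairs$target]
  pairs[ls < lt, , drop = FALSE]
}

#' Mutate a genome
#'
#' Applies, in order: one add-connection attempt and one
#' remove-connection attempt (probability `p_add` / `p_remove` each; add
#' picks uniformly among absent legal strictly-forward pairs, and skips
#' silently on a saturated network); per connection, endpoint
#' reassignment with probability `p_reassign` (one rejection-resample on
#' an illegal proposal, then no-op) and polynomial weight mutation with
#' probability `weight_rate_numerator / n`; per node, polynomial
#' mutation of bias and modul with probability `p_bias` / `p_modul`.
#' Layer skips are allowed; lateral and recurrent connections never
#' arise.  Uses the R random number stream.
#'
#' @param net a `forage_network` (the genome).
#' @param config an [evolution_config()].
#' @return the mutated `forage_network`.
#' @export
mutate_genome <- function(net, config = evolution_config()) {
  nodes <- net$nodes
  lp <- legal_pairs(nodes)
  n_conn <- nrow(net$connections)
  p_weight <- if (n_conn > 0) min(1, config$weight_rate_numerator / n_conn) else 0
  res <- cpp_mutate(net$connections$source, net$connections$target,
                    net$connections$weight, nodes$bias, nodes$modul,
                    nodes$layer, lp$source, lp$target,
                    config$p_add, config$p_remove, config$p_reassign,
                    p_weight, config$p_bias, config$p_modul, config$eta_m)
  net$connections <- data.frame(source = res$source, target = res$target,
                                weight = res$weight)
  net$nodes$bias <- res$bias
  net$nodes$modul <- res$modul
  net
}

#' Behavioral diversity scores
#'
#' Each individual's behavior is the concatenated eat/not-eat vector
#' over its evaluation lifetimes.  Its diversity score is the mean
#' normalized Hamming distance between its vector and every other
#' individual's.
#'
#' @param behaviors 0/1 matrix, one row per individual.
#' @return numeric vector of scores in \[0, 1\].
#' @export
behavioral_diversity <- function(behaviors) {
  behaviors <- as.matrix(behaviors)
  n <- nrow(behaviors)
  L <- ncol(behaviors)
  if (n < 2L) return(rep(0, n))
  s <- 2 * behaviors - 1
  matches <- (L + tcrossprod(s)) / 2
  ham <- (L - matches) / L
  diag(ham) <- 0
  rowSums(ham) / (n - 1)
}

#' Fast non-dominated sorting
#'
#' NSGA-II-style Pareto ranking.  All objective columns are maximized
#' (negate a column to minimize it).
#'
#' @param objectives numeric matrix, one row per individual.
#' @return list with `rank` (1 = non-dominated front) and `fronts`
#'   (list of index vectors).
#' @export
nondominated_sort <- function(objectives) {
  obj <- as.matrix(objectives)
  n <- nrow(obj)
  ge <- matrix(TRUE, n, n)
  gt <- matrix(FALSE, n, n)
  for (k in seq_len(ncol(obj))) {
    dif <- outer(obj[, k], obj[, k], `-`)
    ge <- ge & (dif >= 0)
    gt <- gt | (dif > 0)
  }
  dom <- ge & gt                       # dom[i, j]: i dominates j
  n_dominators <- colSums(dom)
  rank <- integer(n)
  fronts <- list()
  r <- 0L
  remaining <- rep(TRUE, n)
  while (any(remaining)) {
    r <- r + 1L
    front <- which(remaining & n_dominators == 0L)
    if (!length(front)) stop("cyclic dominance; objectives contain NA?")
    rank[front] <- r
    fronts[[r]] <- front
    remaining[front] <- FALSE
    n_dominators <- n_dominators - colSums(dom[front, , drop = FALSE])
    n_dominators[!remaining] <- -1L
  }
  list(rank = rank, fronts = fronts)
}

#' Crowding distance within fronts
#'
#' @param objectives numeric matrix (maximization orientation).
#' @param rank integer Pareto ranks from [nondominated_sort()].
#' @return numeric vector of crowding distances (`Inf` at front edges).
#' @export
crowding_distance <- function(objectives, rank) {
  obj <- as.matrix(objectives)
  n <- nrow(obj)
  cd <- numeric(n)
  for (r in unique(rank)) {
    idx <- which(rank == r)
    if (length(idx) <= 2L) {
      cd[idx] <- Inf
      next
    }
    for (k in seq_len(ncol(obj))) {
      o <- obj[idx, k]
      ord <- order(o)
      rng <- o[ord[length(ord)]] - o[ord[1]]
      cd[idx[ord[1]]] <- Inf
      cd[idx[ord[length(ord)]]] <- Inf
      if (rng > 0) {
        mid <- 2:(length(ord) - 1)
        cd[idx[ord[mid]]] <- cd[idx[ord[mid]]] +
          (o[ord[mid + 1]] - o[ord[mid - 1]]) / rng
      }
    }
  }
  cd
}

# NSGA-II environmental selection: fill by front, break the last front by
# crowding distance (deterministic tie-break: lower index first).
pnsga_select <- function(objectives, n_select) {
  ns <- nondominated_sort(objectives)
  cd <- crowding_distance(objectives, ns$rank)
  ord <- order(ns$rank, -cd, seq_along(ns$rank))
  sel <- ord[seq_len(min(n_select, length(ord)))]
  list(indices = sel, rank = ns$rank, crowding = cd)
}

#' One PNSGA generation step
#'
#' Samples which objectives enter selection this generation (performance
#' and behavioral diversity always; connection cost with probability
#' `cost_probability`, and only for `PCC`/`PCC_D` treatments), performs
#' NSGA-II non-dominated sorting with crowding on the included
#' objectives to select the survivors, and produces offspring by binary
#' tournament (rank, then crowding) followed by mutation only.
#'
#' @param population list of `forage_network` genomes (the evaluated
#'   candidate pool).
#' @param objectives matrix with columns `performance`, `diversity` and
#'   `cost` (raw connection count; internally negated for minimization),
#'   one row per genome.
#' @param config an [evolution_config()].
#' @param treatment see [treatment_info()].
#' @param n_offspring number of offspring to produce (default: the
#'   population size in `config`).
#' @return list with `population` (selected survivors), `indices`,
#'   `offspring` (mutated genomes), and `cost_included` (logical).
#' @export
pnsga_generation <- function(population, objectives, config, treatment,
                             n_offspring = config$population_size) {
  info <- treatment_info(treatment)
  cost_included <- info$cost && runif(1) < config$cost_probability
  obj <- cbind(performance = objectives[, "performance"],
               diversity = objectives[, "diversity"])
  if (cost_included) obj <- cbind(obj, cost = -objectives[, "cost"])
  sel <- pnsga_select(obj, config$population_size)
  surv <- sel$indices
  rank <- sel$rank[surv]
  cd <- sel$crowding[surv]
  pick_parent <- function() {
    ij <- sample.int(length(surv), 2L, replace = TRUE)
    i <- ij[1]; j <- ij[2]
    if (rank[i] < rank[j]) i
    else if (rank[j] < rank[i]) j
    else if (cd[i] >= cd[j]) i else j
  }
  offspring <- lapply(seq_len(n_offspring), function(k)
    mutate_genome(population[[surv[pick_parent()]]], config))
  list(population = population[surv], indices = surv,
       offspring = offspring, cost_included = cost_included)
}

#' Evaluate a population on a set of environments
#'
#' Runs every genome through every environment with learning on
#' (training lifetimes) and returns the per-genome mean fitness together
#' with the concatenated behavior matrix used for the diversity
#' objective.
#'
#' @param population list of `forage_network` genomes sharing one geometry.
#' @param envs list of `forage_environment`s.
#' @inheritParams simulate_lifetime
#' @return list with `performance` (numeric) and `behavior` (0/1 matrix).
#' @export
evaluate_population <- function(population, envs,
                                treatment = c("diffusion", "standard"),
                                plasticity = plasticity_config(),
                                sources = point_sources(),
                                modul_threshold = 0.4) {
  treatment <- match.arg(treatment)
  proto <- population[[1]]
  check_task_shape(proto)
  genomes <- lapply(population, function(net)
    list(source = net$connections$source, target = net$connections$target,
         weight = net$connections$weight, bias = net$nodes$bias,
         modul = net$nodes$modul))
  steps <- lapply(envs, function(e) {
    s <- env_steps(e)
    storage.mode(s$foods) <- "integer"
    s
  })
  outs <- output_ids(proto)
  res <- cpp_evaluate_population(
    genomes, steps, proto$nodes$layer, proto$nodes$x, proto$nodes$y,
    treatment == "diffusion",
    plasticity$update_pairing == "eligibility", modul_threshold,
    plasticity$learning_rate, plasticity$sigma, plasticity$radius_cutoff,
    falloff_prefactor(plasticity), sources$x, sources$y,
    outs[1], outs[2], proto$config$sigmoid_slope)
  list(performance = res$fitness, behavior = res$behavior)
}

#' Evolve a population on the seasonal foraging task
#'
#' The full neuroevolution loop: every generation draws `n_lifetimes`
#' fresh environments shared by the whole candidate pool (parents plus
#' the previous generation's offspring), evaluates training-lifetime
#' performance and behavioral diversity (plus connection cost for `PCC*`
#' treatments), applies PNSGA selection and breeds by mutation only.
#' Uses the R random number stream; `set.seed()` first for reproducible
#' runs.
#'
#' @param treatment one of `"PA"`, `"PCC"`, `"PA_D"`, `"PCC_D"`.
#' @param config an [evolution_config()].
#' @param plasticity a [plasticity_config()].
#' @param network a [network_config()].
#' @param sources a [point_sources()] table.
#' @param verbose print progress every `verbose` generations (0 = quiet).
#' @return an object of class `evolution_archive`: `history` data.frame
#'   (per-generation best/median fitness, median connection count, cost
#'   inclusion), final `population` and `objectives`, and the `champion`
#'   (highest-performance individual of the last generation) with its
#'   `champion_fitness`.
#' @export
evolve <- function(treatment, config = evolution_config(),
                   plasticity = plasticity_config(),
                   network = network_config(),
                   sources = point_sources(), verbose = 0) {
  info <- treatment_info(treatment)
  sim_treatment <- if (info$diffusion) "diffusion" else "standard"
  pop <- lapply(seq_len(config$population_size), function(i)
    build_network(network, "full_adjacent"))
  offspring <- list()
  history <- vector("list", config$generations)
  champion <- NULL
  champion_fitness <- -Inf
  final_obj <- NULL

  for (gen in seq_len(config$generations)) {
    envs <- lapply(seq_len(config$n_lifetimes), function(i)
      generate_environment())
    pool <- c(pop, offspring)
    ev <- evaluate_population(pool, envs, sim_treatment, plasticity,
                              sources, config$modul_threshold)
    objectives <- cbind(performance = ev$performance,
                        diversity = behavioral_diversity(ev$behavior),
                        cost = vapply(pool, function(g)
                          nrow(g$connections), numeric(1)))
    step <- pnsga_generation(pool, objectives, config, treatment)
    pop <- step$population
    offspring <- step$offspring
    perf <- objectives[step$indices, "performance"]
    best_idx <- step$indices[which.max(perf)]
    champion <- pool[[best_idx]]
    champion_fitness <- max(perf)
    final_obj <- objectives[step$indices, , drop = FALSE]
    history[[gen]] <- data.frame(
      generation = gen,
      best_fitness = max(perf),
      median_fitness = median(perf),
      median_connections = median(objectives[step$indices, "cost"]),
      cost_included = step$cost_included)
    if (verbose > 0 && gen %% verbose == 0)
      message(sprintf("gen %d: best %.4f median %.4f", gen, max(perf),
                      median(perf)))
  }
  structure(list(treatment = treatment, config = config,
                 history = if (config$generations)
                   do.call(rbind, history) else
                   data.frame(generation = integer(0)),
                 population = pop,
                 objectives = final_obj,
                 champion = champion,
                 champion_fitness = champion_fitness),
            class = "evolution_archive")
}

#' @export
print.evolution_archive <- function(x, ...) {
  cat(sprintf("<evolution_archive> %s: %d generations, population %d, champion fitness %.4f\n",
              x$treatment, nrow(x$history), length(x$population),
              x$champion_fitness))
  invisible(x)
}
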