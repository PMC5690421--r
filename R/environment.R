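#' The eight 3-bit food items
#'
#' Food items are encoded as 3-bit vectors of 1s and -1s; all eight
#' patterns exist.  Item `i` (1-based) has bit `j` equal to +1 when bit
#' `j` of `i - 1` is set, and -1 otherwise.
#'
#' @return an 8 x 3 matrix of -1/+1, one row per item.
#' @export
food_items <- function() {
  m <- sapply(0:2, function(j) ifelse(bitwAnd(0:7, bitwShiftL(1L, j)) > 0, 1, -1))
  dimnames(m) <- list(NULL, paste0("bit", 0:2))
  m
}

#' A seasonal decision rule
#'
#' A food item is nutritious in a season iff its `decision_bit` equals
#' `nutritious_value`; everything else is poisonous.  Each rule therefore
#' splits the eight items into exactly four nutritious and four poisonous.
#'
#' @param decision_bit which bit (0, 1 or 2) decides.
#' @param nutritious_value the value (-1 or +1) of the decision bit that
#'   marks an item nutritious.
#' @return an object of class `season_rule`.
#' @export
season_rule <- function(decision_bit, nutritious_value) {
  stopifnot(decision_bit %in% 0:2, nutritious_value %in% c(-1, 1))
  structure(list(decision_bit = as.integer(decision_bit),
                 nutritious_value = as.numeric(nutritious_value)),
            class = "season_rule")
}

#' Classify food items under a seasonal rule
#'
#' @param items matrix of -1/+1 food encodings (rows are items), or a
#'   single length-3 vector.
#' @param rule a [season_rule()].
#' @return logical vector: `TRUE` for nutritious.
#' @export
is_nutritious <- function(items, rule) {
  if (is.null(dim(items))) items <- matrix(items, nrow = 1)
  items[, rule$decision_bit + 1L] == rule$nutritious_value
}

#' Generate a random foraging environment
#'
#' An environment is a pair of seasonal decision rules (summer and
#' winter) together with the presentation order of the food items over
#' the agent's lifetime.  The decision bit is uniform over \{0, 1, 2\}
#' and its nutritious polarity uniform over \{-1, +1\}, independently per
#' season; each day presents all eight items once in a uniformly random
#' order.  A lifetime spans `years` years of two 5-day seasons each
#' (summer then winter), i.e. 240 presentations at the defaults.
#'
#' @param years number of years (default 3).
#' @param days_per_season days in each season (default 5).
#' @return an object of class `forage_environment` with elements
#'   `summer_rule`, `winter_rule`, `order` (days x 8 matrix of item ids)
#'   and the sizes.
#' @export
generate_environment <- function(years = 3L, days_per_season = 5L) {
  random_rule <- function()
    season_rule(sample(0:2, 1), sample(c(-1, 1), 1))
  n_days <- years * 2L * days_per_season
  ord <- t(vapply(seq_len(n_days), function(d) sample.int(8L), integer(8)))
  structure(list(summer_rule = random_rule(),
                 winter_rule = random_rule(),
                 order = ord,
                 years = as.integer(years),
                 days_per_season = as.integer(days_per_season)),
            class = "forage_environment")
}

#' Construct an environment from explicit parts
#'
#' @param summer_rule,winter_rule [season_rule()] objects.
#' @param order optional days x 8 matrix of item ids (each row a
#'   permutation of 1:8); random when `NULL`.
#' @inheritParams generate_environment
#' @return a `forage_environment`.
#' @export
make_environment <- function(summer_rule, winter_rule, order = NULL,
                             years = 3L, days_per_season = 5L) {
  n_days <- years * 2L * days_per_season
  if (is.null(order))
    order <- t(vapply(seq_len(n_days), function(d) sample.int(8L), integer(8)))
  stopifnot(nrow(order) == n_days,
            all(apply(order, 1, function(r) setequal(r, 1:8))))
  structure(list(summer_rule = summer_rule, winter_rule = winter_rule,
                 order = order, years = as.integer(years),
                 days_per_season = as.integer(days_per_season)),
            class = "forage_environment")
}

#' @export
print.forage_environment <- function(x, ...) {
  cat(sprintf(
    "<forage_environment> %d years x 2 seasons x %d days; summer: bit %d == %+d, winter: bit %d == %+d\n",
    x$years, x$days_per_season,
    x$summer_rule$decision_bit, x$summer_rule$nutritious_value,
    x$winter_rule$decision_bit, x$winter_rule$nutritious_value))
  invisible(x)
}

# Expand an environment into per-presentation step tables used by the
# simulation engine: food bits, season (0 summer / 1 winter), season
# boundary flags, season block index and nutritiousness of each item.
env_steps <- function(env) {
  items <- food_items()
  n_days <- nrow(env$order)
  item_seq <- as.vector(t(env$order))          # day-major presentation order
  day_of_step <- rep(seq_len(n_days), each = 8L)
  block <- (day_of_step - 1L) %/% env$days_per_season   # 0-based season block
  season <- block %% 2L                                  # 0 summer, 1 winter
  new_season <- c(TRUE, diff(block) > 0L)
  foods <- items[item_seq, , drop = FALSE]
  nutr <- ifelse(season == 0L,
                 is_nutritious(foods, env$summer_rule),
                 is_nutritious(foods, env$winter_rule))
  list(foods = foods, season = as.integer(season),
       new_season = new_season, block = as.integer(block),
       nutritious = as.logical(nutr),
       n_steps = length(item_seq), n_blocks = max(block) + 1L)
}

#' Serialize an environment to JSON (and back)
#'
#' @param env a `forage_environment`.
#' @param path optional file path.
#' @return JSON string, or a `forage_environment` for the reader.
#' @export
environment_to_json <- function(env, path = NULL) {
  obj <- list(summer_rule = unclass(env$summer_rule),
              winter_rule = unclass(env$winter_rule),
              order = env$order, years = env$years,
              days_per_season = env$days_per_season)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = FALSE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname environment_to_json
#' @param json JSON string or file path.
#' @export
environment_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  make_environment(
    season_rule(obj$summer_rule$decision_bit, obj$summer_rule$nutritious_value),
    season_rule(obj$winter_rule$decision_bit, obj$winter_rule$nutritious_value),
    order = obj$order, years = obj$years,
    days_per_season = obj$days_per_season)
}
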