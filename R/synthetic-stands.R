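# Seeded synthetic stands, inventory series and climate series. These
# emulate the structures the analyses assume -- even-aged stands (unimodal
# diameter distributions), single-tree-selection stands (negative-exponential
# diameter distributions), nested-circle census plots with a 12-cm threshold,
# and a drought scenario that suppresses growth as a function of species and
# size percentile -- so every downstream stage is testable without real data.

# Run `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("a single integer seed is required for every stochastic step",
         call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Stand generator configuration
#'
#' @param structure `"even_aged"` (truncated-normal diameters) or
#'   `"selection"` (shifted, upper-truncated exponential diameters). Both
#'   laws respect the 12-cm census threshold.
#' @param n_trees number of trees.
#' @param diameter_law for `even_aged`: `list(mean_cm =, sd_cm =)`; for
#'   `selection`: `list(rate_per_cm =, max_cm =)`. Defaults: mean 30 cm /
#'   sd 8 cm, rate 0.08 per cm / max 80 cm.
#' @param growth_law `list(alpha, beta, gamma, sd, sd_interval)`: the annual
#'   diameter increment of a tree with initial diameter `d` is
#'   `max(0, alpha + beta * d^gamma + eps)` cm with tree-level noise
#'   `eps ~ N(0, sd^2)`; `sd_interval` adds independent interval-level noise
#'   in longitudinal series (default 0 so a null scenario leaves per-year
#'   increments identical across periods).
#' @param beech_fraction_ba target share of stand basal area in beech, in
#'   \[0, 1\]; realized share is within 5 percentage points or generation
#'   errors out.
#' @param weighting `"unit"` (large experimental plots, weight 1) or `"nfi"`
#'   (nested circles: weight 50 below 36 cm, 20 at or above).
#' @param seed integer seed; generation is deterministic given the seed.
#' @return a `stand_config` list.
#' @export
stand_config <- function(structure = c("even_aged", "selection"),
                         n_trees = 100L,
                         diameter_law = NULL,
                         growth_law = list(alpha = 0.05, beta = 0.01,
                                           gamma = 1, sd = 0.1,
                                           sd_interval = 0),
                         beech_fraction_ba = 0.5,
                         weighting = c("unit", "nfi"),
                         seed = 1L) {
  structure_ <- match.arg(structure)
  weighting <- match.arg(weighting)
  if (is.null(diameter_law)) {
    diameter_law <- if (structure_ == "even_aged") {
      list(mean_cm = 30, sd_cm = 8)
    } else {
      list(rate_per_cm = 0.08, max_cm = 80)
    }
  }
  gl <- utils::modifyList(list(alpha = 0.05, beta = 0.01, gamma = 1,
                               sd = 0.1, sd_interval = 0), growth_law)
  stopifnot(n_trees >= 1, gl$beta >= 0, gl$gamma > 0, gl$sd >= 0,
            gl$sd_interval >= 0,
            beech_fraction_ba >= 0, beech_fraction_ba <= 1)
  structure(list(structure = structure_, n_trees = as.integer(n_trees),
                 diameter_law = diameter_law, growth_law = gl,
                 beech_fraction_ba = beech_fraction_ba,
                 weighting = weighting, seed = as.integer(seed)),
            class = "stand_config")
}

MIN_CENSUS_DBH <- 12

# Diameter draws honouring the 12-cm census threshold.
draw_diameters <- function(config) {
  n <- config$n_trees
  law <- config$diameter_law
  if (config$structure == "even_aged") {
    # truncated normal via rejection; lower bound at the census threshold
    out <- numeric(0)
    while (length(out) < n) {
      x <- stats::rnorm(2L * n, law$mean_cm, law$sd_cm)
      out <- c(out, x[x >= MIN_CENSUS_DBH])
    }
    out[seq_len(n)]
  } else {
    # shifted exponential, inverse-CDF truncated at max_cm
    u <- stats::runif(n)
    span <- law$max_cm - MIN_CENSUS_DBH
    MIN_CENSUS_DBH - log(1 - u * (1 - exp(-law$rate_per_cm * span))) /
      law$rate_per_cm
  }
}

# Randomized-greedy species assignment: among up to 50 random permutations,
# pick the beech prefix whose weighted basal-area share is closest to the
# target. Errors when no prefix lands within 5 percentage points
# (infeasible for tiny n / extreme targets).
assign_species <- function(dbh_cm, weight, beech_fraction_ba) {
  ba <- weight * basal_area(dbh_cm)
  best <- NULL; best_diff <- Inf
  for (try in 1:50) {
    perm <- sample.int(length(ba))
    share <- c(0, cumsum(ba[perm])) / sum(ba)
    k <- which.min(abs(share - beech_fraction_ba)) - 1L
    diff <- abs(share[k + 1L] - beech_fraction_ba)
    if (diff < best_diff) {
      best_diff <- diff
      best <- if (k > 0L) perm[seq_len(k)] else integer()
    }
    if (best_diff <= 0.01) break
  }
  if (best_diff > 0.05) {
    stop("cannot realize beech basal-area share ", beech_fraction_ba,
         " within 5 percentage points for n = ", length(ba), call. = FALSE)
  }
  species <- rep("other", length(ba))
  species[best] <- "beech"
  species
}

#' Generate a synthetic stand census
#'
#' Draws diameters from the configured structural law, assigns species to hit
#' the target beech basal-area share, assigns nested-circle weights when
#' `weighting = "nfi"`, and attaches an annual diameter increment
#' `max(0, alpha + beta * d^gamma + eps)` per tree. Deterministic given the
#' config seed.
#'
#' @param config a [stand_config()].
#' @param plot_id plot identifier.
#' @param census_date census date for the snapshot.
#' @return a `plot_census`: list with `plot_id`, `census_date`, `trees`
#'   (data.frame: tree_id, dbh_cm, dbh_increment_cm, species, status,
#'   weight), `structure`, `stand_type` and `stand_basal_area` (m2/ha for
#'   nfi weighting, m2 per plot otherwise).
#' @export
generate_stand <- function(config, plot_id = "plot1",
                           census_date = as.Date("2010-04-01")) {
  stopifnot(inherits(config, "stand_config"))
  with_seed(config$seed, {
    d <- draw_diameters(config)
    w <- if (config$weighting == "nfi") expansion_weight(d) else
      rep(1, length(d))
    species <- assign_species(d, w, config$beech_fraction_ba)
    gl <- config$growth_law
    eps <- stats::rnorm(length(d), 0, gl$sd)
    incr <- pmax(0, gl$alpha + gl$beta * d^gl$gamma + eps)
    trees <- data.frame(tree_id = sprintf("t%04d", seq_along(d)),
                        dbh_cm = d, dbh_increment_cm = incr,
                        species = species, status = "live", weight = w,
                        stringsAsFactors = FALSE)
    plot_census(plot_id, census_date, trees, structure = config$structure)
  })
}

#' Plot census container
#'
#' @param plot_id identifier.
#' @param census_date `Date`.
#' @param trees data.frame with at least `tree_id`, `dbh_cm`, `species`,
#'   `status`, `weight`; optionally `dbh_increment_cm`.
#' @param structure `"even_aged"` or `"selection"` (or `NA`).
#' @return a `plot_census` list; `stand_type` is derived from the weighted
#'   beech basal-area share (>= 50% = beech_dominated) over live trees.
#' @export
plot_census <- function(plot_id, census_date, trees,
                        structure = NA_character_) {
  stopifnot(is.data.frame(trees))
  live <- trees[trees$status == "live", , drop = FALSE]
  sba <- sum(live$weight * basal_area(live$dbh_cm))
  share <- if (sba > 0) {
    sum(live$weight * basal_area(live$dbh_cm) *
          (live$species == "beech")) / sba
  } else NA_real_
  structure(list(plot_id = as.character(plot_id),
                 census_date = as.Date(census_date), trees = trees,
                 structure = structure,
                 stand_type = if (!is.na(share) && share >= 0.5)
                   "beech_dominated" else "beech_admixed",
                 beech_share = share, stand_basal_area = sba),
            class = "plot_census")
}

#' @export
print.plot_census <- function(x, ...) {
  cat(sprintf("<plot_census %s @ %s> %d trees, %s, %s, BA %.2f\n", x$plot_id,
              format(x$census_date), nrow(x$trees), x$structure, x$stand_type,
              x$stand_basal_area))
  invisible(x)
}

#' Default growth-period table
#'
#' Seven growth periods spanning pre-drought decades, the 2018 drought year
#' and the two post-drought years.
#'
#' @return data.frame with `label`, `start_year`, `end_year`.
#' @export
default_periods <- function() {
  data.frame(label = c("1984-1994", "1995-2004", "2005-2009", "2010-2017",
                       "2018", "2019", "2020"),
             start_year = c(1984L, 1995L, 2005L, 2010L, 2018L, 2019L, 2020L),
             end_year = c(1994L, 2004L, 2009L, 2017L, 2018L, 2019L, 2020L),
             stringsAsFactors = FALSE)
}

#' Drought scenario
#'
#' Per-period, per-species growth reductions that scale with the size
#' percentile of a tree within its plot: the growth multiplier is
#' `1 - reduction * percentile`, so multipliers lie in (0, 1], decrease with
#' size and equal 1 when `reduction = 0`. The default scenario concentrates
#' the loss on large beech trees and is strongest after the drought year
#' (multiplier 0.4 for the largest beech in the post-drought years).
#'
#' @param periods period table as from [default_periods()]; spans must be
#'   ordered and non-overlapping.
#' @param reductions data.frame(`label`, `species`, `reduction`) with
#'   `species` in `"beech"`, `"other"` or `"*"` and `reduction` in \[0, 1);
#'   missing (label, species) pairs default to 0.
#' @return a `drought_scenario` list.
#' @export
drought_scenario <- function(periods = default_periods(),
                             reductions = data.frame(
                               label = c("2018", "2018", "2019", "2019",
                                         "2020", "2020"),
                               species = c("beech", "other", "beech", "other",
                                           "beech", "other"),
                               reduction = c(0.45, 0.3, 0.6, 0.2, 0.6, 0.2),
                               stringsAsFactors = FALSE)) {
  if (!is.data.frame(periods) || nrow(periods) == 0L) {
    stop("scenario needs at least one period", call. = FALSE)
  }
  stopifnot(all(c("label", "start_year", "end_year") %in% names(periods)))
  if (any(periods$end_year < periods$start_year)) {
    stop("period end before start", call. = FALSE)
  }
  if (nrow(periods) > 1L &&
      any(periods$start_year[-1L] <= periods$end_year[-nrow(periods)])) {
    stop("period spans must be ordered and non-overlapping", call. = FALSE)
  }
  if (nrow(reductions) &&
      any(reductions$reduction < 0 | reductions$reduction >= 1)) {
    stop("reductions must lie in [0, 1) so multipliers stay in (0, 1]",
         call. = FALSE)
  }
  structure(list(periods = periods, reductions = reductions),
            class = "drought_scenario")
}

#' Null scenario: every growth multiplier is 1
#' @inheritParams drought_scenario
#' @export
null_scenario <- function(periods = default_periods()) {
  drought_scenario(periods, reductions = data.frame(
    label = character(), species = character(), reduction = numeric(),
    stringsAsFactors = FALSE))
}

# Growth multiplier for one period label, vectorized over trees.
scenario_multiplier <- function(scenario, label, species, size_percentile) {
  red <- rep(0, length(species))
  r <- scenario$reductions
  if (nrow(r)) {
    for (sp in c("*", unique(species))) {
      hit <- r$label == label & r$species == sp
      if (any(hit)) {
        who <- if (sp == "*") rep(TRUE, length(species)) else species == sp
        red[who] <- r$reduction[hit][1L]
      }
    }
  }
  1 - red * size_percentile
}

# Census dates implied by a period table: the series opens in spring of the
# first period's start year; a multi-year period closes in spring of the year
# after its last growing season, a single-year period closes with a
# late-season (mid-September) census of that year.
period_census_dates <- function(periods) {
  closing <- as.Date(ifelse(periods$start_year == periods$end_year,
                            sprintf("%d-09-15", periods$end_year),
                            sprintf("%d-04-01", periods$end_year + 1L)))
  c(as.Date(sprintf("%d-04-01", periods$start_year[1L])), closing)
}

#' Generate a longitudinal inventory series for one plot
#'
#' Starts from a [generate_stand()] snapshot at the first census and rolls
#' the stand through the scenario's periods. Each tree's baseline annual
#' diameter increment is fixed by the growth law at its initial size (plus
#' optional interval-level noise), and is multiplied by the scenario's
#' period/species/size-percentile multiplier and the interval length in
#' growing seasons. Nested-circle weights are re-evaluated at every census,
#' so trees crossing 36 cm change representation. A spring census closes the
#' previous growing season; the drought-year census is taken in September.
#'
#' @param config a [stand_config()].
#' @param scenario a [drought_scenario()].
#' @param plot_id plot identifier.
#' @return data.frame in census format: `plot_id`, `tree_id`, `census_date`,
#'   `dbh_cm`, `species`, `status`.
#' @export
generate_inventory_series <- function(config, scenario = null_scenario(),
                                      plot_id = "plot1") {
  stopifnot(inherits(config, "stand_config"),
            inherits(scenario, "drought_scenario"))
  periods <- scenario$periods
  dates <- period_census_dates(periods)
  snap <- generate_stand(config, plot_id, dates[1L])
  trees <- snap$trees
  gl <- config$growth_law
  n <- nrow(trees)
  pct <- (rank(trees$dbh_cm, ties.method = "first") - 0.5) / n
  baseline <- trees$dbh_increment_cm  # max(0, alpha + beta d0^gamma + eps)
  d <- trees$dbh_cm
  rows <- vector("list", nrow(periods) + 1L)
  rows[[1L]] <- data.frame(plot_id = plot_id, tree_id = trees$tree_id,
                           census_date = dates[1L], dbh_cm = d,
                           species = trees$species, status = "live",
                           stringsAsFactors = FALSE)
  eta <- if (gl$sd_interval > 0) {
    with_seed(config$seed + 1L,
              matrix(stats::rnorm(n * nrow(periods), 0, gl$sd_interval),
                     nrow = n))
  } else matrix(0, nrow = n, ncol = nrow(periods))
  for (j in seq_len(nrow(periods))) {
    years <- periods$end_year[j] - periods$start_year[j] + 1L
    mult <- scenario_multiplier(scenario, periods$label[j], trees$species,
                                pct)
    annual <- pmax(0, baseline + eta[, j]) * mult
    d <- d + annual * years
    rows[[j + 1L]] <- data.frame(plot_id = plot_id, tree_id = trees$tree_id,
                                 census_date = dates[j + 1L], dbh_cm = d,
                                 species = trees$species, status = "live",
                                 stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate a multi-plot inventory dataset
#'
#' Convenience wrapper producing a census table for `n_plots` plots, half
#' beech-dominated (target beech basal-area share 0.70) and half
#' beech-admixed (0.15), alternating even-aged and selection structures.
#' Per-plot seeds are derived from `seed`.
#'
#' @param n_plots number of plots.
#' @param scenario a [drought_scenario()].
#' @param n_trees trees per plot (single value or range to sample from).
#' @param growth_law passed to [stand_config()].
#' @param seed master seed.
#' @return data.frame in census format (all plots stacked).
#' @export
generate_inventory_dataset <- function(n_plots, scenario = null_scenario(),
                                       n_trees = c(30L, 60L),
                                       growth_law = list(alpha = 0.05,
                                                         beta = 0.01,
                                                         gamma = 1, sd = 0.1,
                                                         sd_interval = 0.02),
                                       seed = 1L) {
  stopifnot(n_plots >= 1)
  plan <- with_seed(seed, data.frame(
    seed = sample.int(.Machine$integer.max - 1L, n_plots),
    n = if (length(n_trees) > 1L)
      sample(seq(min(n_trees), max(n_trees)), n_plots, replace = TRUE)
    else rep(n_trees, n_plots)))
  out <- vector("list", n_plots)
  for (i in seq_len(n_plots)) {
    cfg <- stand_config(
      structure = if (i %% 2L == 1L) "even_aged" else "selection",
      n_trees = plan$n[i], growth_law = growth_law,
      beech_fraction_ba = if (i <= ceiling(n_plots / 2)) 0.70 else 0.15,
      weighting = "nfi", seed = plan$seed[i])
    out[[i]] <- generate_inventory_series(cfg, scenario,
                                          plot_id = sprintf("p%03d", i))
  }
  do.call(rbind, out)
}

#' Generate a monthly climate series
#'
#' Sinusoidal seasonal temperature cycle (peak in July) with Gaussian noise,
#' precipitation drawn from a clamped normal (never negative), and a
#' sinusoidal solar-radiation cycle. Deterministic per seed.
#'
#' @param site_seed integer seed (also used as the site id suffix).
#' @param years integer vector of calendar years.
#' @param mean_annual_temp degrees C.
#' @param seasonal_amplitude degrees C (half peak-to-trough).
#' @param precip_mean,precip_sd monthly precipitation law, mm.
#' @param temp_sd monthly temperature noise, degrees C.
#' @param site_id identifier.
#' @return data.frame: `site_id`, `year`, `month`, `temp_c`, `precip_mm`,
#'   `srad_wm2`.
#' @export
generate_climate <- function(site_seed, years, mean_annual_temp = 8,
                             seasonal_amplitude = 9, precip_mean = 100,
                             precip_sd = 35, temp_sd = 1,
                             site_id = paste0("site", site_seed)) {
  if (length(years) == 0L) stop("`years` must be non-empty", call. = FALSE)
  grid <- expand.grid(month = 1:12, year = as.integer(years))
  with_seed(site_seed, {
    cyc <- cos(2 * pi * (grid$month - 7) / 12)
    temp <- mean_annual_temp + seasonal_amplitude * cyc +
      stats::rnorm(nrow(grid), 0, temp_sd)
    prec <- pmax(0, stats::rnorm(nrow(grid), precip_mean, precip_sd))
    srad <- pmax(0, 160 + 90 * cyc + stats::rnorm(nrow(grid), 0, 10))
    data.frame(site_id = site_id, year = grid$year, month = grid$month,
               temp_c = temp, precip_mm = prec, srad_wm2 = srad,
               stringsAsFactors = FALSE)
  })
}
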