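# Nested-plot drought analysis: expansion weights, period assignment,
# annualized basal-area increments, per-period growth dominance, and the
# linear mixed-effect models with Tukey contrasts.

#' Per-hectare expansion weight for a nested circular plot
#'
#' Trees are recorded in a 200-m2 inner circle from 12 cm diameter and in a
#' 500-m2 circle from 36 cm, so a tree represents 10000/200 = 50 or
#' 10000/500 = 20 stems per hectare. The 36-cm boundary belongs to the outer
#' circle.
#'
#' @param diameter_cm diameter(s) at 1.3 m, cm; must be >= 12.
#' @return weight(s): 50 for 12 <= d < 36, 20 for d >= 36.
#' @export
expansion_weight <- function(diameter_cm) {
  if (any(!is.finite(diameter_cm) | diameter_cm < 12)) {
    stop("diameter below the 12-cm census threshold", call. = FALSE)
  }
  ifelse(diameter_cm >= 36, 10000 / 500, 10000 / 200)
}

#' Annualize an increment
#'
#' @param increment increment over the interval (any dimension).
#' @param interval_years positive interval length in years; intervals of one
#'   year or less pass through unchanged.
#' @return per-year increment.
#' @export
annualize <- function(increment, interval_years) {
  if (any(!is.finite(interval_years) | interval_years <= 0)) {
    stop("interval length must be positive", call. = FALSE)
  }
  iy <- rep_len(interval_years, length(increment))
  ifelse(iy <= 1, increment, increment / iy)
}

# Growing seasons bracketed by a census date: a spring census (Jan-May) has
# not yet seen the current season, so it closes season year-1 and opens
# season year; a census from June onwards includes the current season.
season_bounds <- function(date) {
  date <- as.Date(date)
  m <- as.integer(format(date, "%m"))
  y <- as.integer(format(date, "%Y"))
  list(first_open = ifelse(m <= 5L, y, y + 1L),
       last_closed = ifelse(m <= 5L, y - 1L, y))
}

#' Map a census interval onto a growth period
#'
#' The growing seasons covered by the interval run from the first season
#' after the start census to the last season closed by the end census (a
#' spring measurement closes the previous growing season; an August or
#' September measurement includes the current one). The interval is matched
#' to the configured period whose span equals, or fully contains, that
#' season range.
#'
#' @param date_start,date_end census dates (coercible to `Date`),
#'   `date_start < date_end`.
#' @param periods period table as from [default_periods()].
#' @return list: `label`, `first_season`, `last_season`, `interval_years`
#'   (number of growing seasons).
#' @export
assign_period <- function(date_start, date_end, periods = default_periods()) {
  if (as.Date(date_start) >= as.Date(date_end)) {
    stop("census dates must be ordered", call. = FALSE)
  }
  first <- season_bounds(date_start)$first_open
  last <- season_bounds(date_end)$last_closed
  if (first > last) {
    stop("interval (", date_start, ", ", date_end,
         ") covers no complete growing season", call. = FALSE)
  }
  hit <- which(periods$start_year == first & periods$end_year == last)
  if (!length(hit)) {
    hit <- which(periods$start_year <= first & periods$end_year >= last)
  }
  if (!length(hit)) {
    stop("interval seasons ", first, "-", last,
         " map to no configured growth period", call. = FALSE)
  }
  list(label = periods$label[hit[1L]], first_season = first,
       last_season = last, interval_years = last - first + 1L)
}

#' Classify a plot as beech-dominated or beech-admixed
#'
#' Beech-dominated when the weighted beech share of live stand basal area is
#' at least 50%.
#'
#' @param plot a `plot_census` (see [plot_census()]).
#' @return `"beech_dominated"` or `"beech_admixed"`.
#' @export
classify_stand_type <- function(plot) {
  stopifnot(inherits(plot, "plot_census"))
  live <- plot$trees[plot$trees$status == "live", , drop = FALSE]
  if (nrow(live) == 0L) stop("no live trees in plot ", plot$plot_id,
                             call. = FALSE)
  ba <- live$weight * basal_area(live$dbh_cm)
  if (sum(ba * (live$species == "beech")) / sum(ba) >= 0.5)
    "beech_dominated" else "beech_admixed"
}

#' Filter plots by a minimum live-tree count
#'
#' @param plots list of `plot_census` objects.
#' @param min_trees minimum number of live trees (default 8).
#' @return list with `retained` (list of plots) and `log` (data.frame:
#'   plot_id, n_live, retained).
#' @export
filter_plots <- function(plots, min_trees = 8L) {
  if (length(plots) == 0L) {
    warning("no plots supplied")
    return(list(retained = list(),
                log = data.frame(plot_id = character(), n_live = integer(),
                                 retained = logical())))
  }
  n_live <- vapply(plots, function(p) sum(p$trees$status == "live"), 1L)
  keep <- n_live >= min_trees
  list(retained = plots[keep],
       log = data.frame(plot_id = vapply(plots, `[[`, "", "plot_id"),
                        n_live = n_live, retained = keep,
                        stringsAsFactors = FALSE))
}

#' Build per-interval tree and growth-dominance tables from a census table
#'
#' Pairs consecutive censuses within each plot, maps every pair onto a growth
#' period, computes per-tree annualized basal-area increments (BAI, m2/yr),
#' nested-circle expansion weights at the interval's start census, the
#' weighted stand basal area, the stand type at the interval start, and the
#' growth dominance coefficient of each plot-period on tree basal area.
#' Trees must be live at both censuses of an interval; plots with fewer than
#' `min_trees` live trees in an interval are excluded and logged.
#'
#' @param census data.frame in census format: `plot_id`, `tree_id`,
#'   `census_date`, `dbh_cm`, `species`, `status`.
#' @param periods period table (default [default_periods()]).
#' @param min_trees minimum live trees per interval (default 8).
#' @param weighting `"nfi"` (nested-circle weights inside the DC cumulative
#'   sums; the default) or `"unit"` (unweighted, retained for comparison and
#'   flagged in the output).
#' @return list: `tree_table` (one row per tree x interval), `dc_table` (one
#'   row per plot x period), `exclusions` (log of dropped plot-intervals).
#' @export
build_interval_tables <- function(census, periods = default_periods(),
                                  min_trees = 8L,
                                  weighting = c("nfi", "unit")) {
  weighting <- match.arg(weighting)
  req <- c("plot_id", "tree_id", "census_date", "dbh_cm", "species", "status")
  if (!all(req %in% names(census))) {
    stop("census table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  census$census_date <- as.Date(census$census_date)
  tree_rows <- list(); dc_rows <- list(); excl <- list()
  for (pid in unique(census$plot_id)) {
    pc <- census[census$plot_id == pid, , drop = FALSE]
    dates <- sort(unique(pc$census_date))
    for (j in seq_len(length(dates) - 1L)) {
      a <- pc[pc$census_date == dates[j], , drop = FALSE]
      b <- pc[pc$census_date == dates[j + 1L], , drop = FALSE]
      per <- assign_period(dates[j], dates[j + 1L], periods)
      live_a <- a[a$status == "live" & a$dbh_cm >= 12, , drop = FALSE]
      m <- merge(live_a, b[b$status == "live", c("tree_id", "dbh_cm")],
                 by = "tree_id", suffixes = c("", "_end"))
      if (nrow(m) < min_trees) {
        excl[[length(excl) + 1L]] <- data.frame(
          plot_id = pid, period = per$label, n_live = nrow(m),
          reason = "fewer live trees than minimum", stringsAsFactors = FALSE)
        next
      }
      w <- expansion_weight(m$dbh_cm)
      tree_ba <- basal_area(m$dbh_cm)
      bai <- annualize(basal_area(m$dbh_cm_end) - tree_ba,
                       per$interval_years)
      # stand BA snapshot at interval start includes trees that die or are
      # cut within the interval: they competed during the prior period
      snap <- plot_census(pid, dates[j], data.frame(
        tree_id = live_a$tree_id, dbh_cm = live_a$dbh_cm,
        species = live_a$species, status = live_a$status,
        weight = expansion_weight(live_a$dbh_cm), stringsAsFactors = FALSE))
      stand_ba <- snap$stand_basal_area
      stype <- snap$stand_type
      tree_rows[[length(tree_rows) + 1L]] <- data.frame(
        plot_id = pid, tree_id = m$tree_id, period = per$label,
        interval_years = per$interval_years, species = m$species,
        tree_ba = tree_ba, bai = bai, weight = w, stand_ba = stand_ba,
        stand_type = stype, stringsAsFactors = FALSE)
      dc <- growth_dominance_coefficient(
        data.frame(tree_id = m$tree_id, size = tree_ba, growth = bai,
                   weight = if (weighting == "nfi") w else 1),
        variable = "basal_area", plot_id = pid)
      dc_rows[[length(dc_rows) + 1L]] <- data.frame(
        plot_id = pid, period = per$label, stand_type = stype,
        stand_ba = stand_ba, n_trees = dc$n_trees, dc = dc$value,
        weighting = weighting,
        flags = paste(dc$flags, collapse = ";"), stringsAsFactors = FALSE)
    }
  }
  list(tree_table = do.call(rbind, tree_rows),
       dc_table = do.call(rbind, dc_rows),
       exclusions = if (length(excl)) do.call(rbind, excl) else
         data.frame(plot_id = character(), period = character(),
                    n_live = integer(), reason = character()))
}

# Period factor with the drought year as reference level, in period order.
period_factor <- function(x, periods, reference = "2018") {
  lev <- periods$label[periods$label %in% unique(x)]
  stats::relevel(factor(x, levels = lev), ref = reference)
}

# Fit response ~ period * stand_type with the given random-effects term and
# derive cell means, Tukey-adjusted pairwise period contrasts within each
# stand type, and grouping letters.
fit_period_effects <- function(data, response, random,
                               periods = default_periods(),
                               reference = "2018", alpha = 0.05) {
  if (length(unique(data$period)) < 2L) {
    stop("at least two growth periods are required", call. = FALSE)
  }
  data$period <- period_factor(data$period, periods, reference)
  data$stand_type <- factor(data$stand_type)
  one_type <- nlevels(data$stand_type) < 2L
  fixed <- if (one_type) paste(response, "~ period") else
    paste(response, "~ period * stand_type")
  fml <- stats::as.formula(paste(fixed, "+", random))
  fit <- suppressMessages(lme4::lmer(fml, data = data))
  beta <- lme4::fixef(fit)
  keep <- !is.na(beta)
  V <- as.matrix(stats::vcov(fit))
  grid <- unique(data[, intersect(c("period", "stand_type"), names(data)),
                      drop = FALSE])
  grid <- grid[order(grid$stand_type, as.integer(grid$period)), ,
               drop = FALSE]
  tt <- stats::delete.response(stats::terms(stats::as.formula(fixed)))
  X <- stats::model.matrix(tt, grid)[, names(beta)[keep], drop = FALSE]
  est <- drop(X %*% beta[keep])
  se <- sqrt(rowSums((X %*% V) * X))
  cells <- data.frame(period = as.character(grid$period),
                      stand_type = as.character(grid$stand_type),
                      estimate = est, se = se, stringsAsFactors = FALSE)
  df_res <- nrow(data) - sum(keep)
  comp <- list(); letters <- list()
  for (st in unique(cells$stand_type)) {
    idx <- which(cells$stand_type == st)
    k <- length(idx)
    if (k < 2L) next
    pr <- utils::combn(idx, 2L)
    rows <- apply(pr, 2L, function(ij) {
      l <- X[ij[1L], ] - X[ij[2L], ]
      d <- sum(l * beta[keep])
      s <- sqrt(drop(t(l) %*% V %*% l))
      z <- d / s
      # single-step Tukey adjustment via the studentized range
      p <- stats::ptukey(sqrt(2) * abs(z), nmeans = k,
                         df = max(df_res, 1), lower.tail = FALSE)
      c(d, s, z, p)
    })
    cmp <- data.frame(stand_type = st,
                      period_a = cells$period[pr[1L, ]],
                      period_b = cells$period[pr[2L, ]],
                      estimate = rows[1L, ], se = rows[2L, ],
                      statistic = rows[3L, ], p_adj = pmin(rows[4L, ], 1),
                      stringsAsFactors = FALSE)
    comp[[st]] <- cmp
    pm <- matrix(1, k, k, dimnames = list(cells$period[idx],
                                          cells$period[idx]))
    for (q in seq_len(ncol(pr))) {
      i <- cells$period[pr[1L, q]]; j <- cells$period[pr[2L, q]]
      pm[i, j] <- pm[j, i] <- cmp$p_adj[q]
    }
    letters[[st]] <- data.frame(
      stand_type = st, period = cells$period[idx],
      letters = tukey_letters(pm, cells$estimate[idx], alpha),
      stringsAsFactors = FALSE)
  }
  cells <- merge(cells, do.call(rbind, letters),
                 by = c("stand_type", "period"), all.x = TRUE, sort = FALSE)
  structure(list(model = fit, cells = cells,
                 comparisons = do.call(rbind, comp),
                 alpha = alpha, reference = reference),
            class = "period_effects")
}

#' @export
print.period_effects <- function(x, ...) {
  cat("Period effects (reference:", x$reference, ")\n")
  print(x$cells, row.names = FALSE)
  invisible(x)
}

#' Compact letter display from an adjusted p-value matrix
#'
#' Insert-and-absorb algorithm: starts from one group holding all levels,
#' splits a group for every significant pair it contains, absorbs redundant
#' subsets, and assigns letters ordered by decreasing mean. Levels sharing a
#' letter are not significantly different.
#'
#' @param p_matrix symmetric matrix of adjusted p-values with level
#'   dimnames.
#' @param means cell means (for letter ordering).
#' @param alpha significance level.
#' @return character vector of letter strings, one per level.
#' @export
tukey_letters <- function(p_matrix, means, alpha = 0.05) {
  lev <- rownames(p_matrix)
  k <- length(lev)
  groups <- list(seq_len(k))
  pairs <- which(upper.tri(p_matrix) & p_matrix < alpha, arr.ind = TRUE)
  if (nrow(pairs)) {
    for (q in seq_len(nrow(pairs))) {
      i <- pairs[q, 1L]; j <- pairs[q, 2L]
      nxt <- list()
      for (g in groups) {
        if (i %in% g && j %in% g) {
          nxt <- c(nxt, list(setdiff(g, i)), list(setdiff(g, j)))
        } else nxt <- c(nxt, list(g))
      }
      # absorb groups that are subsets of another
      nxt <- nxt[lengths(nxt) > 0L]
      keep <- rep(TRUE, length(nxt))
      for (a in seq_along(nxt)) {
        for (b in seq_along(nxt)) {
          if (a != b && keep[a] && keep[b] &&
              all(nxt[[a]] %in% nxt[[b]]) &&
              (length(nxt[[a]]) < length(nxt[[b]]) || a > b)) {
            keep[a] <- FALSE
          }
        }
      }
      groups <- unique(nxt[keep])
    }
  }
  ord <- order(vapply(groups, function(g) max(means[g]), 1), decreasing = TRUE)
  groups <- groups[ord]
  out <- rep("", k)
  for (gi in seq_along(groups)) {
    for (m in groups[[gi]]) out[m] <- paste0(out[m], letters[gi])
  }
  out
}

#' Mixed model for the growth dominance coefficient across periods
#'
#' Fits `dc ~ period * stand_type` with a plot-level random intercept, the
#' drought year (2018) as reference period, and Tukey-adjusted pairwise
#' period comparisons within each stand type with grouping letters.
#'
#' @param dc_table `dc_table` from [build_interval_tables()].
#' @param periods period table; `reference` must be one of its labels.
#' @param reference reference period label (default `"2018"`).
#' @param alpha significance level for the letters.
#' @return a `period_effects` object: `model` (lmer fit), `cells`
#'   (period x stand-type means, SEs and letters), `comparisons`.
#' @export
fit_dc_period_model <- function(dc_table, periods = default_periods(),
                                reference = "2018", alpha = 0.05) {
  fit_period_effects(dc_table, "dc", "(1 | plot_id)", periods, reference,
                     alpha)
}

#' Mixed model for annual basal-area increment across periods
#'
#' Tree-level annual BAI modelled as `bai ~ period * stand_type` with trees
#' nested within plots as random intercepts, 2018 as the reference period.
#'
#' @param tree_table `tree_table` from [build_interval_tables()].
#' @inheritParams fit_dc_period_model
#' @return a `period_effects` object.
#' @export
fit_bai_period_model <- function(tree_table, periods = default_periods(),
                                 reference = "2018", alpha = 0.05) {
  fit_period_effects(tree_table, "bai", "(1 | plot_id / tree_id)", periods,
                     reference, alpha)
}

#' Per-period size and density effects on annual BAI
#'
#' For each growth period and stand type, fits a linear mixed model of
#' annualized BAI on tree basal area and stand basal area with a plot random
#' intercept, and reports both slopes with standard errors plus the simple
#' regression R2 of BAI on tree basal area. Cells with fewer than
#' `min_trees` trees, or where the mixed fit is unavailable, are flagged.
#'
#' @param tree_table `tree_table` from [build_interval_tables()].
#' @param min_trees minimum trees per cell (default 10).
#' @return data.frame per (period, stand_type): `slope_tree_ba`,
#'   `se_tree_ba`, `slope_stand_ba`, `se_stand_ba`, `r2_tree_ba`, `n_trees`,
#'   `flag`.
#' @export
size_and_density_slopes <- function(tree_table, min_trees = 10L) {
  out <- list()
  for (st in unique(tree_table$stand_type)) {
    for (per in unique(tree_table$period)) {
      cell <- tree_table[tree_table$stand_type == st &
                           tree_table$period == per, , drop = FALSE]
      row <- data.frame(period = per, stand_type = st,
                        slope_tree_ba = NA_real_, se_tree_ba = NA_real_,
                        slope_stand_ba = NA_real_, se_stand_ba = NA_real_,
                        r2_tree_ba = NA_real_, n_trees = nrow(cell),
                        flag = "", stringsAsFactors = FALSE)
      if (nrow(cell) < min_trees) {
        row$flag <- "too_few_trees"
      } else {
        co <- tryCatch({
          if (stats::var(cell$stand_ba) > 0 &&
              length(unique(cell$plot_id)) > 1L) {
            fit <- suppressMessages(suppressWarnings(
              lme4::lmer(bai ~ tree_ba + stand_ba + (1 | plot_id),
                         data = cell)))
            list(b = lme4::fixef(fit), V = as.matrix(stats::vcov(fit)),
                 flag = "")
          } else {
            fit <- stats::lm(bai ~ tree_ba, data = cell)
            list(b = c(stats::coef(fit), stand_ba = NA_real_),
                 V = rbind(cbind(stats::vcov(fit), NA), NA),
                 flag = "single_plot_lm")
          }
        }, error = function(e) NULL)
        if (is.null(co)) {
          row$flag <- "degenerate_fit"
        } else {
          row$slope_tree_ba <- unname(co$b["tree_ba"])
          row$se_tree_ba <- sqrt(co$V[2L, 2L])
          row$slope_stand_ba <- unname(co$b["stand_ba"])
          row$se_stand_ba <- sqrt(co$V[3L, 3L])
          row$flag <- co$flag
        }
        r2fit <- stats::lm(bai ~ tree_ba, data = cell)
        row$r2_tree_ba <- summary(r2fit)$r.squared
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}
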