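# Site and climate covariates for the growth dominance coefficient:
# Thornthwaite potential evapotranspiration, seasonal aggregates,
# collinearity screening and AICc-based mixed-model selection.

days_in_month <- function(year, month) {
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[month] +
    ifelse(month == 2L & leap, 1L, 0L)
}

# Mean day length (hours) at mid-month from solar declination.
day_length_hours <- function(latitude_deg, year, month) {
  jday <- cumsum(c(0, 31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30))[month] +
    days_in_month(year, month) / 2
  decl <- 0.409 * sin(2 * pi * jday / 365 - 1.39)
  phi <- latitude_deg * pi / 180
  x <- pmin(1, pmax(-1, -tan(phi) * tan(decl)))
  24 / pi * acos(x)
}

#' Monthly Thornthwaite potential evapotranspiration
#'
#' Classic temperature-based formulation: the annual heat index is
#' \eqn{I = \sum (T/5)^{1.514}} over months with \eqn{T > 0}; the exponent is
#' \eqn{a = 6.75\times 10^{-7} I^3 - 7.71\times 10^{-5} I^2 + 1.792\times
#' 10^{-2} I + 0.49239}; unadjusted PET is \eqn{16 (10T/I)^a} mm for
#' \eqn{0 < T < 26.5} C, zero for \eqn{T \le 0}, and the standard
#' high-temperature polynomial \eqn{-415.85 + 32.24T - 0.43T^2} at or above
#' 26.5 C. Values are adjusted by the day-length / month-length correction
#' `K = (L/12) * (days/30)` for the site latitude. The heat index is
#' evaluated per calendar year, which must be complete (12 months). A year
#' with all months at or below 0 C gets PET 0 throughout, flagged.
#'
#' @param series data.frame with columns `year`, `month`, `temp_c` (one site).
#' @param latitude_deg site latitude in decimal degrees.
#' @return the series with columns `pet_mm` (adjusted) and `pet_flag` added.
#' @export
thornthwaite_pet <- function(series, latitude_deg) {
  stopifnot(all(c("year", "month", "temp_c") %in% names(series)))
  out <- series
  out$pet_mm <- NA_real_
  out$pet_flag <- ""
  for (y in unique(series$year)) {
    rows <- which(series$year == y)
    if (!setequal(series$month[rows], 1:12)) {
      stop("year ", y, " is incomplete: Thornthwaite needs all 12 months",
           call. = FALSE)
    }
    Tm <- series$temp_c[rows]
    I <- sum((pmax(Tm, 0) / 5)^1.514)
    if (I == 0) {
      out$pet_mm[rows] <- 0
      out$pet_flag[rows] <- "all_months_freezing"
      next
    }
    a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
    pet <- ifelse(Tm <= 0, 0,
                  ifelse(Tm < 26.5, 16 * (10 * Tm / I)^a,
                         -415.85 + 32.24 * Tm - 0.43 * Tm^2))
    K <- day_length_hours(latitude_deg, y, series$month[rows]) / 12 *
      days_in_month(y, series$month[rows]) / 30
    out$pet_mm[rows] <- pet * K
  }
  out
}

SEASONS <- list(spring = 3:5, summer = 6:8, autumn = 9:11,
                winter = c(12L, 1L, 2L), growing = 3:8)

#' Seasonal and annual climate aggregates
#'
#' Temperature is averaged and precipitation and PET are summed within each
#' season (spring: Mar-May, summer: Jun-Aug, autumn: Sep-Nov, winter:
#' Dec-Feb); winter spans the year boundary, with December attached to the
#' following year's winter. Solar radiation is averaged over the growing
#' season (Mar-Aug). Annual values use calendar years. Incomplete seasons
#' (e.g. the first winter, missing the previous December) are `NA`.
#'
#' @param series data.frame with `site_id`, `year`, `month`, `temp_c`,
#'   `precip_mm`, and optionally `pet_mm` and `srad_wm2`.
#' @return data.frame, one row per site and year, with columns
#'   `temp_annual_mean`, `temp_<season>_mean`, `precip_annual_sum`,
#'   `precip_<season>_sum`, and when available `pet_<season>_sum`,
#'   `pet_annual_sum`, `srad_growing_mean`.
#' @export
seasonal_aggregates <- function(series) {
  stopifnot(all(c("site_id", "year", "month", "temp_c", "precip_mm") %in%
                  names(series)))
  agg_one <- function(vals, months, want, fun) {
    if (!setequal(months, want) || anyNA(vals)) return(NA_real_)
    fun(vals)
  }
  out <- list()
  for (sid in unique(series$site_id)) {
    sc <- series[series$site_id == sid, , drop = FALSE]
    for (y in sort(unique(sc$year))) {
      # season year-assignment: December of y-1 belongs to winter of y
      syear <- sc$year + (sc$month == 12L)
      row <- list(site_id = sid, year = y)
      yr <- sc[sc$year == y, , drop = FALSE]
      row$temp_annual_mean <- agg_one(yr$temp_c, yr$month, 1:12, mean)
      row$precip_annual_sum <- agg_one(yr$precip_mm, yr$month, 1:12, sum)
      for (season in c("spring", "summer", "autumn", "winter")) {
        mo <- SEASONS[[season]]
        sel <- if (season == "winter") syear == y & sc$month %in% mo else
          sc$year == y & sc$month %in% mo
        row[[paste0("temp_", season, "_mean")]] <-
          agg_one(sc$temp_c[sel], sc$month[sel], mo, mean)
        row[[paste0("precip_", season, "_sum")]] <-
          agg_one(sc$precip_mm[sel], sc$month[sel], mo, sum)
        if (!is.null(sc$pet_mm)) {
          row[[paste0("pet_", season, "_sum")]] <-
            agg_one(sc$pet_mm[sel], sc$month[sel], mo, sum)
        }
      }
      if (!is.null(sc$pet_mm)) {
        row$pet_annual_sum <- agg_one(yr$pet_mm, yr$month, 1:12, sum)
      }
      if (!is.null(sc$srad_wm2)) {
        sel <- sc$year == y & sc$month %in% SEASONS$growing
        row$srad_growing_mean <-
          agg_one(sc$srad_wm2[sel], sc$month[sel], SEASONS$growing, mean)
      }
      out[[length(out) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Multi-year climate normals per site
#'
#' Averages the yearly aggregates of [seasonal_aggregates()] over a year
#' window (default 1981-2018), ignoring incomplete years.
#'
#' @param aggregates output of [seasonal_aggregates()].
#' @param years year window.
#' @return data.frame, one row per site.
#' @export
climate_normals <- function(aggregates, years = 1981:2018) {
  sel <- aggregates[aggregates$year %in% years, , drop = FALSE]
  vars <- setdiff(names(sel), c("site_id", "year"))
  out <- lapply(split(sel, sel$site_id), function(d) {
    cbind(data.frame(site_id = d$site_id[1L], stringsAsFactors = FALSE),
          as.data.frame(lapply(d[vars], mean, na.rm = TRUE)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Greedy collinearity screen
#'
#' Computes pairwise absolute Pearson correlations among candidate
#' predictors and, while any pair exceeds the threshold, removes from the
#' worst pair the member with the larger mean absolute correlation to all
#' other remaining predictors (ties broken by declared column order: the
#' later column is dropped). Constant predictors are dropped up front.
#' Re-screening a retained set changes nothing.
#'
#' @param predictors data.frame of numeric candidate predictors.
#' @param threshold maximum allowed pairwise |r| (default 0.50).
#' @return list: `retained` (character), `dropped` (data.frame with
#'   `variable`, `reason`, `trigger`), `steps` (audit trail).
#' @export
screen_collinear <- function(predictors, threshold = 0.50) {
  stopifnot(is.data.frame(predictors), ncol(predictors) >= 1L)
  vars <- names(predictors)
  dropped <- list(); steps <- character()
  const <- vars[vapply(predictors, function(x) stats::sd(x, na.rm = TRUE),
                       1) == 0 | vapply(predictors, function(x)
                         all(is.na(x)), NA)]
  for (v in const) {
    dropped[[v]] <- data.frame(variable = v, reason = "constant",
                               trigger = NA_real_)
    steps <- c(steps, paste0("dropped ", v, ": constant"))
  }
  keep <- setdiff(vars, const)
  while (length(keep) >= 2L) {
    cm <- abs(stats::cor(predictors[keep], use = "pairwise.complete.obs"))
    diag(cm) <- 0
    worst <- max(cm)
    if (worst <= threshold) break
    pair_idx <- which(cm == worst, arr.ind = TRUE)
    pair_idx <- pair_idx[order(pair_idx[, 1L], pair_idx[, 2L]), ,
                         drop = FALSE]
    i <- pair_idx[1L, 1L]; j <- pair_idx[1L, 2L]
    mi <- mean(cm[i, -i]); mj <- mean(cm[j, -j])
    out_idx <- if (mi > mj) i else if (mj > mi) j else max(i, j)
    v <- keep[out_idx]
    dropped[[v]] <- data.frame(variable = v, reason = "collinear",
                               trigger = worst)
    steps <- c(steps, sprintf("dropped %s: |r| = %.3f with %s", v, worst,
                              keep[setdiff(c(i, j), out_idx)]))
    keep <- setdiff(keep, v)
  }
  list(retained = keep,
       dropped = if (length(dropped)) do.call(rbind, dropped) else
         data.frame(variable = character(), reason = character(),
                    trigger = numeric()),
       steps = steps)
}

# Second-order Akaike information criterion.
aicc <- function(fit) {
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  if (n - k - 1 <= 0) return(Inf)
  -2 * as.numeric(ll) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Variance-partition (Nakagawa-style) marginal and conditional R2 for a
# gaussian lmer fit: fixed / (fixed + random + residual) and
# (fixed + random) / (fixed + random + residual).
r2_mixed <- function(fit) {
  if (inherits(fit, "merMod")) {
    var_f <- stats::var(as.vector(stats::model.matrix(fit) %*%
                                    lme4::fixef(fit)))
    vc <- lme4::VarCorr(fit)
    var_r <- sum(vapply(vc, function(m) sum(diag(m)), 1))
    var_e <- attr(vc, "sc")^2
  } else {
    var_f <- stats::var(stats::fitted(fit))
    var_r <- 0
    var_e <- summary(fit)$sigma^2
  }
  tot <- var_f + var_r + var_e
  c(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}

coef_table <- function(fit) {
  sm <- if (inherits(fit, "merMod")) summary(fit)$coefficients else
    summary(fit)$coefficients[, 1:3, drop = FALSE]
  est <- sm[, 1L]; se <- sm[, 2L]
  p <- 2 * stats::pnorm(abs(est / se), lower.tail = FALSE)
  data.frame(term = rownames(sm), estimate = est, se = se,
             star = ifelse(p < 0.05, "*", ""), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' AICc model selection for the growth dominance coefficient
#'
#' Screens the candidate predictors for collinearity, then fits every subset
#' of the retained predictors up to `max_terms` fixed effects (plus the full
#' retained set) as a linear mixed model with a plot random intercept
#' (maximum likelihood), ranks candidates by AICc with Akaike weights, and
#' reports coefficient tables with significance stars and marginal /
#' conditional R2 for the best and the full model. Candidates with more
#' parameters than observations are skipped with a reason. When plots have
#' no repeated measures the random intercept is unidentifiable and a plain
#' linear model is used, flagged in the report.
#'
#' @param dc_table data.frame with columns `plot_id`, `dc` and one column
#'   per candidate predictor (constant within plot or per plot-period).
#' @param predictors character vector naming the candidate predictor
#'   columns; empty for an intercept-only report.
#' @param threshold collinearity threshold (default 0.50).
#' @param max_terms maximum number of fixed effects per candidate subset
#'   (default 4); the full screened model is always included.
#' @return list: `ranking` (data.frame: model, k, AICc, delta, weight),
#'   `best`, `full` (each: formula string, coefficients, AICc, r2),
#'   `screen` (collinearity audit), `skipped`.
#' @export
dc_climate_model_selection <- function(dc_table, predictors,
                                       threshold = 0.50, max_terms = 4L) {
  stopifnot(all(c("plot_id", "dc") %in% names(dc_table)))
  missing_pred <- setdiff(predictors, names(dc_table))
  if (length(missing_pred)) {
    stop("predictor column(s) not in table: ",
         paste(missing_pred, collapse = ", "), call. = FALSE)
  }
  screen <- if (length(predictors)) {
    screen_collinear(dc_table[predictors], threshold)
  } else list(retained = character(),
              dropped = data.frame(), steps = character())
  retained <- screen$retained
  subsets <- list(character())
  for (size in seq_len(min(max_terms, length(retained)))) {
    cmb <- utils::combn(retained, size, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  if (length(retained) > max_terms) subsets <- c(subsets, list(retained))
  use_lmer <- anyDuplicated(dc_table$plot_id) > 0L
  fit_one <- function(terms) {
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    if (use_lmer) {
      fml <- stats::as.formula(paste("dc ~", rhs, "+ (1 | plot_id)"))
      suppressMessages(suppressWarnings(
        lme4::lmer(fml, data = dc_table, REML = FALSE)))
    } else {
      stats::lm(stats::as.formula(paste("dc ~", rhs)), data = dc_table)
    }
  }
  fits <- list(); rows <- list(); skipped <- list()
  for (terms in subsets) {
    label <- if (length(terms)) paste(terms, collapse = " + ") else
      "(intercept only)"
    k <- length(terms) + 1L + if (use_lmer) 2L else 1L
    if (k + 1L >= nrow(dc_table)) {
      skipped[[label]] <- "more parameters than observations"
      next
    }
    fit <- tryCatch(fit_one(terms), error = function(e) NULL)
    if (is.null(fit)) { skipped[[label]] <- "fit failed"; next }
    fits[[label]] <- fit
    rows[[label]] <- data.frame(model = label, k = k, AICc = aicc(fit),
                                stringsAsFactors = FALSE)
  }
  ranking <- do.call(rbind, rows)
  ranking <- ranking[order(ranking$AICc), , drop = FALSE]
  ranking$delta <- ranking$AICc - ranking$AICc[1L]
  ranking$weight <- exp(-0.5 * ranking$delta) /
    sum(exp(-0.5 * ranking$delta))
  rownames(ranking) <- NULL
  report <- function(label) {
    fit <- fits[[label]]
    r2 <- r2_mixed(fit)
    list(model = label, coefficients = coef_table(fit), AICc = aicc(fit),
         r2_marginal = unname(r2["marginal"]),
         r2_conditional = unname(r2["conditional"]),
         engine = if (use_lmer) "lmer" else "lm")
  }
  full_label <- if (length(retained))
    paste(retained, collapse = " + ") else "(intercept only)"
  list(ranking = ranking, best = report(ranking$model[1L]),
       full = report(full_label), screen = screen,
       skipped = if (length(skipped))
         data.frame(model = names(skipped),
                    reason = unlist(skipped), row.names = NULL) else NULL)
}
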