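# Sample-size and size-range sensitivity experiments: how well do growth
# partitioning indices computed from small random samples of trees agree
# with the full-plot values, and how much does removing the largest trees
# bias the growth dominance coefficient?

# Stable 31-bit hash of a string, used to key per-plot sampling seeds to the
# plot identity (not to row or plot order).
string_seed <- function(x) {
  v <- utf8ToInt(x)
  h <- 0
  for (i in seq_along(v)) h <- (h * 31 + v[i]) %% 2147483629
  as.integer(h)
}

sub_seed <- function(seed, plot_id, n, replicate) {
  as.integer((as.numeric(seed) * 2654435 + string_seed(plot_id) +
                n * 97003 + replicate * 13007) %% 2147483629) + 1L
}

#' Compute a partitioning index on a random subsample of a plot
#'
#' Draws a simple random sample of `n` trees without replacement and computes
#' the requested index on the chosen target variable. Sampling is keyed to
#' the sorted tree identifiers and the seed, so it is deterministic and
#' invariant to the row order of the input. Requesting more trees than the
#' plot holds raises a skip signal (condition class `growthdom_skip`).
#'
#' @param plot a `plot_census` whose trees carry `dbh_cm` and
#'   `dbh_increment_cm`.
#' @param n sample size.
#' @param index_kind `"DC"` or `"SGR"`.
#' @param variable `"diameter"`, `"basal_area"` or `"stem_mass"`.
#' @param seed integer seed.
#' @param coeffs [allometry_table()] used for `stem_mass`.
#' @return a `partition_result`.
#' @export
subsample_index <- function(plot, n, index_kind = c("DC", "SGR"),
                            variable = c("basal_area", "diameter",
                                         "stem_mass"),
                            seed = 1L, coeffs = allometry_table()) {
  index_kind <- match.arg(index_kind)
  variable <- match.arg(variable)
  stopifnot(inherits(plot, "plot_census"))
  trees <- plot$trees[plot$trees$status == "live", , drop = FALSE]
  trees <- trees[order(trees$tree_id), , drop = FALSE]
  if (n > nrow(trees)) {
    stop(errorCondition(
      paste0("plot ", plot$plot_id, " has ", nrow(trees),
             " live trees, fewer than the requested sample of ", n),
      class = c("growthdom_skip", "error")))
  }
  sel <- if (n == nrow(trees)) seq_len(nrow(trees)) else
    with_seed(seed, sample.int(nrow(trees), n))
  sub <- tree_measures(trees[sel, , drop = FALSE], variable, coeffs)
  sub$weight <- 1  # random subsampling breaks per-hectare representation
  if (index_kind == "DC") {
    growth_dominance_coefficient(sub, variable, plot_id = plot$plot_id)
  } else {
    size_growth_relationship(sub, variable, plot_id = plot$plot_id)
  }
}

#' Sample-size sensitivity of partitioning indices
#'
#' For each stand structure stratum and each sample size in the ladder,
#' draws `replicates` independent subsamples per plot, computes the index,
#' and reports the Pearson correlation between full-plot and subsample
#' values across plots, averaged over replicates. Cells whose correlation is
#' undefined (zero variance, or index failures on every plot) are reported
#' as missing with a reason code rather than dropped.
#'
#' @param plots list of `plot_census` objects (intended: at least 100 trees
#'   each and at least 3 plots per structure stratum; fewer plots produce a
#'   low-power warning, not an error).
#' @param ladder sample sizes (default 5, 8, 10, 20, 30, 50, 100).
#' @param index_kind `"DC"` or `"SGR"`.
#' @param variable target variable.
#' @param replicates subsample draws per plot and sample size (default 25;
#'   1 mimics a single-draw design).
#' @param seed master seed.
#' @param coeffs [allometry_table()] for `stem_mass`.
#' @return data.frame (`sensitivity_table`): `structure`, `index_kind`,
#'   `variable`, `sample_size`, `pearson_r`, `n_plots`,
#'   `replicates_per_plot`, `flag`.
#' @export
sensitivity_analysis <- function(plots,
                                 ladder = c(5L, 8L, 10L, 20L, 30L, 50L, 100L),
                                 index_kind = c("DC", "SGR"),
                                 variable = c("basal_area", "diameter",
                                              "stem_mass"),
                                 replicates = 25L, seed = 1L,
                                 coeffs = allometry_table()) {
  index_kind <- match.arg(index_kind)
  variable <- match.arg(variable)
  stopifnot(length(plots) >= 2L, all(ladder >= 2L))
  strata <- vapply(plots, function(p)
    if (is.na(p$structure)) "unknown" else p$structure, "")
  out <- list()
  for (st in unique(strata)) {
    idx <- which(strata == st)
    if (length(idx) < 3L) {
      warning("structure stratum ", st, " has only ", length(idx),
              " plots; correlations will have low power")
    }
    full <- vapply(plots[idx], function(p) {
      tryCatch(subsample_index(p, sum(p$trees$status == "live"), index_kind,
                               variable, seed = 0L, coeffs)$value,
               error = function(e) NA_real_)
    }, 1)
    for (n in ladder) {
      rs <- numeric(0); reason <- character(0)
      for (r in seq_len(replicates)) {
        sub <- vapply(seq_along(idx), function(k) {
          p <- plots[[idx[k]]]
          tryCatch(subsample_index(p, n, index_kind, variable,
                                   seed = sub_seed(seed, p$plot_id, n, r),
                                   coeffs)$value,
                   error = function(e) NA_real_)
        }, 1)
        ok <- is.finite(full) & is.finite(sub)
        if (sum(ok) < 3L) { reason <- c(reason, "too_few_pairs"); next }
        if (stats::sd(full[ok]) == 0 || stats::sd(sub[ok]) == 0) {
          reason <- c(reason, "zero_variance"); next
        }
        rs <- c(rs, stats::cor(full[ok], sub[ok]))
      }
      out[[length(out) + 1L]] <- data.frame(
        structure = st, index_kind = index_kind, variable = variable,
        sample_size = n,
        pearson_r = if (length(rs)) mean(rs) else NA_real_,
        n_plots = length(idx), replicates_per_plot = replicates,
        flag = if (length(rs)) "" else paste(unique(reason), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("sensitivity_table", "data.frame")
  res
}

#' Effect of removing the largest trees on the growth dominance coefficient
#'
#' For each plot, draws one random sample of `base_n` trees, computes the DC,
#' then recomputes it after removing the largest `n_removed` trees from the
#' same sample (paired design), and runs a two-sided Wilcoxon signed-rank
#' test on the paired plot values for each removal level.
#'
#' @param plots list of `plot_census` objects, each with at least `base_n`
#'   live trees.
#' @param base_n size of the random base sample (default 100).
#' @param removals numbers of largest trees to remove (default 10 and 20);
#'   must be below `base_n`.
#' @param variable target variable.
#' @param seed master seed.
#' @param coeffs [allometry_table()] for `stem_mass`.
#' @return list of `removal_test` results, one per removal level: `pairs`
#'   (plot_id, dc_full, dc_reduced), `n_removed`, `statistic`, `p_value`,
#'   `mean_shift` (reduced minus full), `flag`.
#' @export
largest_tree_removal_test <- function(plots, base_n = 100L,
                                      removals = c(10L, 20L),
                                      variable = c("basal_area", "diameter",
                                                   "stem_mass"),
                                      seed = 1L,
                                      coeffs = allometry_table()) {
  variable <- match.arg(variable)
  if (any(removals >= base_n)) {
    stop("cannot remove ", max(removals), " trees from samples of ", base_n,
         call. = FALSE)
  }
  lapply(removals, function(k) {
    pairs <- lapply(plots, function(p) {
      trees <- p$trees[p$trees$status == "live", , drop = FALSE]
      trees <- trees[order(trees$tree_id), , drop = FALSE]
      if (base_n > nrow(trees)) {
        stop("plot ", p$plot_id, " has fewer than ", base_n, " live trees",
             call. = FALSE)
      }
      sel <- with_seed(sub_seed(seed, p$plot_id, base_n, 0L),
                       sample.int(nrow(trees), base_n))
      samp <- tree_measures(trees[sel, , drop = FALSE], variable, coeffs)
      samp$weight <- 1
      keep <- order(samp$size, decreasing = TRUE)[-seq_len(k)]
      data.frame(
        plot_id = p$plot_id,
        dc_full = growth_dominance_coefficient(samp, variable)$value,
        dc_reduced = growth_dominance_coefficient(samp[keep, , drop = FALSE],
                                                  variable)$value,
        stringsAsFactors = FALSE)
    })
    pairs <- do.call(rbind, pairs)
    diffs <- pairs$dc_reduced - pairs$dc_full
    if (all(abs(diffs) < 1e-12)) {
      res <- list(statistic = NA_real_, p_value = NA_real_,
                  flag = "degenerate_all_differences_zero")
    } else {
      wt <- stats::wilcox.test(pairs$dc_reduced, pairs$dc_full,
                               paired = TRUE, exact = FALSE)
      res <- list(statistic = unname(wt$statistic), p_value = wt$p.value,
                  flag = "")
    }
    structure(list(n_removed = k, pairs = pairs,
                   wilcoxon_statistic = res$statistic,
                   p_value = res$p_value, mean_shift = mean(diffs),
                   flag = res$flag),
              class = "removal_test")
  })
}

#' @export
print.removal_test <- function(x, ...) {
  cat(sprintf(
    "<removal_test> largest %d removed: mean DC shift %+.4f, V = %s, p = %s%s\n",
    x$n_removed, x$mean_shift, format(x$wilcoxon_statistic),
    format.pval(x$p_value),
    if (nzchar(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}
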