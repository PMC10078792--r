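# Growth partitioning indices: the growth dominance coefficient (DC) and the
# size-growth relationship slope (SGR), plus the per-tree derived quantities
# (basal area, stem mass) that they consume.

#' Construct a tree record table
#'
#' A tree record table is an ordinary `data.frame` with one row per tree and
#' at least the columns `size` (positive; diameter in cm, basal area in m2 or
#' stem mass in kg) and `growth` (increment in the same dimension family as
#' `size`). Optional columns: `tree_id` (opaque identifier; defaults to the
#' row number), `species` (character code), `status` (`live`, `dead` or
#' `thinned`) and `weight` (positive per-hectare representation factor,
#' default 1).
#'
#' @param size numeric vector of positive sizes.
#' @param growth numeric vector of increments, same length as `size`.
#' @param tree_id identifiers; default `seq_along(size)`.
#' @param species character species codes, recycled.
#' @param weight positive representation weights, recycled.
#' @return a `data.frame` usable by [growth_dominance_coefficient()] and
#'   [size_growth_relationship()].
#' @export
tree_records <- function(size, growth, tree_id = seq_along(size),
                         species = "other", weight = 1) {
  stopifnot(length(size) == length(growth))
  data.frame(tree_id = as.character(tree_id), size = as.numeric(size),
             growth = as.numeric(growth),
             species = rep_len(as.character(species), length(size)),
             weight = rep_len(as.numeric(weight), length(size)),
             stringsAsFactors = FALSE)
}

# Validate and normalize a tree record table for an index computation.
# Returns the table with tree_id / weight columns filled in.
check_tree_records <- function(trees, min_n = 1L) {
  if (!is.data.frame(trees)) stop("`trees` must be a data.frame", call. = FALSE)
  if (nrow(trees) == 0L) stop("empty tree table: at least ", min_n,
                              " tree(s) required", call. = FALSE)
  for (col in c("size", "growth")) {
    if (is.null(trees[[col]])) stop("missing column `", col, "`", call. = FALSE)
  }
  if (is.null(trees$tree_id)) trees$tree_id <- as.character(seq_len(nrow(trees)))
  if (is.null(trees$weight)) trees$weight <- 1
  bad <- which(!is.finite(trees$size) | trees$size <= 0)
  if (length(bad)) {
    stop("non-positive or non-finite size for tree record(s): ",
         paste(utils::head(trees$tree_id[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(trees$weight) | trees$weight <= 0)) {
    stop("weights must be positive and finite", call. = FALSE)
  }
  if (nrow(trees) < min_n) {
    stop("need at least ", min_n, " trees, got ", nrow(trees), call. = FALSE)
  }
  trees
}

# Deterministic ascending order by size; ties broken by ascending growth,
# then tree_id. Makes the cumulative curve reproducible when sizes repeat.
order_by_size <- function(trees) {
  trees[order(trees$size, trees$growth, trees$tree_id), , drop = FALSE]
}

new_partition_result <- function(value, index_kind, variable, n_trees,
                                 plot_id = NA_character_, flags = character()) {
  structure(list(value = value, index_kind = index_kind, variable = variable,
                 n_trees = n_trees, plot_id = plot_id, flags = flags),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("<%s on %s> value = %.6g (n = %d%s)%s\n", x$index_kind,
              x$variable, x$value, x$n_trees,
              if (is.na(x$plot_id)) "" else paste0(", plot ", x$plot_id),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","),
                                          "]") else ""))
  invisible(x)
}

#' Growth dominance coefficient
#'
#' Arranges trees in ascending order of size, forms the weighted cumulative
#' proportional size \eqn{s_i} and the weighted cumulative proportional
#' growth \eqn{\Delta_i} (with \eqn{s_0 = \Delta_0 = 0}), and evaluates the
#' trapezoid form
#' \deqn{DC = 1 - \sum_{i=1}^{n} (s_i - s_{i-1})(\Delta_i + \Delta_{i-1}).}
#' `DC = 0` means trees grew in proportion to their size; `DC > 0` means
#' large trees grew disproportionately more for their size; `DC < 0` means
#' small trees did. With non-negative growth the value lies in \[-1, 1\].
#'
#' Negative increments (shrinkage, measurement noise) are clamped to zero by
#' default, which preserves the bound; `negative_growth_policy = "keep"`
#' retains them and flags the result, and the caller accepts out-of-bound
#' values.
#'
#' @param trees tree record table (see [tree_records()]); per-hectare weights
#'   multiply both size and growth contributions.
#' @param variable label for the size dimension: `"diameter"`, `"basal_area"`
#'   or `"stem_mass"` (metadata only; `size`/`growth` must already be on that
#'   scale).
#' @param negative_growth_policy `"clamp_to_zero"` (default) or `"keep"`.
#' @param plot_id optional provenance label.
#' @return a `partition_result` with `index_kind = "DC"`.
#' @export
growth_dominance_coefficient <- function(trees,
                                         variable = c("basal_area", "diameter",
                                                      "stem_mass"),
                                         negative_growth_policy =
                                           c("clamp_to_zero", "keep"),
                                         plot_id = NA_character_) {
  variable <- match.arg(variable)
  negative_growth_policy <- match.arg(negative_growth_policy)
  trees <- check_tree_records(trees, min_n = 1L)
  flags <- character()
  if (negative_growth_policy == "clamp_to_zero") {
    if (any(trees$growth < 0)) flags <- c(flags, "negative_growth_clamped")
    trees$growth <- pmax(trees$growth, 0)
  } else if (any(trees$growth < 0)) {
    flags <- c(flags, "negative_growth_kept")
  }
  trees <- order_by_size(trees)
  ws <- trees$weight * trees$size
  wg <- trees$weight * trees$growth
  if (sum(wg) <= 0) {
    stop("total growth is not positive after the negative-growth policy; DC undefined",
         call. = FALSE)
  }
  s <- cumsum(ws) / sum(ws)
  d <- cumsum(wg) / sum(wg)
  dc <- 1 - sum((s - c(0, s[-length(s)])) * (d + c(0, d[-length(d)])))
  new_partition_result(dc, "DC", variable, nrow(trees), plot_id, flags)
}

#' Size-growth relationship slope
#'
#' Ordinary-least-squares slope of proportional individual growth
#' \eqn{p_i = g_i / \sum w g} on proportional individual size
#' \eqn{q_i = x_i / \sum w x}, with representation weights applied to both
#' normalizing sums and as regression weights. Growth exactly proportional to
#' size gives slope 1; equal growth for all trees gives slope 0.
#'
#' @inheritParams growth_dominance_coefficient
#' @return a `partition_result` with `index_kind = "SGR"`.
#' @export
size_growth_relationship <- function(trees,
                                     variable = c("basal_area", "diameter",
                                                  "stem_mass"),
                                     plot_id = NA_character_) {
  variable <- match.arg(variable)
  trees <- check_tree_records(trees, min_n = 2L)
  w <- trees$weight
  if (sum(w * trees$growth) == 0) {
    stop("total growth is zero; SGR undefined", call. = FALSE)
  }
  q <- trees$size / sum(w * trees$size)
  p <- trees$growth / sum(w * trees$growth)
  qbar <- sum(w * q) / sum(w)
  pbar <- sum(w * p) / sum(w)
  sqq <- sum(w * (q - qbar)^2)
  if (sqq <= .Machine$double.eps * max(q)^2 * length(q)) {
    stop("degenerate fit: zero variance in proportional size", call. = FALSE)
  }
  slope <- sum(w * (q - qbar) * (p - pbar)) / sqq
  new_partition_result(slope, "SGR", variable, nrow(trees), plot_id)
}

#' Tree basal area from diameter
#'
#' Cross-sectional stem area at 1.3 m height, `pi * (d / 200)^2`, in m2 for a
#' diameter in cm.
#'
#' @param diameter_cm positive diameter(s) at 1.3 m, cm.
#' @return basal area in m2.
#' @export
basal_area <- function(diameter_cm) {
  if (any(!is.finite(diameter_cm) | diameter_cm <= 0)) {
    stop("diameter must be positive and finite", call. = FALSE)
  }
  pi * (diameter_cm / 200)^2
}

#' Allometry coefficient table
#'
#' Species-specific power-law coefficients for stem mass,
#' `M = multiplier * d^exponent` (d in cm, M in kg). The species `"*"` acts
#' as a wildcard fallback. The functional form is a configurable stand-in:
#' published European biomass equation systems supply their own species
#' coefficients, which are external to this package.
#'
#' @param species character species codes (`"*"` = wildcard).
#' @param multiplier positive multipliers.
#' @param exponent positive exponents.
#' @return a `data.frame` of class `allometry_table`.
#' @export
allometry_table <- function(species = "*", multiplier = 0.095,
                            exponent = 2.4) {
  tab <- data.frame(species = as.character(species),
                    multiplier = as.numeric(multiplier),
                    exponent = as.numeric(exponent),
                    stringsAsFactors = FALSE)
  if (any(!is.finite(tab$multiplier) | tab$multiplier <= 0) ||
      any(!is.finite(tab$exponent) | tab$exponent <= 0)) {
    stop("allometry multiplier and exponent must be positive", call. = FALSE)
  }
  if (anyDuplicated(tab$species)) {
    stop("duplicate species in allometry table", call. = FALSE)
  }
  class(tab) <- c("allometry_table", "data.frame")
  tab
}

resolve_allometry <- function(species, coeffs) {
  idx <- match(species, coeffs$species)
  wild <- match("*", coeffs$species)
  idx[is.na(idx)] <- wild
  if (anyNA(idx)) {
    stop("no allometry coefficients for species ",
         paste(unique(species[is.na(match(species, coeffs$species))]),
               collapse = ", "), " and no wildcard entry", call. = FALSE)
  }
  coeffs[idx, , drop = FALSE]
}

#' Stem mass from diameter
#'
#' Power-law stem mass `M = multiplier * d^exponent` with per-species
#' coefficients resolved from an [allometry_table()] (wildcard fallback).
#' Strictly increasing in diameter.
#'
#' @param diameter_cm positive diameter(s), cm.
#' @param species species code(s), recycled.
#' @param coeffs an [allometry_table()].
#' @return stem mass in kg.
#' @export
stem_mass <- function(diameter_cm, species = "*", coeffs = allometry_table()) {
  if (any(!is.finite(diameter_cm) | diameter_cm <= 0)) {
    stop("diameter must be positive and finite", call. = FALSE)
  }
  species <- rep_len(as.character(species), length(diameter_cm))
  cf <- resolve_allometry(species, coeffs)
  cf$multiplier * diameter_cm^cf$exponent
}

# Derive size and growth on the requested variable scale from an interval
# table holding dbh at the start census and the diameter increment over the
# interval (both cm). Basal-area and stem-mass growth are end-minus-start
# transforms, not transforms of the diameter increment.
tree_measures <- function(interval, variable = c("basal_area", "diameter",
                                                 "stem_mass"),
                          coeffs = allometry_table()) {
  variable <- match.arg(variable)
  d0 <- interval$dbh_cm
  d1 <- interval$dbh_cm + pmax(interval$dbh_increment_cm, 0)
  species <- if (is.null(interval$species)) "*" else interval$species
  sz <- switch(variable,
               diameter = d0,
               basal_area = basal_area(d0),
               stem_mass = stem_mass(d0, species, coeffs))
  gr <- switch(variable,
               diameter = d1 - d0,
               basal_area = basal_area(d1) - basal_area(d0),
               stem_mass = stem_mass(d1, species, coeffs) -
                 stem_mass(d0, species, coeffs))
  out <- interval
  out$size <- sz
  out$growth <- gr
  out
}
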