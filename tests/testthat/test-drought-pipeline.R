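test_that("expansion weights follow the nested-circle design", {
  expect_equal(expansion_weight(15), 50)
  expect_equal(expansion_weight(40), 20)
  expect_equal(expansion_weight(36), 20)  # boundary joins the outer circle
  expect_equal(expansion_weight(35.999), 50)
  expect_error(expansion_weight(11.9), "threshold")
})

test_that("annualize divides by interval length and validates it", {
  expect_equal(annualize(0.006, 3), 0.002)
  expect_equal(annualize(0.002, 1), 0.002)
  expect_error(annualize(0.01, 0), "positive")
  # regression: vector increments with a scalar interval must stay vectors
  expect_equal(annualize(c(0.006, 0.009), 3), c(0.002, 0.003))
  expect_length(annualize(rep(0.01, 5), 1), 5L)
})

test_that("census intervals map onto growth periods", {
  p <- assign_period("2010-04-01", "2018-04-01")
  expect_equal(p$label, "2010-2017")
  expect_equal(p$interval_years, 8L)
  expect_equal(assign_period("2018-04-01", "2018-09-15")$label, "2018")
  expect_equal(assign_period("2019-09-15", "2020-09-15")$label, "2020")
  expect_equal(assign_period("1984-04-01", "1995-04-01")$interval_years, 11L)
  expect_error(assign_period("2018-09-15", "2018-04-01"), "ordered")
  expect_error(assign_period("1950-04-01", "1960-04-01"), "no configured")
  # every census pair among the default dates maps to exactly one label
  dates <- c("1984-04-01", "1995-04-01", "2005-04-01", "2010-04-01",
             "2018-04-01", "2018-09-15", "2019-09-15", "2020-09-15")
  labels <- sapply(seq_len(length(dates) - 1L), function(j)
    assign_period(dates[j], dates[j + 1L])$label)
  expect_identical(labels, default_periods()$label)
})

test_that("stand-type classification uses the weighted 50% beech share", {
  trees <- data.frame(tree_id = as.character(1:2), dbh_cm = c(40, 20),
                      species = c("beech", "other"), status = "live",
                      weight = expansion_weight(c(40, 20)))
  p <- plot_census("x", as.Date("2018-04-01"), trees)
  # beech share = 20*ba(40) / (20*ba(40) + 50*ba(20)) = 0.615 -> dominated
  expect_equal(classify_stand_type(p), "beech_dominated")
  trees$species <- c("other", "beech")
  expect_equal(classify_stand_type(plot_census("x", "2018-04-01", trees)),
               "beech_admixed")
  # share exactly 0.5 counts as dominated
  eq <- data.frame(tree_id = as.character(1:2), dbh_cm = c(30, 30),
                   species = c("beech", "other"), status = "live",
                   weight = 1)
  expect_equal(classify_stand_type(plot_census("x", "2018-04-01", eq)),
               "beech_dominated")
  dead <- eq; dead$status <- "dead"
  expect_error(classify_stand_type(plot_census("x", "2018-04-01", dead)),
               "no live trees")
})

test_that("plot filter retains >= 8 live trees and logs exclusions", {
  mkplot <- function(id, n) plot_census(id, "2018-04-01", data.frame(
    tree_id = as.character(seq_len(n)), dbh_cm = runif(n, 12, 40),
    species = "other", status = "live", weight = 1))
  res <- filter_plots(list(mkplot("a", 7L), mkplot("b", 8L),
                           mkplot("c", 30L)))
  expect_equal(vapply(res$retained, `[[`, "", "plot_id"), c("b", "c"))
  expect_false(res$log$retained[res$log$plot_id == "a"])
  expect_warning(filter_plots(list()), "no plots")
})

test_that("interval tables conserve stand basal area and honour filters", {
  cen <- generate_inventory_dataset(6L, null_scenario(), n_trees = c(6L, 40L),
                                    seed = 14L)
  tabs <- build_interval_tables(cen, min_trees = 8L)
  # conservation: stand_ba equals sum over trees of weight x tree basal area
  key <- paste(tabs$tree_table$plot_id, tabs$tree_table$period)
  for (k in unique(key)) {
    rows <- tabs$tree_table[key == k, ]
    expect_equal(rows$stand_ba[1L],
                 sum(rows$weight * rows$tree_ba), tolerance = 1e-9)
  }
  # plots with < 8 trees are excluded and logged
  n0 <- table(cen$plot_id[cen$census_date == min(cen$census_date)])
  small <- names(n0)[n0 < 8]
  if (length(small)) {
    expect_true(all(small %in% tabs$exclusions$plot_id))
    expect_false(any(small %in% tabs$dc_table$plot_id))
  }
  expect_true(all(tabs$dc_table$n_trees >= 8))
  expect_setequal(unique(tabs$dc_table$period), default_periods()$label)
})

test_that("period model: reference coding invariance and single-period error", {
  cen <- generate_inventory_dataset(16L, null_scenario(), n_trees = 20L,
                                    seed = 5L)
  tabs <- build_interval_tables(cen)
  fit18 <- fit_dc_period_model(tabs$dc_table, reference = "2018")
  fit19 <- fit_dc_period_model(tabs$dc_table, reference = "2019")
  expect_lt(max(abs(fitted(fit18$model) - fitted(fit19$model))), 1e-8)
  # cell means agree between parameterizations
  a <- fit18$cells[order(fit18$cells$stand_type, fit18$cells$period), ]
  b <- fit19$cells[order(fit19$cells$stand_type, fit19$cells$period), ]
  expect_equal(a$estimate, b$estimate, tolerance = 1e-8)
  one <- tabs$dc_table[tabs$dc_table$period == "2018", ]
  expect_error(fit_dc_period_model(one), "two growth periods")
})

test_that("Tukey letters are consistent with the p-value matrix", {
  lev <- c("A", "B", "C", "D")
  pm <- matrix(1, 4, 4, dimnames = list(lev, lev))
  pm["A", "D"] <- pm["D", "A"] <- 0.001
  pm["A", "C"] <- pm["C", "A"] <- 0.02
  lt <- tukey_letters(pm, means = c(A = 4, B = 3, C = 2, D = 1),
                      alpha = 0.05)
  names(lt) <- lev
  share <- function(i, j) {
    any(strsplit(lt[[i]], "")[[1]] %in% strsplit(lt[[j]], "")[[1]])
  }
  for (i in lev) for (j in lev) {
    if (i != j) expect_equal(share(i, j), pm[i, j] >= 0.05,
                             info = paste(i, j))
  }
  # all-equal case: one letter for everyone
  pm1 <- matrix(1, 3, 3, dimnames = list(lev[1:3], lev[1:3]))
  expect_true(all(tukey_letters(pm1, c(1, 2, 3)) == "a"))
})

test_that("BAI period model recovers a drought-year growth dip", {
  sc <- drought_scenario(reductions = data.frame(
    label = "2018", species = "*", reduction = 0.5))
  cen <- generate_inventory_dataset(24L, sc, n_trees = 25L,
                                    growth_law = list(alpha = 0.05,
                                                      beta = 0.01, gamma = 1,
                                                      sd = 0.1,
                                                      sd_interval = 0.02),
                                    seed = 31L)
  tabs <- build_interval_tables(cen)
  fit <- fit_bai_period_model(tabs$tree_table)
  cells <- fit$cells
  for (st in unique(cells$stand_type)) {
    cc <- cells[cells$stand_type == st, ]
    expect_equal(cc$period[which.min(cc$estimate)], "2018")
  }
  expect_error(fit_bai_period_model(tabs$tree_table[0, ]), ".")
})

test_that("size and density slopes recover the growth law", {
  # growth law beta > 0, gamma = 1 on diameter implies positive BAI-size
  # slope; check sign and that weak cells are flagged
  cen <- generate_inventory_dataset(16L, null_scenario(), n_trees = 30L,
                                    seed = 8L)
  tabs <- build_interval_tables(cen)
  sl <- size_and_density_slopes(tabs$tree_table)
  ok <- sl$flag %in% c("", "single_plot_lm")
  expect_true(any(ok))
  expect_true(all(sl$slope_tree_ba[ok] > 0))
  expect_true(all(sl$r2_tree_ba[ok] > 0.2))
  tiny <- tabs$tree_table[1:5, ]
  expect_equal(unique(size_and_density_slopes(tiny)$flag), "too_few_trees")
})
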