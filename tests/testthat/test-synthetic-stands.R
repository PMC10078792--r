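test_that("stand generation is deterministic and honours thresholds", {
  cfg <- stand_config("even_aged", n_trees = 150L, seed = 42L)
  a <- generate_stand(cfg)
  b <- generate_stand(cfg)
  expect_identical(a$trees, b$trees)
  expect_true(all(a$trees$dbh_cm >= 12))
  # seed isolation: generation does not disturb the caller's RNG stream
  set.seed(5); x1 <- runif(1)
  set.seed(5); invisible(generate_stand(cfg)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("structural laws have the intended shapes", {
  # even-aged: roughly symmetric unimodal diameters
  d <- generate_stand(stand_config("even_aged", n_trees = 500L,
                                   seed = 7L))$trees$dbh_cm
  skew <- mean((d - mean(d))^3) / stats::sd(d)^3
  expect_lt(abs(skew), 0.5)
  # selection: reverse-J; most trees in the smallest third of the range
  ok <- 0L
  for (s in 1:40) {
    d <- generate_stand(stand_config("selection", n_trees = 500L,
                                     diameter_law = list(rate_per_cm = 0.08,
                                                         max_cm = 80),
                                     seed = s))$trees$dbh_cm
    lower_third <- min(d) + (max(d) - min(d)) / 3
    expect_gt(mean(d < lower_third), 0.5)
    # strict monotonicity across every occupied 4-cm bin fails regularly
    # for a true shifted exponential (sparse tail bins invert by chance);
    # the reverse-J check uses 8-cm bins over the well-populated 12-44 cm
    h <- hist(d, breaks = c(seq(12, 44, by = 8), 84), plot = FALSE)$counts
    if (all(diff(h[1:4]) <= 0)) ok <- ok + 1L
  }
  expect_gte(ok / 40, 0.95)
})

test_that("beech share targeting works and errors when infeasible", {
  for (target in c(0, 0.15, 0.5, 0.7)) {
    st <- generate_stand(stand_config("even_aged", n_trees = 200L,
                                      beech_fraction_ba = target,
                                      seed = 11L))
    expect_lte(abs(st$beech_share - target), 0.05)
  }
  expect_error(generate_stand(stand_config("even_aged", n_trees = 2L,
                                           beech_fraction_ba = 0.5,
                                           seed = 1L)),
               "share")
})

test_that("proportional growth law yields DC = 0 by construction", {
  cfg <- stand_config("even_aged", n_trees = 80L,
                      growth_law = list(alpha = 0, beta = 0.01, gamma = 1,
                                        sd = 0),
                      seed = 3L)
  st <- generate_stand(cfg)
  tr <- tree_measures(st$trees, "diameter")
  expect_lt(abs(growth_dominance_coefficient(tr, "diameter")$value), 1e-12)
})

test_that("scenario validation enforces the multiplier and period contracts", {
  expect_error(drought_scenario(periods = data.frame()), "at least one")
  bad <- default_periods(); bad$start_year[2] <- 1990L
  expect_error(drought_scenario(periods = bad), "non-overlapping")
  expect_error(drought_scenario(reductions = data.frame(
    label = "2018", species = "beech", reduction = 1)), "multipliers")
  sc <- drought_scenario()
  m <- scenario_multiplier(sc, "2019", c("beech", "other"), c(1, 1))
  expect_equal(m, c(0.4, 0.8))
  expect_true(all(scenario_multiplier(sc, "1984-1994",
                                      c("beech", "other"), c(1, 1)) == 1))
})

test_that("null-scenario series keeps per-year increments constant", {
  cfg <- stand_config("even_aged", n_trees = 30L, seed = 9L,
                      weighting = "nfi")
  ser <- generate_inventory_series(cfg, null_scenario(), plot_id = "pX")
  per <- default_periods()
  dates <- sort(unique(ser$census_date))
  expect_equal(length(dates), nrow(per) + 1L)
  rates <- sapply(seq_len(nrow(per)), function(j) {
    a <- ser[ser$census_date == dates[j], ]
    b <- ser[ser$census_date == dates[j + 1], ]
    yrs <- per$end_year[j] - per$start_year[j] + 1L
    (b$dbh_cm[match(a$tree_id, b$tree_id)] - a$dbh_cm) / yrs
  })
  expect_true(all(abs(rates - rates[, 1]) < 1e-12))
})

test_that("drought scenario lowers post-drought growth of large beech", {
  cfg <- stand_config("even_aged", n_trees = 40L, seed = 21L,
                      beech_fraction_ba = 0.7)
  ser <- generate_inventory_series(cfg, drought_scenario(), plot_id = "pY")
  dates <- sort(unique(ser$census_date))
  d18 <- ser[ser$census_date == as.Date("2018-04-01"), ]
  d19 <- ser[ser$census_date == as.Date("2019-09-15"), ]
  d20 <- ser[ser$census_date == as.Date("2020-09-15"), ]
  big_beech <- d18$tree_id[d18$species == "beech" &
                             rank(d18$dbh_cm) > 0.8 * nrow(d18)]
  post <- d20$dbh_cm[match(big_beech, d20$tree_id)] -
    d19$dbh_cm[match(big_beech, d19$tree_id)]
  pre <- (d18$dbh_cm[match(big_beech, d18$tree_id)] -
            ser$dbh_cm[ser$census_date == dates[4] &
                         ser$tree_id %in% big_beech]) / 8
  expect_lt(mean(post), mean(pre))
})

test_that("weights change when trees cross the 36-cm circle boundary", {
  trees_lo <- data.frame(tree_id = "t1", dbh_cm = 35, species = "other",
                         status = "live", weight = expansion_weight(35))
  expect_equal(trees_lo$weight, 50)
  expect_equal(expansion_weight(36), 20)
})

test_that("climate generator contracts hold", {
  expect_error(generate_climate(1L, integer()), "non-empty")
  flat <- generate_climate(3L, 2000:2001, mean_annual_temp = 10,
                           seasonal_amplitude = 0, temp_sd = 0)
  expect_true(all(abs(flat$temp_c - 10) < 1e-12))
  cl <- generate_climate(4L, 1990:2010, precip_mean = 10, precip_sd = 60)
  expect_true(all(cl$precip_mm >= 0))
  expect_identical(generate_climate(5L, 2000:2002),
                   generate_climate(5L, 2000:2002))
})

test_that("multi-plot dataset alternates structure and stand type", {
  cen <- generate_inventory_dataset(4L, null_scenario(), n_trees = 25L,
                                    seed = 2L)
  expect_setequal(unique(cen$plot_id), sprintf("p%03d", 1:4))
  first <- cen[cen$census_date == min(cen$census_date), ]
  shares <- sapply(split(first, first$plot_id), function(d) {
    ba <- basal_area(d$dbh_cm) * expansion_weight(d$dbh_cm)
    sum(ba[d$species == "beech"]) / sum(ba)
  })
  expect_true(all(shares[c("p001", "p002")] >= 0.5))
  expect_true(all(shares[c("p003", "p004")] < 0.5))
})
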