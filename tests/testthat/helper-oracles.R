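# Independent oracles used across the suite. These deliberately avoid the
# package's own computational path.

# Lorenz-area oracle for the growth dominance coefficient: build the
# piecewise-linear cumulative curve through (0,0) and the (s_i, delta_i)
# points, integrate it numerically on a dense grid augmented with the knots,
# and return 1 - 2 * area.
oracle_dc <- function(size, growth, weight = rep(1, length(size)),
                      grid_n = 20000L) {
  ord <- order(size, growth)
  s <- cumsum(weight[ord] * size[ord]) / sum(weight * size)
  d <- cumsum(weight[ord] * growth[ord]) / sum(weight * growth)
  xs <- sort(unique(c(0, s, seq(0, 1, length.out = grid_n))))
  ys <- stats::approx(c(0, s), c(0, d), xout = xs, ties = "ordered")$y
  area <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  1 - 2 * area
}

# Closed-form weighted OLS slope of y on x.
oracle_ols_slope <- function(x, y, w = rep(1, length(x))) {
  xb <- sum(w * x) / sum(w)
  yb <- sum(w * y) / sum(w)
  sum(w * (x - xb) * (y - yb)) / sum(w * (x - xb)^2)
}

# A random stand with positive sizes and non-negative growth.
random_stand <- function(seed, max_n = 200L) {
  set.seed(seed)
  n <- sample.int(max_n, 1L)
  size <- if (seed %% 2L == 0L) stats::rlnorm(n, 3, 0.6) else
    stats::rexp(n, 0.05) + 1
  growth <- pmax(0, stats::rnorm(n, 0.3 + 0.01 * size, 0.3))
  if (sum(growth) == 0) growth[1L] <- 0.1
  tree_records(size, growth)
}

# Independent Thornthwaite implementation for the oracle comparison: scalar
# loop written from the published constants, with its own day-length code.
oracle_thornthwaite <- function(temp12, lat_deg, year = 2001L) {
  I <- 0
  for (tt in temp12) if (tt > 0) I <- I + (tt / 5)^1.514
  if (I == 0) return(rep(0, 12))
  a <- 0.49239 + 0.01792 * I - 0.0000771 * I^2 + 0.000000675 * I^3
  mid <- c(16, 45.5, 75, 105.5, 136, 166.5, 197, 228, 258.5, 289, 319.5, 350)
  ndays <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  out <- numeric(12)
  for (m in 1:12) {
    tt <- temp12[m]
    pet <- if (tt <= 0) 0 else if (tt < 26.5) 16 * (10 * tt / I)^a else
      -415.85 + 32.24 * tt - 0.43 * tt^2
    delta <- 0.409 * sin(2 * pi * mid[m] / 365 - 1.39)
    cosw <- -tan(lat_deg * pi / 180) * tan(delta)
    cosw <- min(1, max(-1, cosw))
    daylen <- 24 / pi * acos(cosw)
    out[m] <- pet * (daylen / 12) * (ndays[m] / 30)
  }
  out
}

# Small deterministic plot with a power-law size-growth relation.
power_law_plot <- function(plot_id, n = 120L, gamma = 1.5, seed = 1L,
                           structure = "even_aged") {
  set.seed(seed)
  d <- sort(stats::runif(n, 12, 70))
  trees <- data.frame(tree_id = sprintf("t%03d", seq_len(n)), dbh_cm = d,
                      dbh_increment_cm = 0.002 * d^gamma,
                      species = "other", status = "live", weight = 1,
                      stringsAsFactors = FALSE)
  plot_census(plot_id, as.Date("2000-04-01"), trees, structure = structure)
}
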