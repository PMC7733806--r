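two_atom_topo <- function() {
  mini_structure(list(list("CA", "ALA", 1, 0, 0, 0),
                      list("CA", "ALA", 2, 5, 0, 0)))
}

test_that("one-frame trajectories reproduce the static operations", {
  pair <- pump_pair_fixture()
  s <- pair$wt
  tj <- trajectory(s, matrix(as.numeric(t(coords(s))), nrow = 1))
  a <- evaluate_observable(tj, obs_triplet_angle(13, 86, 98))
  expect_equal(a$values, residue_triplet_angle(s, 13, 86, 98))
  d <- evaluate_observable(tj, obs_distance(337, 312))
  expect_equal(d$values, residue_pair_distance(s, 337, 312))
})

test_that("a linearly receding atom gives a linear distance series", {
  frames <- t(vapply(0:99, function(i) c(0, 0, 0, 5 + 0.1 * i, 0, 0),
                     numeric(6)))
  tj <- trajectory(two_atom_topo(), frames)
  ts <- evaluate_observable(tj, obs_distance(1, 2))
  expect_equal(ts$values[1], 5)
  expect_equal(unique(round(diff(ts$values), 9)), 0.1)
})

test_that("per-frame H-bond counts equal the generator ground truth", {
  # assemble a 6-frame trajectory over a donor/acceptor pair whose
  # separation crosses the criterion on a known schedule
  d_sched <- c(2.8, 3.2, 4.5, 3.4, 6.0, 3.0)
  topo <- mini_structure(list(list("N", "GLY", 1, 0, 0, 0),
                              list("O", "SER", 101, 2.8, 0, 0)))
  frames <- t(vapply(d_sched, function(d) c(0, 0, 0, d, 0, 0), numeric(6)))
  tj <- trajectory(topo, frames)
  ts <- evaluate_observable(
    tj, obs_hbond_count(atom_selection(ranges = list(c(1, 99))),
                        atom_selection(ranges = list(c(101, 199)))))
  expect_equal(ts$values, as.numeric(d_sched <= 3.5))
})

test_that("misspecified observables fail before frame iteration", {
  tj <- trajectory(two_atom_topo(), matrix(c(0, 0, 0, 5, 0, 0), 1))
  expect_error(evaluate_observable(tj, obs_distance(1, 99)), "not found")
})

test_that("densities integrate to one and modes land on the truth", {
  bt <- make_bimodal_trace(c(7.5, 8.8), c(0.3, 0.3), c(0.5, 0.5), 1e5,
                           seed = 31)
  dens <- histogram_density(bt$ts)
  area <- sum(diff(dens$x) * (head(dens$y, -1) + tail(dens$y, -1)) / 2)
  expect_equal(area, 1, tolerance = 1e-6)
  modes <- find_modes(dens)
  expect_length(modes, 2)
  expect_equal(modes[1], 7.5, tolerance = 0.1)
  expect_equal(modes[2], 8.8, tolerance = 0.1)
  # fixed-bin variant also normalizes (rectangle quadrature over bins)
  db <- histogram_density(bt$ts, method = "bins", bins = 40)
  expect_equal(sum(db$y * db$widths), 1, tolerance = 1e-6)
})

test_that("KDE mode of a large normal sample sits at the mean", {
  set.seed(32)
  ts <- time_series(1:1e5, rnorm(1e5))
  m <- find_modes(histogram_density(ts))
  expect_length(m, 1)
  expect_lt(abs(m), 0.05)
})

test_that("uniform samples give flat bin densities", {
  set.seed(33)
  ts <- time_series(1:2e4, runif(2e4))
  db <- histogram_density(ts, method = "bins", bins = 10)
  expect_true(all(abs(db$y - 1) < 0.1))
})

test_that("minor components below the prominence threshold are dropped", {
  bt <- make_bimodal_trace(c(7.5, 12), c(0.3, 0.3), c(0.99, 0.01), 1e5,
                           seed = 34)
  modes <- find_modes(histogram_density(bt$ts))
  expect_length(modes, 1)
  expect_equal(modes, 7.5, tolerance = 0.1)
  # single component -> one mode
  st <- make_bimodal_trace(7.5, 0.3, 1, 1e4, seed = 35)
  expect_length(find_modes(histogram_density(st$ts)), 1)
})

test_that("mode positions ignore affine rescaling of density heights", {
  bt <- make_bimodal_trace(c(7.5, 8.8), c(0.3, 0.3), c(0.5, 0.5), 2e4,
                           seed = 36)
  dens <- histogram_density(bt$ts)
  scaled <- dens
  scaled$y <- dens$y * 37.5
  expect_equal(find_modes(scaled), find_modes(dens))
})

test_that("too-few samples are refused", {
  expect_error(histogram_density(time_series(1:5, 1:5)), "at least 10")
})

test_that("two-state classification is hysteretic", {
  # constant low -> all low, no transitions
  ts <- time_series(1:50, rep(7, 50))
  st <- classify_two_state(ts)
  expect_true(all(st$states == "low"))
  expect_equal(nrow(st$transitions), 0)
  # step 7 -> 13 at frame 26
  ts2 <- time_series(1:50, c(rep(7, 25), rep(13, 25)))
  st2 <- classify_two_state(ts2)
  expect_equal(st2$transitions$direction, "low->high")
  expect_equal(st2$transitions$frame, 26)
  # oscillation inside the band produces no transitions
  set.seed(41)
  ts3 <- time_series(1:200, runif(200, 10.5, 11.5))
  st3 <- classify_two_state(ts3)
  expect_equal(nrow(st3$transitions), 0)
  expect_true(all(st3$states == "undecided"))
  # after a decided frame, in-band frames inherit the last state
  ts4 <- time_series(1:4, c(7, 11, 11, 13))
  st4 <- classify_two_state(ts4)
  expect_equal(st4$states, c("low", "low", "low", "high"))
  expect_error(classify_two_state(ts, 12, 10), "below")
})

test_that("irreversibility detects one-way switches", {
  up <- classify_two_state(time_series(1:4, c(7, 7, 13, 13)))
  r <- is_irreversible(up)
  expect_true(r$irreversible)
  expect_equal(r$first_switch_frame, 3)
  back <- classify_two_state(time_series(1:6, c(7, 13, 13, 7, 7, 7)))
  expect_false(is_irreversible(back)$irreversible)
  none <- classify_two_state(time_series(1:3, c(7, 7, 7)))
  r0 <- is_irreversible(none)
  expect_true(r0$irreversible)
  expect_true(is.na(r0$first_switch_frame))
})

test_that("narrowing the hysteresis band approaches simple thresholding", {
  set.seed(42)
  v <- c(rep(7, 50), rep(13, 50)) + rnorm(100, sd = 0.2)
  ts <- time_series(1:100, v)
  tight <- classify_two_state(ts, 10 - 1e-9, 10 + 1e-9)
  expect_equal(tight$states, ifelse(v <= 10 - 1e-9, "low", "high"))
})

test_that("trace correlation behaves like Pearson r", {
  a <- time_series(1:100, sin(1:100))
  expect_equal(trace_correlation(a, a), 1)
  b <- a
  b$values <- -a$values
  expect_equal(trace_correlation(a, b), -1)
  # affine invariance (positive scale)
  c1 <- a
  c1$values <- 3.2 * a$values + 7
  expect_equal(trace_correlation(a, c1), 1, tolerance = 1e-12)
  # seeded bivariate normal with rho = 0.8
  set.seed(43)
  x <- rnorm(1e4)
  y <- 0.8 * x + sqrt(1 - 0.8^2) * rnorm(1e4)
  r <- trace_correlation(time_series(1:1e4, x), time_series(1:1e4, y))
  expect_equal(r, 0.8, tolerance = 0.02)
  flat <- time_series(1:100, rep(1, 100))
  expect_error(trace_correlation(a, flat), "zero variance")
})

test_that("series medians follow the standard definition", {
  expect_equal(series_median(time_series(1:3, c(1, 2, 3))), 2)
  expect_equal(series_median(time_series(1:4, c(1, 2, 3, 4))), 2.5)
  set.seed(44)
  ts <- time_series(1:1e4, rnorm(1e4, mean = 146, sd = 3))
  expect_equal(series_median(ts), 146, tolerance = 0.1)
})
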