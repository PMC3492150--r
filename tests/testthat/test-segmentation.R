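test_that("fork-rate to slope conversion follows the stated formula", {
  p <- fit_parameters(fork_rate_range = c(0.25, 4), s_phase_minutes = 480)
  sb <- slope_bounds(p, 1.0)
  expect_equal(sb$slope_min, 1 / (4 * 1000 * 480))
  expect_equal(sb$slope_max / sb$slope_min, 16)   # 4 / 0.25
  p2 <- fit_parameters(s_phase_minutes = 960)
  sb2 <- slope_bounds(p2, 1.0)
  expect_equal(sb2$slope_min, sb$slope_min / 2)
  expect_equal(sb2$slope_max, sb$slope_max / 2)
})

test_that("MAD noise estimator recovers sigma on flat and piecewise signals", {
  expect_equal(estimate_noise_mad(rep(2, 100)), 0)
  expect_error(estimate_noise_mad(1:5), "at least 8")

  set.seed(101)
  x <- rnorm(10000, sd = 0.2)
  expect_equal(estimate_noise_mad(x), 0.2, tolerance = 0.05 * 0.2 / 0.2)

  # piecewise-linear trend + noise: junction steps are sparse outliers
  sim <- simulate_clean_signal(simulation_spec(), seed = 21)
  noisy <- add_gaussian_noise(sim$signal, 0.15, seed = 22, range = 1)
  est <- estimate_noise_mad(noisy$values)
  expect_equal(est, 0.15, tolerance = 0.10)
})

test_that("prefilter is a median-3 with kept endpoints and an off switch", {
  sig <- make_signal(c(1, 1, 1 + 1.0, 1, 1))   # +10 sigma spike at center
  off <- prefilter(sig, fit_parameters(prefilter = FALSE))
  expect_identical(off, sig)
  on <- prefilter(sig, fit_parameters())
  expect_equal(on$values, rep(1, 5))
  expect_identical(on$positions, sig$positions)
  mono <- make_signal(seq(1, 2, length.out = 9))
  expect_equal(prefilter(mono, fit_parameters())$values, mono$values)
})

test_that("hough transform recovers noiseless lines within the slope range", {
  p <- fit_parameters(signal_range = 1)
  x <- SPACING * (1:20)
  flat <- rep(1.5, 20)
  cand <- hough_lines(x, flat, p, noise_sd = 0.005)
  expect_equal(cand$slope[1], 0)
  expect_equal(cand$votes[1], 20)
  expect_equal(cand$intercept[1], 1.5, tolerance = 0.01)

  # one flat + one admissibly sloped line of 10 probes each
  sb <- slope_bounds(p, 1)
  sl <- exp(mean(log(c(sb$slope_min, sb$slope_max))))
  y2 <- c(rep(1.2, 10), 1.2 + sl * (x[11:20] - x[10]))
  cand2 <- hough_lines(x, y2, p, noise_sd = 0.005)
  flat_hit <- cand2[cand2$slope == 0 & abs(cand2$intercept - 1.2) < 0.02, ]
  expect_true(nrow(flat_hit) >= 1 && max(flat_hit$votes) >= 9)
  slope_hit <- cand2[cand2$slope > 0 & cand2$votes >= 9, ]
  expect_true(nrow(slope_hit) >= 1)
  # the best sloped candidate matches a least-squares fit of the known subset
  ls <- lm(y2[10:20] ~ x[10:20])
  best <- slope_hit[which.max(slope_hit$votes), ]
  expect_equal(best$slope, unname(coef(ls)[2]), tolerance = 0.15)

  # a line at twice the admissible maximum slope cannot be captured by any
  # in-range candidate over more than half its points: the nearest admissible
  # slope still diverges by >= slope_max, leaving the vote band within a few
  # probes of the crossing point
  x3 <- 5000 * (1:20)
  y3 <- 1.2 + 2 * sb$slope_max * (x3 - x3[1])
  cand3 <- hough_lines(x3, y3, p, noise_sd = 0.005)
  expect_true(all(cand3$votes[cand3$slope != 0] < 10))
})

test_that("windowed DP handles constant, V-shaped and penalty-limit cases", {
  p <- fit_parameters(signal_range = 1)
  x <- SPACING * (1:30)
  const <- dp_segment_window(x, rep(1.4, 30), params = p, noise_sd = 0.005)
  expect_equal(length(const$types), 1)
  expect_equal(const$types, "CTR")
  expect_lt(const$sse, 1e-10)

  # V shape: CTR, admissible TTR down, CTR over 60 probes
  sb <- slope_bounds(p, 1)
  sl <- 2 * sb$slope_min
  x60 <- SPACING * (1:60)
  drop_len <- 15
  v <- c(rep(1.9, 20), 1.9 - sl * SPACING * seq_len(drop_len),
         rep(1.9 - sl * SPACING * drop_len, 25))
  vfit <- dp_segment_window(x60, v, params = p, noise_sd = 0.005)
  expect_equal(vfit$types, c("CTR", "TTR", "CTR"))
  expect_lt(rmse_percent(vfit$fitted, v, 1), 0.1)
  expect_equal(vfit$tau[2] / SPACING, 20, tolerance = 1 / 20)
  expect_equal(vfit$tau[3] / SPACING, 35, tolerance = 1 / 35)

  # infinite breakpoint penalty forces a single segment
  pinf <- fit_parameters(signal_range = 1, breakpoint_penalty = 1e9)
  one <- dp_segment_window(x60, v, params = pinf, noise_sd = 0.005)
  expect_equal(length(one$types), 1)
})

test_that("DP objective matches the exhaustive oracle on small windows", {
  p <- fit_parameters(signal_range = 1, max_breakpoints_per_window = 2,
                      refine = FALSE)
  sb <- slope_bounds(p, 1)
  set.seed(33)
  for (rep in 1:4) {
    n <- 60
    x <- SPACING * (1:n)
    j1 <- sample(15:25, 1); j2 <- sample(35:45, 1)
    sl <- exp(runif(1, log(sb$slope_min), log(sb$slope_max)))
    lev <- runif(1, 1.4, 2)
    clean <- c(rep(lev, j1), lev - sl * SPACING * seq_len(j2 - j1),
               rep(lev - sl * SPACING * (j2 - j1), n - j2))
    y <- clean + rnorm(n, 0, 0.1)
    cand <- hough_lines(x, y, p, noise_sd = 0.1)
    fit <- dp_segment_window(x, y, cand, p, noise_sd = 0.1)
    penalty <- fit$penalty
    oracle <- oracle_objective(x, y,
                               rbind(cand[, c("slope", "intercept")],
                                     repliseg:::.fallback_lines(
                                       x, y, sb)[, c("slope", "intercept")]),
                               penalty, max_segments = 3)
    expect_lte(fit$objective, 1.05 * oracle)
  }
})

test_that("noiseless chromosomes are recovered almost exactly", {
  spec <- small_spec(n_probes = 600)
  for (seed in c(2, 5)) {
    sim <- simulate_clean_signal(spec, seed = seed)
    fit <- segment_signal(sim$signal, sim_params())
    expect_lt(rmse_percent(fit$fitted, sim$truth$clean_values, 1), 0.1)
    # every true junction has a recovered breakpoint within one probe
    bk <- fit$segments$start[-1]
    true_bp <- sim$signal$positions[sim$truth$true_breakpoints]
    miss <- vapply(true_bp, function(tb) min(abs(bk - tb)), numeric(1))
    expect_true(mean(miss <= SPACING) > 0.9)
  }
})

test_that("segmentation output is continuous, admissible and deterministic", {
  spec <- small_spec(n_probes = 600)
  sim <- simulate_clean_signal(spec, seed = 9)
  noisy <- add_gaussian_noise(sim$signal, 0.15, seed = 10, range = 1)
  fit1 <- segment_signal(noisy, sim_params())
  fit2 <- segment_signal(noisy, sim_params())
  expect_identical(fit1$segments, fit2$segments)
  expect_identical(fit1$fitted, fit2$fitted)

  seg <- fit1$segments
  for (bl in unique(seg$block)) {
    sb <- seg[seg$block == bl, ]
    if (nrow(sb) > 1) {
      expect_equal(sb$value_start[-1], sb$value_end[-nrow(sb)])
    }
  }
  bounds <- slope_bounds(sim_params(), 1)
  ttr <- seg[seg$type == "TTR", ]
  expect_true(all(abs(ttr$slope) >= bounds$slope_min - 1e-12))
  expect_true(all(abs(ttr$slope) <= bounds$slope_max + 1e-12))
  expect_true(all(seg$slope[seg$type == "CTR"] == 0))

  sigma <- fit1$noise_sd
  expect_true(all(fit1$fitted >= min(noisy$values) - 3 * sigma))
  expect_true(all(fit1$fitted <= max(noisy$values) + 3 * sigma))
})

test_that("too-short chromosomes are skipped with a warning", {
  sig <- make_signal(c(1, 1.1, 1.2, 1.3, 1.4))
  expect_warning(out <- segment_signal(sig), "fewer than 8")
  expect_null(out)
})

test_that("large probe gaps split the fit into independent blocks", {
  lev <- c(rep(1.8, 40), rep(1.2, 40))
  pos <- c(SPACING * (1:40), 10e6 + SPACING * (1:40))
  sig <- probe_signal("chrG", pos, lev)
  fit <- segment_signal(sig, sim_params())
  expect_equal(length(unique(fit$segments$block)), 2)
  # no segment spans the gap
  expect_true(all(fit$segments$end <= 40 * SPACING |
                    fit$segments$start >= 10e6))
})
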