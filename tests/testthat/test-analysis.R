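make_annot <- function(tor, activity = rep("CTR", length(tor)),
                       chromosome = "chrT") {
  data.frame(chromosome = chromosome,
             position = SPACING * seq_along(tor),
             fitted_tor = tor,
             activity = activity,
             dist_to_breakpoint = Inf,
             stringsAsFactors = FALSE)
}

test_that("ToR map similarity follows the 30%-of-phase rule", {
  set.seed(41)
  tor <- runif(500, 1, 2)
  a <- make_annot(tor)
  expect_equal(compare_tor_maps(a, a), 1.0)
  expect_equal(compare_tor_maps(a, make_annot(tor + 0.31)), 1.0)
  # an offset is removed by per-map normalization; use a partial corruption:
  shifted <- tor
  idx <- seq_len(100)                      # exactly 20% of probes
  shifted[idx] <- tor[idx] + ifelse(tor[idx] < 1.5, 0.5, -0.5)
  b <- make_annot(shifted)
  # normalize both maps identically by pinning the extremes
  a2 <- a; a2$fitted_tor[c(1, 2)] <- c(0.9, 2.1)
  b2 <- b; b2$fitted_tor[c(1, 2)] <- c(0.9, 2.1)
  got <- compare_tor_maps(a2, b2)
  expect_equal(got, mean(abs(a2$fitted_tor - b2$fitted_tor) / 1.2 < 0.30))
  expect_equal(got, compare_tor_maps(b2, a2))   # symmetry
  expect_error(compare_tor_maps(a[1:50, ], a[1:50, ]), "100")
})

test_that("activity agreement is computed over the defined intersection", {
  act <- rep(c("CTR", "TTR"), each = 250)
  a <- make_annot(runif(500), act)
  expect_equal(compare_activity_types(a, a), 1.0)
  b <- a; b$activity <- ifelse(a$activity == "CTR", "TTR", "CTR")
  expect_equal(compare_activity_types(a, b), 0.0)
  c10 <- a; c10$activity[1:50] <- "TTR"    # 10% discordance
  expect_equal(compare_activity_types(a, c10), 0.90)
  u <- a; u$activity <- "undefined"
  expect_error(compare_activity_types(a, u), "defined")
})

test_that("matched pairs honor the tolerance and equalize ToR distributions", {
  set.seed(43)
  tor <- runif(3000, 1, 2)
  ctr <- make_annot(tor, rep("CTR", 3000))
  ttr <- make_annot(tor, rep("TTR", 3000), chromosome = "chrU")
  exact <- select_matched_pairs(ctr, ttr, n_pairs = 200, tolerance = 1e-9,
                                seed = 44)
  expect_equal(nrow(exact), 200)
  expect_true(all(abs(exact$ctr_tor - exact$ttr_tor) < 2e-9))

  # distinct pools: tolerance respected, reproducible, near-uniform ToR
  set.seed(45)
  ctr2 <- make_annot(runif(3000, 1, 2), rep("CTR", 3000))
  ttr2 <- make_annot(runif(3000, 1, 2), rep("TTR", 3000), chromosome = "chrU")
  p1 <- select_matched_pairs(ctr2, ttr2, n_pairs = 1000, seed = 46)
  p2 <- select_matched_pairs(ctr2, ttr2, n_pairs = 1000, seed = 46)
  expect_identical(p1$ctr_position, p2$ctr_position)
  tol <- attr(p1, "tolerance")
  expect_true(all(abs(p1$ctr_tor - p1$ttr_tor) <= tol))
  # no probe reused
  expect_false(any(duplicated(p1$ctr_position)))
  expect_false(any(duplicated(p1$ttr_position)))
  ks <- suppressWarnings(ks.test(p1$ctr_tor, p1$ttr_tor))
  expect_lt(unname(ks$statistic), 0.1)

  # exhausted pools return fewer pairs with a warning
  tiny <- ctr2[1:5, ]
  expect_warning(few <- select_matched_pairs(tiny, ttr2, n_pairs = 50,
                                             seed = 47),
                 "pairs")
  expect_lte(nrow(few), 5)
})

test_that("intergenic filtering keeps probes more than 20 kb from genes", {
  genes <- data.frame(chromosome = "chrT", start = 100000, end = 200000)
  probes <- data.frame(
    chromosome = "chrT",
    position = c(150000,          # inside the gene
                 200000 + 19000,  # 19 kb away -> removed
                 200000 + 21000,  # 21 kb away -> kept
                 100000 - 30000)  # 30 kb upstream -> kept
  )
  out <- filter_intergenic(probes, genes)
  expect_equal(out$position, c(221000, 70000))
  expect_identical(filter_intergenic(probes, genes[0, ]), probes)
})

test_that("windowed feature density counts and averages correctly", {
  probes <- c(1e6, 2e6, 3e6)
  expect_equal(window_feature_density(numeric(0), probes, 30000),
               c(0, 0, 0))
  expect_equal(window_feature_density(probes, probes, 1), c(1, 1, 1))

  # five features around one probe, 30 kb window -> three inside
  feats <- 2e6 + c(-20000, -10000, 0, 12000, 40000)
  expect_equal(window_feature_density(feats, 2e6, 30000), 3)

  # tiling windows partition the features: counts sum to the total
  set.seed(48)
  feats2 <- sort(runif(500, 0, 10e6))
  centers <- seq(50000, 10e6 - 50000, by = 100000)
  counts <- window_feature_density(feats2, centers, 100000 - 1)
  expect_equal(sum(counts), 500)

  # weighted mode: mean weight in window, NA when empty
  w <- c(10, 20, 30, 40, 50)
  # features at -10 kb, 0, +12 kb are inside: mean(20, 30, 40)
  expect_equal(window_feature_density(feats, 2e6, 30000, weights = w), 30)
  expect_true(is.na(window_feature_density(feats, 8e6, 30000, weights = w)))
})

test_that("enrichment nulls preserve chromosome, length and honor n_random", {
  sim <- simulate_clean_signal(small_spec(n_probes = 600), seed = 51)
  fit <- segmentation_from_truth(sim)
  ann <- classify_probes(fit)
  ctr_pos <- ann$position[ann$activity == "CTR"]
  set.seed(52)
  starts <- sample(ctr_pos, 25) - 10000
  regions <- data.frame(chromosome = "chrSim", start = starts,
                        end = starts + 20000)
  enr <- suppressWarnings(
    ctr_residence_enrichment(regions, fit, n_random = 20, seed = 53)
  )
  expect_equal(enr$observed, 100)           # planted exclusively in CTRs
  expect_length(enr$null, 20)
  expect_true(enr$p > 0 && enr$p <= 1)
  expect_equal(enr$p, (sum(enr$null >= 100) + 1) / 21)
})

test_that("paired t-test handles degenerate and powered cases", {
  pairs <- data.frame(
    target_tor = runif(100),
    ctr_chromosome = "chrT", ctr_position = SPACING * (1:100),
    ctr_tor = runif(100),
    ttr_chromosome = "chrU", ttr_position = SPACING * (1:100),
    ttr_tor = runif(100)
  )
  feats <- data.frame(
    chromosome = rep(c("chrT", "chrU"), each = 100),
    position = rep(SPACING * (1:100), 2),
    value = rep(5, 200)
  )
  same <- paired_difference_test(pairs, feats)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  feats2 <- feats
  feats2$value[feats2$chromosome == "chrU"] <- 6   # constant +1, zero variance
  shift <- paired_difference_test(pairs, feats2)
  expect_equal(shift$mean_difference, 1)
  expect_equal(shift$p_value, 0)

  # delta = 0.5 sigma with n = 1000 pairs: essentially certain detection
  set.seed(54)
  pairs2 <- data.frame(
    target_tor = runif(1000),
    ctr_chromosome = "chrT", ctr_position = SPACING * (1:1000),
    ctr_tor = runif(1000),
    ttr_chromosome = "chrU", ttr_position = SPACING * (1:1000),
    ttr_tor = runif(1000)
  )
  feats3 <- data.frame(
    chromosome = rep(c("chrT", "chrU"), each = 1000),
    position = rep(SPACING * (1:1000), 2),
    value = c(rnorm(1000), rnorm(1000, mean = 0.5))
  )
  pw <- paired_difference_test(pairs2, feats3)
  expect_lt(pw$p_value, 1e-6)

  expect_error(paired_difference_test(pairs[1:5, ], feats), "10")
})
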