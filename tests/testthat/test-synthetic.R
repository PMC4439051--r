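scenario_1c <- function(n_cases = 50, ratio = 2, n_pop = NULL, ic = NULL,
                        spread = 800) {
  w <- rect_window(0, 10000, 0, 10000)
  synthetic_scenario(w, data.frame(x = 5000, y = 5000, spread = spread,
                                   weight = 1),
                     n_cases = n_cases, matching_ratio = ratio,
                     n_population = n_pop, injected_cluster = ic,
                     strata_spec = list(birth_years = 2000:2003,
                                        sex_prob = c(M = .5, F = .5),
                                        regions = c(A = .6, B = .4)))
}

test_that("population sampling follows the mixture and is reproducible", {
  sc <- scenario_1c(spread = 50)
  set.seed(1); p1 <- sample_population(sc, 500)
  set.seed(1); p2 <- sample_population(sc, 500)
  expect_identical(p1, p2)
  # tiny spread: everything within a few spreads of the centre
  expect_true(all(sqrt((p1[, 1] - 5000)^2 + (p1[, 2] - 5000)^2) < 5 * 50))
  # two equal-weight centres: per-centre counts within binomial 99% bounds
  w <- rect_window(0, 10000, 0, 10000)
  sc2 <- synthetic_scenario(w, data.frame(x = c(2000, 8000), y = c(5000, 5000),
                                          spread = c(100, 100),
                                          weight = c(1, 1)),
                            n_cases = 10)
  set.seed(2)
  pts <- sample_population(sc2, 10000)
  left <- sum(pts[, 1] < 5000)
  expect_true(abs(left - 5000) < 2.576 * sqrt(10000 * 0.25))
})

test_that("a mixture with no mass in the window errors out", {
  w <- rect_window(0, 100, 0, 100)
  sc <- synthetic_scenario(w, data.frame(x = 1e6, y = 1e6, spread = 10,
                                         weight = 1), n_cases = 2)
  set.seed(3)
  expect_error(sample_population(sc, 10), "retry cap")
})

test_that("case assignment produces an exactly matched design", {
  sc <- scenario_1c(n_cases = 100, ratio = 6, n_pop = 2500)
  set.seed(4)
  d <- assign_cases(sample_population(sc), sc)
  expect_equal(d$n_cases, 100)
  expect_equal(d$n_controls, 600)
  expect_true(check_matched_design(d, ratio = 6))
  # per-stratum control totals are exactly ratio x case totals
  sid <- paste(d$region, d$birth_year, d$sex)
  for (s in unique(sid[d$label == "case"])) {
    expect_equal(sum(d$label == "control" & sid == s),
                 6 * sum(d$label == "case" & sid == s))
  }
})

test_that("an exhausted stratum is reported by name", {
  sc <- scenario_1c(n_cases = 30, ratio = 6, n_pop = 212)
  set.seed(5)
  expect_error(assign_cases(sample_population(sc), sc), "stratum exhausted")
})

test_that("relative risk scales the inside-disc case fraction", {
  ic <- list(x = 5000, y = 5000, radius = 1000, relative_risk = 10)
  w <- rect_window(0, 10000, 0, 10000)
  set.seed(6)
  rate_in <- rate_out <- numeric(40)
  for (r in 1:40) {
    pool <- cbind(runif(3000, 0, 10000), runif(3000, 0, 10000))
    sc <- synthetic_scenario(w, data.frame(x = 5000, y = 5000, spread = 1,
                                           weight = 1),
                             n_cases = 150, matching_ratio = 1,
                             n_population = 3000, injected_cluster = ic,
                             strata_spec = list(birth_years = 2000,
                                                sex_prob = c(M = 1),
                                                regions = c(A = 1)))
    d <- assign_cases(pool, sc)
    inside_pool <- sqrt((pool[, 1] - 5000)^2 + (pool[, 2] - 5000)^2) <= 1000
    case_idx <- sqrt((d$x[d$label == "case"] - 5000)^2 +
                     (d$y[d$label == "case"] - 5000)^2) <= 1000
    rate_in[r] <- sum(case_idx) / sum(inside_pool)
    rate_out[r] <- (150 - sum(case_idx)) / sum(!inside_pool)
  }
  rr_hat <- mean(rate_in) / mean(rate_out)
  expect_gt(rr_hat, 6)
  expect_lt(rr_hat, 14)
})

test_that("null assignment places no excess risk in any disc", {
  w <- rect_window(0, 10000, 0, 10000)
  set.seed(7)
  inside <- total_in <- 0
  for (r in 1:50) {
    pool <- cbind(runif(1000, 0, 10000), runif(1000, 0, 10000))
    sc <- synthetic_scenario(w, data.frame(x = 5000, y = 5000, spread = 1,
                                           weight = 1),
                             n_cases = 100, matching_ratio = 1,
                             n_population = 1000,
                             strata_spec = list(birth_years = 2000,
                                                sex_prob = c(M = 1),
                                                regions = c(A = 1)))
    d <- assign_cases(pool, sc)
    in_disc <- sqrt((pool[, 1] - 5000)^2 + (pool[, 2] - 5000)^2) <= 2000
    total_in <- total_in + sum(in_disc)
    inside <- inside + sum(sqrt((d$x[d$label == "case"] - 5000)^2 +
                                (d$y[d$label == "case"] - 5000)^2) <= 2000)
  }
  # overall case rate is 0.1; the inside-disc rate should match it
  expect_true(abs(inside / total_in - 0.1) < 3 * sqrt(0.1 * 0.9 / total_in))
})

test_that("privacy jitter replaces trailing digits and stays in bounds", {
  w <- rect_window(0, 100000, 0, 100000)
  set.seed(8)
  p <- point_pattern(runif(200, 10, 99990), runif(200, 10, 99990), w)
  j1 <- jitter_coordinates(p, digits = 1)
  expect_true(all(floor(j1$x / 10) == floor(p$x / 10)))
  expect_true(all(abs(j1$x - p$x) < 10))
  expect_true(all(abs(j1$y - p$y) < 10))
  expect_true(all(j1$x %% 1 == 0))  # the meter digit becomes a random integer
  j3 <- jitter_coordinates(p, digits = 3)
  expect_true(all(abs(j3$x - p$x) < 1000))
  expect_true(all(points_in_window(j3$x, j3$y, w)))
  neg <- point_pattern(-5, 5, rect_window(-10, 10, 0, 10))
  expect_error(jitter_coordinates(neg), "nonnegative")
})

test_that("meter-scale jitter barely perturbs the K function", {
  w <- rect_window(0, 10000, 0, 10000)
  set.seed(9)
  rel <- numeric(10)
  for (r in 1:10) {
    p <- point_pattern(runif(300, 0, 10000), runif(300, 0, 10000), w)
    k0 <- k_function(p, s_grid = 2000, correction = "none")$k_values
    k1 <- k_function(jitter_coordinates(p, 1), s_grid = 2000,
                     correction = "none")$k_values
    rel[r] <- abs(k1 - k0) / k0
  }
  expect_lt(mean(rel), 0.01)
})

test_that("generated datasets pass the pattern invariants end to end", {
  sc <- scenario_1c(n_cases = 40, ratio = 6, n_pop = 1500)
  sc$seed <- 123
  d <- generate_cc_data(sc)
  expect_s3_class(d, "cc_pattern")
  expect_equal(d$n_cases + d$n_controls, d$n)
  expect_equal(d$n_controls, 6 * d$n_cases)
  expect_true(all(points_in_window(d$x, d$y, d$window)))
  expect_true(check_matched_design(d, ratio = 6))
  d2 <- generate_cc_data(sc)
  expect_identical(d$x, d2$x)  # scenario seed pins the dataset
})

test_that("generated null datasets are calibrated against the envelope", {
  # end to end: matched generation -> random-labeling envelope; exceedance
  # at a pre-fixed distance should be ~ 2/(n_sim + 1)
  w <- rect_window(0, 10000, 0, 10000)
  set.seed(1234)
  hits <- 0
  for (r in 1:150) {
    sc <- synthetic_scenario(w, data.frame(x = c(3000, 7000),
                                           y = c(5000, 5000),
                                           spread = c(1200, 2500),
                                           weight = c(.6, .4)),
                             n_cases = 25, matching_ratio = 6,
                             strata_spec = list(birth_years = 2002:2005,
                                                sex_prob = c(M = .5, F = .5),
                                                regions = c(A = .7, B = .3)))
    d <- generate_cc_data(sc)
    env <- random_labeling_envelope(d, s_grid = c(1000, 2500), n_sim = 39,
                                    correction = "none")
    hits <- hits + (env$exceed_lower[2] || env$exceed_upper[2])
  }
  expect_gte(hits / 150, 0.01)
  expect_lte(hits / 150, 0.11)
})
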