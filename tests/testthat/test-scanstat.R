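test_that("likelihood kernel follows the count definition", {
  # equal risk inside and outside: not a candidate
  expect_identical(log_lr_kernel(1, 2, 2, 4), -Inf)
  # no cases inside can never be a candidate while cases exist outside
  expect_identical(log_lr_kernel(0, 5, 10, 100), -Inf)
  # the pure-case five-person window of the published leukemia cluster
  expect_equal(log_lr_kernel(5, 5, 633, 4461), 633 * (log(633) - log(4461)),
               tolerance = 1e-12)
  # generic configuration against the independent count formula
  expect_equal(log_lr_kernel(7, 20, 30, 300), oracle_llr(7, 20, 30, 300))
  expect_error(log_lr_kernel(0, 0, 5, 10), "no at-risk")
  expect_error(log_lr_kernel(5, 4, 1, 10))
})

test_that("full Bernoulli kernel is a true log likelihood ratio", {
  n <- 8; N <- 20; m <- 30; M <- 300
  C <- n + m; Tt <- N + M
  ll <- n * log(n / N) + (N - n) * log((N - n) / N) +
    m * log(m / M) + (M - m) * log((M - m) / M)
  l0 <- C * log(C / Tt) + (Tt - C) * log((Tt - C) / Tt)
  expect_equal(log_lr_kernel(n, N, m, M, kernel = "bernoulli"), ll - l0)
  expect_gte(log_lr_kernel(n, N, m, M, kernel = "bernoulli"), 0)
  expect_identical(log_lr_kernel(1, 2, 2, 4, kernel = "bernoulli"), -Inf)
})

test_that("expected cases is C * N_in / N_total and sums over partitions", {
  expect_equal(round(expected_cases(638, 5, 4466), 1), 0.7)
  expect_equal(round(expected_cases(102, 4, 714), 2), 0.57)
  expect_equal(expected_cases(100, 0, 500), 0)
  expect_error(expected_cases(10, 0, 0), "no at-risk")
  set.seed(6)
  parts <- c(0, sort(sample(1:499, 4)), 500)
  sizes <- diff(parts)
  expect_equal(sum(expected_cases(87, sizes, 500)), 87)
})

test_that("window enumeration matches geometry and the exhaustive oracle", {
  w <- rect_window(-10, 300, -10, 10)
  d1 <- cc_pattern(0, 0, "case", w)
  # a lone case: only the singleton window
  ew <- enumerate_windows(d1, 150)
  expect_equal(nrow(ew), 1)
  expect_equal(ew$members[[1]], 1)
  # collinear points at 0, 100, 200 m, centre at 0, max radius 150
  d3 <- cc_pattern(c(0, 100, 200), c(0, 0, 0),
                   c("case", "control", "control"), w)
  ew3 <- enumerate_windows(d3, 150)
  expect_equal(lapply(ew3$members, sort), list(1L, c(1L, 2L)))
  # distinct inside-sets equal brute-force enumeration on random instances
  for (seed in c(3, 4, 5)) {
    inst <- random_cc_instance(20, seed = seed)
    maxr <- sqrt(inst$window$area) / 2
    got <- enumerate_windows(inst$data, maxr)
    want <- oracle_windows(inst$x, inst$y, inst$label == "case", maxr)
    for (c0 in unique(got$center)) {
      sets <- lapply(got$members[got$center == c0], sort)
      expect_setequal(sapply(sets, paste, collapse = ","),
                      sapply(want[[as.character(c0)]], paste, collapse = ","))
    }
  }
})

test_that("the primary cluster attains the brute-force maximum likelihood", {
  for (seed in 16:25) {
    inst <- random_cc_instance(50, seed = seed)
    maxr <- sqrt(inst$window$area) / 2
    res <- scan_bernoulli(inst$data, maxr, n_replications = 0)
    want <- oracle_max_llr(inst$x, inst$y, inst$label == "case", maxr)
    if (is.finite(want)) {
      expect_equal(res$primary$log_lr, want, tolerance = 1e-12)
      expect_true(all(res$ranked$log_lr <= res$primary$log_lr + 1e-12))
    } else {
      expect_null(res$primary)
    }
  }
})

test_that("cluster counts, members and expected cases are consistent", {
  inst <- random_cc_instance(40, seed = 33)
  res <- scan_bernoulli(inst$data, sqrt(inst$window$area) / 2,
                        n_replications = 99, seed = 1)
  for (i in seq_len(nrow(res$ranked))) {
    mem <- res$member_indices[[i]]
    expect_equal(length(mem), res$ranked$atrisk_inside[i])
    expect_equal(sum(inst$label[mem] == "case"), res$ranked$n_inside[i])
    expect_equal(res$ranked$n_inside[i] + res$ranked$n_outside[i],
                 res$total_cases)
    expect_equal(res$ranked$atrisk_inside[i] + res$ranked$atrisk_outside[i],
                 res$total_atrisk)
    expect_equal(res$ranked$expected_cases[i],
                 expected_cases(res$total_cases, res$ranked$atrisk_inside[i],
                                res$total_atrisk))
    # candidate indicator: risk inside exceeds risk outside
    expect_gt(res$ranked$n_inside[i] / res$ranked$atrisk_inside[i],
              res$ranked$n_outside[i] / res$ranked$atrisk_outside[i])
  }
  # reported discs do not overlap
  if (nrow(res$ranked) > 1) {
    for (i in 2:nrow(res$ranked)) for (j in 1:(i - 1)) {
      dc <- sqrt((res$ranked$center_x[i] - res$ranked$center_x[j])^2 +
                 (res$ranked$center_y[i] - res$ranked$center_y[j])^2)
      expect_gte(dc, res$ranked$radius[i] + res$ranked$radius[j])
    }
  }
})

test_that("Monte Carlo p-values are bounded below and runs are reproducible", {
  inst <- random_cc_instance(40, seed = 55)
  r1 <- scan_bernoulli(inst$data, 2000, n_replications = 99, seed = 12)
  r2 <- scan_bernoulli(inst$data, 2000, n_replications = 99, seed = 12)
  expect_identical(r1$ranked, r2$ranked)
  expect_identical(r1$t_null, r2$t_null)
  expect_gte(min(r1$ranked$p_value), 1 / 100)
  expect_lte(max(r1$ranked$p_value), 1)
  r0 <- scan_bernoulli(inst$data, 2000, n_replications = 0)
  expect_true(all(is.na(r0$ranked$p_value)))
})

test_that("likelihood ties break by smaller radius then lower centre index", {
  w <- rect_window(-10, 2000, -10, 10)
  # two separated case pairs with identical window counts
  d <- cc_pattern(c(0, 30, 1000, 1040, 500, 1500),
                  c(0, 0, 0, 0, 0, 0),
                  c("case", "case", "case", "case", "control", "control"), w)
  res <- scan_bernoulli(d, 200, n_replications = 0)
  expect_equal(res$primary$center, 1)
  expect_equal(res$primary$radius, 30)
})

test_that("a window with no elevated risk yields an empty ranked list", {
  w <- rect_window(0, 10, 0, 10)
  d <- cc_pattern(c(5, 5), c(5, 5), c("case", "control"), w)
  res <- scan_bernoulli(d, 5, n_replications = 19, seed = 1)
  expect_null(res$primary)
  expect_equal(nrow(res$ranked), 0)
})

test_that("an injected cluster holding real population mass is recovered", {
  # 2 km disc so the disc actually contains at-risk individuals; this guards
  # the detector end-to-end (see the methods vignette for the power profile)
  w <- rect_window(0, 20000, 0, 20000)
  set.seed(71)
  hits <- 0
  for (r in 1:30) {
    sc <- synthetic_scenario(w, data.frame(x = 1e4, y = 1e4, spread = 1e6,
                                           weight = 1),
                             n_cases = 85, matching_ratio = 6,
                             n_population = 600,
                             strata_spec = list(birth_years = 2004,
                                                sex_prob = c(M = 1),
                                                regions = c(R1 = 1)),
                             injected_cluster = list(x = 1e4, y = 1e4,
                                                     radius = 2000,
                                                     relative_risk = 10))
    pool <- cbind(runif(600, 0, 20000), runif(600, 0, 20000))
    d <- assign_cases(pool, sc)
    res <- scan_bernoulli(d, 5000, n_replications = 0)
    if (!is.null(res$primary) &&
        sqrt((res$primary$center_x - 1e4)^2 +
             (res$primary$center_y - 1e4)^2) <= 1000)
      hits <- hits + 1
  }
  expect_gte(hits / 30, 0.6)
})

test_that("centring windows on all at-risk locations can only raise the maximum", {
  inst <- random_cc_instance(30, seed = 91)
  maxr <- sqrt(inst$window$area) / 3
  rc <- scan_bernoulli(inst$data, maxr, n_replications = 0)
  ra <- scan_bernoulli(inst$data, maxr, n_replications = 0, centers = "all")
  if (!is.null(rc$primary) && !is.null(ra$primary))
    expect_gte(ra$primary$log_lr, rc$primary$log_lr - 1e-12)
})
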