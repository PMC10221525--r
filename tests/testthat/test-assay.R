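test_that("Poisson partitioning matches the closed-form positive fraction", {
  # lambda = c * V = 1 => positive fraction 1 - exp(-1)
  a <- simulate_partition_assay(2e3, v_droplet = 5e-4, n_droplets = 2e4,
                                seed = 7)
  expect_length(a$copies, 2e4)
  p_exp <- 1 - exp(-1)
  se <- sqrt(p_exp * (1 - p_exp) / a$n_droplets)
  expect_lt(abs(a$n_positive / a$n_droplets - p_exp), 3 * se)

  # no-template control: zero copies everywhere
  ntc <- simulate_partition_assay(0, 5e-4, 1e3, seed = 1)
  expect_true(all(ntc$copies == 0))
  expect_identical(ntc$n_positive, 0L)

  # deterministic given the seed
  b <- simulate_partition_assay(2e3, 5e-4, 1e3, seed = 42)
  b2 <- simulate_partition_assay(2e3, 5e-4, 1e3, seed = 42)
  expect_identical(b$copies, b2$copies)

  # observed fraction tracks 1 - exp(-lambda) across lambda (3 MC SEs)
  for (lam in c(0.05, 0.5, 2)) {
    a <- simulate_partition_assay(lam / 5e-4, 5e-4, 2e4, seed = 11)
    p <- 1 - exp(-lam)
    expect_lt(abs(a$n_positive / 2e4 - p), 3 * sqrt(p * (1 - p) / 2e4))
  }
})

test_that("positive classification agrees with exhaustive counting", {
  a <- simulate_partition_assay(4e3, 5e-4, 1e3, seed = 3)
  for (thr in 1:3) {
    brute <- sum(vapply(a$copies, function(k) k >= thr, logical(1)))
    expect_identical(classify_positives(a, thr), brute)
  }
  expect_identical(classify_positives(simulate_partition_assay(0, 5e-4, 100,
                                                               seed = 1)), 0L)
})

test_that("concentration estimation inverts the Poisson model", {
  v <- 5e-4
  # exact inversion round trip: lambda_hat = -log(1 - p)
  n <- 2e4L
  npos <- 7869L
  est <- estimate_concentration(npos, n, v)
  expect_equal(1 - exp(-est$c_hat * v), npos / n, tolerance = 1e-12)
  # p = 1 - exp(-0.5) -> c = 1000 copies/uL
  npos2 <- round((1 - exp(-0.5)) * n)
  est2 <- estimate_concentration(npos2, n, v)
  expect_equal(est2$c_hat, 0.5 / v, tolerance = 1e-3)
  expect_true(est2$ci[1] < est2$c_hat && est2$c_hat < est2$ci[2])

  expect_identical(estimate_concentration(0, n, v)$c_hat, 0)
  expect_error(estimate_concentration(n, n, v), "saturated")
})

test_that("estimator bias is small over the dynamic range", {
  v <- 5e-4; n <- 2e4
  for (lam in c(0.01, 0.1, 1, 5)) {
    c_true <- lam / v
    rel <- vapply(1:100, function(r) {
      a <- simulate_partition_assay(c_true, v, n, seed = 1000 + r)
      est <- estimate_concentration(a$n_positive, n, v)
      (est$c_hat - c_true) / c_true
    }, numeric(1))
    expect_lt(abs(stats::median(rel)), 0.02)
  }
})

test_that("calibration fit recovers exact and simulated dilution lines", {
  cin <- c(10, 1e2, 1e3, 2e3, 1e4)
  f0 <- fit_calibration(cin, cin)
  expect_equal(unname(coef(f0)["slope"]), 1, tolerance = 1e-12)
  expect_equal(unname(coef(f0)["intercept"]), 0, tolerance = 1e-12)
  expect_equal(f0$r_squared, 1, tolerance = 1e-12)
  expect_equal(predict(f0, c(50, 500)), c(50, 500), tolerance = 1e-9)

  # simulated five-point series: slope near 1 on the log10-log10 scale
  d <- run_dilution_series(cin, seed = 5)
  expect_equal(d$fit$slope, 1, tolerance = 0.05)
  expect_gt(d$fit$r_squared, 0.995)

  expect_error(fit_calibration(c(10, 100), c(10, 100)), "3")
  expect_error(fit_calibration(c(-1, 10, 100), c(1, 10, 100)), "positive")
})

test_that("detection probability and limit of detection behave sanely", {
  v <- 5e-4; n <- 2e3
  lod <- assess_lod(c(0, 10, 100, 1000), v_droplet = v, n_droplets = n,
                    n_replicates = 10, k_min = 3, seed = 2)
  curve <- lod$curve
  expect_equal(curve$detect_prob[curve$c_input == 0], 0)
  # lambda * n >> k_min: certain detection (Poisson tail)
  expect_equal(curve$detect_prob[curve$c_input == 1000], 1)
  expect_true(all(diff(curve$detect_prob) >= 0))
  expect_true(is.na(lod$lod) || lod$lod %in% curve$c_input)
})
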