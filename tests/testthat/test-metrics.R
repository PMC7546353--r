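test_that("HIC15 matches closed forms and the brute-force window search", {
  # constant 100 g resultant: HIC = 100^2.5 * 0.015 = 1500
  rec <- record_from_linacc(matrix(c(100, 0, 0) * 9.80665, 100, 3,
                                   byrow = TRUE))
  expect_equal(hic15(rec), 1500, tolerance = 1e-10)
  expect_equal(hic15(record_from_linacc(matrix(0, 100, 3))), 0)
  set.seed(14)
  for (i in 1:20) {
    a <- matrix(abs(rnorm(300, sd = 80)), 100, 3)
    rec <- record_from_linacc(a)
    expect_equal(hic15(rec),
                 brute_windowed(resultant(a) / 9.80665, 1000, 0.015),
                 tolerance = 1e-10)
  }
})

test_that("RIC36 matches its closed form and the brute-force search", {
  # constant 1000 rad/s^2 resultant over the full record
  w <- matrix(0, 100, 3)
  w[, 1] <- 1000 * (0:99) / 1000  # ramp: alpha = 1000 everywhere
  rec <- record_from_angvel(w)
  expect_equal(ric36(rec), 1000^2.5 * 0.036, tolerance = 1e-9)
  expect_equal(ric36(record_from_angvel(matrix(0, 100, 3))), 0)
  set.seed(15)
  for (i in 1:10) {
    wv <- matrix(cumsum(rnorm(300, sd = 0.5)), 100, 3)
    rec <- record_from_angvel(wv)
    alpha_res <- resultant(derive_angular_acceleration(rec))
    expect_equal(ric36(rec), brute_windowed(alpha_res, 1000, 0.036),
                 tolerance = 1e-10)
  }
})

test_that("HIC/RIC are sign-invariant and scale as amplitude^2.5", {
  ds <- small_dataset(n = 3, seed = 61)
  for (rec in ds$records) {
    flipped <- kinematic_record(rec$record_id, -rec$lin_acc, -rec$ang_vel)
    expect_equal(hic15(flipped), hic15(rec))
    expect_equal(ric36(flipped), ric36(rec))
    scaled <- kinematic_record(rec$record_id, 2 * rec$lin_acc,
                               2 * rec$ang_vel)
    expect_equal(hic15(scaled), 2^2.5 * hic15(rec), tolerance = 1e-10)
    expect_equal(ric36(scaled), 2^2.5 * ric36(rec), tolerance = 1e-10)
  }
})

test_that("BrIC normalizes per-axis peaks against critical values", {
  crit <- c(66.25, 56.45, 42.87)
  w <- matrix(0, 100, 3)
  w[40, 1] <- crit[1]
  expect_equal(bric(record_from_angvel(w)), 1)
  w[50, 2] <- -crit[2]
  w[60, 3] <- crit[3]
  expect_equal(bric(record_from_angvel(w)), sqrt(3))
  expect_equal(bric(record_from_angvel(matrix(0, 100, 3))), 0)
  expect_error(bric(record_from_angvel(w), critical_values = c(1, -1, 1)),
               "positive")
  # monotone non-decreasing in each per-axis peak
  set.seed(3)
  w0 <- matrix(rnorm(300, sd = 5), 100, 3)
  base <- bric(record_from_angvel(w0))
  for (d in 1:3) {
    w1 <- w0
    w1[which.max(abs(w1[, d])), d] <- 2 * w1[which.max(abs(w1[, d])), d]
    expect_gte(bric(record_from_angvel(w1)), base)
  }
})

test_that("BAM matches the steady state, converges under step refinement, and vanishes in the rigid limit", {
  expect_equal(bam(record_from_angvel(matrix(0, 100, 3)), test_bam_params()), 0)
  # constant alpha0 on one axis: theta settles at I*alpha0/k
  m <- 2000
  alpha0 <- 500
  w <- matrix(0, m, 3)
  w[, 1] <- alpha0 * (0:(m - 1)) / 1000
  # overdamped parameters: no transient overshoot, so the maximum equals
  # the settled steady state I*alpha0/k
  expect_equal(bam(record_from_angvel(w), bam_params(0.016, 142, 6)),
               0.016 * alpha0 / 142, tolerance = 1e-4)
  # halving the step changes an impulsive solution by < 0.1%
  rec <- small_dataset(n = 1, seed = 5)$records[[1]]
  b1 <- bam(rec, test_bam_params(substeps = 2))
  b2 <- bam(rec, test_bam_params(substeps = 4))
  expect_lt(abs(b2 - b1) / b2, 1e-3)
  # stiffness x 1e6: rigid coupling, theta -> 0 (finer substeps keep the
  # explicit scheme inside its stability region)
  stiff <- bam_params(0.016, 142e6, 0.9, substeps = 64)
  expect_lt(bam(rec, stiff), b1 * 1e-3)
})

test_that("percent errors follow the definition and flag zero ground truth", {
  expect_equal(metric_error(1, 1), 0)
  expect_equal(metric_error(1.1, 1.0), 10)
  expect_true(is.na(metric_error(0.5, 0)))
  expect_equal(metric_error(c(2, 3), c(4, 2)), c(50, 50))
})

test_that("threshold classification produces the hand-counted confusion table", {
  cr <- classify_and_confuse(c(1, 3, 5, 7), c(1, 5, 3, 7), 4)
  expect_identical(c(cr$tp, cr$fn, cr$fp, cr$tn), c(1L, 1L, 1L, 1L))
  expect_equal(cr$sensitivity, 0.5)
  expect_equal(cr$specificity, 0.5)
  perfect <- classify_and_confuse(c(1, 10), c(1, 10), 5)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  miss <- classify_and_confuse(c(1, 10), c(1, 2), 5)
  expect_equal(miss$sensitivity, 0)
  expect_error(classify_and_confuse(1:3, 1:2, 1), "equal length")
})

test_that("the Friedman statistic matches hand computation and the reference implementation", {
  # identical columns: degenerate, chi2 = 0, p = 1
  expect_warning(fr0 <- friedman_rank_test(matrix(1, 4, 3)), "degenerate")
  expect_equal(fr0$chi2, 0)
  expect_equal(fr0$p_value, 1)
  # strict orderings across 4 records and 3 methods: chi2 = 8
  strict <- matrix(c(1, 2, 3,
                     4, 5, 6,
                     7, 8, 9,
                     1, 3, 5), 4, 3, byrow = TRUE)
  fr <- friedman_rank_test(strict)
  expect_equal(fr$chi2, 8)
  expect_identical(fr$df, 2L)
  # cross-implementation oracle on random data
  set.seed(19)
  for (i in 1:5) {
    vals <- matrix(rnorm(60), 20, 3)
    fr <- friedman_rank_test(vals)
    ref <- stats::friedman.test(vals)
    expect_lt(abs(fr$chi2 - unname(ref$statistic)), 1e-8)
    expect_lt(abs(fr$p_value - ref$p.value), 1e-8)
  }
  # ties are mid-ranked with the tie correction, as in the reference
  tied <- matrix(c(1, 1, 2,
                   3, 2, 2,
                   5, 5, 5,
                   1, 2, 3,
                   4, 4, 1), 5, 3, byrow = TRUE)
  expect_lt(abs(friedman_rank_test(tied)$chi2 -
                  unname(stats::friedman.test(tied)$statistic)), 1e-8)
})
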