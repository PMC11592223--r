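test_that("linear detrending removes exactly the least-squares line", {
  t <- seq_len(200)
  expect_true(all(abs(detrend_linear(3 + 0.5 * t)) < 1e-9))

  sine <- sin(2 * pi * t / 40)
  out <- detrend_linear(5 - 0.2 * t + sine)
  # the sine is (numerically) orthogonal-ish to the line over full periods
  expect_equal(out, detrend_linear(sine), tolerance = 1e-9)

  set.seed(44)
  noise <- rnorm(500)
  out <- detrend_linear(noise)
  expect_lt(abs(mean(out)), 1e-9)
  tc <- seq_along(out) - mean(seq_along(out))
  expect_lt(abs(sum(tc * out) / sum(tc^2)), 1e-9)
})

test_that("the LMS encodes the local-maximum comparisons entry by entry", {
  x <- c(0, 1, 0, 2, 0)
  lms <- ampd_lms(x, seed = 8)
  expect_identical(dim(lms$M), c(2L, 5L))
  # manual evaluation of the comparison for every (k, i):
  # k = 1, valid i = 3..5: samples 2,3,4 vs lag-1 neighbours
  #   x2=1 > x1,x3 -> zero; x3=0 -> no; x4=2 > x3,x5 -> zero
  # k = 2, valid i = 4: sample 3: x3=0 > x1? no
  zero_cells <- which(lms$M == 0, arr.ind = TRUE)
  expect_identical(unname(zero_cells[order(zero_cells[, 2]), ]),
                   matrix(c(1L, 3L, 1L, 5L), 2, 2, byrow = TRUE))
  nz <- lms$M[lms$M != 0]
  expect_true(all(nz >= 1 & nz < 2)) # r + alpha with alpha = 1

  # strictly increasing signal: no local maxima at any scale
  lms_up <- ampd_lms(seq_len(12), seed = 1)
  expect_true(all(lms_up$M != 0))
})

test_that("lambda picks the scale with the most local maxima", {
  N <- 600
  sig <- margin_cosine(N, 6)
  x <- detrend_linear(sig$x)
  lms <- ampd_lms(x, seed = 2)
  # brute-force scan of all scales
  zeros <- vapply(seq_len(lms$L), function(k) {
    j <- (k + 1L):(N - k)
    sum(x[j] > x[j - k] & x[j] > x[j + k])
  }, integer(1))
  expect_identical(lms$lambda, which.min(N - zeros))
  # the selected window length stays below the half-period
  expect_lt(2 * lms$lambda, sig$period)
  expect_identical(nrow(lms$Mr), lms$lambda)
})

test_that("AMPD finds sinusoid peaks at the analytic maxima and nothing else", {
  expect_identical(length(ampd(detrend_linear(seq_len(50)), seed = 1)$peaks), 0L)

  sig <- margin_cosine(500, 5)
  res <- ampd(detrend_linear(sig$x), seed = 6)
  expect_identical(length(res$peaks), length(sig$maxima))
  expect_true(all(abs(res$peaks - sig$maxima) <= 1))
})

test_that("detected peaks are true local maxima and seed-invariant", {
  set.seed(60)
  for (rep in 1:10) {
    N <- 400
    t <- seq_len(N) / N
    x <- rowSums(sapply(1:sample(2:4, 1), function(i) {
      runif(1, 0.5, 2) * sin(2 * pi * runif(1, 2, 5) * t + runif(1, 0, 2 * pi))
    }))
    x <- detrend_linear(x)
    a <- ampd(x, seed = 1)
    b <- ampd(x, seed = 999)
    expect_identical(a$peaks, b$peaks)
    expect_true(length(a$peaks) >= 1)
    # neighbour-comparison oracle
    for (p in a$peaks) {
      expect_true(x[p] > x[p - 1] && x[p] > x[p + 1])
    }
    expect_true(all(diff(a$peaks) > 0))
  }
})

test_that("peak filtering keeps the two scapular bumps", {
  expect_identical(filter_to_two_peaks(c(40, 90), rep(1, 120)), c(40L, 90L))

  # two broad bumps plus one narrow noise spike
  n <- 300
  x <- 50 + 30 * exp(-(seq_len(n) - 90)^2 / (2 * 15^2)) +
    35 * exp(-(seq_len(n) - 210)^2 / (2 * 15^2))
  x[150] <- x[150] + 6 # spike
  kept <- filter_to_two_peaks(c(90, 150, 210), x)
  expect_identical(kept, c(90L, 210L))

  expect_error(filter_to_two_peaks(c(50), rep(1, 100)), class = "bimodal_failure")
})

test_that("the ATR angle is the arctangent of the peak line", {
  expect_equal(atr_angle(c(10, 50), c(110, 50)), 0)
  expect_equal(atr_angle(c(10, 10), c(60, 60)), 45)
  expect_equal(atr_angle(c(0, 0), c(sqrt(3), 1)), 30, tolerance = 1e-9)
  expect_equal(atr_angle(c(0, 0), c(-sqrt(3), 1)), 30, tolerance = 1e-9)
  expect_error(atr_angle(c(5, 1), c(5, 2)), "degenerate")
})

test_that("the full pipeline recovers synthetic trunk rotations", {
  sym <- synth_sagittal_case(true_atr = 0, seed = 21)
  r0 <- measure_atr(sym$mask, operator = "prewitt", seed = 1)
  expect_lte(r0$atr_deg, 0.5)

  case <- synth_sagittal_case(true_atr = 10, seed = 22)
  angles <- vapply(c("prewitt", "roberts", "log"), function(op) {
    measure_atr(case$mask, operator = op, seed = 1)$atr_deg
  }, numeric(1))
  expect_true(all(abs(angles - 10) <= 1))
  # operator agreement on the same clean mask
  expect_lte(max(angles) - min(angles), 1)

  expect_error(measure_atr(matrix(0, 50, 50), seed = 1), "empty profile")
})

test_that("measure_atr accepts a contour profile directly", {
  case <- synth_sagittal_case(true_atr = 12, seed = 23)
  prof <- extract_profile(binarize(case$mask, 128))
  r <- measure_atr(prof, seed = 4)
  expect_lt(abs(r$atr_deg - 12), 1)
})
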