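test_that("low-degree shapes are reproduced exactly", {
  t <- c(0, 1, 2, 3, 4) * 100
  # collinear points: the zero function
  fit0 <- spine_curve(list(t = t, d = rep(0, 5)))
  expect_true(all(abs(coef(fit0)) < 1e-9))
  expect_lt(fit0$residual_ss, 1e-12)

  # d(t) = t^2 on small abscissae: a2 = 1, all others 0
  t2 <- 0:4
  fit2 <- spine_curve(list(t = t2, d = t2^2))
  expect_equal(unname(coef(fit2)), c(0, 0, 1, 0, 0), tolerance = 1e-9)
})

test_that("the sine fit equals an independent Vandermonde solve", {
  L <- 1
  A <- 0.3
  t <- c(0, 0.25, 0.5, 0.75, 1) * L
  d <- A * sin(2 * pi * t / L)
  fit <- spine_curve(list(t = t, d = d))
  oracle <- qr.solve(outer(t, 0:4, `^`), d)
  expect_equal(unname(coef(fit)), unname(oracle), tolerance = 1e-8)
})

test_that("interpolation is exact on random well-spaced 5-point sets", {
  set.seed(42)
  for (rep in 1:200) {
    t <- (0:4 + runif(5, -0.3, 0.3)) * 100
    d <- runif(5, -50, 50)
    fit <- spine_curve(list(t = t, d = d))
    expect_lt(max(abs(predict(fit, t) - d)), 1e-6)
  }
})

test_that("derivatives are analytic and match finite differences", {
  expect_equal(predict(spine_curve(list(t = 0:4, d = rep(3, 5))), 2, order = 1), 0)
  expect_equal(predict(spine_curve(list(t = 0:4, d = (0:4)^2)), 3, order = 1), 6,
               tolerance = 1e-9)

  set.seed(7)
  t <- c(0, 90, 210, 330, 400)
  d <- runif(5, -40, 40)
  fit <- spine_curve(list(t = t, d = d))
  ts <- runif(100, 10, 390)
  h <- 1e-3
  fd2 <- (predict(fit, ts + h) - 2 * predict(fit, ts) + predict(fit, ts - h)) / h^2
  expect_equal(predict(fit, ts, order = 2), fd2, tolerance = 1e-4)
  fd1 <- (predict(fit, ts + h) - predict(fit, ts - h)) / (2 * h)
  expect_equal(predict(fit, ts, order = 1), fd1, tolerance = 1e-6)
})

test_that("degenerate inputs raise the documented errors", {
  expect_error(spine_curve(list(t = c(0, 0, 1, 2, 3), d = 1:5)), "singular")
  fit <- spine_curve(list(t = 0:4 * 100, d = rep(0, 5)))
  expect_error(predict(fit, 500), "domain")
  expect_error(predict(fit, 100, order = 3), "order")
  expect_error(spine_curve(list(t = 0:4, d = rep(0, 5)), n_samples = 10),
               "n_samples")
})

test_that("tangent points land on the analytic extrema", {
  L <- 400
  t <- c(0, 0.25, 0.5, 0.75, 1) * L
  w_t <- L / 10 # one window width in t units

  # straight line: no sign change
  expect_identical(nrow(tangent_points(spine_curve(list(t = t, d = 0.2 * t)))), 0L)

  # single-extremum arc: vertex at L/2
  d <- 0.1 * L * 4 * (t / L) * (1 - t / L)
  tp <- tangent_points(spine_curve(list(t = t, d = d)))
  expect_identical(nrow(tp), 1L)
  expect_lt(abs(tp$t - L / 2), w_t)
  expect_identical(tp$slope_change, "pos_to_neg")

  # full sine period: extrema near L/4 and 3L/4
  d <- 0.08 * L * sin(2 * pi * t / L)
  tp <- tangent_points(spine_curve(list(t = t, d = d)))
  expect_identical(nrow(tp), 2L)
  expect_lt(abs(tp$t[1] - L / 4), w_t)
  expect_lt(abs(tp$t[2] - 3 * L / 4), w_t)
  expect_identical(tp$slope_change, c("pos_to_neg", "neg_to_pos"))
})

test_that("tangent detection is mirror-equivariant and scale-invariant", {
  L <- 400
  t <- c(0, 0.25, 0.5, 0.75, 1) * L
  d <- 0.07 * L * sin(2 * pi * t / L)
  tp <- tangent_points(spine_curve(list(t = t, d = d)))

  flipped <- tangent_points(spine_curve(list(t = t, d = -d)))
  expect_equal(flipped$t, tp$t, tolerance = 1e-6)
  expect_identical(flipped$slope_change, c("neg_to_pos", "pos_to_neg"))

  scaled <- tangent_points(spine_curve(list(t = 3 * t, d = 3 * d)))
  expect_equal(scaled$t, 3 * tp$t, tolerance = 1e-6)
  expect_identical(
    classify_curve_type(scaled)$label,
    classify_curve_type(tp)$label
  )
})

test_that("tangent-point count maps to the C/S/multi taxonomy", {
  for (spec in list(
    list(kind = "straight", label = "C", n = 0L, degenerate = TRUE),
    list(kind = "C", label = "C", n = 1L, degenerate = FALSE),
    list(kind = "S", label = "S", n = 2L, degenerate = FALSE),
    list(kind = "multi", label = "multi", n = 3L, degenerate = FALSE)
  )) {
    case <- synth_coronal_case(spec$kind, amplitude = 0.08, seed = 1)
    ct <- curve_type(spine_curve(case$keypoints))
    expect_identical(ct$label, spec$label)
    expect_identical(nrow(ct$tangent_points), spec$n)
    expect_identical(ct$degenerate, spec$degenerate)
  }
})

test_that("noiseless archetypes classify correctly across amplitudes", {
  for (kind in c("C", "S", "multi")) {
    for (a in c(0.01, 0.05, 0.1, 0.15)) {
      case <- synth_coronal_case(kind, amplitude = a, seed = 3)
      expect_identical(
        curve_type(spine_curve(case$keypoints))$label, kind,
        info = sprintf("%s at amplitude %.2f", kind, a)
      )
    }
  }
})
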