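test_that("Cobb angle matches analytic values on polynomial arcs", {
  L <- 400
  t <- c(0, 0.25, 0.5, 0.75, 1) * L

  # straight spine: zero everywhere
  cb0 <- cobb_angle(spine_curve(list(t = t, d = rep(0, 5))))
  expect_equal(cb0$total_angle, 0, tolerance = 1e-9)
  expect_identical(cb0$curve_type, "C")

  # parabolic C-arc d = 0.1 L * 4 (t/L)(1 - t/L): end slopes +/- 0.4,
  # so the included angle is exactly 2 * atan(0.4)
  d <- 0.1 * L * 4 * (t / L) * (1 - t / L)
  cb <- cobb_angle(spine_curve(list(t = t, d = d)))
  expect_equal(cb$total_angle, 2 * atan(0.4) * 180 / pi, tolerance = 1e-3)
  expect_identical(nrow(cb$segments), 1L)
})

test_that("S-curve Cobb equals the closed form of its cubic interpolant", {
  # the quartic through (0, A, 0, -A, 0) at quarter nodes is the odd cubic
  # with endpoint slope (32/3) A / L and midpoint slope -(16/3) A / L;
  # the segment rule then gives 2 * (atan(32A/3L) + atan(16A/3L))
  L <- 400
  t <- c(0, 0.25, 0.5, 0.75, 1) * L
  for (A_f in c(0.02, 0.08)) {
    d <- A_f * L * sin(2 * pi * t / L)
    cb <- cobb_angle(spine_curve(list(t = t, d = d)))
    expected <- 2 * (atan(32 * A_f / 3) + atan(16 * A_f / 3)) * 180 / pi
    expect_equal(cb$total_angle, expected, tolerance = 0.05)
    expect_identical(nrow(cb$segments), 2L)
    expect_equal(sum(cb$segments$angle), cb$total_angle)
  }
})

test_that("Cobb is invariant to translation, scaling and mirroring", {
  case <- synth_coronal_case("S", amplitude = 0.06, seed = 9)
  t <- spine_points(case$keypoints)$y
  d <- spine_points(case$keypoints)$x
  base <- cobb_angle(spine_curve(list(t = t, d = d)))$total_angle
  expect_equal(
    cobb_angle(spine_curve(list(t = t + 50, d = d - 30)))$total_angle,
    base, tolerance = 1e-6
  )
  expect_equal(
    cobb_angle(spine_curve(list(t = 2.5 * t, d = 2.5 * d)))$total_angle,
    base, tolerance = 1e-6
  )
  expect_equal(
    cobb_angle(spine_curve(list(t = t, d = -d)))$total_angle,
    base, tolerance = 1e-6
  )
})

test_that("Cobb grows strictly with amplitude on the C family", {
  angles <- vapply(seq(0.02, 0.14, by = 0.04), function(a) {
    case <- synth_coronal_case("C", amplitude = a, seed = 2)
    cobb_angle(spine_curve(case$keypoints))$total_angle
  }, numeric(1))
  expect_true(all(diff(angles) > 0))
})

test_that("type/tangent-point mismatches are rejected", {
  case <- synth_coronal_case("S", amplitude = 0.08, seed = 4)
  curve <- spine_curve(case$keypoints)
  type <- curve_type(curve)
  type$label <- "C" # two tangent points cannot be a C
  expect_error(cobb_angle(curve, type), "inconsistent input")
})

test_that("triangle base angles follow the law of cosines", {
  # symmetric configuration: equal base angles
  kp <- make_kp(x = c(160, 150, 145, 152, 160, 60, 260),
                y = c(40, 140, 240, 340, 440, 120, 120))
  tri <- triangle_asymmetry(kp)
  expect_equal(tri$abs_diff, 0, tolerance = 1e-9)
  expect_equal(tri$base_angle_left + tri$base_angle_right + tri$apex_angle,
               180, tolerance = 1e-6)

  # hand-computed asymmetric case: scapulae (0,4) and (4,4), apex (1,6)
  kp2 <- back_keypoints(
    x = c(1, 1, 1, 1, 1, 0, 4), y = c(1, 2, 3, 4, 6, 4, 4),
    image_width = 10, image_height = 10
  )
  tri2 <- triangle_asymmetry(kp2)
  # law-of-cosines oracle on the fixed coordinates
  sides <- c(ab = 4, as = sqrt(1 + 4), bs = sqrt(9 + 4))
  left <- acos((sides["ab"]^2 + sides["as"]^2 - sides["bs"]^2) /
                 (2 * sides["ab"] * sides["as"])) * 180 / pi
  right <- acos((sides["ab"]^2 + sides["bs"]^2 - sides["as"]^2) /
                  (2 * sides["ab"] * sides["bs"])) * 180 / pi
  expect_equal(tri2$base_angle_left, unname(left), tolerance = 1e-9)
  expect_equal(tri2$base_angle_right, unname(right), tolerance = 1e-9)
  expect_equal(tri2$abs_diff, unname(abs(left - right)), tolerance = 1e-9)
})

test_that("triangle asymmetry is mirror-invariant and rejects collinearity", {
  case <- synth_coronal_case("C", amplitude = 0.05, seed = 5,
                             scapula_asymmetry = 0.04)
  kp <- case$keypoints
  base <- triangle_asymmetry(kp)$abs_diff
  # left-right mirror: |left - right| is symmetric, so abs_diff is unchanged
  mirrored <- kp
  mirrored$points$x <- kp$image_width - 1 - mirrored$points$x
  expect_equal(triangle_asymmetry(mirrored)$abs_diff, base, tolerance = 1e-9)

  flat <- back_keypoints(
    x = c(1, 1, 1, 1, 2, 1, 3), y = c(1, 2, 3, 4, 5, 5, 5),
    image_width = 10, image_height = 10
  )
  expect_error(triangle_asymmetry(flat), "collinear")
})

test_that("severity classes follow the half-open clinical boundaries", {
  expect_identical(grade_from_cobb(5)$class_index, 0L)
  expect_identical(grade_from_cobb(5)$class_label, "<10")
  expect_identical(grade_from_cobb(19.5)$class_index, 1L)
  expect_identical(grade_from_cobb(45)$class_index, 3L) # ">=45" inclusive
  expect_identical(grade_from_cobb(44.999)$class_index, 2L)
  expect_error(grade_from_cobb(-1), "non-negative")

  expect_identical(grade_from_triangle(0)$class_index, 0L)
  expect_identical(grade_from_triangle(6, c(2, 5, 10))$class_index, 2L)
  expect_error(grade_from_triangle(1, c(5, 3, 10)), "ascending")

  # monotone: larger scores never map lower
  idx <- vapply(seq(0, 30, by = 0.25),
                function(v) grade_from_triangle(v)$class_index, integer(1))
  expect_true(all(diff(idx) >= 0))
})

test_that("fusion grading routes by curvature type", {
  c_case <- synth_coronal_case("C", amplitude = 0.06, seed = 11)
  g_c <- fusion_grade(c_case$keypoints)
  expect_identical(g_c$method, "triangle")
  expect_identical(g_c$curve_type, "C")

  s_case <- synth_coronal_case("S", amplitude = 0.08, seed = 12)
  g_s <- fusion_grade(s_case$keypoints)
  expect_identical(g_s$method, "cobb")
  expect_identical(g_s$curve_type, "S")

  straight <- synth_coronal_case("straight", seed = 13)
  g0 <- fusion_grade(straight$keypoints)
  expect_identical(g0$method, "triangle")
  expect_true(g0$degenerate)
  expect_identical(g0$class_index, 0L)
})
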