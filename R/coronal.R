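#' Cobb angle of the fitted spine curve
#'
#' Photographic analogue of the clinical Cobb angle, computed from the
#' fitted coronal spine curve.
#'
#' For a C-shaped curve the domain is split at the tangent point `x` into
#' `[t_min, x]` and `(x, t_max]`; in each side the point of maximum
#' absolute slope marks the most-tilted ("upper"/"lower") vertebra, and the
#' Cobb angle is the included angle between the two tangents,
#' `|atan(m_upper) - atan(m_lower)|` in degrees. For S-shaped and
#' multi-curved spines the curve is first split at its inflection points
#' (zero crossings of the analytic second derivative, refined by root
#' finding), the C-rule is applied to each convex/concave part, and the
#' per-part angles are summed. A degenerate (straight) curve is treated as
#' a single part split at the domain midpoint, yielding an angle of zero.
#'
#' @param curve a [spine_curve] object.
#' @param type a `curve_type` object for the same curve; computed with the
#'   default settings when omitted.
#' @return An object of class `cobb_angle`: list with `total_angle`
#'   (degrees, sum of the segment angles), `segments` (data frame with
#'   `t_upper`, `t_lower`, `slope_upper`, `slope_lower`, `angle`) and
#'   `curve_type`.
#' @examples
#' case <- synth_coronal_case("C", amplitude = 0.05, seed = 1)
#' cobb_angle(spine_curve(case$keypoints))
#' @export
cobb_angle <- function(curve, type = NULL) {
  if (is.null(type)) type <- curve_type(curve)
  tp <- type$tangent_points
  n_tp <- nrow(tp)
  ok <- switch(type$label,
    C = n_tp <= 1L,
    S = n_tp == 2L,
    multi = n_tp > 2L,
    FALSE
  )
  if (!ok) {
    stopf(
      "inconsistent input: label %s with %d tangent points",
      type$label, n_tp
    )
  }
  rng <- curve$t_range

  if (type$label == "C") {
    parts <- list(rng)
  } else {
    infl <- inflection_points(curve)
    bounds <- sort(unique(c(rng, infl)))
    parts <- Map(c, bounds[-length(bounds)], bounds[-1L])
  }

  segments <- lapply(parts, function(p) cobb_segment(curve, p, tp))
  segments <- do.call(rbind, segments)
  structure(
    list(
      total_angle = sum(segments$angle),
      segments = segments,
      curve_type = type$label,
      degenerate = isTRUE(type$degenerate)
    ),
    class = "cobb_angle"
  )
}

# interior zero crossings of the second derivative, refined by bisection
inflection_points <- function(curve) {
  tt <- curve$grid
  d2 <- predict(curve, tt, order = 2L)
  ch <- which(d2[-length(d2)] * d2[-1L] < 0)
  tol <- 1e-3 * diff(curve$t_range)
  vapply(ch, function(i) {
    stats::uniroot(
      function(t) predict(curve, t, order = 2L),
      lower = tt[i], upper = tt[i + 1L], tol = tol * 1e-3
    )$root
  }, numeric(1))
}

# Cobb angle of one convex/concave part by the C-rule
cobb_segment <- function(curve, part, tp) {
  inner <- tp$t[tp$t > part[1L] & tp$t < part[2L]]
  split_at <- if (length(inner)) {
    # several tangent points inside one part: use the highest-curvature one
    inner[which.max(tp$curvature[match(inner, tp$t)])]
  } else {
    mean(part)
  }
  grid <- curve$grid
  side <- function(lo, hi) {
    tt <- c(lo, grid[grid > lo & grid < hi], hi)
    sl <- predict(curve, tt, order = 1L)
    i <- which.max(abs(sl))
    c(t = tt[i], slope = sl[i])
  }
  up <- side(part[1L], split_at)
  lo <- side(split_at, part[2L])
  data.frame(
    t_upper = up[["t"]], t_lower = lo[["t"]],
    slope_upper = up[["slope"]], slope_lower = lo[["slope"]],
    angle = deg(abs(atan(up[["slope"]]) - atan(lo[["slope"]])))
  )
}

#' @export
print.cobb_angle <- function(x, ...) {
  cat(sprintf(
    "Cobb angle: %.2f deg (%s curve%s, %d segment%s)\n",
    x$total_angle, x$curve_type,
    if (x$degenerate) ", degenerate" else "",
    nrow(x$segments), if (nrow(x$segments) == 1L) "" else "s"
  ))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Base-angle asymmetry of the scapular spine triangle
#'
#' The scapular spine triangle joins the two scapular keypoints and the
#' lowest spine keypoint (`spine4`). Its two base angles sit at the
#' scapular vertices; their absolute difference indexes coronal trunk
#' asymmetry and grows with the lateral curvature of the spine.
#'
#' @param kp a [back_keypoints] object with both scapulae and `spine4`
#'   visible and non-collinear.
#' @return An object of class `scapula_triangle`: list with
#'   `base_angle_left`, `base_angle_right`, `apex_angle` (degrees) and
#'   `abs_diff = |base_angle_left - base_angle_right|`.
#' @examples
#' kp <- back_keypoints(
#'   x = c(160, 150, 145, 152, 160, 90, 230),
#'   y = c(40, 140, 240, 340, 440, 120, 120),
#'   image_width = 320, image_height = 480
#' )
#' triangle_asymmetry(kp)
#' @export
triangle_asymmetry <- function(kp) {
  kp <- validate_back_keypoints(kp)
  pts <- kp$points
  need <- c("scapula_left", "scapula_right", "spine4")
  if (!all(pts$visible[match(need, pts$label)])) {
    stopf("scapula_left, scapula_right and spine4 must all be visible")
  }
  P <- function(lab) unlist(pts[pts$label == lab, c("x", "y")], use.names = FALSE)
  A <- P("scapula_left")
  B <- P("scapula_right")
  S <- P("spine4")
  cross <- (B[1] - A[1]) * (S[2] - A[2]) - (B[2] - A[2]) * (S[1] - A[1])
  span <- max(abs(c(B - A, S - A)))
  if (abs(cross) < 1e-9 * max(1, span^2)) {
    stopf("degenerate triangle: scapulae and spine endpoint are collinear")
  }
  vangle <- function(v1, v2) {
    deg(acos(pmin(1, pmax(-1, sum(v1 * v2) /
                            sqrt(sum(v1^2) * sum(v2^2))))))
  }
  left <- vangle(B - A, S - A)
  right <- vangle(A - B, S - B)
  apex <- vangle(A - S, B - S)
  structure(
    list(
      base_angle_left = left, base_angle_right = right, apex_angle = apex,
      abs_diff = abs(left - right)
    ),
    class = "scapula_triangle"
  )
}

#' @export
print.scapula_triangle <- function(x, ...) {
  cat(sprintf(
    "Scapular spine triangle: base angles %.2f / %.2f deg, |diff| = %.2f deg\n",
    x$base_angle_left, x$base_angle_right, x$abs_diff
  ))
  invisible(x)
}

severity_labels <- c("<10", "10-19", "20-44", ">=45")

new_severity_grade <- function(class_index, method, score) {
  structure(
    list(
      class_index = as.integer(class_index),
      class_label = severity_labels[class_index + 1L],
      method = method,
      score_value = score
    ),
    class = "severity_grade"
  )
}

#' Severity grade from a Cobb angle
#'
#' Maps a Cobb angle to the clinical four-class severity scale using
#' half-open intervals `[0, 10)`, `[10, 20)`, `[20, 45)`, `[45, Inf)`,
#' honoring "<10" and ">=45" exactly.
#'
#' @param angle Cobb angle in degrees, non-negative.
#' @return A `severity_grade` object with `class_index` (0-3),
#'   `class_label`, `method = "cobb"` and `score_value`.
#' @export
grade_from_cobb <- function(angle) {
  if (!is_number(angle) || angle < 0) stopf("angle must be non-negative")
  idx <- findInterval(angle, c(10, 20, 45))
  new_severity_grade(idx, "cobb", angle)
}

#' Severity grade from the scapular-triangle asymmetry
#'
#' Maps the absolute base-angle difference of the scapular spine triangle
#' to the four-class severity scale through three ascending thresholds
#' (half-open intervals, same convention as [grade_from_cobb()]). The
#' clinical literature provides no canonical thresholds; the defaults are
#' an explicit, overridable calibration.
#'
#' @param abs_diff absolute base-angle difference in degrees.
#' @param thresholds three strictly ascending degree thresholds.
#' @return A `severity_grade` object with `method = "triangle"`.
#' @export
grade_from_triangle <- function(abs_diff, thresholds = c(2, 5, 10)) {
  if (length(thresholds) != 3L || any(diff(thresholds) <= 0)) {
    stopf("thresholds must be 3 strictly ascending values")
  }
  if (!is_number(abs_diff) || abs_diff < 0) {
    stopf("abs_diff must be non-negative")
  }
  idx <- findInterval(abs_diff, thresholds)
  new_severity_grade(idx, "triangle", abs_diff)
}

#' Fused severity grading of coronal scoliosis
#'
#' Routing rule combining the two coronal severity estimators by curvature
#' type: the scapular-triangle asymmetry grades C-shaped (and degenerate
#' straight) spines, while the Cobb angle of the fitted curve grades
#' S-shaped and multi-curved spines, where the triangle method is known to
#' be unreliable.
#'
#' @param kp a [back_keypoints] object.
#' @param triangle_thresholds thresholds for [grade_from_triangle()].
#' @param n_samples,window_frac,step settings passed to [spine_curve()] and
#'   [curve_type()].
#' @return A `severity_grade` object whose `method` records which estimator
#'   fired, with extra fields `curve_type`, `degenerate`, and the
#'   underlying `cobb_deg` or `triangle_diff_deg`.
#' @examples
#' case <- synth_coronal_case("S", amplitude = 0.08, seed = 7)
#' fusion_grade(case$keypoints)
#' @export
fusion_grade <- function(kp, triangle_thresholds = c(2, 5, 10),
                         n_samples = 200L, window_frac = 0.1, step = 2L) {
  curve <- spine_curve(kp, n_samples = n_samples)
  type <- curve_type(curve, window_frac = window_frac, step = step)
  if (type$label == "C") {
    tri <- triangle_asymmetry(kp)
    g <- grade_from_triangle(tri$abs_diff, triangle_thresholds)
    g$triangle_diff_deg <- tri$abs_diff
  } else {
    cb <- cobb_angle(curve, type)
    g <- grade_from_cobb(cb$total_angle)
    g$cobb_deg <- cb$total_angle
  }
  g$curve_type <- type$label
  g$degenerate <- type$degenerate
  g
}

#' @export
print.severity_grade <- function(x, ...) {
  cat(sprintf(
    "Severity grade: class %d (\"%s\") by %s method (score %.2f deg)\n",
    x$class_index, x$class_label, x$method, x$score_value
  ))
  if (!is.null(x$curve_type)) {
    cat(sprintf(
      "  curve type: %s%s\n", x$curve_type,
      if (isTRUE(x$degenerate)) " (degenerate)" else ""
    ))
  }
  invisible(x)
}

#' @export
as.list.severity_grade <- function(x, ...) {
  out <- list(
    class_index = x$class_index, class_label = x$class_label,
    method = x$method, score_value = x$score_value
  )
  for (f in c("curve_type", "degenerate", "cobb_deg", "triangle_diff_deg")) {
    if (!is.null(x[[f]])) out[[f]] <- x[[f]]
  }
  out
}
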