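#' Fit the quartic spine curve to the five spine keypoints
#'
#' Least-squares fit of a degree-4 polynomial to the five spine keypoints,
#' the continuous representation of the coronal spine line that all
#' downstream coronal measurements (tangent points, curve type, Cobb angle)
#' work on.
#'
#' The fit is performed in a spine-aligned frame: because the spine is
#' near-vertical in a standing back photo and its keypoints are strictly
#' monotone in the vertical pixel coordinate, the independent variable `t`
#' is the vertical coordinate (`y`, pixels, increasing downward) and the
#' dependent variable `d` the lateral position (`x`, pixels). With five
#' distinct abscissae the degree-4 least-squares solution interpolates the
#' points exactly. Internally the Vandermonde system is solved on the unit
#' interval `u = (t - t_min) / (t_max - t_min)` for numerical stability;
#' coefficients are available in either frame via [coef.spine_curve()].
#'
#' @param kp a [back_keypoints] object whose five spine points are visible,
#'   or a data frame / list with numeric `t` and `d` of equal length 5.
#' @param n_samples number of points of the dense evaluation grid used by
#'   [tangent_points()] and [cobb_angle()] (at least 20).
#'
#' @return An object of class `spine_curve`: list with `coefficients`
#'   (pixel frame, `a0` ... `a4`), `scaled_coefficients` (unit-interval
#'   frame), `t_range`, `grid` (dense `t` grid), `n_samples`,
#'   `residual_ss` (sum of squared node residuals), `data` (the five
#'   `(t, d)` pairs) and `source_id`.
#'
#' @seealso [predict.spine_curve()], [tangent_points()], [curve_type()],
#'   [cobb_angle()]
#' @examples
#' case <- synth_coronal_case("C", amplitude = 0.05, seed = 1)
#' fit <- spine_curve(case$keypoints)
#' fit
#' @export
spine_curve <- function(kp, n_samples = 200L) {
  if (inherits(kp, "back_keypoints")) {
    sp <- spine_points(kp)
    if (!all(sp$visible)) stopf("all five spine points must be visible")
    t <- sp$y
    d <- sp$x
    src <- kp$source_id
  } else {
    t <- as.numeric(kp$t)
    d <- as.numeric(kp$d)
    src <- ""
  }
  if (length(t) != 5L || length(d) != 5L) {
    stopf("spine curve fitting needs exactly 5 points")
  }
  if (anyDuplicated(t)) stopf("singular system: duplicate spine abscissae")
  if (is.unsorted(t, strictly = TRUE)) {
    o <- order(t)
    t <- t[o]
    d <- d[o]
  }
  n_samples <- as.integer(n_samples)
  if (n_samples < 20L) stopf("n_samples must be at least 20")
  t0 <- t[1L]
  L <- t[5L] - t[1L]
  u <- (t - t0) / L
  V <- outer(u, 0:4, `^`)
  b <- tryCatch(
    solve(V, d),
    error = function(e) stopf("singular system: %s", conditionMessage(e))
  )
  fit <- structure(
    list(
      coefficients = pixel_frame_coef(b, t0, L),
      scaled_coefficients = as.numeric(b),
      t_range = c(t[1L], t[5L]),
      grid = seq(t[1L], t[5L], length.out = n_samples),
      n_samples = n_samples,
      residual_ss = NA_real_,
      data = data.frame(t = t, d = d),
      source_id = src
    ),
    class = "spine_curve"
  )
  fit$residual_ss <- sum((predict(fit, t) - d)^2)
  fit
}

# expand scaled-frame coefficients b (in u = (t - t0)/L) to the pixel frame
pixel_frame_coef <- function(b, t0, L) {
  a <- numeric(5L)
  for (j in 0:4) {
    # b_j * ((t - t0)/L)^j contributes binomial terms to powers 0..j of t
    for (i in 0:j) {
      a[i + 1L] <- a[i + 1L] +
        b[j + 1L] * choose(j, i) * (-t0)^(j - i) / L^j
    }
  }
  names(a) <- paste0("a", 0:4)
  a
}

#' Evaluate a fitted spine curve or its derivatives
#'
#' Analytic evaluation of the fitted quartic: lateral deviation
#' (`order = 0`, pixels), slope (`order = 1`, dimensionless) or second
#' derivative (`order = 2`, 1/pixels).
#'
#' @param object a [spine_curve] object.
#' @param t vertical coordinates (pixels) within the fitted domain.
#' @param order derivative order, 0, 1 or 2.
#' @param ... unused.
#' @return Numeric vector of the same length as `t`.
#' @export
predict.spine_curve <- function(object, t, order = 0L, ...) {
  if (missing(t)) t <- object$grid
  order <- as.integer(order)
  if (!order %in% 0:2) stopf("order must be 0, 1 or 2")
  rng <- object$t_range
  tol <- 1e-8 * max(1, diff(rng))
  if (any(t < rng[1L] - tol | t > rng[2L] + tol)) {
    stopf("t outside curve domain [%g, %g]", rng[1L], rng[2L])
  }
  L <- diff(rng)
  u <- (t - rng[1L]) / L
  b <- object$scaled_coefficients
  val <- switch(order + 1L,
    ((((b[5L] * u + b[4L]) * u + b[3L]) * u + b[2L]) * u + b[1L]),
    (((4 * b[5L] * u + 3 * b[4L]) * u + 2 * b[3L]) * u + b[2L]) / L,
    ((12 * b[5L] * u + 6 * b[4L]) * u + 2 * b[3L]) / L^2
  )
  as.numeric(val)
}

#' @export
coef.spine_curve <- function(object, frame = c("pixel", "scaled"), ...) {
  frame <- match.arg(frame)
  if (frame == "pixel") object$coefficients else object$scaled_coefficients
}

#' @export
fitted.spine_curve <- function(object, ...) predict(object, object$data$t)

#' @export
residuals.spine_curve <- function(object, ...) {
  object$data$d - fitted(object)
}

#' @export
print.spine_curve <- function(x, ...) {
  cat("Quartic spine curve fit (lateral deviation d(t), spine frame)\n")
  cat(sprintf(
    "  domain t in [%.1f, %.1f] px, %d grid samples\n",
    x$t_range[1L], x$t_range[2L], x$n_samples
  ))
  cat("  pixel-frame coefficients:\n")
  print(signif(x$coefficients, 6))
  cat(sprintf("  node residual sum of squares: %.3g px^2\n", x$residual_ss))
  invisible(x)
}

#' @export
plot.spine_curve <- function(x, ...) {
  tt <- x$grid
  graphics::plot(
    predict(x, tt), tt, type = "l", ylim = rev(range(tt)),
    xlab = "lateral position (px)", ylab = "vertical position (px)", ...
  )
  graphics::points(x$data$d, x$data$t, pch = 19)
  invisible(x)
}

# unsigned curvature |d''| / (1 + d'^2)^(3/2) of the fitted curve at t
curve_curvature <- function(curve, t) {
  d1 <- predict(curve, t, order = 1L)
  d2 <- predict(curve, t, order = 2L)
  abs(d2) / (1 + d1^2)^1.5
}

#' Detect tangent points of the spine curve by sliding window
#'
#' A tangent point (curve apex) is a point where the slope of the lateral
#' deviation changes sign. A window of `round(n_samples * window_frac)`
#' grid samples slides along the dense grid in steps of `step` samples;
#' slope sign changes inside the window are located exactly by root finding
#' on the analytic first derivative. A flagged point is retained only if
#' its unsigned curvature exceeds the median curvature of the non-flagged
#' grid samples (curvature check), and flags closer than one window width
#' are merged, keeping the higher-curvature one (ties: smaller `t` wins).
#'
#' Two guards reject artifacts of the interpolating quartic rather than of
#' the anatomy: sign changes within half a window width of either domain
#' end are dropped (an interpolant oscillates near the ends of its data
#' range, and such end wiggles often carry *higher* curvature than a true
#' apex), and when several apexes remain, those whose lateral prominence
#' (the smaller deviation change towards the adjacent apexes or domain
#' ends) falls below `rel_prominence` times the largest candidate's are
#' dropped as sub-dominant noise wiggles. Both guards are inert on clean
#' archetypal curves, whose apexes are interior and of comparable
#' prominence.
#'
#' @param curve a [spine_curve] object.
#' @param window_frac window size as a fraction of the grid length
#'   (default 1/10, i.e. 20 samples on the default grid).
#' @param step window step in samples.
#' @param rel_prominence dominance threshold of the prominence guard,
#'   as a fraction of the most prominent candidate apex.
#' @return A data frame of class `tangent_points` with columns `t`
#'   (pixels), `slope_change` (`"pos_to_neg"` or `"neg_to_pos"`) and
#'   `curvature` (1/pixels, unsigned); zero rows for a monotone curve.
#' @seealso [curve_type()]
#' @export
tangent_points <- function(curve, window_frac = 0.1, step = 2L,
                           rel_prominence = 0.2) {
  n <- curve$n_samples
  w <- max(3L, as.integer(round(n * window_frac)))
  step <- max(1L, as.integer(step))
  tt <- curve$grid
  slope <- predict(curve, tt, order = 1L)

  # candidate crossings: adjacent grid pairs with a slope sign change,
  # visited through the sliding windows
  cand_left <- integer(0)
  for (st in seq(1L, max(1L, n - w + 1L), by = step)) {
    id <- st:min(n, st + w - 1L)
    sl <- slope[id]
    ch <- which(sl[-length(sl)] * sl[-1L] < 0)
    cand_left <- union(cand_left, id[ch])
  }
  # exact zeros of the slope on the grid bracketed by opposite signs
  zs <- which(slope == 0)
  zs <- zs[zs > 1L & zs < n]
  zs <- zs[slope[zs - 1L] * slope[zs + 1L] < 0]

  refine <- function(i) {
    stats::uniroot(
      function(t) predict(curve, t, order = 1L),
      lower = tt[i], upper = tt[i + 1L], tol = 1e-10 * diff(curve$t_range)
    )$root
  }
  t_star <- c(vapply(cand_left, refine, numeric(1)), tt[zs])
  dir_left <- c(cand_left, pmax(zs - 1L, 1L))
  direction <- ifelse(slope[dir_left] > 0, "pos_to_neg", "neg_to_pos")

  if (!length(t_star)) {
    return(empty_tangent_points(w, step))
  }
  o <- order(t_star)
  t_star <- t_star[o]
  direction <- direction[o]

  # boundary guard: an interpolating quartic oscillates near the ends of
  # its data range, so a sign change within half a window of either domain
  # end is a fitting artifact, not an anatomical apex
  spacing0 <- diff(curve$t_range) / (n - 1L)
  margin <- w * spacing0 / 2
  interior <- t_star > curve$t_range[1L] + margin &
    t_star < curve$t_range[2L] - margin
  t_star <- t_star[interior]
  direction <- direction[interior]
  if (!length(t_star)) {
    return(empty_tangent_points(w, step))
  }

  # curvature check against non-flagged grid samples
  kappa <- curve_curvature(curve, t_star)
  grid_kappa <- curve_curvature(curve, tt)
  spacing <- diff(curve$t_range) / (n - 1L)
  flagged <- rep(FALSE, n)
  for (ts in t_star) {
    flagged[abs(tt - ts) <= spacing] <- TRUE
  }
  med <- stats::median(grid_kappa[!flagged])
  keep <- kappa > med
  t_star <- t_star[keep]
  direction <- direction[keep]
  kappa <- kappa[keep]
  if (!length(t_star)) {
    return(empty_tangent_points(w, step))
  }

  # merge flags closer than one window width, keeping the higher curvature
  w_t <- w * spacing
  repeat {
    if (length(t_star) < 2L) break
    gaps <- diff(t_star)
    j <- which(gaps < w_t)
    if (!length(j)) break
    j <- j[[1L]]
    # drop the lower-curvature member; ties keep the smaller t
    drop <- if (kappa[j + 1L] > kappa[j]) j else j + 1L
    t_star <- t_star[-drop]
    direction <- direction[-drop]
    kappa <- kappa[-drop]
  }

  # dominance check: a genuine apex moves the lateral deviation by an
  # amount comparable to the other apexes; a residual noise wiggle of the
  # interpolant does not. Prominence of an apex = smaller lateral change
  # towards its two neighbours (adjacent apexes or domain ends).
  if (length(t_star) > 1L) {
    nodes <- c(curve$t_range[1L], t_star, curve$t_range[2L])
    dv <- predict(curve, nodes)
    prom <- vapply(seq_along(t_star), function(i) {
      min(abs(dv[i + 1L] - dv[i]), abs(dv[i + 1L] - dv[i + 2L]))
    }, numeric(1))
    keep <- prom >= rel_prominence * max(prom)
    t_star <- t_star[keep]
    direction <- direction[keep]
    kappa <- kappa[keep]
  }

  structure(
    data.frame(t = t_star, slope_change = direction, curvature = kappa,
               stringsAsFactors = FALSE),
    class = c("tangent_points", "data.frame"),
    window = w, step = step
  )
}

empty_tangent_points <- function(w, step) {
  structure(
    data.frame(t = numeric(0), slope_change = character(0),
               curvature = numeric(0), stringsAsFactors = FALSE),
    class = c("tangent_points", "data.frame"),
    window = w, step = step
  )
}

#' Classify the coronal curvature type from tangent points
#'
#' One tangent point means a C-shaped (single) curve, two an S-shaped
#' (double) curve, and more than two a multi-curved spine. A curve with no
#' tangent point (near-straight spine) is labeled `C` with the
#' `degenerate` flag set, since the clinical taxonomy has no separate
#' "straight" class.
#'
#' @param tp a `tangent_points` data frame from [tangent_points()].
#' @return An object of class `curve_type`: list with `label` (`"C"`,
#'   `"S"` or `"multi"`), `degenerate` flag, `tangent_points`, `window`
#'   and `step`.
#' @seealso [curve_type()] for the one-call wrapper.
#' @export
classify_curve_type <- function(tp) {
  n <- nrow(tp)
  label <- if (n <= 1L) "C" else if (n == 2L) "S" else "multi"
  structure(
    list(
      label = label,
      degenerate = n == 0L,
      tangent_points = tp,
      window = attr(tp, "window"),
      step = attr(tp, "step")
    ),
    class = "curve_type"
  )
}

#' Detect tangent points and classify the curvature type
#'
#' Convenience wrapper running [tangent_points()] then
#' [classify_curve_type()] on a fitted spine curve.
#'
#' @inheritParams tangent_points
#' @return A `curve_type` object; see [classify_curve_type()].
#' @examples
#' case <- synth_coronal_case("S", amplitude = 0.08, seed = 2)
#' curve_type(spine_curve(case$keypoints))
#' @export
curve_type <- function(curve, window_frac = 0.1, step = 2L) {
  classify_curve_type(tangent_points(curve, window_frac, step))
}

#' @export
print.curve_type <- function(x, ...) {
  cat(sprintf(
    "Coronal curvature type: %s%s (%d tangent point%s)\n",
    x$label, if (x$degenerate) " (degenerate/straight)" else "",
    nrow(x$tangent_points), if (nrow(x$tangent_points) == 1L) "" else "s"
  ))
  if (nrow(x$tangent_points)) {
    print(as.data.frame(x$tangent_points), row.names = FALSE)
  }
  invisible(x)
}

# JSON-ready representation of a fitted curve and its type
#' @export
as.list.curve_type <- function(x, ...) {
  list(
    label = x$label,
    degenerate = x$degenerate,
    tangent_points = as.data.frame(x$tangent_points),
    window = x$window,
    step = x$step
  )
}
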