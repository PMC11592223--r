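# Ground-truthed synthetic generators for every pipeline stage.
#
# Coronal archetypes are a sine family: lateral deviation
# d(t) = amplitude * L * sin(m * pi * t / L) over the spine axis t in
# [0, L], with m = 1 (C), 2 (S), 3 (multi) interior extrema, and m = 0 a
# straight spine. The analytic Cobb ground truth applies the same
# segment rule as cobb_angle() to the generating sine: each of the m
# convex/concave parts contributes 2 * atan(amplitude * m * pi).

#' Synthetic coronal case with analytic ground truth
#'
#' Generates one set of back keypoints from a sine-family spine archetype
#' with known curvature type and analytic Cobb angle. The five spine
#' keypoints sample the generating curve at `t = {0, 1/4, 1/2, 3/4, 1} *
#' spine_length`; the scapular points are placed symmetrically about the
#' spine axis, with an optional vertical asymmetry. Gaussian positional
#' noise of standard deviation `noise_sd` pixels is added to every
#' keypoint coordinate.
#'
#' @param kind `"C"`, `"S"`, `"multi"` or `"straight"`.
#' @param amplitude lateral deviation amplitude as a fraction of spine
#'   length, in `[0, 0.2]`.
#' @param spine_length spine length in pixels (at least 100).
#' @param noise_sd keypoint position noise in pixels.
#' @param seed integer seed; the case is bit-reproducible given the seed.
#' @param scapula_asymmetry vertical offset of the right scapula as a
#'   fraction of spine length (drives the triangle base-angle difference).
#' @return An object of class `synthetic_coronal_case`: list with
#'   `keypoints` ([back_keypoints]), `kind`, `true_type` (the C/S/multi
#'   label; a straight spine is a degenerate C), `true_cobb` (degrees),
#'   `amplitude`, `noise_sd`, `seed`.
#' @examples
#' case <- synth_coronal_case("S", amplitude = 0.08, seed = 42)
#' case$true_cobb
#' @export
synth_coronal_case <- function(kind = c("C", "S", "multi", "straight"),
                               amplitude = 0.05, spine_length = 400,
                               noise_sd = 0, seed = NULL,
                               scapula_asymmetry = 0) {
  kind <- match.arg(kind)
  if (!is_number(amplitude) || amplitude < 0 || amplitude > 0.2) {
    stopf("amplitude must lie in [0, 0.2]")
  }
  if (!is_number(spine_length) || spine_length < 100) {
    stopf("spine_length must be at least 100 pixels")
  }
  m <- switch(kind, straight = 0L, C = 1L, S = 2L, multi = 3L)
  L <- spine_length
  W <- round(0.8 * L)
  H <- round(1.3 * L)
  y0 <- round(0.1 * L)
  xc <- W / 2

  t_nodes <- c(0, 0.25, 0.5, 0.75, 1) * L
  d_nodes <- if (m == 0L) rep(0, 5L) else {
    amplitude * L * sin(m * pi * t_nodes / L)
  }
  x <- c(xc + d_nodes, xc - 0.3 * L, xc + 0.3 * L)
  y <- c(y0 + t_nodes, y0 + 0.2 * L, y0 + 0.2 * L + scapula_asymmetry * L)

  if (noise_sd > 0) {
    noise <- with_seed(seed, stats::rnorm(14L, sd = noise_sd))
    x <- x + noise[1:7]
    y <- y + noise[8:14]
  }
  x <- pmin(pmax(x, 0), W - 1)
  y <- pmin(pmax(y, 0), H - 1)

  kp <- back_keypoints(
    x = x, y = y, image_width = W, image_height = H,
    source_id = sprintf("synthetic-%s-a%.3f", kind, amplitude)
  )
  structure(
    list(
      keypoints = kp,
      kind = kind,
      true_type = if (kind == "straight") "C" else kind,
      true_cobb = if (m == 0L) 0 else m * 2 * deg(atan(amplitude * m * pi)),
      amplitude = amplitude,
      noise_sd = noise_sd,
      seed = seed
    ),
    class = "synthetic_coronal_case"
  )
}

#' @export
print.synthetic_coronal_case <- function(x, ...) {
  cat(sprintf(
    "Synthetic coronal case: %s, amplitude %.3f, true Cobb %.2f deg, noise %.2f px\n",
    x$kind, x$amplitude, x$true_cobb, x$noise_sd
  ))
  invisible(x)
}

#' Balanced cohort of synthetic coronal cases
#'
#' `n_per_class` cases for each of the C, S and multi archetypes, with
#' amplitudes cycling over a declared grid and per-case seeds derived
#' deterministically from the cohort seed.
#'
#' @param n_per_class cases per curvature class (at least 1).
#' @param noise_sd keypoint position noise in pixels.
#' @param seed cohort seed.
#' @param amplitudes amplitude grid (fractions of spine length).
#' @param spine_length spine length in pixels.
#' @return An object of class `synth_cohort`: list with `cases` (list of
#'   [synth_coronal_case()] results) and `manifest` (data frame with
#'   `kind`, `true_type`, `amplitude`, `true_cobb`, `seed`).
#' @export
synth_cohort <- function(n_per_class = 100L, noise_sd = 0, seed = 1L,
                         amplitudes = seq(0.01, 0.15, by = 0.02),
                         spine_length = 400) {
  n_per_class <- as.integer(n_per_class)
  if (n_per_class < 1L) stopf("n_per_class must be at least 1")
  kinds <- rep(c("C", "S", "multi"), each = n_per_class)
  amps <- rep_len(rep(amplitudes, length.out = n_per_class), length(kinds))
  case_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                           length(kinds)))
  cases <- Map(function(k, a, s) {
    synth_coronal_case(k, amplitude = a, spine_length = spine_length,
                       noise_sd = noise_sd, seed = s)
  }, kinds, amps, case_seeds)
  names(cases) <- NULL
  manifest <- data.frame(
    kind = kinds,
    true_type = vapply(cases, `[[`, "", "true_type"),
    amplitude = amps,
    true_cobb = vapply(cases, `[[`, 0, "true_cobb"),
    seed = case_seeds,
    stringsAsFactors = FALSE
  )
  structure(list(cases = cases, manifest = manifest), class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic coronal cohort: %d cases (%s)\n",
    length(x$cases),
    paste(sprintf("%d %s", table(x$manifest$kind),
                  names(table(x$manifest$kind))), collapse = ", ")
  ))
  invisible(x)
}

#' Synthetic bent-back mask with known trunk rotation
#'
#' Builds a binary silhouette of a forward-bent back whose upper contour
#' is a baseline plus two Gaussian scapular bumps. The taller bump is
#' calibrated so that the line through the two realized bump apexes of
#' the continuous profile makes exactly `true_atr` degrees with the
#' horizontal; the mask is then rasterized by filling the columns below
#' the (rounded) profile. Column-wise Gaussian jitter of the contour
#' boundary models segmentation noise.
#'
#' @param true_atr target angle of trunk rotation in degrees, `[0, 45)`.
#' @param width,height image dimensions in pixels.
#' @param separation horizontal distance between bump centers (at least
#'   `width / 5` and four bump widths).
#' @param bump_height height of the lower (left) bump in pixels.
#' @param bump_width Gaussian sigma of the bumps in pixels.
#' @param baseline height of the flat back line above the image bottom.
#' @param noise_sd per-column contour jitter in pixels.
#' @param seed integer seed; the mask is bit-reproducible given the seed.
#' @return An object of class `synthetic_sagittal_case`: list with `mask`
#'   (matrix in `{0, 255}`), `profile_true` (continuous heights per
#'   column), `apexes` (2 x 2 matrix `(column, height)` of the two
#'   continuous-profile apexes), `true_atr`, `noise_sd`, `seed` and the
#'   geometry parameters.
#' @examples
#' case <- synth_sagittal_case(true_atr = 10, seed = 1)
#' dim(case$mask)
#' @export
synth_sagittal_case <- function(true_atr = 10, width = 512L, height = 384L,
                                separation = 200, bump_height = 60,
                                bump_width = 25, baseline = 80,
                                noise_sd = 0, seed = NULL) {
  if (!is_number(true_atr) || true_atr < 0 || true_atr >= 45) {
    stopf("true_atr must lie in [0, 45)")
  }
  if (separation < width / 5) {
    stopf("separation must be at least width / 5")
  }
  if (separation < 4 * bump_width) {
    stopf("bumps overlap beyond resolvability (separation < 4 * bump_width)")
  }
  c1 <- width / 2 - separation / 2
  c2 <- width / 2 + separation / 2
  A1 <- bump_height
  A2 <- A1 + separation * tan(true_atr * pi / 180)
  g <- function(x, c0) exp(-(x - c0)^2 / (2 * bump_width^2))
  prof <- function(x, a2) baseline + A1 * g(x, c1) + a2 * g(x, c2)

  # calibrate the right bump so the realized apex line is exactly true_atr
  apex <- function(c0, a2) {
    o <- stats::optimize(function(x) prof(x, a2),
                         interval = c(c0 - 2 * bump_width, c0 + 2 * bump_width),
                         maximum = TRUE)
    c(o$maximum, o$objective)
  }
  for (it in 1:40) {
    pa <- apex(c1, A2)
    pb <- apex(c2, A2)
    target <- (pb[1L] - pa[1L]) * tan(true_atr * pi / 180)
    err <- target - (pb[2L] - pa[2L])
    if (abs(err) < 1e-10) break
    A2 <- A2 + err
  }

  cols <- seq_len(width)
  h_true <- prof(cols, A2)
  h_px <- h_true
  if (noise_sd > 0) {
    h_px <- h_px + with_seed(seed, stats::rnorm(width, sd = noise_sd))
  }
  h_px <- pmin(pmax(round(h_px), 1L), height)
  if (max(h_true) > height - 2) stopf("profile exceeds image height")

  mask <- matrix(0, height, width)
  for (j in cols) {
    mask[(height - h_px[j] + 1L):height, j] <- 255
  }
  structure(
    list(
      mask = mask,
      profile_true = h_true,
      apexes = rbind(a = pa, b = pb),
      true_atr = true_atr,
      width = width, height = height, separation = separation,
      bump_height = bump_height, bump_width = bump_width,
      baseline = baseline, noise_sd = noise_sd, seed = seed
    ),
    class = "synthetic_sagittal_case"
  )
}

#' @export
print.synthetic_sagittal_case <- function(x, ...) {
  cat(sprintf(
    "Synthetic sagittal case: true ATR %.2f deg, %d x %d mask, noise %.2f px\n",
    x$true_atr, x$height, x$width, x$noise_sd
  ))
  invisible(x)
}
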