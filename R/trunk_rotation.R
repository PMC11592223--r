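# Sagittal-plane pipeline: AMPD peak detection on the back-contour profile
# and the angle of trunk rotation (ATR).

#' Linearly detrend a uniformly sampled signal
#'
#' Subtracts the least-squares line so that the result has zero mean and
#' zero best-fit slope; required before building the local maxima
#' scalogram.
#'
#' @param x numeric signal, length at least 2.
#' @return Detrended numeric vector of the same length.
#' @export
detrend_linear <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stopf("signal must have at least 2 samples")
  t <- seq_len(n)
  tc <- t - mean(t)
  beta <- sum(tc * x) / sum(tc^2)
  x - mean(x) - beta * tc
}

#' Local maxima scalogram (LMS) of a signal
#'
#' First stage of automatic multiscale peak detection (AMPD). For scales
#' `k = 1 ... L` with `L = ceiling(N/2) - 1` (window lengths `w_k = 2k`)
#' the `L x N` matrix `M` holds, at column `i` for
#' `i = k+2, ..., N-k+1`,
#' `m[k, i] = 0` when `x[i-1] > x[i-k-1]` and `x[i-1] > x[i+k-1]`
#' (sample `i-1` is a local maximum at scale `k`), and `r + alpha`
#' otherwise, where `r` is a fresh uniform random number in `[0, 1)` and
#' `alpha = 1`; boundary columns are always assigned `r + alpha`. The row
#' sums `gamma_k` locate the scale `lambda = argmin gamma_k` that carries
#' the most local maxima; rows beyond `lambda` are discarded to form the
#' reshaped matrix `Mr`.
#'
#' @param x detrended numeric signal, at least 8 samples.
#' @param seed optional integer seed for the random entries (the detected
#'   peaks do not depend on it; see [ampd()]).
#' @param alpha constant offset of the random entries.
#' @return An object of class `ampd_lms`: list with `M` (`L x N`), `gamma`,
#'   `lambda`, `Mr` (`lambda x N`), `L`, `n` and `seed`.
#' @references Scholkmann, Boss and Wolf (2012), Algorithms 5(4):588-603.
#' @export
ampd_lms <- function(x, seed = NULL, alpha = 1) {
  x <- as.numeric(x)
  n <- length(x)
  L <- as.integer(ceiling(n / 2) - 1)
  if (L < 1L) stopf("signal too short for the LMS (need at least 4 samples)")
  zeros <- integer(L) # deterministic zero count per scale
  M <- with_seed(seed, {
    M <- matrix(stats::runif(L * n) + alpha, L, n)
    for (k in seq_len(L)) {
      i <- (k + 2L):(n - k + 1L) # columns of the valid range at scale k
      j <- i - 1L                # the signal sample each column tests
      is_max <- x[j] > x[j - k] & x[j] > x[j + k]
      M[k, i[is_max]] <- 0
      zeros[k] <- sum(is_max)
    }
    M
  })
  gamma <- rowSums(M)
  # gamma_k = (n - zeros_k) * (alpha + mean r): its ordering is carried by
  # the deterministic zero pattern; selecting the scale from that part
  # makes lambda -- and hence the detected peak set -- seed-independent
  lambda <- which.min(n - zeros)
  structure(
    list(
      M = M, gamma = gamma, lambda = lambda,
      Mr = M[seq_len(lambda), , drop = FALSE],
      L = L, n = n, seed = seed
    ),
    class = "ampd_lms"
  )
}

#' @export
print.ampd_lms <- function(x, ...) {
  cat(sprintf(
    "AMPD local maxima scalogram: %d scales x %d samples, lambda = %d\n",
    x$L, x$n, x$lambda
  ))
  invisible(x)
}

#' Automatic multiscale peak detection (AMPD)
#'
#' Detects the peaks of a detrended, uniformly sampled, periodic or
#' quasi-periodic signal. Peaks are the columns of the reshaped local
#' maxima scalogram (see [ampd_lms()]) whose standard deviation is zero,
#' i.e. the samples that are local maxima at every scale up to `lambda`.
#' Because the non-zero scalogram entries are random, a column standard
#' deviation of zero is (almost surely) only possible when all its entries
#' are the deterministic zeros, so the detected peak set does not depend
#' on `seed`. Column indices are mapped back to signal samples, so the
#' returned `peaks` index directly into `x`.
#'
#' The method has a known blind zone: a maximum closer than about `lambda`
#' samples to either end of the signal falls into the boundary region of
#' the scalogram and cannot be detected.
#'
#' @param x detrended numeric signal (see [detrend_linear()]).
#' @param seed optional integer seed for the scalogram randomness.
#' @param tol tolerance on the column standard deviation counted as zero.
#' @return An object of class `ampd`: list with `peaks` (strictly
#'   increasing sample indices into `x`), `sigma` (per-sample standard
#'   deviation of the reshaped scalogram), `lambda`, `L`, `n`, `seed`.
#' @examples
#' t <- seq(0, 1, length.out = 400)
#' x <- detrend_linear(sin(2 * pi * 4 * (t - 0.15)))
#' ampd(x, seed = 1)$peaks
#' @export
ampd <- function(x, seed = NULL, tol = 1e-12) {
  if (length(x) < 8L) stopf("signal too short for peak detection (need >= 8)")
  lms <- ampd_lms(x, seed = seed)
  Mr <- lms$Mr
  if (lms$lambda == 1L) {
    sigma_col <- rep(NA_real_, lms$n)
    peaks_col <- which(Mr[1L, ] == 0)
  } else {
    sigma_col <- apply(Mr, 2L, stats::sd)
    peaks_col <- which(sigma_col <= tol)
  }
  # column i tests sample i - 1 (see ampd_lms); report sample indices
  peaks <- peaks_col - 1L
  sigma <- c(sigma_col[-1L], NA_real_)
  structure(
    list(
      peaks = peaks, sigma = sigma, lambda = lms$lambda,
      L = lms$L, n = lms$n, seed = seed
    ),
    class = "ampd"
  )
}

#' @export
print.ampd <- function(x, ...) {
  cat(sprintf(
    "AMPD: %d peak%s on %d samples (lambda = %d)\n",
    length(x$peaks), if (length(x$peaks) == 1L) "" else "s", x$n, x$lambda
  ))
  if (length(x$peaks)) cat(" ", x$peaks, "\n")
  invisible(x)
}

# topographic prominence of peak p in signal x: height above the higher of
# the two side minima, each taken up to the nearest higher sample (or the
# signal end when none exists on that side)
peak_prominence <- function(x, p) {
  n <- length(x)
  walk <- function(step) {
    i <- p + step
    m <- Inf
    while (i >= 1L && i <= n && x[i] <= x[p]) {
      m <- min(m, x[i])
      i <- i + step
    }
    if (!is.finite(m)) m <- x[p]
    m
  }
  x[p] - max(walk(-1L), walk(1L))
}

#' Reduce detected peaks to the two scapular prominences
#'
#' The bent-back profile is expected to be bimodal: one bulge per scapula.
#' With exactly two detected peaks both pass through. With more, each peak
#' is scored by its topographic prominence divided by the local flatness
#' of the profile (standard deviation of the heights in a window of
#' `+/- flat_halfwidth` columns), and the two highest-scoring peaks at
#' least `min_separation` columns apart are retained. Fewer than two
#' admissible peaks raise a `bimodal_failure` error, signaling an unusable
#' photograph.
#'
#' @param peaks integer column indices of detected peaks.
#' @param heights numeric profile heights the peaks index into.
#' @param min_separation minimum column distance between the retained
#'   pair; defaults to a tenth of the profile length.
#' @param flat_halfwidth half-width of the flatness window; defaults to a
#'   twentieth of the profile length.
#' @return Integer vector of the two retained peak columns, increasing.
#' @export
filter_to_two_peaks <- function(peaks, heights,
                                min_separation = NULL, flat_halfwidth = NULL) {
  n <- length(heights)
  if (is.null(min_separation)) min_separation <- n / 10
  if (is.null(flat_halfwidth)) flat_halfwidth <- max(2L, round(n / 20))
  if (length(peaks) < 2L) {
    stop(structure(
      class = c("bimodal_failure", "error", "condition"),
      list(
        message = "bimodal detection failure: fewer than 2 peaks found",
        call = sys.call(-1)
      )
    ))
  }
  peaks <- sort(as.integer(peaks))
  if (length(peaks) == 2L) return(peaks)
  score <- vapply(peaks, function(p) {
    win <- max(1L, p - flat_halfwidth):min(n, p + flat_halfwidth)
    flat <- max(stats::sd(heights[win]), 1e-9)
    peak_prominence(heights, p) / flat
  }, numeric(1))
  o <- order(score, decreasing = TRUE)
  best <- peaks[o[1L]]
  for (cand in peaks[o[-1L]]) {
    if (abs(cand - best) >= min_separation) {
      return(sort(c(best, cand)))
    }
  }
  stop(structure(
    class = c("bimodal_failure", "error", "condition"),
    list(
      message = "bimodal detection failure: no admissible peak pair",
      call = sys.call(-1)
    )
  ))
}

#' Angle of trunk rotation between two profile peaks
#'
#' The angle between the line joining the two scapular prominences and the
#' horizontal: `atan(|dh| / |dcol|)` in degrees.
#'
#' @param peak_a,peak_b numeric `(column, height)` pairs in pixels.
#' @return Angle in degrees, in `[0, 90)`.
#' @export
atr_angle <- function(peak_a, peak_b) {
  dc <- peak_b[[1L]] - peak_a[[1L]]
  if (dc == 0) stopf("degenerate peak pair: equal columns")
  deg(atan(abs(peak_b[[2L]] - peak_a[[2L]]) / abs(dc)))
}

#' Measure the angle of trunk rotation from a bent-back image
#'
#' Full sagittal pipeline: preprocess, binarize (unless the input already
#' is a binary mask), detect edges with the chosen operator, extract the
#' per-column contour profile, repair invalid columns, detrend, run AMPD,
#' reduce the peaks to the two scapular prominences and compute the ATR
#' angle from the line joining them.
#'
#' Interior invalid profile columns are linearly interpolated and marginal
#' ones trimmed before peak detection, which needs a gap-free uniform
#' signal. Because mask-derived heights are integers, apex plateaus of
#' exactly equal heights can occur; after detrending, an infinitesimal
#' deterministic tilt (far below the 1-pixel height quantum) is added to
#' break such ties, and each detected peak is re-centered on the plateau
#' of equal original heights containing it.
#'
#' @param x a grayscale image matrix, binary mask matrix, PNG file path, or
#'   a [contour_profile].
#' @param operator edge operator passed to [edge_detect()].
#' @param denoise,equalize preprocessing flags (grayscale input only).
#' @param threshold binarization threshold (grayscale input only).
#' @param sigma Gaussian sigma for the LOG operator.
#' @param seed integer seed for the AMPD scalogram randomness.
#' @return An object of class `atr_result`: list with `atr_deg`, `peaks`
#'   (2 x 2 matrix, columns `column`/`height`), `operator`,
#'   `n_peaks_raw`, `lambda`, `seed` and `profile`.
#' @examples
#' case <- synth_sagittal_case(true_atr = 10, seed = 3)
#' measure_atr(case$mask, operator = "prewitt", seed = 1)
#' @export
measure_atr <- function(x, operator = c("prewitt", "roberts", "log"),
                        denoise = TRUE, equalize = FALSE,
                        threshold = "otsu", sigma = 1.4, seed = NULL) {
  operator <- match.arg(operator)
  if (is.character(x) && length(x) == 1L) x <- read_gray(x)
  from_profile <- inherits(x, "contour_profile")
  if (from_profile) {
    profile <- x
  } else {
    x <- check_image(x)
    is_mask <- length(unique(as.vector(x))) <= 2L
    if (!is_mask) {
      x <- preprocess_image(x, denoise = denoise, equalize = equalize)
      x <- binarize(x, threshold)
    }
    # an image without a usable silhouette is a pipeline failure, like an
    # unusable bimodal profile, not a schema error
    profile <- tryCatch(
      extract_profile(edge_detect(x, operator, sigma = sigma)),
      error = function(e) stop(structure(
        class = c("bimodal_failure", "error", "condition"),
        list(message = conditionMessage(e), call = sys.call(-1))
      ))
    )
  }

  h <- profile$heights
  valid <- profile$valid
  if (!any(valid)) stopf("empty profile")
  first <- which(valid)[1L]
  last <- which(valid)[sum(valid)]
  offset <- first - 1L
  h <- h[first:last]
  valid <- valid[first:last]
  if (any(!valid)) { # interior gaps: linear interpolation
    h <- stats::approx(which(valid), h[valid], xout = seq_along(h))$y
  }

  sig <- detrend_linear(h)
  # deterministic tie-break tilt, far below the 1 px quantization step
  tilt <- 1e-9 * max(1, diff(range(sig))) / length(sig)
  sig <- sig + tilt * seq_along(sig)
  res <- ampd(sig, seed = seed)
  raw_peaks <- res$peaks + offset

  # re-center each peak on its plateau of equal (original) profile heights
  raw_peaks <- vapply(raw_peaks, function(p) {
    v <- profile$heights
    lo <- p
    while (lo > 1L && isTRUE(v[lo - 1L] == v[p])) lo <- lo - 1L
    hi <- p
    while (hi < length(v) && isTRUE(v[hi + 1L] == v[p])) hi <- hi + 1L
    as.integer(round((lo + hi) / 2))
  }, integer(1))
  raw_peaks <- sort(unique(raw_peaks))

  two <- filter_to_two_peaks(raw_peaks, profile$heights)
  pk <- cbind(
    column = two,
    height = profile$heights[two]
  )
  structure(
    list(
      atr_deg = atr_angle(pk[1L, ], pk[2L, ]),
      peaks = pk,
      operator = if (from_profile) profile$source_operator else operator,
      n_peaks_raw = length(raw_peaks),
      lambda = res$lambda,
      seed = seed,
      profile = profile
    ),
    class = "atr_result"
  )
}

#' @export
print.atr_result <- function(x, ...) {
  cat(sprintf(
    "ATR = %.2f deg (%s operator, %d raw peak%s, lambda = %d)\n",
    x$atr_deg, x$operator, x$n_peaks_raw,
    if (x$n_peaks_raw == 1L) "" else "s", x$lambda
  ))
  cat(sprintf(
    "  prominences at columns %d and %d, heights %.0f and %.0f px\n",
    x$peaks[1L, 1L], x$peaks[2L, 1L], x$peaks[1L, 2L], x$peaks[2L, 2L]
  ))
  invisible(x)
}

#' @export
as.list.atr_result <- function(x, ...) {
  list(
    atr_deg = x$atr_deg,
    peaks = list(as.numeric(x$peaks[1L, ]), as.numeric(x$peaks[2L, ])),
    operator = x$operator,
    n_peaks_raw = x$n_peaks_raw,
    lambda = x$lambda,
    seed = x$seed
  )
}
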