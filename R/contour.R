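# Images are plain numeric matrices with intensities in [0, 255],
# row 1 = top image row, matching the keypoint pixel frame.

#' Read a grayscale image or binary mask from PNG
#'
#' Reads an 8-bit PNG and returns an intensity matrix in `[0, 255]`
#' (row 1 = top row). Color images are converted to grayscale by channel
#' averaging.
#'
#' @param path PNG file path.
#' @return Numeric matrix of intensities in `[0, 255]`.
#' @export
read_gray <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- apply(px[, , 1:3, drop = FALSE], c(1, 2), mean)
  px * 255
}

#' Write an intensity matrix to PNG
#'
#' @param img numeric matrix with intensities in `[0, 255]`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path) {
  png::writePNG(pmin(pmax(img / 255, 0), 1), path)
  invisible(path)
}

check_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img) || !length(img)) {
    stopf("image must be a non-empty numeric matrix")
  }
  if (any(img < 0 | img > 255)) stopf("intensities must lie in [0, 255]")
  img
}

# replicate-edge padding so filtered outputs keep the input dimensions
pad_replicate <- function(img, top, bottom, left, right) {
  h <- nrow(img)
  w <- ncol(img)
  img[
    c(rep(1L, top), seq_len(h), rep(h, bottom)),
    c(rep(1L, left), seq_len(w), rep(w, right)),
    drop = FALSE
  ]
}

# cross-correlation with a small kernel, replicate border, same-size output;
# origin = kernel cell aligned with the output pixel
filter2d <- function(img, kern, origin = c(1L, 1L)) {
  kh <- nrow(kern)
  kw <- ncol(kern)
  top <- origin[1L] - 1L
  left <- origin[2L] - 1L
  P <- pad_replicate(img, top, kh - origin[1L], left, kw - origin[2L])
  h <- nrow(img)
  w <- ncol(img)
  out <- matrix(0, h, w)
  for (a in seq_len(kh)) {
    for (b in seq_len(kw)) {
      if (kern[a, b] == 0) next
      out <- out + kern[a, b] * P[(a - 1L) + seq_len(h), (b - 1L) + seq_len(w)]
    }
  }
  out
}

# separable Gaussian smoothing, replicate border
gaussian_blur <- function(img, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  g <- exp(-(-r:r)^2 / (2 * sigma^2))
  g <- g / sum(g)
  row_k <- matrix(g, nrow = 1L)
  col_k <- matrix(g, ncol = 1L)
  tmp <- filter2d(img, row_k, origin = c(1L, r + 1L))
  filter2d(tmp, col_k, origin = c(r + 1L, 1L))
}

median3 <- function(img) {
  h <- nrow(img)
  w <- ncol(img)
  P <- pad_replicate(img, 1L, 1L, 1L, 1L)
  stack <- vapply(
    1:9,
    function(k) {
      a <- (k - 1L) %/% 3L
      b <- (k - 1L) %% 3L
      P[a + seq_len(h), b + seq_len(w)]
    },
    matrix(0, h, w)
  )
  matrix(apply(stack, c(1, 2), stats::median), h, w)
}

#' Preprocess a grayscale back image
#'
#' Optional 3x3 median-filter denoising and global histogram-equalization
#' contrast enhancement. With both flags off the image is returned
#' unchanged; a constant image is always returned unchanged.
#'
#' @param img intensity matrix in `[0, 255]`.
#' @param denoise apply the median filter.
#' @param equalize apply histogram equalization.
#' @return Intensity matrix of the same dimensions.
#' @export
preprocess_image <- function(img, denoise = TRUE, equalize = FALSE) {
  img <- check_image(img)
  if (denoise) img <- median3(img)
  if (equalize && length(unique(as.vector(img))) > 1L) {
    cdf <- stats::ecdf(as.vector(img))
    p <- cdf(img)
    p0 <- min(p)
    img <- matrix(255 * (p - p0) / (1 - p0 + 1e-12), nrow(img), ncol(img))
  }
  img
}

# Otsu's threshold on a 256-bin histogram; returns an intensity in [0, 255]
otsu_threshold <- function(img) {
  counts <- tabulate(pmin(floor(img), 255) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256L]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  which.max(sigma_b) - 1L + 1L # threshold: foreground at >= t with t = argmax + 1
}

#' Binarize a grayscale image
#'
#' Foreground (255) where intensity is at least `threshold`; `"otsu"`
#' selects the threshold maximizing the between-class variance of the
#' intensity histogram.
#'
#' @param img intensity matrix in `[0, 255]`.
#' @param threshold numeric threshold or `"otsu"`.
#' @return Matrix with values in `{0, 255}`.
#' @export
binarize <- function(img, threshold = "otsu") {
  img <- check_image(img)
  if (identical(threshold, "otsu")) threshold <- otsu_threshold(img)
  (img >= threshold) * 255
}

roberts_kernels <- list(
  dx = matrix(c(1, 0, 0, -1), 2L, 2L, byrow = TRUE),
  dy = matrix(c(0, 1, -1, 0), 2L, 2L, byrow = TRUE)
)

prewitt_kernels <- list(
  dx = matrix(rep(c(-1, 0, 1), 3L), 3L, 3L, byrow = TRUE),
  dy = matrix(rep(c(-1, 0, 1), each = 3L), 3L, 3L, byrow = TRUE)
)

#' Gradient / Laplacian edge detection
#'
#' The three classical operators used for back-contour extraction:
#'
#' * `roberts`: two 2x2 difference kernels; strength
#'   `S = sqrt(dx^2 + dy^2)`.
#' * `prewitt`: two 3x3 first-difference kernels; strength as above.
#' * `log`: Gaussian smoothing followed by the 4-neighbour Laplacian
#'   `f(i+1,j) + f(i-1,j) + f(i,j+1) + f(i,j-1) - 4 f(i,j)`; edges are the
#'   zero crossings of the response, with strength equal to the local
#'   response jump.
#'
#' Borders are handled by replicate padding so the edge map matches the
#' input dimensions.
#'
#' @param img intensity matrix in `[0, 255]`.
#' @param operator `"roberts"`, `"prewitt"` or `"log"`.
#' @param sigma Gaussian sigma for the LOG operator.
#' @return An object of class `edge_map`: list with `strength` (non-negative
#'   matrix), `operator`, and either `dx`, `dy` (roberts/prewitt) or
#'   `laplacian`, `zero_crossing` (log).
#' @export
edge_detect <- function(img, operator = c("prewitt", "roberts", "log"),
                        sigma = 1.4) {
  img <- check_image(img)
  operator <- match.arg(operator)
  kmin <- if (operator == "roberts") 2L else 3L
  if (nrow(img) < kmin || ncol(img) < kmin) {
    stopf("image smaller than the %dx%d operator kernel", kmin, kmin)
  }
  if (operator %in% c("roberts", "prewitt")) {
    ks <- if (operator == "roberts") roberts_kernels else prewitt_kernels
    origin <- if (operator == "roberts") c(1L, 1L) else c(2L, 2L)
    dx <- filter2d(img, ks$dx, origin)
    dy <- filter2d(img, ks$dy, origin)
    em <- list(
      strength = sqrt(dx^2 + dy^2), dx = dx, dy = dy, operator = operator
    )
  } else {
    sm <- gaussian_blur(img, sigma)
    lap_k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3L, 3L, byrow = TRUE)
    lap <- filter2d(sm, lap_k, origin = c(2L, 2L))
    h <- nrow(lap)
    w <- ncol(lap)
    # a crossing is marked at the smaller-magnitude member of any
    # opposite-sign 4-neighbour pair (with tolerance for symmetric ties)
    nbrs <- list(
      lap[, c(1L, seq_len(w - 1L)), drop = FALSE],
      lap[, c(2:w, w), drop = FALSE],
      lap[c(1L, seq_len(h - 1L)), , drop = FALSE],
      lap[c(2:h, h), , drop = FALSE]
    )
    zc <- matrix(FALSE, h, w)
    jump <- matrix(0, h, w)
    for (nb in nbrs) {
      m <- (lap * nb < 0) & (abs(lap) <= abs(nb) * (1 + 1e-9))
      zc <- zc | m
      jump <- pmax(jump, abs(lap - nb) * m)
    }
    em <- list(
      strength = jump, laplacian = lap,
      zero_crossing = zc, operator = "log", sigma = sigma
    )
  }
  structure(em, class = "edge_map")
}

#' @export
print.edge_map <- function(x, ...) {
  cat(sprintf(
    "Edge map (%s operator, %d x %d px, max strength %.1f)\n",
    x$operator, nrow(x$strength), ncol(x$strength), max(x$strength)
  ))
  invisible(x)
}

#' Extract the 1-D back-contour profile
#'
#' Reduces a bent-back silhouette to the univariate signal fed to peak
#' detection: for every image column, the height (in pixels, measured
#' upward from the image bottom) of the top-most foreground pixel of a
#' binary mask, or of the top-most sufficiently strong edge pixel of an
#' [edge_detect()] map. With this orientation the scapular bulges of a
#' forward-bent back are local maxima of the profile. Columns with no
#' foreground (or no strong edge) are marked invalid.
#'
#' @param x a binary mask matrix (two intensity levels, foreground > 0) or
#'   an `edge_map`.
#' @param strength_frac for edge maps: a column's contour pixel is the
#'   top-most pixel with strength at least `strength_frac * max(strength)`.
#' @return An object of class `contour_profile`: list with `heights`
#'   (numeric per column, `NA` where invalid), `valid` (logical),
#'   `image_height`, `source_operator`.
#' @export
extract_profile <- function(x, strength_frac = 0.5) {
  if (inherits(x, "edge_map")) {
    s <- x$strength
    if (max(s) <= 0) stopf("empty profile: edge map has no response")
    fg <- s >= strength_frac * max(s)
    op <- x$operator
  } else {
    x <- check_image(x)
    lv <- unique(as.vector(x))
    if (length(lv) > 2L) {
      stopf("expected a binary mask; run binarize() or edge_detect() first")
    }
    fg <- x > 0
    op <- "mask"
  }
  if (!any(fg)) stopf("empty profile: mask has no foreground")
  H <- nrow(fg)
  top <- apply(fg, 2L, function(cl) if (any(cl)) which(cl)[1L] else NA_integer_)
  heights <- H - top + 1L
  structure(
    list(
      heights = as.numeric(heights), valid = !is.na(top),
      image_height = H, source_operator = op
    ),
    class = "contour_profile"
  )
}

#' @export
print.contour_profile <- function(x, ...) {
  cat(sprintf(
    "Back contour profile: %d columns (%d valid), source %s\n",
    length(x$heights), sum(x$valid), x$source_operator
  ))
  invisible(x)
}

#' @export
plot.contour_profile <- function(x, ...) {
  graphics::plot(
    seq_along(x$heights), x$heights, type = "l",
    xlab = "image column", ylab = "height above bottom (px)", ...
  )
  invisible(x)
}

#' Write / read a contour profile as two-column CSV
#'
#' Columns `column_index,height`; invalid columns are omitted.
#'
#' @param profile a `contour_profile`.
#' @param path CSV path.
#' @return `path` (write) or a `contour_profile` (read).
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(
    column_index = which(profile$valid),
    height = profile$heights[profile$valid]
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @param image_height total image height in pixels (read); defaults to the
#'   maximum stored height.
#' @export
read_profile <- function(path, image_height = NULL) {
  df <- utils::read.csv(path)
  n <- max(df$column_index)
  heights <- rep(NA_real_, n)
  heights[df$column_index] <- df$height
  structure(
    list(
      heights = heights, valid = !is.na(heights),
      image_height = if (is.null(image_height)) max(df$height) else image_height,
      source_operator = "csv"
    ),
    class = "contour_profile"
  )
}
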