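#' Labels of the seven back keypoints
#'
#' Five points along the spine, numbered top to bottom (`spine0` ...
#' `spine4`), plus the left and right scapular prominences. The order of
#' this vector is the canonical storage order of a [back_keypoints] object.
#'
#' @export
keypoint_labels <- c(
  "spine0", "spine1", "spine2", "spine3", "spine4",
  "scapula_left", "scapula_right"
)

#' Back keypoints of one standing photograph
#'
#' Builds and validates the set of seven labeled back keypoints used by the
#' coronal-plane pipeline. Coordinates are in the image pixel frame: origin
#' at the top-left corner, `x` rightward, `y` downward, zero-based, so the
#' topmost spine point has the smallest `y`.
#'
#' @param x,y numeric vectors of length 7, pixel coordinates.
#' @param labels character vector of point labels; must be a permutation of
#'   [keypoint_labels].
#' @param visible logical vector (recycled) flagging annotated points.
#' @param image_width,image_height image dimensions in pixels.
#' @param source_id free-text identifier of the source image.
#'
#' @return An object of class `back_keypoints`: a list with elements
#'   `points` (data frame with columns `label`, `x`, `y`, `visible` in
#'   canonical order), `image_width`, `image_height` and `source_id`.
#'
#' @details Validation enforces one point per label, in-bounds coordinates
#'   for visible points (`0 <= x < image_width`, `0 <= y < image_height`)
#'   and strictly increasing `y` along `spine0` ... `spine4` (the spine must
#'   run top to bottom).
#'
#' @seealso [read_keypoints()], [spine_curve()], [triangle_asymmetry()]
#' @examples
#' kp <- back_keypoints(
#'   x = c(160, 150, 145, 152, 160, 90, 230),
#'   y = c(40, 140, 240, 340, 440, 120, 120),
#'   image_width = 320, image_height = 480
#' )
#' kp
#' @export
back_keypoints <- function(x, y, labels = keypoint_labels, visible = TRUE,
                           image_width, image_height, source_id = "") {
  if (length(x) != length(labels) || length(y) != length(labels)) {
    stopf("x, y and labels must all have length %d", length(keypoint_labels))
  }
  pts <- data.frame(
    label = as.character(labels),
    x = as.numeric(x),
    y = as.numeric(y),
    visible = rep_len(as.logical(visible), length(labels)),
    stringsAsFactors = FALSE
  )
  kp <- structure(
    list(
      points = pts,
      image_width = as.numeric(image_width),
      image_height = as.numeric(image_height),
      source_id = as.character(source_id)
    ),
    class = "back_keypoints"
  )
  validate_back_keypoints(kp)
}

#' Validate a back_keypoints object
#'
#' Checks the schema invariants of a [back_keypoints] object and returns it
#' invisibly unchanged, or fails with an error naming the offending field.
#'
#' @param kp a `back_keypoints` object.
#' @return `kp`, invisibly, if valid.
#' @export
validate_back_keypoints <- function(kp) {
  pts <- kp$points
  for (lab in keypoint_labels) {
    n <- sum(pts$label == lab)
    if (n == 0L) stopf("missing label %s", lab)
    if (n > 1L) stopf("duplicate label %s", lab)
  }
  extra <- setdiff(pts$label, keypoint_labels)
  if (length(extra)) stopf("unknown label %s", extra[[1L]])
  if (!is_number(kp$image_width) || !is_number(kp$image_height) ||
      kp$image_width <= 0 || kp$image_height <= 0) {
    stopf("image_width and image_height must be positive numbers")
  }
  # canonical order
  pts <- pts[match(keypoint_labels, pts$label), , drop = FALSE]
  rownames(pts) <- NULL
  vis <- pts$visible
  bad <- vis & (pts$x < 0 | pts$x >= kp$image_width |
                  pts$y < 0 | pts$y >= kp$image_height |
                  !is.finite(pts$x) | !is.finite(pts$y))
  if (any(bad)) {
    stopf("point %s out of image bounds", pts$label[which(bad)[1L]])
  }
  sp <- pts$y[1:5]
  if (any(diff(sp) <= 0)) {
    stopf("spine points not strictly monotone in y (top to bottom)")
  }
  kp$points <- pts
  invisible(kp)
}

#' @export
print.back_keypoints <- function(x, ...) {
  cat(sprintf(
    "Back keypoints (%g x %g px image%s)\n",
    x$image_width, x$image_height,
    if (nzchar(x$source_id)) paste0(", ", x$source_id) else ""
  ))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Extract the five spine points
#'
#' @param kp a [back_keypoints] object.
#' @return Data frame of the five spine points, ordered `spine0` ...
#'   `spine4` (top to bottom).
#' @export
spine_points <- function(kp) {
  kp <- validate_back_keypoints(kp)
  kp$points[1:5, , drop = FALSE]
}

#' Extract the two scapular points
#'
#' @param kp a [back_keypoints] object.
#' @return Data frame with rows `scapula_left`, `scapula_right`.
#' @export
scapula_points <- function(kp) {
  kp <- validate_back_keypoints(kp)
  kp$points[6:7, , drop = FALSE]
}

#' Read back keypoints from JSON or CSV
#'
#' The JSON schema is
#' `{"image": {"width": w, "height": h}, "source_id": id,
#'   "points": [{"label", "x", "y", "visible"} x 7]}`.
#' The CSV alternative has columns `label,x,y,visible` preceded by comment
#' lines `# image_width:`, `# image_height:` and optionally `# source_id:`.
#' Coordinates are preserved exactly; no rescaling is applied.
#'
#' @param path file path.
#' @param format `"auto"` (by file extension), `"json"` or `"csv"`.
#' @return A validated [back_keypoints] object.
#' @seealso [write_keypoints()]
#' @export
read_keypoints <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  if (!file.exists(path)) stopf("keypoint file not found: %s", path)
  if (format == "json") {
    obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (is.null(obj$image$width) || is.null(obj$image$height)) {
      stopf("missing field image.width/image.height")
    }
    pts <- obj$points
    if (is.null(pts) || is.null(pts$label)) stopf("missing field points")
    back_keypoints(
      x = pts$x, y = pts$y, labels = pts$label,
      visible = if (is.null(pts$visible)) TRUE else pts$visible,
      image_width = obj$image$width, image_height = obj$image$height,
      source_id = if (is.null(obj$source_id)) "" else obj$source_id
    )
  } else {
    hdr <- grep("^#", readLines(path, warn = FALSE), value = TRUE)
    field <- function(name) {
      ln <- grep(paste0("^#\\s*", name, ":"), hdr, value = TRUE)
      if (!length(ln)) return(NULL)
      trimws(sub(paste0("^#\\s*", name, ":"), "", ln[[1L]]))
    }
    w <- field("image_width")
    h <- field("image_height")
    if (is.null(w) || is.null(h)) {
      stopf("missing field image_width/image_height in CSV header")
    }
    tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    back_keypoints(
      x = tab$x, y = tab$y, labels = tab$label,
      visible = if (is.null(tab$visible)) TRUE else tab$visible,
      image_width = as.numeric(w), image_height = as.numeric(h),
      source_id = if (is.null(field("source_id"))) "" else field("source_id")
    )
  }
}

#' Write back keypoints to JSON or CSV
#'
#' @param kp a [back_keypoints] object.
#' @param path output file path.
#' @param format `"auto"` (by extension), `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @seealso [read_keypoints()] for the schema.
#' @export
write_keypoints <- function(kp, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  kp <- validate_back_keypoints(kp)
  if (format == "json") {
    obj <- list(
      image = list(width = kp$image_width, height = kp$image_height),
      source_id = kp$source_id,
      points = kp$points
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# image_width: %.15g", kp$image_width), con)
    writeLines(sprintf("# image_height: %.15g", kp$image_height), con)
    if (nzchar(kp$source_id)) {
      writeLines(sprintf("# source_id: %s", kp$source_id), con)
    }
    utils::write.csv(kp$points, con, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Object keypoint similarity (OKS)
#'
#' Exponential-distance agreement between predicted and reference keypoint
#' sets:
#' \deqn{OKS = \frac{\sum_n \exp(-d_n^2 / (2 s^2 k_n^2))\,
#'   \delta(v_n > 0)}{\sum_n \delta(v_n > 0)}}
#' where \eqn{d_n} is the Euclidean distance between the n-th predicted and
#' reference point, \eqn{s} a global scale in pixels, \eqn{k_n} a
#' per-point weight and \eqn{v_n} the visibility of the reference point.
#' The associated keypoint loss is `1 - OKS`.
#'
#' @param predicted,actual [back_keypoints] objects over the same labels.
#' @param scale scale `s` in pixels; defaults to the diagonal of the
#'   bounding box of the visible reference points.
#' @param weights per-point weights `k_n` (recycled to 7); all must be
#'   positive.
#' @return An object of class `oks` with elements `similarity` (in `[0,1]`),
#'   `loss`, `distances`, `scale`, `weights`, `visible`.
#' @examples
#' kp <- back_keypoints(
#'   x = c(160, 150, 145, 152, 160, 90, 230),
#'   y = c(40, 140, 240, 340, 440, 120, 120),
#'   image_width = 320, image_height = 480
#' )
#' oks(kp, kp)$similarity # exact match: 1
#' @export
oks <- function(predicted, actual, scale = NULL, weights = 1) {
  predicted <- validate_back_keypoints(predicted)
  actual <- validate_back_keypoints(actual)
  k <- rep_len(as.numeric(weights), length(keypoint_labels))
  if (any(k <= 0)) stopf("weights must be positive")
  v <- actual$points$visible
  if (!any(v)) stopf("undefined metric: no visible keypoints")
  d <- sqrt((predicted$points$x - actual$points$x)^2 +
              (predicted$points$y - actual$points$y)^2)
  if (is.null(scale)) {
    ax <- actual$points$x[v]
    ay <- actual$points$y[v]
    scale <- sqrt(diff(range(ax))^2 + diff(range(ay))^2)
  }
  if (!is_number(scale) || scale <= 0) stopf("scale must be a positive number")
  terms <- exp(-d^2 / (2 * scale^2 * k^2))
  sim <- sum(terms[v]) / sum(v)
  structure(
    list(
      similarity = sim, loss = 1 - sim, distances = d,
      scale = scale, weights = k, visible = v
    ),
    class = "oks"
  )
}

#' @export
print.oks <- function(x, ...) {
  cat(sprintf(
    "OKS = %.6f (loss %.6f), scale %.2f px, %d visible points\n",
    x$similarity, x$loss, x$scale, sum(x$visible)
  ))
  invisible(x)
}
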