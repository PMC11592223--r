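# shared fixtures and independent oracles, built in code

# a hand-positioned valid keypoint set
make_kp <- function(x = c(160, 150, 145, 152, 160, 90, 230),
                    y = c(40, 140, 240, 340, 440, 120, 120),
                    visible = TRUE, w = 320, h = 480) {
  back_keypoints(x = x, y = y, visible = visible,
                 image_width = w, image_height = h, source_id = "fixture")
}

# independent nested-loop gradient-magnitude oracle with replicate borders
conv_magnitude_oracle <- function(img, kx, ky, origin) {
  h <- nrow(img)
  w <- ncol(img)
  at <- function(i, j) img[min(max(i, 1L), h), min(max(j, 1L), w)]
  S <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      dx <- 0
      dy <- 0
      for (a in seq_len(nrow(kx))) {
        for (b in seq_len(ncol(kx))) {
          px <- at(i + a - origin[1L], j + b - origin[2L])
          dx <- dx + kx[a, b] * px
          dy <- dy + ky[a, b] * px
        }
      }
      S[i, j] <- sqrt(dx^2 + dy^2)
    }
  }
  S
}

# analytic-phase cosine whose maxima keep clear margins from both signal
# ends (AMPD cannot see maxima inside its boundary blind zone)
margin_cosine <- function(N, periods) {
  P <- N / periods
  n_max <- floor(periods - 0.2)
  a <- (N - (n_max - 1) * P) / 2
  list(
    x = cos(2 * pi * (seq_len(N) - a) / P),
    maxima = round(a + P * (0:(n_max - 1))),
    period = P
  )
}

expect_error_message <- function(expr, pattern) {
  expect_error(expr, regexp = pattern, fixed = FALSE)
}
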