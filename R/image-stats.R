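# Image-pair statistics used to explain cross-image variance in
# discrimination performance: the area of the changed region (critical
# object) from an RGB difference mask, which grid patch contains most of
# it, and the Weibull scale of the image's gradient-magnitude (contrast)
# distribution — higher in cluttered scenes.
#
# Images are plain numeric arrays, H x W x 3 (or H x W grayscale), on the
# 0-255 8-bit scale. `read_image_png()` loads a PNG into this form when the
# `png` package is available; fixtures are generated in code.

#' Changed-region ("critical object") area proportion
#'
#' Flags a pixel as changed when the absolute RGB difference between the
#' two images exceeds `threshold` (default 10 on the 0-255 scale), and
#' returns the flagged fraction of all pixels. The per-pixel difference is
#' aggregated across channels with `max` by default (a pixel changes if any
#' channel does); `"mean"` averages the three channel differences instead.
#'
#' @param img_a,img_b numeric arrays of identical dimensions, 0-255 scale.
#' @param threshold difference threshold; strictly exceeded to flag.
#' @param aggregate `"max"` (default) or `"mean"` across channels.
#' @return fraction of pixels flagged, in `[0, 1]`.
#' @export
object_size <- function(img_a, img_b, threshold = 10,
                        aggregate = c("max", "mean")) {
  mask <- diff_mask(img_a, img_b, threshold, aggregate)
  mean(mask)
}

#' Binary change mask between two images
#'
#' @inheritParams object_size
#' @return logical H x W matrix, `TRUE` where the images differ by more
#'   than `threshold`.
#' @export
diff_mask <- function(img_a, img_b, threshold = 10,
                      aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  if (!identical(dim(img_a), dim(img_b))) {
    stop("images must have identical dimensions", call. = FALSE)
  }
  d <- abs(img_a - img_b)
  if (length(dim(d)) == 3L) {
    d <- if (aggregate == "max") apply(d, c(1, 2), max) else apply(d, c(1, 2), mean)
  }
  d > threshold
}

#' Grid location of the critical object
#'
#' The 3x3 grid patch containing the largest number of changed pixels
#' (ties broken toward the lowest location number).
#'
#' @inheritParams object_size
#' @return integer location 1..9.
#' @export
critical_object_patch <- function(img_a, img_b, threshold = 10,
                                  aggregate = c("max", "mean")) {
  mask <- diff_mask(img_a, img_b, threshold, aggregate)
  if (!any(mask)) {
    stop("no changed pixels above threshold: cannot locate a critical object",
         call. = FALSE)
  }
  counts <- vapply(split_grid(mask * 1), sum, numeric(1))
  unname(which.max(counts)) # first maximum = lowest location number
}

#' Gradient magnitude of a grayscale image
#'
#' Converts RGB to luma (ITU-R 601 weights 0.299/0.587/0.114) and filters
#' with separable Gaussian-derivative kernels at scale `filter_scale`
#' (sigma in pixels), or with 3x3 Sobel kernels. Border handling is
#' replicate-padding.
#'
#' @param img numeric array, H x W or H x W x 3, 0-255 scale.
#' @param filter_scale Gaussian sigma in pixels (ignored for Sobel).
#' @param method `"gaussian"` (default) or `"sobel"`.
#' @return H x W matrix of gradient magnitudes.
#' @export
gradient_magnitude <- function(img, filter_scale = 1,
                               method = c("gaussian", "sobel")) {
  method <- match.arg(method)
  g <- to_gray(img)
  if (method == "sobel") {
    kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
    gx <- .conv2(g, kx)
    gy <- .conv2(g, t(kx))
  } else {
    s <- filter_scale
    r <- max(1L, ceiling(3 * s))
    t <- (-r):r
    gauss <- exp(-t^2 / (2 * s^2)); gauss <- gauss / sum(gauss)
    dgauss <- -t / s^2 * exp(-t^2 / (2 * s^2))
    # normalize so the derivative kernel has unit response to a ramp
    dgauss <- dgauss / sum(-t * dgauss)
    gx <- .sepconv(g, gauss, dgauss)  # d/dx: derivative along columns
    gy <- .sepconv(g, dgauss, gauss)  # d/dy: derivative along rows
  }
  sqrt(gx^2 + gy^2)
}

#' @rdname gradient_magnitude
#' @export
to_gray <- function(img) {
  if (length(dim(img)) == 3L) {
    0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  } else {
    img
  }
}

# Separable convolution with replicate padding: kr applied along rows
# (vertical), kc along columns (horizontal).
.sepconv <- function(m, kr, kc) {
  m <- .conv1(m, kr, along = 1L)
  .conv1(m, kc, along = 2L)
}

.conv1 <- function(m, k, along) {
  r <- (length(k) - 1L) %/% 2L
  if (along == 2L) return(t(.conv1(t(m), k, along = 1L)))
  n <- nrow(m)
  pad_idx <- c(rep(1L, r), seq_len(n), rep(n, r))
  mp <- m[pad_idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    out <- out + k[j] * mp[j:(j + n - 1L), , drop = FALSE]
  }
  out
}

.conv2 <- function(m, k) {
  # small non-separable kernel (Sobel): row-by-row shifts
  kr <- nrow(k); kc <- ncol(k)
  rr <- (kr - 1L) %/% 2L; rc <- (kc - 1L) %/% 2L
  n <- nrow(m); p <- ncol(m)
  mp <- m[c(rep(1L, rr), seq_len(n), rep(n, rr)),
          c(rep(1L, rc), seq_len(p), rep(p, rc)), drop = FALSE]
  out <- matrix(0, n, p)
  for (i in seq_len(kr)) for (j in seq_len(kc)) {
    out <- out + k[i, j] * mp[i:(i + n - 1L), j:(j + p - 1L), drop = FALSE]
  }
  out
}

#' Maximum-likelihood fit of a two-parameter Weibull
#'
#' Profile-likelihood MLE on strictly positive samples: the shape gamma
#' solves a one-dimensional score equation (bracketed and solved with
#' `uniroot`), and the scale beta is then `mean(x^gamma)^(1/gamma)`.
#'
#' @param x positive numeric samples.
#' @return list with `scale` (beta) and `shape` (gamma).
#' @export
weibull_mle <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 10L) stop("need at least 10 finite samples", call. = FALSE)
  if (any(x <= 0)) stop("Weibull support is strictly positive", call. = FALSE)
  lx <- log(x)
  mlx <- mean(lx)
  score <- function(k) {
    xk <- x^k
    sum(xk * lx) / sum(xk) - 1 / k - mlx
  }
  lo <- 1e-3; hi <- 1
  while (score(hi) < 0 && hi < 1e3) hi <- hi * 2
  k <- stats::uniroot(score, c(lo, hi), tol = 1e-10)$root
  beta <- mean(x^k)^(1 / k)
  list(scale = beta, shape = k)
}

#' Weibull contrast scale of an image
#'
#' Fits a two-parameter Weibull by maximum likelihood to the strictly
#' positive gradient magnitudes of the image; the fitted scale beta indexes
#' scene clutter (higher = more cluttered), the shape gamma its spread.
#'
#' @inheritParams gradient_magnitude
#' @param min_samples minimum number of positive gradient samples required.
#' @return list with `scale`, `shape`, and `n` (samples used).
#' @export
weibull_scale <- function(img, filter_scale = 1,
                          method = c("gaussian", "sobel"),
                          min_samples = 100L) {
  gm <- gradient_magnitude(img, filter_scale, method)
  v <- gm[gm > 0]
  if (length(v) < min_samples) {
    stop("degenerate input: too few non-zero gradient magnitudes", call. = FALSE)
  }
  fit <- weibull_mle(v)
  fit$n <- length(v)
  fit
}

#' Generate a synthetic image pair with a planted change
#'
#' Builds two H x W x 3 images that are identical except inside
#' `object_rect`, where every channel of image B is shifted by `delta`
#' (clipped to 0-255). The background is a seeded texture: `"smooth"` is
#' heavily blurred low-contrast noise, `"cluttered"` is high-frequency
#' high-contrast noise — the cluttered preset yields a larger fitted
#' Weibull scale. Stands in for a real changed-scene photograph pair;
#' ground truth (changed-area proportion, critical patch) is returned.
#'
#' @param canvas_size integer: images are `canvas_size` x `canvas_size`.
#' @param object_rect integer vector `c(row0, col0, height, width)` (1-based
#'   top-left corner), wholly inside the canvas.
#' @param delta channel shift applied inside the rectangle (0-255 scale).
#' @param texture_seed integer seed for the background.
#' @param preset `"smooth"` or `"cluttered"`.
#' @return list: `img_a`, `img_b`, `object_proportion`,
#'   `critical_location`, `object_rect`.
#' @export
make_fixture_pair <- function(canvas_size = 120L,
                              object_rect = c(10L, 10L, 30L, 30L),
                              delta = 50, texture_seed = 1L,
                              preset = c("smooth", "cluttered")) {
  preset <- match.arg(preset)
  n <- as.integer(canvas_size)
  r0 <- object_rect[1]; c0 <- object_rect[2]
  hh <- object_rect[3]; ww <- object_rect[4]
  if (r0 < 1 || c0 < 1 || r0 + hh - 1L > n || c0 + ww - 1L > n) {
    stop("`object_rect` must lie wholly inside the canvas", call. = FALSE)
  }
  rng <- .substream(texture_seed)
  base <- matrix(.rng_runif(rng, n * n), n, n)
  if (preset == "smooth") {
    s <- 6
    t <- (-ceiling(3 * s)):ceiling(3 * s)
    k <- exp(-t^2 / (2 * s^2)); k <- k / sum(k)
    base <- .sepconv(base, k, k)
    tex <- 110 + 40 * (base - mean(base)) / stats::sd(base)
  } else {
    tex <- 127 + 90 * (base - 0.5) * 2
  }
  tex <- pmin(pmax(tex, 0), 255)
  img_a <- array(rep(tex, 3L), dim = c(n, n, 3L))
  img_b <- img_a
  ri <- r0:(r0 + hh - 1L); ci <- c0:(c0 + ww - 1L)
  for (ch in 1:3) {
    img_b[ri, ci, ch] <- pmin(pmax(img_b[ri, ci, ch] + delta, 0), 255)
  }
  mask <- matrix(FALSE, n, n); mask[ri, ci] <- TRUE
  counts <- vapply(split_grid(mask * 1), sum, numeric(1))
  list(img_a = img_a, img_b = img_b,
       object_proportion = mean(mask),
       critical_location = unname(which.max(counts)),
       object_rect = object_rect)
}

#' Read a PNG image into a 0-255 array
#'
#' Thin wrapper over `png::readPNG` (drops any alpha channel, rescales to
#' the 0-255 scale used throughout). Requires the `png` package.
#'
#' @param path path to a PNG file.
#' @return numeric array, H x W x 3 or H x W, values 0-255.
#' @export
read_image_png <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("reading PNG files requires the `png` package", call. = FALSE)
  }
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L && dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]
  a * 255
}

#' Per-pair image statistics table
#'
#' Convenience wrapper combining [object_size()], [critical_object_patch()]
#' and [weibull_scale()] for one congruent/incongruent image pair.
#'
#' @param pair_id identifier.
#' @param img_a,img_b the two images of the pair.
#' @param threshold RGB difference threshold.
#' @param filter_scale gradient filter sigma in pixels.
#' @return one-row data.frame: `pair_id`, `object_size`, `log_object_size`,
#'   `critical_location`, `weibull_scale_a/b`, `weibull_shape_a/b`.
#' @export
image_pair_stats <- function(pair_id, img_a, img_b, threshold = 10,
                             filter_scale = 1) {
  os <- object_size(img_a, img_b, threshold)
  loc <- critical_object_patch(img_a, img_b, threshold)
  wa <- weibull_scale(img_a, filter_scale)
  wb <- weibull_scale(img_b, filter_scale)
  data.frame(
    pair_id = pair_id,
    object_size = os,
    log_object_size = if (os > 0) log(os) else NA_real_,
    critical_location = loc,
    weibull_scale_a = wa$scale, weibull_shape_a = wa$shape,
    weibull_scale_b = wb$scale, weibull_shape_b = wb$shape,
    stringsAsFactors = FALSE
  )
}
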