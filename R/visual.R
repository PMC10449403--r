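# Visual-information metrics: edge density, color entropy, Gist entropy.

# 2-D correlation with replicate border padding ("same" output size).
conv2_same <- function(x, k) {
  kr <- nrow(k); kc <- ncol(k)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1)
  pr <- (kr - 1) / 2; pc <- (kc - 1) / 2
  nr <- nrow(x); nc <- ncol(x)
  xp <- x[c(rep(1, pr), seq_len(nr), rep(nr, pr)),
          c(rep(1, pc), seq_len(nc), rep(nc, pc)), drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      if (k[i, j] != 0) {
        out <- out + k[i, j] * xp[i:(i + nr - 1), j:(j + nc - 1)]
      }
    }
  }
  out
}

gaussian_kernel <- function(size, sigma) {
  r <- (size - 1) / 2
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  g <- g / sum(g)
  outer(g, g)
}

# Shift a matrix by (di, dj), zero-filling vacated cells.
shift_mat <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  ri <- max(1, 1 + di):min(nr, nr + di)
  ci <- max(1, 1 + dj):min(nc, nc + dj)
  out[ri, ci] <- m[ri - di, ci - dj]
  out
}

#' Edge density of a scene image
#'
#' Counts edge pixels found by a Canny detector: grayscale conversion (ITU-R
#' 601 luminance), Gaussian blur with a `blur_kernel x blur_kernel` kernel,
#' Sobel gradients, non-maximum suppression along the gradient direction, and
#' hysteresis thresholding. Thresholds apply to the L2 gradient magnitude of
#' the 0-255 intensity image. The blur sigma follows the usual kernel-to-sigma
#' rule `0.3 * ((size - 1)/2 - 1) + 0.8`.
#'
#' @param img a [scene_image()].
#' @param blur_kernel odd kernel size in pixels for the Gaussian blur.
#' @param low_threshold,high_threshold hysteresis bounds on gradient magnitude.
#' @return number of edge-marked pixels (non-negative integer).
#' @export
compute_edge_density <- function(img, blur_kernel = 5, low_threshold = 30,
                                 high_threshold = 150) {
  assert_scene_image(img)
  if (blur_kernel %% 2 != 1 || blur_kernel < 1) {
    stop("'blur_kernel' must be a positive odd integer")
  }
  if (blur_kernel > min(img$height, img$width)) {
    stop("blur kernel larger than image")
  }
  if (low_threshold < 0 || low_threshold > high_threshold) {
    stop("need 0 <= low_threshold <= high_threshold")
  }
  g <- gray_matrix(img)
  sigma <- 0.3 * ((blur_kernel - 1) / 2 - 1) + 0.8
  g <- conv2_same(g, gaussian_kernel(blur_kernel, sigma))

  # Sobel: gx along columns (x), gy along rows (y)
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- conv2_same(g, kx)
  gy <- conv2_same(g, t(kx))
  mag <- sqrt(gx^2 + gy^2)

  # Non-maximum suppression: quantize gradient direction into 4 sectors and
  # keep pixels that are local maxima along that direction (">=" on one side,
  # ">" on the other, so step edges thin to one pixel).
  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- ((ang + pi / 8) %/% (pi / 4)) %% 4 # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  n1 <- matrix(0, nrow(mag), ncol(mag)); n2 <- n1
  offs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  for (s in 0:3) {
    o <- offs[[s + 1]]
    sel <- sector == s
    n1[sel] <- shift_mat(mag, o[1], o[2])[sel]
    n2[sel] <- shift_mat(mag, -o[1], -o[2])[sel]
  }
  keep <- mag >= n1 & mag > n2

  strong <- keep & mag >= high_threshold
  weak <- keep & mag >= low_threshold & !strong
  # Hysteresis: grow strong edges into 8-connected weak pixels to fixpoint.
  if (any(weak) && any(strong)) {
    repeat {
      nb <- shift_mat(strong, 1, 0) | shift_mat(strong, -1, 0) |
        shift_mat(strong, 0, 1) | shift_mat(strong, 0, -1) |
        shift_mat(strong, 1, 1) | shift_mat(strong, 1, -1) |
        shift_mat(strong, -1, 1) | shift_mat(strong, -1, -1)
      grown <- strong | (weak & nb)
      if (identical(grown, strong)) break
      strong <- grown
    }
  }
  sum(strong)
}

#' Chromatic histogram entropy of a scene image
#'
#' Converts the image from sRGB to CIELAB (D65 white point), bins the A* and
#' B* chromatic channels into a `bins_per_axis x bins_per_axis` joint
#' histogram over a fixed axis range, normalizes the histogram to a
#' probability distribution, and returns its Shannon entropy in bits. Values
#' outside the axis range are clipped into the end bins so the binning is
#' image-independent.
#'
#' @param img a [scene_image()].
#' @param bins_per_axis number of bins along each chromatic axis (>= 2).
#' @param ab_range fixed range `c(lo, hi)` for both A* and B*.
#' @return entropy in bits, in `[0, log2(bins_per_axis^2)]`.
#' @export
compute_color_entropy <- function(img, bins_per_axis = 20,
                                  ab_range = c(-110, 110)) {
  assert_scene_image(img)
  if (bins_per_axis < 2) stop("'bins_per_axis' must be >= 2")
  p <- img$pixels / 255
  rgb <- cbind(as.vector(p[, , 1]), as.vector(p[, , 2]), as.vector(p[, , 3]))
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  bin_of <- function(v) {
    b <- floor((v - ab_range[1]) / diff(ab_range) * bins_per_axis) + 1
    pmin(pmax(b, 1), bins_per_axis)
  }
  idx <- (bin_of(lab[, 2]) - 1) * bins_per_axis + bin_of(lab[, 3])
  counts <- tabulate(idx, nbins = bins_per_axis^2)
  shannon_entropy(normalize_prob(counts, "color histogram"))
}

# Gabor transfer functions in the frequency domain (one-sided, analytic),
# following the standard spatial-envelope construction: for scale s with K
# orientations, G = exp(-10*0.35*(f/f0 - 1)^2 - 2*(K^2/64)*pi*t^2) where f is
# the normalized radial frequency, f0 = 0.3/1.85^(s-1), and t is the angular
# distance to the filter orientation.
gist_filter_bank <- function(n, n_scales, orientations_per_scale) {
  fx <- matrix(rep(fft_freqs(n), each = n), n, n) # along columns (x)
  fy <- matrix(rep(fft_freqs(n), times = n), n, n) # along rows (y)
  fr <- sqrt(fx^2 + fy^2)
  th <- atan2(fy, fx)
  filters <- list(); meta <- list(); k <- 0
  for (s in seq_len(n_scales)) {
    kk <- orientations_per_scale[s]
    f0 <- 0.3 / 1.85^(s - 1)
    for (o in seq_len(kk)) {
      th0 <- pi * (o - 1) / kk
      dt <- th - th0
      dt <- atan2(sin(dt), cos(dt)) # wrap to (-pi, pi]: one-sided in frequency
      g <- exp(-10 * 0.35 * (fr / f0 - 1)^2 - 2 * (kk^2 / 64) * pi * dt^2)
      g[1, 1] <- 0 # kill DC
      k <- k + 1
      filters[[k]] <- g
      meta[[k]] <- list(scale = s, orientation = o, theta = th0, f0 = f0)
    }
  }
  list(filters = filters, meta = meta)
}

fft_freqs <- function(n) {
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) # standard DFT frequency order
  k / n
}

block_means <- function(m, g) {
  n <- nrow(m); b <- n / g
  idx <- rep(seq_len(g), each = b)
  t(rowsum(t(rowsum(m, idx)), idx)) / (b * b)
}

#' Gist descriptor of a scene image
#'
#' Multi-scale oriented filter-bank energy summary: the grayscale image is
#' resized to `resize_to x resize_to`, filtered in the frequency domain with
#' Gabor-type filters (`n_scales` scales with `orientations_per_scale`
#' orientations each), and per-filter energy magnitudes are averaged within
#' each cell of a `grid x grid` spatial grid. The concatenated vector (length
#' `sum(orientations_per_scale) * grid^2`, 1152 by default) is normalized to
#' sum to 1 so it can be treated as a probability distribution.
#'
#' @param img a [scene_image()].
#' @param n_scales number of spatial scales.
#' @param orientations_per_scale integer vector, orientations at each scale.
#' @param grid spatial pooling grid size per side.
#' @param resize_to internal square size (power of two) used for filtering.
#' @return numeric vector summing to 1; names encode `s<scale>_o<orient>_c<cell>`.
#' @export
compute_gist <- function(img, n_scales = 3, orientations_per_scale = c(8, 6, 4),
                         grid = 8, resize_to = 256) {
  assert_scene_image(img)
  if (length(orientations_per_scale) != n_scales) {
    stop("'orientations_per_scale' must have one entry per scale")
  }
  if (resize_to %% grid != 0) stop("'grid' must divide 'resize_to'")
  g <- gray_matrix(img) / 255
  if (nrow(g) != resize_to || ncol(g) != resize_to) {
    # EBImage works in (x, y); transpose in and out
    im <- EBImage::Image(t(g))
    g <- t(EBImage::imageData(EBImage::resize(im, w = resize_to, h = resize_to)))
  }
  bank <- gist_filter_bank(resize_to, n_scales, orientations_per_scale)
  fg <- stats::fft(g)
  out <- numeric(0); nms <- character(0)
  for (k in seq_along(bank$filters)) {
    resp <- Mod(stats::fft(fg * bank$filters[[k]], inverse = TRUE)) / resize_to^2
    cells <- block_means(resp, grid)
    m <- bank$meta[[k]]
    out <- c(out, as.vector(cells))
    nms <- c(nms, sprintf("s%d_o%d_c%02d", m$scale, m$orientation,
                          seq_len(grid^2)))
  }
  names(out) <- nms
  normalize_prob(out, "Gist energy (constant image?)")
}

#' Entropy of a Gist descriptor
#'
#' Shannon entropy (bits) of the normalized Gist energy vector. With the
#' default 1152-dimensional descriptor the result lies in `[0, log2(1152)]`.
#'
#' @param g a normalized Gist vector, as from [compute_gist()].
#' @inheritParams shannon_entropy
#' @return entropy in bits.
#' @export
compute_gist_entropy <- function(g, tol = 1e-9) shannon_entropy(g, tol = tol)

#' Visual feature table for a set of images
#'
#' Applies [compute_edge_density()], [compute_color_entropy()] and
#' [compute_gist()]/[compute_gist_entropy()] to every image and assembles the
#' per-image visual feature table.
#'
#' @param images a list of [scene_image()] objects (as from [read_images()]).
#' @param blur_kernel,low_threshold,high_threshold passed to [compute_edge_density()].
#' @param bins_per_axis passed to [compute_color_entropy()].
#' @param n_scales,orientations_per_scale,grid passed to [compute_gist()].
#' @return data.frame with columns `image_id`, `edge_density`,
#'   `color_entropy`, `gist_entropy`.
#' @export
compute_visual_features <- function(images, blur_kernel = 5,
                                    low_threshold = 30, high_threshold = 150,
                                    bins_per_axis = 20, n_scales = 3,
                                    orientations_per_scale = c(8, 6, 4),
                                    grid = 8) {
  stopifnot(length(images) >= 1)
  rows <- lapply(images, function(img) {
    assert_scene_image(img)
    data.frame(
      image_id = img$image_id,
      edge_density = compute_edge_density(img, blur_kernel, low_threshold,
                                          high_threshold),
      color_entropy = compute_color_entropy(img, bins_per_axis),
      gist_entropy = compute_gist_entropy(
        compute_gist(img, n_scales, orientations_per_scale, grid)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
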