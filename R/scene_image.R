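#' Construct a scene image
#'
#' A `scene_image` is an 8-bit RGB raster with an identifier: the unit on
#' which the visual-information metrics operate. Pixel values are stored as a
#' `height x width x 3` numeric array on the 0-255 scale.
#'
#' @param pixels numeric array `height x width x 3` with values in `[0, 255]`,
#'   or in `[0, 1]` (auto-rescaled when the maximum is <= 1).
#' @param image_id character scalar identifying the image.
#' @return an object of class `scene_image` with fields `image_id`, `pixels`,
#'   `height`, `width`.
#' @export
scene_image <- function(pixels, image_id) {
  if (!is.character(image_id) || length(image_id) != 1 || is.na(image_id)) {
    stop("'image_id' must be a single character string")
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    stop("image '", image_id, "': pixels must be a height x width x 3 RGB array")
  }
  if (any(!is.finite(pixels))) {
    stop("image '", image_id, "': pixels contain non-finite values")
  }
  if (max(pixels) <= 1 && min(pixels) >= 0) pixels <- pixels * 255
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("image '", image_id, "': channel values must lie in [0, 255]")
  }
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  if (h < 32 || w < 32) {
    stop("image '", image_id, "': minimum supported size is 32 x 32 (got ",
         h, " x ", w, ")")
  }
  structure(list(image_id = image_id, pixels = pixels, height = h, width = w),
            class = "scene_image")
}

#' @export
print.scene_image <- function(x, ...) {
  cat("<scene_image> ", x$image_id, ": ", x$height, " x ", x$width,
      " RGB\n", sep = "")
  invisible(x)
}

is_scene_image <- function(x) inherits(x, "scene_image")

assert_scene_image <- function(img) {
  if (!is_scene_image(img)) stop("expected a 'scene_image' (see scene_image())")
  invisible(img)
}

# ITU-R 601 luminance, 0-255 scale.
gray_matrix <- function(img) {
  p <- img$pixels
  0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3]
}

#' Read scene images from a directory or manifest
#'
#' Either every PNG/JPEG file in `dir` (image ids are file names without
#' extension) or the files listed in a manifest CSV with columns
#' `image_id,path` (paths relative to the manifest's directory or absolute).
#'
#' @param dir directory containing images, or `NULL` when `manifest` is given.
#' @param manifest path to a manifest CSV, or `NULL`.
#' @return named list of [scene_image()] objects.
#' @export
read_images <- function(dir = NULL, manifest = NULL) {
  if (is.null(dir) == is.null(manifest)) {
    stop("supply exactly one of 'dir' or 'manifest'")
  }
  if (!is.null(manifest)) {
    if (!file.exists(manifest)) stop("manifest file not found: ", manifest)
    tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    if (!all(c("image_id", "path") %in% names(tab))) {
      stop("manifest must have columns 'image_id' and 'path'")
    }
    paths <- ifelse(file.exists(tab$path), tab$path,
                    file.path(dirname(manifest), tab$path))
    ids <- as.character(tab$image_id)
  } else {
    if (!dir.exists(dir)) stop("image directory not found: ", dir)
    paths <- list.files(dir, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(paths) == 0) stop("no PNG/JPEG files found in ", dir)
    ids <- sub("\\.[^.]+$", "", basename(paths))
  }
  if (anyDuplicated(ids)) stop("duplicate image_id in image set")
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    if (!file.exists(paths[i])) stop("image file not found: ", paths[i])
    out[[i]] <- load_scene_image(paths[i], ids[i])
  }
  names(out) <- ids
  out
}

load_scene_image <- function(path, image_id) {
  im <- EBImage::readImage(path)
  d <- EBImage::imageData(im)
  if (length(dim(d)) == 2) d <- array(rep(d, 3), dim = c(dim(d), 3))
  if (dim(d)[3] > 3) d <- d[, , 1:3, drop = FALSE] # drop alpha
  # EBImage stores x (width) in dim 1; transpose to row = y, col = x
  px <- aperm(d, c(2, 1, 3))
  scene_image(px * 255, image_id)
}

#' Write a scene image as PNG
#'
#' @param img a [scene_image()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  assert_scene_image(img)
  d <- aperm(img$pixels / 255, c(2, 1, 3))
  EBImage::writeImage(EBImage::Image(d, colormode = "Color"), path)
  invisible(path)
}
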