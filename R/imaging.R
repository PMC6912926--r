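# Cohort I/O and region-of-interest handling. ROIs follow the metadata
# convention: (x, y, w, h) in pixels, 0-based, half-open, x across width.

#' Load a cohort from a metadata CSV and an image directory
#'
#' Reads one fish per metadata row. PNG and TIFF images are supported.
#' Rows whose image file is missing or unreadable are dropped with a single
#' warning; the number dropped is kept in the `n_dropped` attribute.
#'
#' @param metadata_path Path to a CSV with columns `id`, `image_path`,
#'   `group`, `true_sex`, `body_weight_g`, `total_length_mm`, `roi_x`,
#'   `roi_y`, `roi_w`, `roi_h`.
#' @param image_root Directory against which relative `image_path`s are
#'   resolved; defaults to the metadata file's directory.
#' @return A `fish_cohort` tibble (images as 8-bit integer arrays).
#' @export
load_cohort <- function(metadata_path, image_root = dirname(metadata_path)) {
  if (!file.exists(metadata_path)) {
    stop("metadata file not found: ", metadata_path, call. = FALSE)
  }
  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  required <- c("id", "image_path", "group", "true_sex", "body_weight_g",
                "total_length_mm", "roi_x", "roi_y", "roi_w", "roi_h")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  images <- vector("list", nrow(meta))
  ok <- logical(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    path <- meta$image_path[i]
    if (!grepl("^(/|[A-Za-z]:)", path)) path <- file.path(image_root, path)
    images[i] <- list(tryCatch(read_fish_image(path), error = function(e) NULL))
    ok[i] <- !is.null(images[[i]])
  }
  n_dropped <- sum(!ok)
  if (n_dropped == nrow(meta)) {
    stop("no readable images in cohort", call. = FALSE)
  }
  if (n_dropped > 0) {
    warning(sprintf("dropped %d of %d samples with unreadable images",
                    n_dropped, nrow(meta)), call. = FALSE)
  }
  cohort <- tibble::as_tibble(meta[ok, , drop = FALSE])
  cohort$image <- images[ok]
  cohort <- cohort[, c("id", "image", setdiff(names(cohort), c("id", "image")))]
  class(cohort) <- c("fish_cohort", class(cohort))
  attr(cohort, "n_dropped") <- n_dropped
  cohort
}

#' Read a single RGB image as an 8-bit integer array
#'
#' @param path A `.png`, `.tif` or `.tiff` file.
#' @return `H x W x 3` integer array in `[0, 255]` (alpha dropped).
#' @export
read_fish_image <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("the 'tiff' package is required to read TIFF images", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  }
  if (dim(img)[3] >= 3L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] != 3L) stop("image is not RGB: ", path, call. = FALSE)
  quantize_rgb(img)
}

#' Crop the caudal-fin region of interest
#'
#' @param image `H x W x 3` array.
#' @param roi Numeric `(x, y, w, h)`: 0-based, half-open pixel rectangle,
#'   `x` across width.
#' @return The `(h, w, 3)` sub-array.
#' @examples
#' img <- array(0L, c(8, 10, 3))
#' dim(crop_fin(img, c(2, 1, 5, 4)))
#' @export
crop_fin <- function(image, roi) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stop("`image` must be H x W x 3", call. = FALSE)
  roi <- as.numeric(roi)
  if (length(roi) != 4L) stop("`roi` must be (x, y, w, h)", call. = FALSE)
  x <- roi[1]; y <- roi[2]; w <- roi[3]; h <- roi[4]
  if (w <= 0 || h <= 0 || x < 0 || y < 0 || x + w > d[2] || y + h > d[1]) {
    stop(sprintf("ROI (x=%g, y=%g, w=%g, h=%g) outside image bounds %d x %d",
                 x, y, w, h, d[1], d[2]), call. = FALSE)
  }
  image[(y + 1):(y + h), (x + 1):(x + w), , drop = FALSE]
}

#' Crop every fin ROI in a cohort
#'
#' @param cohort A `fish_cohort`.
#' @return The cohort tibble with a `fin` list-column of cropped RGB arrays.
#' @export
crop_fins <- function(cohort) {
  stopifnot(inherits(cohort, "fish_cohort"))
  cohort$fin <- purrr::pmap(
    list(cohort$image, cohort$roi_x, cohort$roi_y, cohort$roi_w, cohort$roi_h),
    function(img, x, y, w, h) crop_fin(img, c(x, y, w, h))
  )
  cohort
}

#' Bilinear image resize
#'
#' Used by the CNN route to bring whole-body images to the network input
#' size; the histogram route never resizes (normalized histograms are
#' area-invariant).
#'
#' @param image `H x W x 3` numeric array.
#' @param size Target `(height, width)`.
#' @return Resized double array.
#' @export
resize_image <- function(image, size) {
  d <- dim(image)
  h2 <- size[1]; w2 <- size[2]
  if (d[1] == h2 && d[2] == w2) return(image * 1.0)
  # sample source coordinates at target pixel centers
  sy <- (seq_len(h2) - 0.5) * d[1] / h2 + 0.5
  sx <- (seq_len(w2) - 0.5) * d[2] / w2 + 0.5
  y0 <- pmin(pmax(floor(sy), 1), d[1]); y1 <- pmin(y0 + 1, d[1])
  x0 <- pmin(pmax(floor(sx), 1), d[2]); x1 <- pmin(x0 + 1, d[2])
  wy <- pmin(pmax(sy - y0, 0), 1); wx <- pmin(pmax(sx - x0, 0), 1)
  out <- array(0, dim = c(h2, w2, d[3]))
  for (k in seq_len(d[3])) {
    ch <- image[, , k]
    a <- ch[y0, x0, drop = FALSE]; b <- ch[y0, x1, drop = FALSE]
    c2 <- ch[y1, x0, drop = FALSE]; d2 <- ch[y1, x1, drop = FALSE]
    top <- a * outer(rep(1, h2), 1 - wx) + b * outer(rep(1, h2), wx)
    bot <- c2 * outer(rep(1, h2), 1 - wx) + d2 * outer(rep(1, h2), wx)
    out[, , k] <- top * outer(1 - wy, rep(1, w2)) + bot * outer(wy, rep(1, w2))
  }
  out
}
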