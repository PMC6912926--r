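# Per-channel L*a*b* histogram features: the color distribution of the
# caudal fin, summarized as three fixed-edge frequency vectors and
# concatenated into the SVM feature vector.

.lab_channel_ranges <- list(L = c(0, 100), a = c(-128, 127), b = c(-128, 127))

#' Per-channel Lab color histogram
#'
#' Counts pixels into `bins` equal-width bins per channel over the fixed
#' ranges L* in `[0, 100]`, a* and b* in `[-128, 127]` (values outside are
#' clamped into the edge bins). Normalization divides each channel by the
#' pixel count, removing dependence on fin area.
#'
#' @param lab `H x W x 3` L*a*b* array, e.g. from [rgb_to_lab()].
#' @param bins Bins per channel (>= 2); default 64 gives a length-192
#'   feature.
#' @param normalize Divide counts by the pixel count (default `TRUE`).
#' @return A `lab_histogram`: list with `bins`, `normalized`, `edges`
#'   (per-channel boundaries), `counts` (`bins x 3` matrix) and `feature`
#'   (concatenated length-`3 * bins` named vector, L then a then b).
#' @examples
#' h <- lab_histogram(rgb_to_lab(array(200L, c(4, 4, 3))), bins = 8)
#' sum(h$feature)
#' @export
lab_histogram <- function(lab, bins = 64, normalize = TRUE) {
  d <- dim(lab)
  if (length(d) != 3L || d[3] != 3L) stop("`lab` must be H x W x 3", call. = FALSE)
  n_px <- prod(d[1:2])
  if (n_px == 0) stop("empty image", call. = FALSE)
  bins <- as.integer(bins)
  if (bins < 2L) stop("`bins` must be >= 2", call. = FALSE)
  edges <- lapply(.lab_channel_ranges, function(r) seq(r[1], r[2], length.out = bins + 1L))
  counts <- matrix(0, nrow = bins, ncol = 3L,
                   dimnames = list(NULL, c("L", "a", "b")))
  for (k in 1:3) {
    v <- pmin(pmax(c(lab[, , k]), .lab_channel_ranges[[k]][1]),
              .lab_channel_ranges[[k]][2])
    idx <- pmin(findInterval(v, edges[[k]], rightmost.closed = TRUE), bins)
    counts[, k] <- tabulate(idx, nbins = bins)
  }
  if (normalize) counts <- counts / n_px
  feature <- c(counts)
  names(feature) <- paste0(rep(c("L", "a", "b"), each = bins), rep(seq_len(bins), 3L))
  structure(list(bins = bins, normalized = normalize, edges = edges,
                 counts = counts, feature = feature, n_pixels = n_px),
            class = "lab_histogram")
}

#' Euclidean distance between two Lab histograms
#'
#' The L2 distance between concatenated feature vectors; the scalar the
#' kernel machine operates on.
#'
#' @param h1,h2 `lab_histogram` objects with identical bin count and
#'   normalization.
#' @return Nonnegative scalar; zero iff the histograms are equal.
#' @export
histogram_distance <- function(h1, h2) {
  stopifnot(inherits(h1, "lab_histogram"), inherits(h2, "lab_histogram"))
  if (h1$bins != h2$bins || h1$normalized != h2$normalized) {
    stop("histograms have mismatched bins or normalization", call. = FALSE)
  }
  sqrt(sum((h1$feature - h2$feature)^2))
}

#' Fin-color histogram feature matrix for a cohort
#'
#' Crops each fin ROI, converts it to L*a*b* and histograms it. This is the
#' data-frame-first entry to the color classification route.
#'
#' @param cohort A `fish_cohort`.
#' @param bins Bins per channel.
#' @param normalize Passed to [lab_histogram()].
#' @return A tibble: `id`, `group`, `true_sex`, and `3 * bins` feature
#'   columns (`L1...`, `a1...`, `b1...`), with the bin spec in attributes
#'   `bins`/`normalized`.
#' @export
fin_features <- function(cohort, bins = 64, normalize = TRUE) {
  stopifnot(inherits(cohort, "fish_cohort"))
  fins <- crop_fins(cohort)$fin
  feats <- purrr::map(fins, function(f) lab_histogram(rgb_to_lab(f), bins, normalize)$feature)
  mat <- do.call(rbind, feats)
  out <- dplyr::bind_cols(
    tibble::tibble(id = cohort$id, group = cohort$group, true_sex = cohort$true_sex),
    tibble::as_tibble(mat)
  )
  attr(out, "bins") <- as.integer(bins)
  attr(out, "normalized") <- normalize
  out
}

#' Write / read a feature matrix as CSV
#'
#' @param features Tibble from [fin_features()].
#' @param path CSV path.
#' @return `path` (write) or the feature tibble (read), invisibly for write.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  out
}

.feature_columns <- function(features) {
  grep("^[Lab][0-9]+$", names(features), value = TRUE)
}

.feature_matrix <- function(features) {
  cols <- .feature_columns(features)
  if (length(cols) == 0) stop("no histogram feature columns found", call. = FALSE)
  m <- as.matrix(features[, cols])
  rownames(m) <- features$id
  m
}
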