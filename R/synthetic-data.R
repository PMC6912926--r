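# Synthetic fish-image generator. Renders an ellipsoidal body plus a
# triangular caudal fin on a light background, composited in L*a*b* so the
# generated "truth" is in the same units the feature extractor measures.
# Sexual dichromatism enters through two separate cues: fin yellowness (b*)
# for the color route, and body depth/length ratio for the shape route
# (females rounder than males).

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions the downstream analyses assume:
#' males yellower than females in the caudal fin, treated males attenuated,
#' fin color coupled to body weight in males only, and cell means for body
#' weight and length of adult zebrafish under control (28 degrees C) and
#' embryonic heat treatment (35 degrees C).
#'
#' @param n_per_cell Fish per treatment-by-sex cell (balanced mode) or half
#'   the per-group total (ratio mode).
#' @param image_size Integer `(height, width)` in pixels, each at least 64.
#' @param fin_fraction Fraction of image width occupied by the caudal fin.
#' @param yellow_mean_male,yellow_mean_female Mean fin yellowness (Lab b*).
#' @param yellow_sd Between-individual SD of fin yellowness (Lab b*).
#' @param treatment_male_attenuation Subtractive b* shift applied to treated
#'   males' fin yellowness; the default produces roughly the one-in-six
#'   treated-male misclassification rate the color classifier shows.
#' @param size_color_slope_male Change in fin b* per gram of body weight,
#'   males only.
#' @param body_aspect_male,body_aspect_female Body depth/length ratio of the
#'   rendered ellipse (the shape cue; females rounder).
#' @param weight_means,length_means Named per-cell means
#'   (`control_M`, `treatment_M`, `control_F`, `treatment_F`) in g and mm.
#' @param weight_sd,length_sd Within-cell SDs (g, mm).
#' @param noise_sd Per-pixel Gaussian noise SD added in Lab units.
#' @param male_prob_treated,male_prob_control Male probabilities used in
#'   ratio mode; defaults are the observed proportions 0.798 and 0.502.
#' @param mode `"balanced"` (fixed per-cell counts, the default, for
#'   reproducible contingency tables) or `"ratio"` (Bernoulli sex draws).
#' @param seed Integer seed; the whole cohort is a pure function of the
#'   configuration.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_cell = 50,
                       image_size = c(96L, 96L),
                       fin_fraction = 0.25,
                       yellow_mean_male = 40,
                       yellow_mean_female = 16,
                       yellow_sd = 5,
                       treatment_male_attenuation = 7,
                       size_color_slope_male = 60,
                       body_aspect_male = 0.30,
                       body_aspect_female = 0.42,
                       weight_means = c(control_M = 0.3582, treatment_M = 0.3965,
                                        control_F = 0.4321, treatment_F = 0.4357),
                       length_means = c(control_M = 34.9648, treatment_M = 35.2450,
                                        control_F = 34.8316, treatment_F = 35.7502),
                       weight_sd = 0.07,
                       length_sd = 2,
                       noise_sd = 8,
                       male_prob_treated = 0.798,
                       male_prob_control = 0.502,
                       mode = c("balanced", "ratio"),
                       seed = 1L) {
  cfg <- list(
    n_per_cell = as.integer(n_per_cell),
    image_size = as.integer(image_size),
    fin_fraction = fin_fraction,
    yellow_mean_male = yellow_mean_male,
    yellow_mean_female = yellow_mean_female,
    yellow_sd = yellow_sd,
    treatment_male_attenuation = treatment_male_attenuation,
    size_color_slope_male = size_color_slope_male,
    body_aspect_male = body_aspect_male,
    body_aspect_female = body_aspect_female,
    weight_means = weight_means,
    length_means = length_means,
    weight_sd = weight_sd,
    length_sd = length_sd,
    noise_sd = noise_sd,
    male_prob_treated = male_prob_treated,
    male_prob_control = male_prob_control,
    mode = match.arg(mode),
    seed = as.integer(seed)
  )
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.validate_sim_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid `%s`: %s", field, why), call. = FALSE)
  }
  if (is.na(cfg$n_per_cell) || cfg$n_per_cell <= 0L) fail("n_per_cell", "must be a positive count")
  if (length(cfg$image_size) != 2L || any(cfg$image_size < 64L)) {
    fail("image_size", "must be (height, width) with both components >= 64")
  }
  if (cfg$fin_fraction <= 0 || cfg$fin_fraction > 0.3) {
    fail("fin_fraction", "must be in (0, 0.3] so the fin fits in frame")
  }
  if (cfg$yellow_sd < 0) fail("yellow_sd", "must be >= 0")
  if (cfg$noise_sd < 0) fail("noise_sd", "must be >= 0")
  if (cfg$weight_sd < 0) fail("weight_sd", "must be >= 0")
  if (cfg$length_sd < 0) fail("length_sd", "must be >= 0")
  for (p in c("male_prob_treated", "male_prob_control")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) fail(p, "must be a probability in [0, 1]")
  }
  cells <- c("control_M", "treatment_M", "control_F", "treatment_F")
  for (m in c("weight_means", "length_means")) {
    if (!all(cells %in% names(cfg[[m]]))) {
      fail(m, paste("must be named with cells", paste(cells, collapse = ", ")))
    }
    if (any(cfg[[m]] <= 0)) fail(m, "cell means must be positive")
  }
  invisible(cfg)
}

# Fixed Lab paint colors; only fin b* varies between individuals.
.paint <- list(
  background = c(92, 0, 3),
  body       = c(55, 2, 12),
  fin_L      = 65,
  fin_a      = 5
)

# Scene geometry in [0, 1] image coordinates (x across width, y down height).
.scene_geometry <- function(h, w, fin_fraction, aspect) {
  cx <- 0.40 * w
  cy <- 0.50 * h
  ax <- 0.28 * w              # body semi-axis along the length
  ay <- aspect * ax           # body semi-axis along the depth
  x1 <- 0.68 * w              # fin base
  fl <- fin_fraction * w      # fin length
  fh <- 0.30 * h              # fin base height
  roi_x <- ceiling(x1)
  roi_w <- floor(fl / 2)
  roi_y <- ceiling(cy - fh / 4)
  roi_h <- floor(fh / 2) - 1L
  list(cx = cx, cy = cy, ax = ax, ay = ay, x1 = x1, fl = fl, fh = fh,
       roi = c(x = roi_x, y = roi_y, w = roi_w, h = roi_h))
}

# Render one fish: Lab composite -> optional pixel noise -> sRGB -> 8-bit.
.render_fish <- function(h, w, fin_fraction, aspect, fin_b, noise_sd) {
  g <- .scene_geometry(h, w, fin_fraction, aspect)
  xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)  # pixel centers, x
  ys <- matrix(rep(seq_len(h) - 0.5, times = w), h, w) # pixel centers, y
  body <- ((xs - g$cx) / g$ax)^2 + ((ys - g$cy) / g$ay)^2 <= 1
  tt <- (xs - g$x1) / g$fl
  fin <- tt >= 0 & tt <= 1 & abs(ys - g$cy) <= (g$fh / 2) * (1 - tt)
  lab <- array(rep(.paint$background, each = h * w), dim = c(h, w, 3))
  for (k in 1:3) {
    ch <- lab[, , k]
    ch[body] <- .paint$body[k]
    ch[fin] <- c(.paint$fin_L, .paint$fin_a, fin_b)[k]
    lab[, , k] <- ch
  }
  if (noise_sd > 0) {
    lab <- lab + array(stats::rnorm(h * w * 3, 0, noise_sd), dim = dim(lab))
  }
  img <- quantize_rgb(lab_to_rgb(lab))
  # truth in measurement units: the quantized round trip of the fin paint
  true_b <- rgb_to_lab(quantize_rgb(lab_to_rgb(c(.paint$fin_L, .paint$fin_a, fin_b))))[3]
  list(image = img, roi = g$roi, true_fin_b = true_b)
}

.cell_name <- function(group, sex) paste(group, sex, sep = "_")

#' Simulate a synthetic fish cohort
#'
#' Draws per-individual body weight, length and fin yellowness from the
#' configured treatment-by-sex cell distributions, renders one image per
#' fish, and returns everything as a tibble with the image as a list-column.
#' Identical configurations (including the seed) give identical cohorts.
#'
#' Fin yellowness for a male is
#' `yellow_mean_male - attenuation * treated + slope * (weight - cell mean)`
#' plus `Normal(0, yellow_sd)`; females use `yellow_mean_female` with no
#' size coupling. The recorded `true_fin_b` is the rendered fin paint after
#' 8-bit quantization, i.e. exactly what a noiseless measurement of the fin
#' region returns.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, images are written as PNG and
#'   a `metadata.csv` is written next to them (see [write_cohort()]).
#' @return A `fish_cohort` tibble with columns `id`, `image` (list of
#'   `H x W x 3` integer arrays), `group`, `true_sex`, `body_weight_g`,
#'   `total_length_mm`, `roi_x`, `roi_y`, `roi_w`, `roi_h` (0-based,
#'   half-open), `true_fin_b`, and `cell`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_per_cell = 2, seed = 7))
#' truth_table(cohort)
#' @export
simulate_cohort <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  .validate_sim_config(config)
  old_seed <- .hold_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(config$seed)

  groups <- c("control", "treatment")
  if (config$mode == "balanced") {
    cells <- expand.grid(sex = c("F", "M"), group = groups,
                         stringsAsFactors = FALSE)[, c("group", "sex")]
    plan <- cells[rep(seq_len(nrow(cells)), each = config$n_per_cell), ]
  } else {
    n_group <- 2L * config$n_per_cell
    plan <- do.call(rbind, lapply(groups, function(g) {
      p <- if (g == "treatment") config$male_prob_treated else config$male_prob_control
      data.frame(group = g,
                 sex = ifelse(stats::rbinom(n_group, 1L, p) == 1L, "M", "F"))
    }))
  }
  n <- nrow(plan)
  h <- config$image_size[1]
  w <- config$image_size[2]

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    group <- plan$group[i]
    sex <- plan$sex[i]
    cell <- .cell_name(group, sex)
    weight <- max(stats::rnorm(1, config$weight_means[[cell]], config$weight_sd), 0.05)
    len <- max(stats::rnorm(1, config$length_means[[cell]], config$length_sd), 5)
    base_b <- if (sex == "M") {
      config$yellow_mean_male -
        (group == "treatment") * config$treatment_male_attenuation +
        config$size_color_slope_male * (weight - config$weight_means[[cell]])
    } else {
      config$yellow_mean_female
    }
    fin_b <- base_b + stats::rnorm(1, 0, config$yellow_sd)
    aspect <- if (sex == "M") config$body_aspect_male else config$body_aspect_female
    fish <- .render_fish(h, w, config$fin_fraction, aspect, fin_b, config$noise_sd)
    rows[[i]] <- tibble::tibble(
      id = sprintf("fish%04d", i),
      image = list(fish$image),
      group = group,
      true_sex = sex,
      body_weight_g = weight,
      total_length_mm = len,
      roi_x = fish$roi[["x"]], roi_y = fish$roi[["y"]],
      roi_w = fish$roi[["w"]], roi_h = fish$roi[["h"]],
      true_fin_b = fish$true_fin_b,
      cell = cell
    )
  }
  cohort <- dplyr::bind_rows(rows)
  class(cohort) <- c("fish_cohort", class(cohort))
  attr(cohort, "sim_config") <- config
  if (!is.null(dir)) {
    write_cohort(cohort, dir)
    cohort$image_path <- file.path(dir, paste0(cohort$id, ".png"))
  }
  cohort
}

.hold_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Per-sample generating truth of a synthetic cohort
#'
#' The oracle table for recovery tests: one row per fish with its cell,
#' true sex, rendered fin yellowness and body measurements.
#'
#' @param cohort A `fish_cohort` from [simulate_cohort()].
#' @return A tibble with columns `id`, `group`, `true_sex`, `cell`,
#'   `true_fin_b`, `body_weight_g`, `total_length_mm`.
#' @export
truth_table <- function(cohort) {
  stopifnot(inherits(cohort, "fish_cohort"))
  tibble::as_tibble(cohort[, c("id", "group", "true_sex", "cell", "true_fin_b",
                               "body_weight_g", "total_length_mm")])
}

#' Write a cohort to disk as PNG images plus a metadata CSV
#'
#' @param cohort A `fish_cohort`.
#' @param dir Output directory, created if needed.
#' @return The metadata CSV path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fish_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(cohort$id, ".png"))
  for (i in seq_len(nrow(cohort))) {
    png::writePNG(cohort$image[[i]] / 255, paths[i])
  }
  meta <- data.frame(
    id = cohort$id,
    image_path = basename(paths),
    group = cohort$group,
    true_sex = cohort$true_sex,
    body_weight_g = cohort$body_weight_g,
    total_length_mm = cohort$total_length_mm,
    roi_x = cohort$roi_x, roi_y = cohort$roi_y,
    roi_w = cohort$roi_w, roi_h = cohort$roi_h
  )
  meta_path <- file.path(dir, "metadata.csv")
  utils::write.csv(meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(meta_path)
}
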