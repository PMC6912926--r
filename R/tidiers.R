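# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname svm_tidiers
#' @export
tidy.svm_sexer <- function(x, ...) {
  tibble::tibble(
    term = c("n_support_vectors", "gamma", "cost", "bias"),
    estimate = c(nrow(x$support_vectors), x$gamma, x$cost, x$bias)
  )
}

#' Tidiers for SVM sexer fits
#'
#' @param x An `svm_sexer`.
#' @param ... Unused.
#' @return `tidy()`: one row per summary quantity. `glance()`: a one-row
#'   tibble with the model's headline numbers.
#' @name svm_tidiers
#' @export
glance.svm_sexer <- function(x, ...) {
  tibble::tibble(
    n_support_vectors = nrow(x$support_vectors),
    n_features = length(x$feature_names),
    gamma = x$gamma,
    cost = x$cost
  )
}

#' Tidiers for the sex-ratio GLM
#'
#' @param x A `sex_ratio_fit`.
#' @param ... Unused.
#' @return `tidy()`: per-group logit LS-means with SEs and back-transformed
#'   probabilities. `glance()`: deviance summary of the underlying GLM.
#' @name sex_ratio_tidiers
#' @export
tidy.sex_ratio_fit <- function(x, ...) x$estimates

#' @rdname sex_ratio_tidiers
#' @export
glance.sex_ratio_fit <- function(x, ...) {
  g <- x$glm
  tibble::tibble(
    null_deviance = g$null.deviance, df_null = g$df.null,
    deviance = g$deviance, df_residual = g$df.residual,
    aic = stats::AIC(g), n_groups = nrow(x$estimates)
  )
}

#' Tidiers for ANCOVA fits
#'
#' @param x An `ancova_fit`.
#' @param ... Unused.
#' @return `tidy()`: the partial-F ANOVA table of the retained terms.
#'   `glance()`: fit summary (R2, sigma, df, n, terms kept/eliminated).
#' @name ancova_tidiers
#' @export
tidy.ancova_fit <- function(x, ...) ancova_anova(x)

#' @rdname ancova_tidiers
#' @export
glance.ancova_fit <- function(x, ...) {
  s <- summary(x$lm)
  tibble::tibble(
    r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
    sigma = s$sigma, df_residual = stats::df.residual(x$lm),
    n = nrow(x$frame),
    n_terms = length(x$terms), n_eliminated = length(x$eliminated)
  )
}

#' Tidiers for the CNN sexer
#'
#' @param x A `cnn_sexer`.
#' @param ... Unused.
#' @return `tidy()`: the per-epoch training log. `glance()`: architecture
#'   and final-epoch summary.
#' @name cnn_tidiers
#' @export
tidy.cnn_sexer <- function(x, ...) x$training_log

#' @rdname cnn_tidiers
#' @export
glance.cnn_sexer <- function(x, ...) {
  lg <- x$training_log
  tibble::tibble(
    n_parameters = cnn_n_params(x),
    n_units = length(x$units),
    epochs_trained = nrow(lg),
    final_loss = if (nrow(lg) > 0) lg$loss[nrow(lg)] else NA_real_,
    final_accuracy = if (nrow(lg) > 0) lg$accuracy[nrow(lg)] else NA_real_
  )
}
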