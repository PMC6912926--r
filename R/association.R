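# Association between fin-color intensity (z) and body size: polynomial
# ANCOVA with treatment, sex and their interaction as fixed factors, the
# covariate (body weight or total length) entering up to degree 3 alone and
# in interaction with each factor, backward elimination by F tests,
# externally studentized residual screening, and Tukey-Kramer adjusted
# least-squares means. Factors are coded sum-to-zero internally; the
# covariate is mean-centered before raising to powers (collinearity), and
# LS-means are reported at the covariate grand mean unless asked otherwise.

#' ANCOVA specification
#'
#' @param covariate Name of the covariate column: `"body_weight_g"` or
#'   `"total_length_mm"` (any numeric column works).
#' @param response Name of the response column (default `"z"`, the
#'   intensity score).
#' @param max_degree Highest covariate power, 1-3.
#' @param alpha_stay F-test p-value a term must beat to stay during
#'   backward elimination (default 0.05).
#' @param outlier_threshold Absolute externally studentized residual above
#'   which an observation is flagged (default 3).
#' @return An `ancova_spec` list.
#' @export
ancova_spec <- function(covariate = "body_weight_g", response = "z",
                        max_degree = 3, alpha_stay = 0.05,
                        outlier_threshold = 3) {
  if (!max_degree %in% 1:3) stop("`max_degree` must be 1, 2 or 3", call. = FALSE)
  if (alpha_stay <= 0 || alpha_stay >= 1) stop("`alpha_stay` must be in (0, 1)", call. = FALSE)
  structure(list(covariate = covariate, response = response,
                 max_degree = as.integer(max_degree),
                 alpha_stay = alpha_stay,
                 outlier_threshold = outlier_threshold),
            class = "ancova_spec")
}

# Build the modelling frame: factors + centered covariate powers x1..xp.
.ancova_frame <- function(data, spec) {
  for (col in c("group", "sex", spec$response, spec$covariate)) {
    if (!col %in% names(data)) stop("data lacks column `", col, "`", call. = FALSE)
  }
  x <- data[[spec$covariate]]
  if (!is.numeric(x) || stats::sd(x) == 0) {
    stop("covariate `", spec$covariate, "` is degenerate", call. = FALSE)
  }
  center <- mean(x)
  df <- data.frame(
    .id = if ("id" %in% names(data)) data$id else as.character(seq_len(nrow(data))),
    y = data[[spec$response]],
    group = factor(data$group),
    sex = factor(data$sex)
  )
  for (p in seq_len(spec$max_degree)) df[[paste0("x", p)]] <- (x - center)^p
  list(frame = df, center = center)
}

.full_terms <- function(max_degree) {
  xs <- paste0("x", seq_len(max_degree))
  c("group", "sex", "group:sex", xs,
    paste0("sex:", xs), paste0("group:", xs))
}

.fit_terms <- function(frame, terms) {
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  form <- stats::as.formula(paste("y ~", rhs))
  stats::lm(form, data = frame,
            contrasts = list(group = "contr.sum", sex = "contr.sum")[
              intersect(c("group", "sex"), all.vars(form))])
}

# term -> (factor set, covariate power); used for marginality.
.term_parts <- function(term) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  pow <- 0L
  facs <- character()
  for (p in parts) {
    if (grepl("^x[0-9]+$", p)) pow <- as.integer(sub("x", "", p)) else facs <- c(facs, p)
  }
  list(facs = sort(facs), pow = pow)
}

# A is contained in B (A must stay while B is in the model) under factor
# marginality plus the polynomial hierarchy x^p <= x^q for p <= q.
.term_contained <- function(a, b) {
  if (identical(a, b)) return(FALSE)
  pa <- .term_parts(a); pb <- .term_parts(b)
  all(pa$facs %in% pb$facs) &&
    (pa$pow <= pb$pow) &&
    !(pa$pow == 0 && length(pa$facs) == 0)
}

.droppable_terms <- function(terms) {
  terms[!vapply(terms, function(a) any(vapply(terms, function(b)
    .term_contained(a, b), logical(1))), logical(1))]
}

#' Fit the full polynomial ANCOVA
#'
#' Ordinary least squares of the intensity response on treatment, sex,
#' their interaction, centered covariate powers up to `max_degree`, and the
#' power-by-factor interactions.
#'
#' @param data A data frame with columns `id` (optional), `group`, `sex`,
#'   the response and the covariate named in `spec`.
#' @param spec An [ancova_spec()].
#' @return An `ancova_fit`: the `lm` fit plus term bookkeeping, the
#'   covariate center, and the data frame used.
#' @export
fit_ancova <- function(data, spec = ancova_spec()) {
  stopifnot(inherits(spec, "ancova_spec"))
  fr <- .ancova_frame(data, spec)
  cells <- table(fr$frame$group, fr$frame$sex)
  if (nlevels(fr$frame$group) < 2L || nlevels(fr$frame$sex) < 2L || any(cells < 2)) {
    stop("need at least 2 observations per treatment x sex cell", call. = FALSE)
  }
  terms <- .full_terms(spec$max_degree)
  fit <- .fit_terms(fr$frame, terms)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(lm = fit, terms = terms, spec = spec,
                 center = fr$center, frame = fr$frame,
                 eliminated = character()),
            class = "ancova_fit")
}

.refit <- function(afit, terms) {
  fit <- .fit_terms(afit$frame, terms)
  afit$lm <- fit
  afit$eliminated <- c(afit$eliminated, setdiff(afit$terms, terms))
  afit$terms <- terms
  afit
}

#' Backward elimination of nonsignificant terms
#'
#' Repeatedly drops the removable term (one no retained term contains,
#' respecting factor marginality and the polynomial hierarchy) with the
#' largest partial F-test p-value above `alpha_stay`, refitting until every
#' retained term is significant. Exact p-value ties break deterministically
#' by term order. May return the intercept-only model.
#'
#' @param fit An `ancova_fit` from [fit_ancova()].
#' @param alpha_stay Stay threshold; defaults to the spec's.
#' @return The reduced `ancova_fit`; dropped terms are recorded in
#'   `$eliminated` in removal order.
#' @export
backward_eliminate <- function(fit, alpha_stay = NULL) {
  stopifnot(inherits(fit, "ancova_fit"))
  if (is.null(alpha_stay)) alpha_stay <- fit$spec$alpha_stay
  repeat {
    terms <- fit$terms
    if (length(terms) == 0) break
    cand <- .droppable_terms(terms)
    if (length(cand) == 0) break
    pv <- vapply(cand, function(tm) .partial_f_p(fit, tm), numeric(1))
    worst <- cand[which.max(pv)]
    if (is.na(pv[which.max(pv)]) || pv[which.max(pv)] <= alpha_stay) break
    fit <- .refit(fit, setdiff(terms, worst))
  }
  fit
}

# p-value of the partial F test for dropping one term: fit the reduced
# model and compare residual sums of squares. Immune to the formula-label
# reordering that bites drop1 when a scope lacks main effects.
.partial_f_p <- function(afit, term) {
  full <- afit$lm
  red <- .fit_terms(afit$frame, setdiff(afit$terms, term))
  rss_full <- sum(stats::residuals(full)^2)
  rss_red <- sum(stats::residuals(red)^2)
  df_num <- stats::df.residual(red) - stats::df.residual(full)
  df_den <- stats::df.residual(full)
  if (df_num <= 0 || df_den <= 0) return(NA_real_)
  f <- ((rss_red - rss_full) / df_num) / (rss_full / df_den)
  stats::pf(f, df_num, df_den, lower.tail = FALSE)
}

#' Externally studentized residuals and outlier flags
#'
#' Leave-one-out studentized residuals of the fitted model; observations
#' with `|r| > threshold` are flagged.
#'
#' @param fit An `ancova_fit` (or plain `lm`).
#' @param threshold Flagging threshold (default from the spec, 3).
#' @return A tibble `id`, `rstudent`, `outlier`.
#' @export
studentized_outliers <- function(fit, threshold = NULL) {
  lmfit <- if (inherits(fit, "ancova_fit")) fit$lm else fit
  if (is.null(threshold)) {
    threshold <- if (inherits(fit, "ancova_fit")) fit$spec$outlier_threshold else 3
  }
  if (stats::df.residual(lmfit) <= 1) {
    stop("model is (near) saturated; studentized residuals undefined", call. = FALSE)
  }
  r <- stats::rstudent(lmfit)
  ids <- if (inherits(fit, "ancova_fit")) fit$frame$.id else names(r)
  # an (essentially) exact fit has no meaningful studentization: residuals
  # at rounding level must not flag
  raw <- stats::residuals(lmfit)
  y_scale <- stats::sd(stats::fitted(lmfit) + raw)
  exact <- sqrt(mean(raw^2)) <= 1e-10 * max(y_scale, 1e-300)
  tibble::tibble(id = as.character(ids), rstudent = as.numeric(r),
                 outlier = !exact & !is.na(r) & abs(r) > threshold)
}

#' Single-pass outlier removal and refit
#'
#' Flags outliers on the current fit, removes them, and refits the same
#' terms once (one filtering pass).
#'
#' @param fit An `ancova_fit`.
#' @param threshold Passed to [studentized_outliers()].
#' @return List with `fit` (refitted `ancova_fit`) and `outliers` (the
#'   flagged id tibble rows).
#' @export
filter_outliers <- function(fit, threshold = NULL) {
  stopifnot(inherits(fit, "ancova_fit"))
  flags <- studentized_outliers(fit, threshold)
  out <- flags[flags$outlier, ]
  if (nrow(out) > 0) {
    keep <- !fit$frame$.id %in% out$id
    fit$frame <- fit$frame[keep, , drop = FALSE]
    fit$lm <- .fit_terms(fit$frame, fit$terms)
  }
  list(fit = fit, outliers = out)
}

# compact letter display by the insert-and-absorb sweep over the adjusted
# pairwise p matrix; levels sharing a letter are not significantly different
.letter_display <- function(levels, pmat, alpha = 0.05) {
  k <- length(levels)
  groups <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && all(pmat[i:(j + 1), i:(j + 1)][upper.tri(diag(j - i + 2))] > alpha)) {
      j <- j + 1
    }
    g <- i:j
    if (!any(vapply(groups, function(h) all(g %in% h), logical(1)))) {
      groups <- c(groups, list(g))
    }
  }
  letters_out <- character(k)
  for (gi in seq_along(groups)) {
    for (m in groups[[gi]]) {
      letters_out[m] <- paste0(letters_out[m], letters[gi])
    }
  }
  stats::setNames(letters_out, levels)
}

#' Least-squares means with Tukey-Kramer comparisons
#'
#' Model-based predicted cell means for every treatment-by-sex combination
#' (or the single factor present), evaluated at the covariate grand mean by
#' default or at caller-supplied covariate values, with standard errors
#' from the coefficient covariance, Tukey-Kramer adjusted pairwise
#' p-values, and a compact letter display.
#'
#' @param fit An `ancova_fit` or `size_anova_fit`.
#' @param at Optional numeric vector of raw covariate values at which to
#'   evaluate the means (one LS-means table per value, stacked with an
#'   `at` column).
#' @param alpha Significance level for the letter display.
#' @return A list with `means` (tibble: factor levels, `emmean`, `se`,
#'   `df`, confidence limits, `letters`) and `contrasts` (tibble of
#'   adjusted pairwise tests).
#' @export
ls_means <- function(fit, at = NULL, alpha = 0.05) {
  lmfit <- if (inherits(fit, c("ancova_fit", "size_anova_fit"))) fit$lm else fit
  vars <- attr(stats::terms(lmfit), "term.labels")
  facs <- intersect(c("group", "sex"), unique(unlist(strsplit(vars, ":"))))
  if (length(facs) == 0) stop("no factors in the model; LS-means undefined", call. = FALSE)
  spec_formula <- stats::as.formula(paste("~", paste(facs, collapse = "*")))
  xs <- grep("^x[0-9]+$", unique(unlist(strsplit(vars, ":"))), value = TRUE)

  one <- function(raw_value) {
    at_list <- NULL
    if (length(xs) > 0) {
      centered <- if (is.null(raw_value)) 0 else raw_value - fit$center
      at_list <- stats::setNames(
        lapply(xs, function(v) centered^as.integer(sub("x", "", v))), xs)
    }
    em <- emmeans::emmeans(lmfit, spec_formula, at = at_list)
    s <- summary(em, level = 1 - alpha)
    means <- tibble::as_tibble(s)
    names(means)[names(means) == "SE"] <- "se"
    cs <- summary(emmeans::contrast(em, "pairwise", adjust = "tukey"))
    lv <- do.call(paste, c(as.list(s[facs]), sep = " "))
    k <- length(lv)
    pmat <- matrix(1, k, k, dimnames = list(lv, lv))
    pairs_idx <- utils::combn(k, 2)
    for (ci in seq_len(ncol(pairs_idx))) {
      i <- pairs_idx[1, ci]; j <- pairs_idx[2, ci]
      pmat[i, j] <- pmat[j, i] <- cs$p.value[ci]
    }
    ord <- order(means$emmean, decreasing = TRUE)
    lets <- .letter_display(lv[ord], pmat[ord, ord, drop = FALSE], alpha)
    means$letters <- lets[match(lv, names(lets))]
    contrasts <- tibble::tibble(contrast = as.character(cs$contrast),
                                estimate = cs$estimate, se = cs$SE,
                                df = cs$df, t = cs$t.ratio, p_adj = cs$p.value)
    list(means = means, contrasts = contrasts)
  }

  if (is.null(at) || length(xs) == 0) {
    one(if (is.null(at)) NULL else at[1])
  } else {
    res <- lapply(at, one)
    means <- dplyr::bind_rows(lapply(seq_along(at), function(i) {
      m <- res[[i]]$means; m$at <- at[i]; m
    }))
    list(means = means, contrasts = res[[1]]$contrasts)
  }
}

#' Two-way ANOVA of body weight or length
#'
#' `y = mu + treatment + sex + treatment:sex + error` by OLS, the model
#' used for the growth traits, with LS-means per cell.
#'
#' @param data Data frame with `group`, `sex` and the response column.
#' @param response Column name, e.g. `"body_weight_g"`.
#' @return A `size_anova_fit` (lm + ANOVA table + [ls_means()] output).
#' @export
fit_size_anova <- function(data, response = "body_weight_g") {
  for (col in c("group", "sex", response)) {
    if (!col %in% names(data)) stop("data lacks column `", col, "`", call. = FALSE)
  }
  frame <- data.frame(y = data[[response]],
                      group = factor(data$group), sex = factor(data$sex))
  fit <- stats::lm(y ~ group * sex, data = frame,
                   contrasts = list(group = "contr.sum", sex = "contr.sum"))
  out <- structure(list(lm = fit, response = response, frame = frame),
                   class = "size_anova_fit")
  out$anova <- stats::anova(fit)
  out$ls_means <- ls_means(out)
  out
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat("<ancova_fit> response ~", paste(x$terms, collapse = " + "), "\n")
  cat(sprintf("  n = %d, covariate `%s` centered at %.4g\n",
              nrow(x$frame), x$spec$covariate, x$center))
  if (length(x$eliminated) > 0) {
    cat("  eliminated:", paste(x$eliminated, collapse = ", "), "\n")
  }
  invisible(x)
}

#' ANOVA table of an ancova_fit
#'
#' Partial (drop-one) F tests for every retained term.
#'
#' @param fit An `ancova_fit`.
#' @return Tibble with `term`, `df`, `sum_sq`, `f`, `p`.
#' @export
ancova_anova <- function(fit) {
  stopifnot(inherits(fit, "ancova_fit"))
  if (length(fit$terms) == 0) {
    return(tibble::tibble(term = character(), df = numeric(),
                          sum_sq = numeric(), f = numeric(), p = numeric()))
  }
  rows <- lapply(fit$terms, function(tm) {
    red <- .fit_terms(fit$frame, setdiff(fit$terms, tm))
    rss_full <- sum(stats::residuals(fit$lm)^2)
    rss_red <- sum(stats::residuals(red)^2)
    df_num <- stats::df.residual(red) - stats::df.residual(fit$lm)
    df_den <- stats::df.residual(fit$lm)
    if (df_num <= 0 || df_den <= 0) {
      # a main effect absorbed by a retained interaction has no testable df
      return(tibble::tibble(term = tm, df = df_num, sum_sq = rss_red - rss_full,
                            f = NA_real_, p = NA_real_))
    }
    f <- ((rss_red - rss_full) / df_num) / (rss_full / df_den)
    tibble::tibble(term = tm, df = df_num, sum_sq = rss_red - rss_full,
                   f = f, p = stats::pf(f, df_num, df_den, lower.tail = FALSE))
  })
  dplyr::bind_rows(rows)
}

#' Raw-scale polynomial slopes per sex
#'
#' Back-transforms the centered-covariate coefficients to per-sex slopes of
#' the response on the raw covariate (degree-1 component), with confidence
#' intervals from the coefficient covariance.
#'
#' @param fit An `ancova_fit` whose model retains `x1` and/or `sex:x1`.
#' @param level Confidence level.
#' @return Tibble `sex`, `slope`, `se`, `lower`, `upper`.
#' @export
sex_slopes <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "ancova_fit"))
  em <- emmeans::emtrends(fit$lm, ~sex, var = "x1")
  s <- summary(em, level = level)
  tibble::tibble(sex = as.character(s$sex), slope = s$x1.trend, se = s$SE,
                 lower = s$lower.CL, upper = s$upper.CL)
}
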