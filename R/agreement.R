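# Classifier-versus-truth agreement: 2x2 contingency tables, the phi
# (mean square contingency) coefficient, and the logit-link Bernoulli GLM
# for sex ratios with back-transformed least-squares means.

#' 2x2 contingency table of true versus predicted sex
#'
#' @param truth,predicted Equal-length vectors of `"M"`/`"F"`.
#' @return A `confusion_2x2`: named counts `n11` (true M, predicted M),
#'   `n12` (true M, predicted F), `n21` (true F, predicted M), `n22`
#'   (true F, predicted F).
#' @examples
#' confusion(c("M", "M", "F"), c("M", "M", "F"))
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` must have equal length", call. = FALSE)
  }
  if (length(truth) == 0) stop("empty input", call. = FALSE)
  truth <- factor(as.character(truth), levels = c("M", "F"))
  predicted <- factor(as.character(predicted), levels = c("M", "F"))
  if (anyNA(truth) || anyNA(predicted)) stop("labels must be 'M' or 'F'", call. = FALSE)
  tab <- table(truth, predicted)
  structure(c(n11 = tab["M", "M"], n12 = tab["M", "F"],
              n21 = tab["F", "M"], n22 = tab["F", "F"]),
            class = "confusion_2x2")
}

#' Construct a 2x2 table directly from counts
#'
#' @param n11,n12,n21,n22 Nonnegative counts, laid out as in [confusion()].
#' @return A `confusion_2x2`.
#' @export
confusion_from_counts <- function(n11, n12, n21, n22) {
  counts <- c(n11 = n11, n12 = n12, n21 = n21, n22 = n22)
  if (any(counts < 0) || sum(counts) == 0) {
    stop("counts must be nonnegative with a positive total", call. = FALSE)
  }
  structure(counts, class = "confusion_2x2")
}

#' @export
print.confusion_2x2 <- function(x, ...) {
  m <- matrix(unclass(x), 2, 2, byrow = TRUE,
              dimnames = list(truth = c("M", "F"), predicted = c("M", "F")))
  print(m)
  invisible(x)
}

#' Phi coefficient of a 2x2 table
#'
#' The mean square contingency coefficient
#' `phi = (n11 n22 - n12 n21) / sqrt(r1 r2 c1 c2)` with row and column
#' sums `r`, `c`; identical to the Pearson correlation of the two binary
#' indicators. A zero margin leaves phi undefined and raises an error
#' rather than silently returning 0.
#'
#' @param table A `confusion_2x2` (or a 2x2 matrix, rows = truth).
#' @return Scalar in `[-1, 1]`.
#' @examples
#' phi_coefficient(confusion_from_counts(133, 0, 0, 40)) # perfect agreement
#' @export
phi_coefficient <- function(table) {
  if (inherits(table, "confusion_2x2")) {
    n <- unclass(table)
  } else if (is.matrix(table) && all(dim(table) == 2L)) {
    n <- c(n11 = table[1, 1], n12 = table[1, 2], n21 = table[2, 1], n22 = table[2, 2])
  } else {
    stop("`table` must be a confusion_2x2 or a 2x2 matrix", call. = FALSE)
  }
  r1 <- n[["n11"]] + n[["n12"]]; r2 <- n[["n21"]] + n[["n22"]]
  c1 <- n[["n11"]] + n[["n21"]]; c2 <- n[["n12"]] + n[["n22"]]
  if (any(c(r1, r2, c1, c2) == 0)) {
    stop("phi is undefined: a table margin is zero", call. = FALSE)
  }
  (n[["n11"]] * n[["n22"]] - n[["n12"]] * n[["n21"]]) / sqrt(r1 * r2 * c1 * c2)
}

#' Logit-link Bernoulli sex-ratio model
#'
#' Fits `logit(pi_i) = mu + alpha_i` by maximum likelihood with treatment
#' group as the single fixed factor, estimates least-squares means on the
#' logit scale, back-transforms them with the inverse link
#' `pi = exp(eta) / (1 + exp(eta))`, and tests pairwise group contrasts on
#' the logit scale with Tukey-Kramer adjustment (which coincides with the
#' unadjusted t/z test when there are only two groups).
#'
#' For this saturated one-factor model the back-transformed LS-mean equals
#' the observed group proportion and `SE(eta_i) = sqrt(1 / (n p (1 - p)))`.
#'
#' @param males Number of males per group (named vector, or unnamed with
#'   `groups` supplied).
#' @param totals Group sizes.
#' @param groups Optional group labels.
#' @return A `sex_ratio_fit` with elements `estimates` (tibble: group,
#'   `n_male`, `n`, `eta`, `se`, `pi`, `pct`), `contrasts` (tibble of
#'   adjusted pairwise tests) and the underlying `glm` fit.
#' @examples
#' fit_sex_ratio(c(treatment = 158, control = 125), c(198, 249))
#' @export
fit_sex_ratio <- function(males, totals, groups = names(males)) {
  if (is.null(groups)) groups <- paste0("group", seq_along(males))
  if (length(males) != length(totals) || length(males) < 1L) {
    stop("`males` and `totals` must have equal positive length", call. = FALSE)
  }
  if (any(totals <= 0)) stop("`totals` must be positive", call. = FALSE)
  if (any(males < 0 | males > totals)) stop("`males` must lie in [0, totals]", call. = FALSE)
  p_hat <- males / totals
  if (any(p_hat %in% c(0, 1))) {
    warning("complete separation in at least one group; its logit SE is unbounded",
            call. = FALSE)
  }
  dat <- data.frame(group = factor(groups, levels = groups),
                    m = males, f = totals - males)
  fit <- stats::glm(cbind(m, f) ~ group, family = stats::binomial("logit"), data = dat)
  em <- emmeans::emmeans(fit, ~group)
  s <- summary(em)
  estimates <- tibble::tibble(
    group = as.character(s$group),
    n_male = as.numeric(males),
    n = as.numeric(totals),
    eta = s$emmean,
    se = s$SE,
    pi = stats::plogis(s$emmean),
    pct = 100 * stats::plogis(s$emmean)
  )
  contrasts <- if (length(groups) > 1L) {
    cs <- summary(emmeans::contrast(em, method = "pairwise", adjust = "tukey"))
    tibble::tibble(contrast = as.character(cs$contrast),
                   estimate = cs$estimate, se = cs$SE,
                   p_adj = cs$p.value)
  } else {
    tibble::tibble(contrast = character(), estimate = numeric(),
                   se = numeric(), p_adj = numeric())
  }
  structure(list(estimates = estimates, contrasts = contrasts, glm = fit),
            class = "sex_ratio_fit")
}

#' @export
print.sex_ratio_fit <- function(x, ...) {
  cat("<sex_ratio_fit> logit-link Bernoulli GLM\n")
  print(as.data.frame(x$estimates), digits = 4)
  if (nrow(x$contrasts) > 0) {
    cat("contrasts (logit scale, Tukey-Kramer adjusted):\n")
    print(as.data.frame(x$contrasts), digits = 4)
  }
  invisible(x)
}

#' Agreement report for a scored cohort
#'
#' Convenience wrapper used by the pipeline: builds the per-group
#' contingency tables, phi coefficients, and predicted/true male
#' percentages.
#'
#' @param scores A `sex_scores` tibble carrying `true_sex`, `predicted_sex`
#'   and optionally `group`.
#' @return A list with one entry per group: `table`, `phi`,
#'   `pct_male_true`, `pct_male_predicted`, `n`.
#' @export
agreement_report <- function(scores) {
  stopifnot(all(c("true_sex", "predicted_sex") %in% names(scores)))
  groups <- if ("group" %in% names(scores)) split(scores, scores$group) else list(all = scores)
  lapply(groups, function(g) {
    tab <- confusion(g$true_sex, g$predicted_sex)
    list(
      table = unclass(tab),
      phi = tryCatch(phi_coefficient(tab), error = function(e) NA_real_),
      pct_male_true = 100 * mean(g$true_sex == "M"),
      pct_male_predicted = 100 * mean(g$predicted_sex == "M"),
      n = nrow(g)
    )
  })
}
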