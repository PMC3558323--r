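# Association statistics: odds ratios from 2x2 tables, Pearson chi-square
# tests on r x c tables, and logistic regression.  These reproduce the
# Table-3/Table-5 style analyses: relapse odds by instability grade and
# cross-tabulations of grade against clinicopathological factors.

as_2x2 <- function(x) {
  m <- as.matrix(x)
  if (!all(dim(m) == c(2, 2))) abort("Expected a 2x2 table")
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  if (any(m < 0) || anyNA(m)) abort("Counts must be non-negative")
  m
}

#' Wald odds ratio for a 2x2 table
#'
#' Cross-product odds ratio with the Wald 95% confidence interval
#' `exp(log OR +/- 1.96 * SE)`, `SE = sqrt(sum of 1/cell)`, and two-sided
#' Wald p-value — the univariate-logistic-regression odds ratio in closed
#' form.  When any cell is zero the Haldane-Anscombe +0.5 correction is
#' applied to every cell and flagged.
#'
#' @param x A 2x2 matrix: rows = groups (first row the focal group), columns
#'   = outcome (first column events).  `OR = (x11 * x22) / (x12 * x21)`.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `odds_ratio`, `conf.low`, `conf.high`,
#'   `p.value`, `haldane` (logical).
#' @export
#' @examples
#' odds_ratio_wald(matrix(c(21, 23, 7, 65), nrow = 2)) # relapse odds, grade 3 vs 2
odds_ratio_wald <- function(x, conf_level = 0.95) {
  m <- as_2x2(x)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("A margin of the 2x2 table is zero; the odds ratio is undefined")
  }
  haldane <- any(m == 0)
  if (haldane) m <- m + 0.5
  log_or <- log(m[1, 1]) + log(m[2, 2]) - log(m[1, 2]) - log(m[2, 1])
  se <- sqrt(sum(1 / m))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble(
    odds_ratio = exp(log_or),
    conf.low = exp(log_or - z * se),
    conf.high = exp(log_or + z * se),
    p.value = 2 * pnorm(-abs(log_or / se)),
    haldane = haldane
  )
}

#' Pearson chi-square test for an r x c table
#'
#' Pearson statistic without continuity correction, df = (r-1)(c-1),
#' upper-tail p-value.
#'
#' @param x An r x c matrix of counts (at least 2x2).
#' @return A one-row tibble: `statistic`, `df`, `p.value`.
#' @export
#' @examples
#' pearson_chi_square(rbind(c(0, 24, 15), c(19, 64, 13)))
pearson_chi_square <- function(x) {
  m <- as.matrix(x)
  if (any(dim(m) < 2)) abort("Expected at least a 2x2 table")
  if (sum(m) == 0) abort("Table has a zero grand total")
  res <- suppressWarnings(chisq.test(m, correct = FALSE))
  tibble(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p.value = unname(res$p.value)
  )
}

#' Logistic regression of a binary outcome
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares) supporting multi-factor models such as grade plus prognostic
#' index.  Perfect separation is detected and raised as an error naming the
#' offending covariate rather than returning a diverged fit.
#'
#' @param data A data frame.
#' @param formula Model formula with a 0/1 (or two-level factor) outcome.
#' @return An object of class `g2i_logit`; see [tidy()] and [glance()].
#' @export
logistic_regression <- function(data, formula) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (length(unique(y[!is.na(y)])) < 2) {
    abort("Outcome is constant; logistic regression is undefined")
  }
  separation_warned <- FALSE
  fit <- withCallingHandlers(
    glm(formula, family = binomial(), data = data,
      control = list(epsilon = 1e-10, maxit = 100)
    ),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation_warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  big <- abs(coef(fit)) > 12
  big[1] <- FALSE # intercept can legitimately be large-ish; separation shows in slopes
  if (separation_warned && any(big, na.rm = TRUE)) {
    abort(paste0(
      "Perfect separation detected for covariate(s): ",
      paste(names(coef(fit))[which(big)], collapse = ", ")
    ))
  }
  structure(list(fit = fit, formula = formula, n = nrow(mf)), class = "g2i_logit")
}

#' @export
print.g2i_logit <- function(x, ...) {
  cat("Logistic regression:", deparse(x$formula), "\n")
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a logistic regression fit
#'
#' @param x A `g2i_logit` object.
#' @param conf_level Confidence level for the Wald interval on the odds
#'   ratio scale.
#' @param ... Unused.
#' @return A tibble with one row per term: `term`, `estimate` (log-odds),
#'   `std.error`, `statistic`, `p.value`, `odds_ratio`, `conf.low`,
#'   `conf.high`.
#' @export
tidy.g2i_logit <- function(x, conf_level = 0.95, ...) {
  s <- summary(x$fit)$coefficients
  z <- qnorm(1 - (1 - conf_level) / 2)
  rn <- rownames(s)
  s <- unname(s)
  tibble(
    term = rn,
    estimate = s[, 1],
    std.error = s[, 2],
    statistic = s[, 3],
    p.value = s[, 4],
    odds_ratio = exp(s[, 1]),
    conf.low = exp(s[, 1] - z * s[, 2]),
    conf.high = exp(s[, 1] + z * s[, 2])
  )
}

#' @rdname tidy.g2i_logit
#' @export
glance.g2i_logit <- function(x, ...) {
  f <- x$fit
  tibble(
    null.deviance = f$null.deviance,
    df.null = f$df.null,
    deviance = f$deviance,
    df.residual = f$df.residual,
    AIC = stats::AIC(f),
    nobs = x$n
  )
}

#' Grade-association report for a cohort
#'
#' Cross-tabulates a categorical clinical factor against the G2I grade and
#' runs the Pearson chi-square test — one row of a Table-5-style report.
#'
#' @param scores A [score_gnl()] result (or any tibble with `sample_id` and
#'   `grade`).
#' @param clinical Clinical tibble with `sample_id` and the factor.
#' @param factor Name of the clinical column to test.
#' @return A list with the contingency `table` and the chi-square `test`
#'   tibble.
#' @export
grade_association <- function(scores, clinical, factor) {
  merged <- dplyr::inner_join(
    as_tibble(scores)[, c("sample_id", "grade")],
    clinical[, c("sample_id", factor)],
    by = "sample_id"
  )
  merged <- merged[complete.cases(merged), ]
  tab <- table(merged[[factor]], merged$grade)
  list(table = tab, test = pearson_chi_square(tab))
}
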