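# Kaplan-Meier curves and the log-rank test, with the hazard ratio taken
# from the log-rank observed/expected event counts: HR = (O1/E1)/(O2/E2).

#' Kaplan-Meier curves and log-rank test by group
#'
#' Product-limit survival estimate per group and the log-rank chi-square
#' test across groups (df = number of groups - 1).  For two groups the
#' hazard ratio of the first group relative to the second is computed from
#' the log-rank observed and expected event counts.
#'
#' @param records A data frame with one row per subject.
#' @param time,event,group Column names (strings) for follow-up time
#'   (positive), event indicator (0/1) and group label.
#' @return An object of class `g2i_logrank`; see [tidy()], [glance()] and
#'   [autoplot()].
#' @export
km_logrank <- function(records, time = "time", event = "event", group = "group") {
  df <- tibble(
    time = as.numeric(records[[time]]),
    event = as.integer(records[[event]]),
    group = as.character(records[[group]])
  )
  if (any(is.na(df$time) | df$time <= 0)) abort("time must be positive for every record")
  if (any(!df$event %in% c(0L, 1L))) abort("event must be 0 or 1")
  if (sum(df$event) == 0) abort("No events: the log-rank test is undefined")
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  n_groups <- length(unique(df$group))
  if (n_groups >= 2) {
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
    statistic <- unname(sd_$chisq)
    dfree <- n_groups - 1L
    p <- pchisq(statistic, df = dfree, lower.tail = FALSE)
    hr <- if (n_groups == 2) {
      (sd_$obs[1] / sd_$exp[1]) / (sd_$obs[2] / sd_$exp[2])
    } else {
      NA_real_
    }
    obs <- sd_$obs
    expct <- sd_$exp
  } else {
    statistic <- NA_real_
    dfree <- NA_integer_
    p <- NA_real_
    hr <- NA_real_
    obs <- sum(df$event)
    expct <- sum(df$event)
  }
  structure(
    list(
      survfit = fit, data = df,
      statistic = statistic, df = dfree, p.value = p,
      hazard_ratio = hr, observed = obs, expected = expct
    ),
    class = "g2i_logrank"
  )
}

#' @export
print.g2i_logrank <- function(x, ...) {
  cat(sprintf(
    "Log-rank test: chi-square = %.3f on %d df, p = %.3g\n",
    x$statistic, x$df, x$p.value
  ))
  if (!is.na(x$hazard_ratio)) {
    cat(sprintf("Hazard ratio (O/E), group 1 vs 2: %.3f\n", x$hazard_ratio))
  }
  invisible(x)
}

#' Tidy Kaplan-Meier curves
#'
#' @param x A `g2i_logrank` object.
#' @param ... Unused.
#' @return A tibble with `group`, `time`, `n.risk`, `n.event`, `estimate`
#'   (the survival probability), `std.error`.
#' @export
tidy.g2i_logrank <- function(x, ...) {
  s <- summary(x$survfit, censored = TRUE)
  strata <- if (is.null(s$strata)) {
    rep(unique(x$data$group)[1], length(s$time))
  } else {
    sub("^group=", "", as.character(s$strata))
  }
  tibble(
    group = strata,
    time = s$time,
    n.risk = s$n.risk,
    n.event = s$n.event,
    estimate = s$surv,
    std.error = s$std.err
  )
}

#' @rdname tidy.g2i_logrank
#' @export
glance.g2i_logrank <- function(x, ...) {
  tibble(
    statistic = x$statistic,
    df = x$df,
    p.value = x$p.value,
    hazard_ratio = x$hazard_ratio,
    n = nrow(x$data),
    events = sum(x$data$event)
  )
}

#' Plot Kaplan-Meier curves
#'
#' @param object A `g2i_logrank` object.
#' @param ... Unused.
#' @return A ggplot of step survival curves by group.
#' @export
autoplot.g2i_logrank <- function(object, ...) {
  curves <- tidy(object) %>%
    group_by(.data$group) %>%
    dplyr::group_modify(~ bind_rows(
      tibble(
        time = 0, n.risk = max(.x$n.risk), n.event = 0L,
        estimate = 1, std.error = 0
      ),
      .x
    )) %>%
    ungroup()
  ggplot2::ggplot(curves, ggplot2::aes(
    x = .data$time, y = .data$estimate, colour = .data$group
  )) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Time (months)", y = "Metastasis-free survival",
      colour = "Group",
      subtitle = sprintf(
        "Log-rank p = %.3g%s", object$p.value,
        if (!is.na(object$hazard_ratio)) {
          sprintf(", HR = %.2f", object$hazard_ratio)
        } else {
          ""
        }
      )
    ) +
    ggplot2::theme_minimal()
}
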