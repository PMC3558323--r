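test_that("Wald odds ratios reproduce the printed relapse associations", {
  # relapse 21/7 in grade 3 vs 23/65 in grade 2
  or3 <- odds_ratio_wald(matrix(c(21, 23, 7, 65), nrow = 2))
  expect_equal(round(or3$odds_ratio, 1), 8.5)
  expect_equal(round(or3$conf.low, 1), 3.2)
  expect_equal(round(or3$conf.high, 1), 22.6)
  expect_lt(or3$p.value, 0.001)

  # relapse 1/18 in grade 1 vs 23/65 in grade 2
  or1 <- odds_ratio_wald(matrix(c(1, 23, 18, 65), nrow = 2))
  expect_equal(round(or1$odds_ratio, 2), 0.16)
  expect_equal(round(or1$p.value, 2), 0.08)

  # a balanced table: OR 1, CI straddles 1
  or_null <- odds_ratio_wald(matrix(10, 2, 2))
  expect_equal(or_null$odds_ratio, 1)
  expect_lt(or_null$conf.low, 1)
  expect_gt(or_null$conf.high, 1)
})

test_that("odds ratios respect table symmetries and zero-cell handling", {
  withr::with_seed(6, {
    for (case in 1:20) {
      m <- matrix(sample(1:50, 4), 2)
      base <- odds_ratio_wald(m)
      # transposing with both factors flipped preserves the OR
      flipped <- t(m[2:1, 2:1])
      expect_equal(odds_ratio_wald(flipped)$odds_ratio, base$odds_ratio)
      # swapping one factor inverts it
      expect_equal(odds_ratio_wald(m[2:1, ])$odds_ratio, 1 / base$odds_ratio)
    }
  })
  zero <- odds_ratio_wald(matrix(c(0, 10, 10, 10), 2))
  expect_true(zero$haldane)
  expect_error(odds_ratio_wald(matrix(c(0, 0, 10, 10), 2)), "margin")
})

test_that("chi-square tests reproduce the printed cross-tabulations", {
  # TP53 alteration by grade (altered 0/19, 24/88, 15/28)
  p53 <- pearson_chi_square(rbind(c(0, 24, 15), c(19, 64, 13)))
  expect_equal(signif(p53$p.value, 1), 3e-4)
  expect_equal(p53$df, 2)

  # SBR grade x G2I 3x3
  sbr <- pearson_chi_square(rbind(c(6, 15, 4), c(12, 48, 11), c(1, 25, 13)))
  expect_equal(round(sbr$p.value, 3), 0.037)
  expect_equal(sbr$df, 4)

  # proportional rows: statistic 0, p = 1
  prop <- pearson_chi_square(rbind(c(10, 20, 30), c(20, 40, 60)))
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p.value, 1)

  expect_error(pearson_chi_square(matrix(0, 2, 2)), "zero grand total")
})

test_that("chi-square matches a Monte-Carlo permutation oracle", {
  # a 3x3 cross-tabulation of 135 tumors with healthy expected counts, so
  # the asymptotic null is accurate at Monte-Carlo resolution
  tab <- rbind(c(18, 14, 13), c(12, 18, 15), c(10, 13, 22))
  res <- pearson_chi_square(tab)
  n_perm <- 20000
  withr::with_seed(123, {
    sims <- stats::r2dtable(n_perm, rowSums(tab), colSums(tab))
  })
  obs <- chisq_stat(tab)
  mc_p <- mean(vapply(sims, chisq_stat, numeric(1)) >= obs - 1e-9)
  mc_sd <- sqrt(mc_p * (1 - mc_p) / n_perm)
  expect_lt(abs(res$p.value - mc_p), 3 * mc_sd)
})

test_that("logistic regression equals the closed-form 2x2 odds ratio", {
  tab <- matrix(c(21, 23, 7, 65), nrow = 2) # rows: grade 3, grade 2
  df <- tibble::tibble(
    exposed = rep(c(1, 0, 1, 0), times = c(21, 23, 7, 65)),
    outcome = rep(c(1, 1, 0, 0), times = c(21, 23, 7, 65))
  )
  fit <- logistic_regression(df, outcome ~ exposed)
  est <- tidy(fit)
  expect_equal(
    round(est$odds_ratio[est$term == "exposed"], 6),
    round(odds_ratio_wald(tab)$odds_ratio, 6)
  )
  expect_equal(
    est$std.error[est$term == "exposed"],
    sqrt(sum(1 / tab)),
    tolerance = 1e-6
  )
})

test_that("logistic regression recovers known log-odds and flags degeneracies", {
  withr::with_seed(33, {
    n <- 2000
    x <- rnorm(n)
    eta <- -0.5 + 0.8 * x
    y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  })
  fit <- logistic_regression(tibble::tibble(x = x, y = y), y ~ x)
  est <- tidy(fit)
  slope <- est[est$term == "x", ]
  expect_lt(abs(slope$estimate - 0.8), 2 * slope$std.error)
  expect_gt(glance(fit)$null.deviance, glance(fit)$deviance)

  expect_error(
    logistic_regression(tibble::tibble(x = rnorm(20), y = rep(1, 20)), y ~ x),
    "constant"
  )
  sep <- tibble::tibble(x = c(rnorm(20, -3), rnorm(20, 3)), y = rep(c(0, 1), each = 20))
  expect_error(logistic_regression(sep, y ~ x), "separation.*x")
})

test_that("Kaplan-Meier and log-rank match closed forms", {
  # two identical groups: HR = 1, p = 1
  base <- tibble::tibble(time = c(5, 10, 15, 20, 30), event = c(1, 0, 1, 1, 0))
  rec <- dplyr::bind_rows(
    dplyr::mutate(base, group = "A"),
    dplyr::mutate(base, group = "B")
  )
  res <- km_logrank(rec)
  expect_equal(res$hazard_ratio, 1)
  expect_equal(res$p.value, 1, tolerance = 1e-9)

  # no censoring: KM equals the empirical survivor function
  times <- c(3, 6, 9, 12)
  rec1 <- tibble::tibble(time = times, event = 1, group = "A")
  rec1 <- dplyr::bind_rows(rec1, tibble::tibble(time = 100, event = 1, group = "B"))
  km <- tidy(km_logrank(rec1))
  km_a <- km[km$group == "A", ]
  expect_equal(km_a$estimate, 1 - seq_along(times) / length(times))

  # KM is non-increasing and equals 1 before the first event
  withr::with_seed(12, {
    recr <- tibble::tibble(
      time = runif(60, 1, 100),
      event = rbinom(60, 1, 0.6),
      group = rep(c("A", "B"), 30)
    )
  })
  resr <- km_logrank(recr)
  curves <- tidy(resr)
  for (g in c("A", "B")) {
    est <- curves$estimate[curves$group == g]
    expect_true(all(diff(est) <= 1e-12))
    first_event <- min(curves$time[curves$group == g & curves$n.event > 0])
    expect_true(all(curves$estimate[curves$group == g & curves$time < first_event] == 1))
  }

  expect_error(
    km_logrank(tibble::tibble(time = 1:3, event = 0, group = "A")),
    "No events"
  )
  expect_error(
    km_logrank(tibble::tibble(time = c(-1, 2), event = c(1, 1), group = "A")),
    "positive"
  )
})

test_that("log-rank statistic matches a hand-tabulated risk-set computation", {
  # group A events at 1, 2, 3; group B events at 10, 20, 30; no censoring
  rec <- tibble::tibble(
    time = c(1, 2, 3, 10, 20, 30),
    event = 1,
    group = rep(c("A", "B"), each = 3)
  )
  # direct observed-minus-expected tabulation over the six event times
  o_minus_e <- 0
  v <- 0
  at_risk <- rec
  for (t in sort(rec$time)) {
    n_tot <- sum(at_risk$time >= t)
    n_a <- sum(at_risk$time >= t & at_risk$group == "A")
    d <- sum(rec$time == t)
    d_a <- sum(rec$time == t & rec$group == "A")
    e_a <- d * n_a / n_tot
    o_minus_e <- o_minus_e + (d_a - e_a)
    if (n_tot > 1) {
      v <- v + d * (n_a / n_tot) * (1 - n_a / n_tot) * (n_tot - d) / (n_tot - 1)
    }
  }
  expected_chisq <- o_minus_e^2 / v
  res <- km_logrank(rec)
  expect_equal(res$statistic, expected_chisq, tolerance = 1e-9)
  expect_equal(res$df, 1L)
})

test_that("grade associations cross-tabulate scores against clinical factors", {
  scores <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:30),
    grade = rep(1:3, each = 10)
  )
  clinical <- tibble::tibble(
    sample_id = scores$sample_id,
    mib1 = rep(c("<20%", ">=20%"), 15)
  )
  res <- grade_association(scores, clinical, "mib1")
  expect_equal(sum(res$table), 30)
  expect_equal(res$test$df, 2)
})
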