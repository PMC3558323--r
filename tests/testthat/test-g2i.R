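test_that("local-score smoothing absorbs short islands with agreeing flanks", {
  expect_equal(
    local_score_smooth(c(1L, 1L, 0L, 1L, 1L), min_run = 2),
    rep(1L, 5)
  )
  # a run of exactly min_run is immune
  x <- c(0L, 0L, 1L, 1L, 0L, 0L)
  expect_equal(local_score_smooth(x, min_run = 2), x)
  # disagreeing flanks / chromosome-end runs are left alone
  x <- c(-1L, 1L, 0L, 0L)
  expect_equal(local_score_smooth(x, min_run = 2), x)
})

test_that("local-score smoothing is idempotent and never increases N", {
  count_runs <- function(x) {
    r <- rle(x[!is.na(x)])
    sum(r$values != 0)
  }
  withr::with_seed(11, {
    for (case in 1:50) {
      x <- sample(c(-1L, 0L, 1L), sample(5:40, 1), replace = TRUE)
      once <- local_score_smooth(x, min_run = 2)
      expect_identical(local_score_smooth(once, min_run = 2), once)
      expect_lte(count_runs(once), count_runs(x))
    }
    # also with a larger min_run
    for (case in 1:20) {
      x <- sample(c(-1L, 0L, 1L), 30, replace = TRUE)
      once <- local_score_smooth(x, min_run = 3)
      expect_identical(local_score_smooth(once, min_run = 3), once)
      expect_lte(count_runs(once), count_runs(x))
    }
  })
})

test_that("A is the unweighted mean per-arm altered fraction", {
  map <- tiny_clone_map()
  n <- nrow(map)
  # all-normal profile
  gnl <- gnl_tbl(list(s1 = rep(0L, n)), map)
  expect_equal(fraction_genome_altered(gnl, map)$A, 0)

  # restrict to chr1: 4 clones on p (2 altered), 4 first q clones used below
  # two arms with 2/4 and 1/4 altered -> A = 0.375
  map2 <- map[map$chromosome == "1", ][c(1:4, 5:8), ]
  st <- c(1L, 1L, 0L, 0L, -1L, 0L, 0L, 0L)
  gnl2 <- gnl_tbl(list(s1 = st), map2)
  expect_equal(fraction_genome_altered(gnl2, map2)$A, (0.5 + 0.25) / 2)

  # everything altered
  gnl3 <- gnl_tbl(list(s1 = rep(1L, n)), map)
  expect_equal(fraction_genome_altered(gnl3, map)$A, 1)

  # X-chromosome statuses are excluded
  st_x <- rep(0L, n)
  st_x[map$chromosome == "X"] <- 1L
  expect_equal(fraction_genome_altered(gnl_tbl(list(s1 = st_x), map), map)$A, 0)
})

test_that("flipping a normal clone to altered never decreases A", {
  map <- tiny_clone_map()
  withr::with_seed(5, {
    for (case in 1:20) {
      st <- sample(c(-1L, 0L, 1L), nrow(map), replace = TRUE)
      a0 <- fraction_genome_altered(gnl_tbl(list(s = st), map), map)$A
      normals <- which(st == 0L & is.element(map$chromosome, c("1", "2")))
      if (length(normals) == 0) next
      st2 <- st
      st2[sample(normals, 1)] <- sample(c(-1L, 1L), 1)
      a1 <- fraction_genome_altered(gnl_tbl(list(s = st2), map), map)$A
      expect_gte(a1, a0)
    }
  })
})

test_that("N counts altered runs per autosome", {
  # chr1 = (0,+1,+1,0,-1), chr2 = (+1,+1) -> 3 regions
  map <- tiny_clone_map()[c(1:5, 11:12), ]
  gnl <- gnl_tbl(list(s1 = c(0L, 1L, 1L, 0L, -1L, 1L, 1L)), map)
  expect_equal(count_altered_regions(gnl, map)$N, 3L)

  # all normal
  expect_equal(count_altered_regions(gnl_tbl(list(s1 = rep(0L, 7)), map), map)$N, 0L)

  # whole-arm gains meeting at the centromere merge into one region
  map1 <- tiny_clone_map()[1:10, ]
  expect_equal(count_altered_regions(gnl_tbl(list(s1 = rep(1L, 10)), map1), map1)$N, 1L)

  # X-chromosome runs are not counted
  mapx <- tiny_clone_map()
  stx <- rep(0L, nrow(mapx))
  stx[mapx$chromosome == "X"] <- -1L
  expect_equal(count_altered_regions(gnl_tbl(list(s1 = stx), mapx), mapx)$N, 0L)
})

test_that("runs are bridged over short missing gaps and broken at long ones", {
  map <- tiny_clone_map()[1:10, ]
  # gap of 2 missing inside a gain run: still one region
  st <- c(1L, 1L, NA, NA, 1L, 1L, 0L, 0L, 0L, 0L)
  expect_equal(count_altered_regions(gnl_tbl(list(s = st), map), map)$N, 1L)
  # gap of 5 missing splits the run
  st2 <- c(1L, 1L, NA, NA, NA, NA, NA, 1L, 1L, 0L)
  expect_equal(count_altered_regions(gnl_tbl(list(s = st2), map), map)$N, 2L)
})

test_that("grade classification implements the published rules and boundaries", {
  expect_equal(classify_g2i(0.20, 30), 1L)
  expect_equal(classify_g2i(0.50, 100), 3L)
  # cohort-mean style point: A below a2 excludes grade 3, N above n1 excludes grade 1
  expect_equal(classify_g2i(0.28, 64), 2L)
  # boundary convention: strict on A, inclusive on N
  expect_equal(classify_g2i(0.48, 42), 2L)
  expect_equal(classify_g2i(0.47, 42), 1L)
  expect_equal(classify_g2i(0.36, 65), 3L)
  expect_equal(classify_g2i(0.35, 65), 2L)
  # strict variant turns the inclusive N boundaries into grade 2
  th <- g2i_thresholds(boundary = "strict")
  expect_equal(classify_g2i(0.47, 42, th), 2L)
  expect_equal(classify_g2i(0.36, 65, th), 2L)
  expect_equal(classify_g2i(0.36, 66, th), 3L)
})

test_that("the three grade predicates partition the (A, N) plane", {
  grid <- expand.grid(
    A = c(0, 0.1, 0.34, 0.35, 0.36, 0.47, 0.48, 0.49, 0.73, 1),
    N = c(0L, 10L, 41L, 42L, 43L, 64L, 65L, 66L, 129L, 300L)
  )
  for (boundary in c("prose", "strict")) {
    th <- g2i_thresholds(boundary = boundary)
    g <- classify_g2i(grid$A, grid$N, th)
    expect_true(all(g %in% 1:3))
    expect_equal(length(g), nrow(grid))
    # each point gets exactly one grade and the mapping is deterministic
    expect_identical(g, classify_g2i(grid$A, grid$N, th))
  }
  withr::with_seed(2, {
    g <- classify_g2i(runif(500), sample(0:200, 500, TRUE))
    expect_true(all(g %in% 1:3))
  })
})

test_that("zero-noise archetypes score to their planted truth", {
  cm <- simulate_clone_map(1200, seed = 21)

  # flat archetype: A = 0, N = 0, grade 1
  p <- simulate_profile("flat_a", cm, seed = 1, noise_sd = 0)
  prof <- profiles_tbl(list(s1 = p$log2$log2), cm)
  sc <- suppressWarnings(score_profiles(prof, cm))
  expect_equal(sc$A, 0)
  expect_equal(sc$N, 0L)
  expect_equal(sc$grade, 1L)

  # 1q gain + 16q loss only: exactly one gained and one lost run, A = 2/39
  spec <- bare_archetype("t1q16q_b", noise_sd = 0)
  p2 <- simulate_profile(spec, cm, seed = 2)
  r <- rle(p2$truth$status[is_auto <- cm$chromosome %in% as.character(1:22)])
  expect_equal(sum(r$values == 1L), 1)
  expect_equal(sum(r$values == -1L), 1)
  gained <- cm$chromosome[is_auto][rep(r$values, r$lengths) == 1L]
  expect_true(all(gained == "1"))
  prof2 <- profiles_tbl(list(s1 = p2$log2$log2), cm)
  sc2 <- suppressWarnings(score_profiles(prof2, cm))
  expect_equal(sc2$A, 2 / 39, tolerance = 1e-12)
  expect_equal(sc2$N, 2L)

  # firestorm: N equals the planted run count from an independent truth scan
  p3 <- simulate_profile("firestorm_f", cm, seed = 3, noise_sd = 0)
  runs <- 0L
  for (ch in as.character(1:22)) {
    r <- rle(p3$truth$status[cm$chromosome == ch])
    runs <- runs + sum(r$values != 0L)
  }
  prof3 <- profiles_tbl(list(s1 = p3$log2$log2), cm)
  sc3 <- suppressWarnings(score_profiles(prof3, cm))
  expect_equal(sc3$N, runs)
  expect_equal(sc3$grade, p3$truth$grade)
})

test_that("threshold grid search recovers a planted separation", {
  withr::with_seed(99, {
    n <- 600
    scores <- tibble::tibble(A = runif(n, 0, 0.7), N = sample(0:120, n, TRUE))
    planted <- g2i_thresholds(a1 = 0.4, n1 = 40L, a2 = 0.3, n2 = 60L)
    grade <- classify_g2i(scores$A, scores$N, planted)
    outcome <- rbinom(n, 1, c(0.03, 0.25, 0.8)[grade])
    best <- optimize_thresholds(
      scores, outcome,
      a_grid = seq(0.2, 0.5, by = 0.05), n_grid = seq(20, 80, by = 10)
    )
    expect_lte(abs(best$a1 - 0.4), 0.05 + 1e-9)
    expect_lte(abs(best$a2 - 0.3), 0.05 + 1e-9)
    expect_lte(abs(best$n1 - 40), 10)
    expect_lte(abs(best$n2 - 60), 10)
  })
})

test_that("threshold search is deterministic and rejects degenerate inputs", {
  withr::with_seed(4, {
    scores <- tibble::tibble(A = runif(50), N = sample(0:100, 50, TRUE))
    outcome <- rbinom(50, 1, 0.5) # independent of the scores
  })
  b1 <- optimize_thresholds(scores, outcome, a_grid = c(0.3, 0.5), n_grid = c(40, 60))
  b2 <- optimize_thresholds(scores, outcome, a_grid = c(0.3, 0.5), n_grid = c(40, 60))
  expect_identical(unclass(b1)[c("a1", "n1", "a2", "n2")], unclass(b2)[c("a1", "n1", "a2", "n2")])
  expect_error(
    optimize_thresholds(scores, rep(1, 50), a_grid = 0.3, n_grid = 40),
    "both classes"
  )
  # grid that cannot split anyone: all samples grade 2 for every candidate
  sc1 <- tibble::tibble(A = rep(0.9, 10), N = rep(50L, 10))
  expect_error(
    optimize_thresholds(sc1, rep(c(0, 1), 5), a_grid = 0.1, n_grid = c(10L)),
    "Degenerate"
  )
})

test_that("the grade-model deviance objective matches glm", {
  withr::with_seed(8, {
    grade <- sample(1:3, 200, TRUE)
    outcome <- rbinom(200, 1, c(0.1, 0.3, 0.7)[grade])
  })
  fit <- stats::glm(outcome ~ factor(grade), family = binomial())
  expect_equal(
    g2i:::grade_model_deviance(grade, outcome),
    unname(fit$deviance),
    tolerance = 1e-8
  )
})
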