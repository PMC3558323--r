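test_that("GNL distances behave like 1 - Pearson correlation", {
  map <- tiny_clone_map()
  n <- nrow(map)
  withr::with_seed(1, base <- sample(c(-1L, 0L, 1L), n, replace = TRUE))
  gnl <- gnl_tbl(list(a = base, b = base, c = -base), map)
  d <- as.matrix(gnl_distance(gnl, map))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 2) # negation: r = -1
  expect_equal(diag(d), setNames(rep(0, 3), c("a", "b", "c")))
  expect_equal(d, t(d))

  # orthogonal alteration sets on a 4-clone toy, hand-computed correlation
  map4 <- map[1:4, ]
  x <- c(1L, 0L, 0L, 0L)
  y <- c(0L, 1L, 0L, 0L)
  d4 <- as.matrix(gnl_distance(gnl_tbl(list(x = x, y = y), map4), map4))
  expect_equal(d4["x", "y"], 1 - stats::cor(x, y))
  expect_equal(d4["x", "y"], 1 + 1 / 3)
})

test_that("constant profiles get distance 1 except to their identical twins", {
  map <- tiny_clone_map()
  n <- nrow(map)
  withr::with_seed(2, varying <- sample(c(-1L, 1L), n, replace = TRUE))
  gnl <- gnl_tbl(list(flat1 = rep(0L, n), flat2 = rep(0L, n), v = varying), map)
  expect_warning(d <- as.matrix(gnl_distance(gnl, map)), "Constant")
  expect_equal(d["flat1", "flat2"], 0)
  expect_equal(d["flat1", "v"], 1)
})

test_that("clustering recovers planted partitions and respects k", {
  map <- tiny_clone_map()
  n <- nrow(map)
  withr::with_seed(3, {
    proto1 <- sample(c(0L, 1L), n, replace = TRUE)
    proto2 <- sample(c(0L, -1L), n, replace = TRUE)
    flip <- function(proto) {
      i <- sample(n, 2)
      proto[i] <- sample(c(-1L, 0L, 1L), 2, replace = TRUE)
      proto
    }
    profs <- c(
      setNames(lapply(1:6, function(i) flip(proto1)), paste0("a", 1:6)),
      setNames(lapply(1:6, function(i) flip(proto2)), paste0("b", 1:6))
    )
  })
  gnl <- gnl_tbl(profs, map)
  cl <- cluster_gnl(gnl, map, k = 2)
  truth <- rep(c("a", "b"), each = 6)
  expect_equal(ari(truth, tidy(cl)$cluster), 1)

  # k = n gives singletons; k > n errors
  d <- gnl_distance(gnl, map)
  expect_equal(sort(unique(tidy(agglomerative_cluster(d, k = 12))$cluster)), 1:12)
  expect_error(agglomerative_cluster(d, k = 13), "k must lie")

  # labels are invariant (up to renaming) under sample reordering
  perm <- withr::with_seed(9, sample(names(profs)))
  gnl_perm <- gnl_tbl(profs[perm], map)
  cl_perm <- cluster_gnl(gnl_perm, map, k = 2)
  merged <- merge(tidy(cl), tidy(cl_perm), by = "sample_id")
  expect_equal(ari(merged$cluster.x, merged$cluster.y), 1)
})

test_that("frequency profiles are per-clone fractions, stable under duplication", {
  map <- tiny_clone_map()
  n <- nrow(map)
  st <- replicate(10, integer(n), simplify = FALSE)
  names(st) <- sprintf("s%02d", 1:10)
  for (i in 1:8) st[[i]][3] <- -1L # 8 of 10 lose clone 3
  st[[1]][5] <- 1L
  gnl <- gnl_tbl(st, map)
  fr <- frequency_profile(gnl, map)
  expect_equal(fr$loss_frac[3], 0.8)
  expect_equal(fr$gain_frac[5], 0.1)
  expect_true(all(fr$gain_frac + fr$loss_frac <= 1))

  # single sample: fractions are its indicator vectors
  fr1 <- frequency_profile(gnl_tbl(st[1], map), map)
  expect_equal(fr1$gain_frac, as.numeric(st[[1]] == 1L))
  expect_equal(fr1$loss_frac, as.numeric(st[[1]] == -1L))

  # duplicating every sample leaves fractions unchanged
  dup <- c(st, setNames(st, paste0(names(st), "_dup")))
  expect_equal(frequency_profile(gnl_tbl(dup, map), map)$loss_frac, fr$loss_frac)
})

test_that("recurrent regions are maximal runs above the threshold", {
  map <- tiny_clone_map()[1:10, ] # chr1 only
  freq <- tibble::tibble(
    clone_id = map$clone_id,
    gain_frac = 0,
    loss_frac = rep(0.9, 10)
  )
  rr <- recurrent_regions(freq, map, threshold = 0.8)
  expect_equal(nrow(rr), 1)
  expect_equal(rr$n_clones, 10L)
  expect_equal(rr$direction, "loss")

  # nothing reaches a threshold of 1
  expect_equal(nrow(recurrent_regions(freq, map, threshold = 1)), 0)

  # alternating 0.9/0.5: one run per high clone
  freq$loss_frac <- rep(c(0.9, 0.5), 5)
  rr2 <- recurrent_regions(freq, map, threshold = 0.8)
  expect_equal(nrow(rr2), 5)
  expect_true(all(rr2$n_clones == 1L))
})

test_that("differential regions combine the Fisher and frequency filters", {
  map <- tiny_clone_map()
  n <- nrow(map)
  mk <- function(k, total, clone, dir) {
    st <- lapply(seq_len(total), function(i) {
      v <- integer(n)
      if (i <= k) v[clone] <- dir
      v
    })
    st
  }
  # clone 4 lost in 28/28 of the focal group, 0/107 elsewhere
  g1 <- mk(28, 28, 4, -1L)
  names(g1) <- sprintf("f%03d", seq_along(g1))
  g2 <- mk(0, 107, 4, -1L)
  names(g2) <- sprintf("r%03d", seq_along(g2))
  groups <- setNames(rep(c("focal", "rest"), c(28, 107)), c(names(g1), names(g2)))
  dr <- differential_regions(gnl_tbl(c(g1, g2), map), map, groups, focal = "focal")
  expect_equal(nrow(dr), 1)
  expect_equal(dr$direction, "loss")
  expect_equal(dr$first_index, 4L)
  expect_lt(dr$max_p, 1e-4)
  expect_equal(dr$min_freq, 1)

  # identical compositions: nothing passes
  same <- c(mk(5, 10, 4, -1L), mk(5, 10, 4, -1L))
  names(same) <- sprintf("s%03d", seq_along(same))
  groups2 <- setNames(rep(c("focal", "rest"), each = 10), names(same))
  expect_equal(nrow(differential_regions(gnl_tbl(same, map), map, groups2, focal = "focal")), 0)

  # frequency below the cut-off is excluded no matter the p-value
  g1b <- mk(8, 20, 4, -1L) # freq 0.4
  names(g1b) <- sprintf("f%03d", seq_along(g1b))
  g2b <- mk(0, 200, 4, -1L)
  names(g2b) <- sprintf("r%03d", seq_along(g2b))
  groups3 <- setNames(rep(c("focal", "rest"), c(20, 200)), c(names(g1b), names(g2b)))
  expect_equal(
    nrow(differential_regions(gnl_tbl(c(g1b, g2b), map), map, groups3, focal = "focal")),
    0
  )
})

test_that("Fisher p-values agree with a direct hypergeometric oracle", {
  cases <- list(
    c(28, 28, 0, 107), c(10, 20, 3, 30), c(5, 8, 5, 8), c(1, 15, 9, 12),
    c(50, 80, 20, 120), c(0, 10, 10, 10)
  )
  for (cs in cases) {
    k1 <- cs[1]; n1 <- cs[2]; k2 <- cs[3]; n2 <- cs[4]
    tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2)
    expect_equal(
      stats::fisher.test(tab)$p.value,
      fisher_p_oracle(k1, n1, k2, n2),
      tolerance = 1e-9
    )
  }
})
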