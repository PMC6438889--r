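test_that("circular block bootstrap keeps length, wraps blocks, and covers i.i.d. limit", {
  # single block spanning the run is always a rotation of 1..n
  for (s in 1:5) {
    idx <- circular_block_bootstrap(6, block_length = 6, seed = s)
    expect_length(idx, 6)
    expect_setequal(idx, 1:6)
    expect_true(all(diff(idx) %in% c(1L, 1L - 6L)))
  }
  # length contract across a parameter sweep
  set.seed(1)
  for (i in 1:30) {
    n <- sample(5:200, 1)
    b <- sample.int(n, 1)
    expect_length(circular_block_bootstrap(n, b), n)
  }
  # block length 1 is multinomial resampling: frequencies within 3 SE of 1/n
  set.seed(2)
  n <- 5
  draws <- unlist(lapply(1:2000, function(i) circular_block_bootstrap(n, 1)))
  counts <- tabulate(draws, n)
  expected <- length(draws) / n
  se <- sqrt(length(draws) * (1 / n) * (1 - 1 / n))
  expect_true(all(abs(counts - expected) <= 3 * se))
  expect_error(circular_block_bootstrap(10, 0), "block_length")
  expect_error(circular_block_bootstrap(10, 11), "block_length")
})

test_that("ward partition separates exact duplicates and honours the full cut", {
  set.seed(3)
  base <- matrix(rnorm(40), 20, 2)
  ts <- base[, c(1, 1, 2, 2)] + 0  # two groups of identical columns
  colnames(ts) <- paste0("R", 1:4)
  p <- ward_partition(ts, 2)
  expect_equal(p$labels[1], p$labels[2])
  expect_equal(p$labels[3], p$labels[4])
  expect_false(p$labels[1] == p$labels[3])

  ts2 <- matrix(rnorm(100), 20, 5)
  expect_equal(sort(ward_partition(ts2, 5)$labels), 1:5)

  bad <- cbind(ts2, 0)
  colnames(bad) <- paste0("R", 1:6)
  expect_error(ward_partition(bad, 2), "R6")
})

test_that("ward partition recovers 3 independent latent groups, matching the brute-force best cut", {
  set.seed(4)
  lat <- matrix(rnorm(300 * 3), 300, 3)
  ts <- lat[, c(1, 1, 2, 2, 3, 3)] +
    0.3 * matrix(rnorm(300 * 6), 300, 6)
  p <- ward_partition(ts, 3)$labels

  # oracle: among all assignments of 6 regions to 3 non-empty groups,
  # maximise the total within-cluster correlation
  r <- cor(ts)
  best <- NULL; best_score <- -Inf
  for (code in 0:(3^6 - 1)) {
    lab <- (code %/% 3^(0:5)) %% 3
    if (length(unique(lab)) != 3) next
    score <- sum(r[outer(lab, lab, "==") & upper.tri(r)])
    if (score > best_score) {
      best_score <- score; best <- lab
    }
  }
  expect_equal(mclust::adjustedRandIndex(p, best), 1)
  expect_equal(mclust::adjustedRandIndex(p, c(1, 1, 2, 2, 3, 3)), 1)
})

test_that("ward partitions are invariant to positive affine transforms of the series", {
  set.seed(5)
  ts <- matrix(rnorm(60 * 8), 60, 8)
  p1 <- ward_partition(ts, 3)
  scaled <- sweep(sweep(ts, 2, runif(8, 0.5, 3), "*"), 2, rnorm(8), "+")
  expect_equal(ward_partition(scaled, 3)$labels, p1$labels)
})

test_that("individual stability: bounds, replication granularity, and planted recovery", {
  set.seed(6)
  lat <- matrix(rnorm(120 * 2), 120, 2)
  ts <- lat[, c(1, 1, 1, 2, 2, 2)] + 0.25 * matrix(rnorm(120 * 6), 120, 6)
  colnames(ts) <- paste0("R", 1:6)

  st <- individual_stability(ts, k = 2, n_boot = 100, seed = 1)
  S <- st$values
  expect_true(isSymmetric(S))
  expect_equal(diag(S), setNames(rep(1, 6), colnames(ts)))
  expect_true(all(S >= 0 & S <= 1))
  # entries are exact multiples of 1/n_boot
  expect_equal(S * 100, round(S * 100), tolerance = 1e-12)

  within <- S[1:3, 1:3][upper.tri(matrix(0, 3, 3))]
  between <- S[1:3, 4:6]
  expect_gt(mean(within), 0.95)
  expect_lt(mean(between), 0.05)

  # identical columns always co-cluster
  ts_dup <- ts; ts_dup[, 2] <- ts_dup[, 1]
  st_dup <- individual_stability(ts_dup, k = 3, n_boot = 25, seed = 2)
  expect_equal(st_dup$values[1, 2], 1)

  one <- individual_stability(ts, k = 2, n_boot = 1, seed = 3)
  expect_true(all(one$values %in% c(0, 1)))
})

test_that("group stability: singleton and zero-variance cases collapse to the consensus", {
  set.seed(7)
  lat <- matrix(rnorm(100 * 2), 100, 2)
  ts <- lat[, c(1, 1, 2, 2)] + 0.3 * matrix(rnorm(400), 100, 4)
  st <- individual_stability(ts, k = 2, n_boot = 50, seed = 1)

  gs1 <- group_stability(list(st), k = 2, n_boot_group = 50, seed = 2)
  cons <- consensus_partition(st, 2)
  expect_equal(gs1$values, co_cluster_ref(cons$labels, dimnames(st$values)))

  gs3 <- group_stability(list(st, st, st), k = 2, n_boot_group = 30, seed = 3)
  expect_true(all(gs3$values %in% c(0, 1)))
  expect_error(group_stability(list(), k = 2), "at least one")
})

test_that("two planted subpopulations yield intermediate stability for split pairs", {
  # subjects of type 1 cluster regions as (12)(34); type 2 as (13)(24)
  mk <- function(pairing, seed) {
    set.seed(seed)
    lat <- matrix(rnorm(150 * 2), 150, 2)
    ts <- lat[, pairing] + 0.25 * matrix(rnorm(600), 150, 4)
    colnames(ts) <- paste0("R", 1:4)
    individual_stability(ts, k = 2, n_boot = 60, seed = seed)
  }
  mats <- c(lapply(1:4, function(s) mk(c(1, 1, 2, 2), s)),
            lapply(5:8, function(s) mk(c(1, 2, 1, 2), s)))
  gs <- group_stability(mats, k = 2, n_boot_group = 200, seed = 9)
  # pair (1,2) co-clusters for half the subjects, (1,3) for the other half
  expect_gt(gs$values[1, 2], 0.2); expect_lt(gs$values[1, 2], 0.8)
  expect_gt(gs$values[1, 3], 0.2); expect_lt(gs$values[1, 3], 0.8)
  # (1,4) is split in neither subpopulation
  expect_lt(gs$values[1, 4], 0.2)
})

test_that("consensus partition recovers block-diagonal stability and degenerate cuts", {
  S <- matrix(0, 6, 6)
  S[1:3, 1:3] <- 1; S[4:6, 4:6] <- 1
  p <- consensus_partition(S, 2)
  expect_equal(mclust::adjustedRandIndex(p$labels, rep(1:2, each = 3)), 1)
  expect_equal(consensus_partition(S, 1)$labels, rep(1L, 6))
})

test_that("multiresolution BASC resolves nested planted structure at both scales", {
  # 4 true clusters arranged into 2 superclusters via strong inter-cluster
  # edge effects shared by every group
  effects <- list()
  for (g in c("A", "B")) {
    effects <- c(effects, list(list(pair = c(1, 2), group = g, delta = 0.45),
                               list(pair = c(3, 4), group = g, delta = 0.45)))
  }
  cfg <- tiny_config(group_sizes = c(A = 3, B = 3), n_regions = 16,
                     n_true_clusters = 4, timepoints_per_run = 120,
                     rho_within = 0.7, rho_between = 0.05,
                     edge_effects = effects, seed = 11L)
  co <- simulate_cohort(cfg)
  res <- run_multiresolution(co, grid = c(2, 4), n_boot = 40,
                             n_boot_group = 40, seed = 13)
  expect_named(res, c("2", "4"))
  truth4 <- true_partition(cfg)
  truth2 <- ifelse(truth4 <= 2, 1L, 2L)
  expect_equal(mclust::adjustedRandIndex(res[["4"]]$partition$labels, truth4), 1)
  expect_equal(mclust::adjustedRandIndex(res[["2"]]$partition$labels, truth2), 1)

  res2 <- run_multiresolution(co, grid = c(2, 4), n_boot = 40,
                              n_boot_group = 40, seed = 13)
  expect_identical(lapply(res, `[[`, "partition"),
                   lapply(res2, `[[`, "partition"))
})

test_that("caching reproduces the uncached result byte-for-byte", {
  cfg <- tiny_config(group_sizes = c(A = 2, B = 2), timepoints_per_run = 60,
                     seed = 21L)
  co <- simulate_cohort(cfg)
  cache <- withr::local_tempdir()
  r1 <- run_multiresolution(co, grid = 4, n_boot = 10, n_boot_group = 10,
                            seed = 2, cache_dir = cache)
  r2 <- run_multiresolution(co, grid = 4, n_boot = 10, n_boot_group = 10,
                            seed = 2, cache_dir = cache)
  r3 <- run_multiresolution(co, grid = 4, n_boot = 10, n_boot_group = 10,
                            seed = 2)
  expect_identical(r1, r2)
  expect_identical(r1, r3)
})
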