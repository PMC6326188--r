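test_that("JS metric: identity, disjoint point masses, hand-computed case", {
  p <- random_simplex()
  expect_equal(js_metric(p, p), 0)
  a <- rep(0, 20); a[1] <- 1
  b <- rep(0, 20); b[2] <- 1
  expect_equal(js_metric(a, b), 1)
  # ((.5,.5,0...), (0,.5,.5,0...)) -> sqrt(0.5)
  x <- c(0.5, 0.5, rep(0, 18)); y <- c(0, 0.5, 0.5, rep(0, 17))
  expect_equal(js_metric(x, y), sqrt(0.5), tolerance = 1e-14)
  expect_error(js_metric(c(0.5, 0.6, rep(0, 18)), x), "sum to 1")
  expect_error(js_metric(c(-0.1, 1.1, rep(0, 18)), x), "negative")
})

test_that("JS metric equals a brute-force divergence oracle on random simplex pairs", {
  set.seed(20)
  for (i in 1:1000) {
    p <- random_simplex(); q <- random_simplex()
    expect_lt(abs(js_metric(p, q) - oracle_js(p, q)), 1e-12)
  }
})

test_that("JS metric behaves as a metric on random simplex triples", {
  set.seed(21)
  for (i in 1:200) {
    p <- random_simplex(); q <- random_simplex(); r <- random_simplex()
    expect_equal(js_metric(p, q), js_metric(q, p), tolerance = 1e-14)
    expect_lte(js_metric(p, r), js_metric(p, q) + js_metric(q, r) + 1e-12)
    expect_gt(js_metric(p, q), 0)  # distinct random points
  }
})

test_that("rmsd statistics match an exhaustive-pair oracle and decompose correctly", {
  set.seed(22)
  p <- random_profile(3)
  reps_a <- make_replicates(p, 2, 0.05)
  reps_b <- make_replicates(p, 2, 0.05)
  st <- rmsd_statistics(1, reps_a, reps_b)
  # brute force: 1+1 within pairs, 4 between pairs
  rows <- lapply(c(reps_a, reps_b), function(x) x$values[1, ])
  d <- function(i, j) oracle_js(rows[[i]], rows[[j]])
  within <- c(d(1, 2), d(3, 4))
  between <- c(d(1, 3), d(1, 4), d(2, 3), d(2, 4))
  expect_equal(unname(st["rmsd_within"]), sqrt(mean(within^2)), tolerance = 1e-12)
  expect_equal(unname(st["rmsd_between"]), sqrt(mean(between^2)), tolerance = 1e-12)
  expect_equal(unname(st["rmsd_corrected"]),
               sqrt(mean(between^2)) - sqrt(mean(within^2)), tolerance = 1e-12)

  # identical replicates everywhere -> all zeros
  same <- list(p, p)
  expect_equal(unname(rmsd_statistics(1, same, same)), c(0, 0, 0))
  # sets internally identical but different across -> within 0, corrected = between
  q <- random_profile(3, seed = 23)
  st2 <- rmsd_statistics(1, list(p, p), list(q, q))
  expect_equal(unname(st2["rmsd_within"]), 0)
  expect_equal(unname(st2["rmsd_corrected"]), unname(st2["rmsd_between"]))
  expect_error(rmsd_statistics(1, list(p), list(q, q)), ">= 2 replicates")
})

test_that("permutation test: tie saturation, relabeling count, exact vs oracle", {
  p <- random_profile(2, seed = 24)
  same <- list(p, p, p)
  expect_equal(permutation_test(1, same, same), 1.0)

  # n = m = 2: p is a multiple of 1/6
  set.seed(25)
  reps_a <- make_replicates(p, 2, 0.08)
  reps_b <- make_replicates(p, 2, 0.08)
  pv <- permutation_test(1, reps_a, reps_b)
  expect_true(any(abs(pv - (1:6) / 6) < 1e-12))

  # exhaustive enumeration equals an independent oracle for n = m in {2, 3}
  for (n in 2:3) {
    set.seed(30 + n)
    ra <- make_replicates(p, n, 0.06)
    rb <- make_replicates(random_profile(2, seed = 40 + n), n, 0.06)
    pv <- permutation_test(2, ra, rb)
    rows <- lapply(c(ra, rb), function(x) x$values[2, ])
    k <- 2 * n
    stat <- function(idx_a) {
      idx_b <- setdiff(seq_len(k), idx_a)
      dw <- c(); db <- c()
      for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        dij <- oracle_js(rows[[i]], rows[[j]])
        if ((i %in% idx_a) == (j %in% idx_a)) dw <- c(dw, dij) else db <- c(db, dij)
      }
      sqrt(mean(db^2)) - sqrt(mean(dw^2))
    }
    sets <- combn(k, n)
    stats <- apply(sets, 2, stat)
    oracle_p <- mean(stats >= stats[1] - 1e-12)
    expect_equal(pv, oracle_p, tolerance = 1e-12)
  }
})

test_that("subsampled mode with a generous cap reproduces the exact p-value", {
  p <- random_profile(2, seed = 26)
  set.seed(27)
  ra <- make_replicates(p, 3, 0.06)
  rb <- make_replicates(p, 3, 0.06)
  p_exact <- permutation_test(1, ra, rb, max_permutations = 10000L)
  p_cap <- permutation_test(1, ra, rb, max_permutations = choose(6, 3))
  expect_equal(p_exact, p_cap)
})

test_that("BH q-values match an independent step-up oracle", {
  set.seed(28)
  for (i in 1:50) {
    pv <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(bh_qvalues(pv), oracle_bh(pv), tolerance = 1e-12)
  }
})

test_that("self-comparison with identical replicate sets flags nothing", {
  p <- random_profile(20, seed = 29)
  set.seed(30)
  reps <- make_replicates(p, 6, 0.05)
  cmp <- compare_replicate_sets(p, p, reps, reps)
  expect_equal(cmp$summary$n_significant, 0L)
  expect_true(all(cmp$results$p == 1))
  expect_equal(cmp$summary$mean_js, 0)
})

test_that("permutation p-values are super-uniform under the null", {
  g <- generate_ddg(synthetic_spec(n_sites = 56, seed = 31))
  p <- ddg_to_preferences(g$ddg)
  set.seed(32)
  sg <- calibrate_sigma(p, 0.60)
  pv <- c()
  for (k in 1:5) {
    ra <- make_replicates(p, 6, sg)
    rb <- make_replicates(p, 6, sg)
    pv <- c(pv, compare_replicate_sets(p, p, ra, rb)$results$p)
  }
  n <- length(pv)
  for (t in c(0.05, 0.1, 0.25)) {
    mc_se <- sqrt(t * (1 - t) / n)
    expect_lte(mean(pv <= t), t + 3 * mc_se)
  }
})

test_that("planted disjoint point masses are recovered at high replicate correlation", {
  g <- generate_ddg(synthetic_spec(n_sites = 100, seed = 33))
  p0 <- ddg_to_preferences(g$ddg)
  planted <- seq(5, 95, by = 10)
  pl <- plant_point_masses(p0, planted)
  set.seed(34)
  cmp <- compare_profiles(pl$a, pl$b, target_r = 0.9)
  res <- cmp$results
  expect_gte(sum(res$significant[planted]), 9)
  expect_lte(sum(res$significant[-planted]), 0.05 * 90)
})

test_that("detection power is non-decreasing in replicate correlation", {
  g <- generate_ddg(synthetic_spec(n_sites = 100, seed = 35))
  p0 <- ddg_to_preferences(g$ddg)
  planted <- seq(3, 93, by = 10)
  pl <- plant_point_masses(p0, planted)
  set.seed(36)
  hits <- vapply(c(0.6, 0.9), function(r) {
    sum(compare_profiles(pl$a, pl$b, target_r = r)$results$significant[planted])
  }, 0)
  expect_gte(hits[2], hits[1])
})

test_that("empty alignment and degenerate inputs error clearly", {
  p <- random_profile(3, seed = 37)
  q <- random_profile(4, seed = 38)
  expect_error(compare_profiles(p, q), "differ in length")
})
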