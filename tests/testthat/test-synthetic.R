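test_that("ddG generation: zero-scale limit, determinism, burial-entropy ordering", {
  spec0 <- synthetic_spec(n_sites = 10, burial_fraction = 0,
                          ddg_scale_exposed = 0, ddg_scale_buried = 0, seed = 60)
  g0 <- generate_ddg(spec0)
  expect_true(all(g0$ddg$values == 0))
  p0 <- ddg_to_preferences(g0$ddg)
  expect_true(all(abs(p0$values - 1 / 20) < 1e-12))

  spec <- synthetic_spec(n_sites = 200, seed = 61)
  g1 <- generate_ddg(spec)
  g2 <- generate_ddg(spec)
  expect_identical(g1$ddg$values, g2$ddg$values)
  expect_identical(g1$burial, g2$burial)
  expect_equal(sum(g1$burial), round(0.35 * 200))

  # buried sites have lower preference entropy than exposed sites
  ent <- site_entropy(ddg_to_preferences(g1$ddg))
  expect_lt(mean(ent[g1$burial]), mean(ent[!g1$burial]))
  # profiles are non-uniform but not degenerate
  expect_gt(mean(ent), 1.5)
  expect_lt(mean(ent), 4.2)
})

test_that("toy structures have ideal geometry and pass model invariants", {
  h <- generate_toy_structure(10, "helix")
  d <- sqrt(rowSums(diff(ca_coords(h))^2))
  expect_true(all(abs(d - 3.8) < 0.1))
  s1 <- generate_toy_structure(25, "random_compact", seed = 62)
  s2 <- generate_toy_structure(25, "random_compact", seed = 62)
  expect_identical(ca_coords(s1), ca_coords(s2))
  expect_true(all(vapply(s1$residues, function(r) all(is.finite(r$atoms)), TRUE)))
  expect_true(all(vapply(s1$residues, function(r) "CA" %in% rownames(r$atoms), TRUE)))
  b <- generate_toy_structure(30, "two_helix_bundle")
  net <- build_contacts(b, "sidechain_3p5")
  expect_gt(nrow(net$edges), 0)  # inter-helix side-chain contacts exist
})

test_that("homolog pair: exact substitution count, trivial limits, ground truth", {
  spec <- synthetic_spec(n_sites = 100, divergence_target = 0.3,
                         coordinate_noise = 0.4, seed = 63)
  pair <- generate_homolog_pair(spec)
  expect_equal(length(pair$substituted_sites), 30L)
  expect_equal(sum(pair$seq_a != pair$seq_b), 30L)
  expect_equal(pair$alignment$sequence_divergence,
               sequence_divergence(pair$alignment, pair$seq_a, pair$seq_b))
  # homolog ddG rows are zero at the homolog wildtype
  wtb <- match(pair$seq_b, AA_ALPHABET)
  expect_true(all(abs(pair$ddg_b$values[cbind(1:100, wtb)]) < 1e-12))

  # degenerate spec: identical pair
  spec0 <- synthetic_spec(n_sites = 40, divergence_target = 0,
                          coordinate_noise = 0, seed = 64)
  p0 <- generate_homolog_pair(spec0)
  expect_equal(srmsd(p0$alignment), 0)
  expect_identical(p0$seq_a, p0$seq_b)
  expect_equal(nrow(p0$alignment$pairs), 40L)
})

test_that("full synthetic pipeline is deterministic under a fixed spec and seed", {
  spec <- synthetic_spec(n_sites = 30, divergence_target = 0.2, seed = 65)
  a <- generate_homolog_pair(spec)
  b <- generate_homolog_pair(spec)
  expect_identical(a$ddg_b$values, b$ddg_b$values)
  expect_identical(ca_coords(a$structure_b), ca_coords(b$structure_b))
  expect_identical(a$alignment$pairs, b$alignment$pairs)
})

test_that("mean JS distance between pair profiles grows with divergence", {
  js_at <- function(div) {
    spec <- synthetic_spec(n_sites = 80, divergence_target = div,
                           coordinate_noise = 0.2, seed = 66)
    pair <- generate_homolog_pair(spec)
    pa <- ddg_to_preferences(pair$ddg_a)
    pb <- ddg_to_preferences(pair$ddg_b)
    mean(vapply(seq_len(nrow(pair$alignment$pairs)), function(i)
      js_metric(pa$values[pair$alignment$pairs$site_a[i], ],
                pb$values[pair$alignment$pairs$site_b[i], ]), 0))
  }
  js <- vapply(c(0, 0.3, 0.8), js_at, 0)
  expect_true(all(diff(js) > 0))
})

test_that("planted sites are recovered from the generated homolog pair", {
  planted <- c(4, 11, 23, 37, 42)
  spec <- synthetic_spec(n_sites = 50, divergence_target = 0,
                         coordinate_noise = 0, planted_sites = planted,
                         seed = 67)
  pair <- generate_homolog_pair(spec)
  pa <- ddg_to_preferences(pair$ddg_a)
  pb <- ddg_to_preferences(pair$ddg_b)
  set.seed(68)
  cmp <- compare_profiles(pa, pb, pair$alignment, target_r = 0.9)
  hits <- cmp$results$significant[match(planted, cmp$results$site_a)]
  other <- cmp$results$significant[!cmp$results$site_a %in% planted]
  # redrawn rows are a weaker signal than disjoint point masses: require most
  expect_gte(sum(hits), 3)
  expect_lte(sum(other), 3)
})
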