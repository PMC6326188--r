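rotation_z <- function(th)
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)

transform_structure <- function(s, R, t) {
  res <- s$residues
  for (i in seq_along(res))
    res[[i]]$atoms <- res[[i]]$atoms %*% R +
      matrix(t, nrow(res[[i]]$atoms), 3, byrow = TRUE)
  structure_model(res, protein_id = paste0(s$protein_id, "_t"))
}

test_that("superposition: identity, known-rotation recovery, displaced residue", {
  s <- generate_toy_structure(30, "random_compact", seed = 50)
  sup <- superpose(s, s)
  expect_equal(nrow(sup$alignment$pairs), 30L)
  expect_lt(max(sup$alignment$pairs$ca_dist), 1e-9)
  expect_equal(sup$rotation, diag(3), tolerance = 1e-9)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)

  R <- rotation_z(0.8) %*% matrix(c(1, 0, 0, 0, cos(0.3), -sin(0.3),
                                    0, sin(0.3), cos(0.3)), 3, 3)
  sb <- transform_structure(s, R, c(4, -7, 2))
  sup2 <- superpose(s, sb)
  expect_lt(max(abs(sup2$rotation - t(R))), 1e-6)
  expect_lt(max(sup2$alignment$pairs$ca_dist), 1e-6)

  # one residue displaced 10 angstrom: unpaired, everything else paired
  res <- s$residues
  res[[7]]$atoms <- res[[7]]$atoms + matrix(c(10, 0, 0), nrow(res[[7]]$atoms), 3, byrow = TRUE)
  sd7 <- structure_model(res)
  sup3 <- superpose(s, sd7)
  expect_false(7L %in% sup3$alignment$pairs$site_a)
  expect_equal(nrow(sup3$alignment$pairs), 29L)
  # structures with no common geometry at the 3.5 angstrom scale
  far <- structure_model(lapply(1:4, function(i)
    list(residue_number = i, ins = "", aa = "A",
         atoms = rbind(CA = c(100 * i, 0, 0)))))
  expect_error(superpose(s, far), "no significant superposition")
})

test_that("srmsd is the mean paired distance and is rigid-motion invariant", {
  a <- alignment_map(data.frame(site_a = 1:2, site_b = 1:2, ca_dist = c(1, 3)))
  expect_equal(srmsd(a), 2.0)
  set.seed(51)
  d <- runif(10, 0, 3)
  a2 <- alignment_map(data.frame(site_a = 1:10, site_b = 1:10, ca_dist = d))
  expect_equal(srmsd(a2), mean(d), tolerance = 1e-12)
  expect_error(srmsd(alignment_map(data.frame(site_a = integer(0),
                                              site_b = integer(0),
                                              ca_dist = numeric(0)))),
               "empty")

  # same rigid transform applied to both structures leaves srmsd unchanged
  s <- generate_toy_structure(25, "random_compact", seed = 52)
  res <- s$residues
  set.seed(520)
  for (i in seq_along(res))
    res[[i]]$atoms <- res[[i]]$atoms + matrix(rnorm(length(res[[i]]$atoms), 0, 0.3),
                                              nrow(res[[i]]$atoms), 3)
  sb <- structure_model(res)  # jittered homolog, nonzero deviation
  base <- srmsd(superpose(s, sb)$alignment)
  R <- rotation_z(1.1); t <- c(12, -3, 4)
  base_t <- srmsd(superpose(transform_structure(s, R, t),
                            transform_structure(sb, R, t))$alignment)
  expect_equal(base, base_t, tolerance = 1e-9)
})

test_that("contact dialects apply the 3.5 angstrom rule to the right atoms", {
  # two residues: side chains at parameterizable distance, backbone far apart
  mk <- function(cb_gap, o_n_gap = 10) {
    r1 <- list(residue_number = 1L, ins = "", aa = "A",
               atoms = rbind(N = c(0, 5, 0), CA = c(0, 0, 0),
                             C = c(0, -5, 0), O = c(0, -5, o_n_gap),
                             CB = c(1, 0, 0)))
    r2 <- list(residue_number = 2L, ins = "", aa = "A",
               atoms = rbind(N = c(0, -5, o_n_gap + 3.3), CA = c(20, 0, 0),
                             C = c(20, -5, 0), O = c(20, 5, 0),
                             CB = c(1 + cb_gap, 0, 0)))
    structure_model(list(r1, r2))
  }
  expect_equal(nrow(build_contacts(mk(3.4), "sidechain_3p5")$edges), 1L)
  expect_equal(nrow(build_contacts(mk(3.6), "sidechain_3p5")$edges), 0L)
  # backbone O-N at 3.3 angstrom: edge under allatom only
  s <- mk(3.6)
  expect_equal(nrow(build_contacts(s, "allatom_3p5")$edges), 1L)
  expect_equal(nrow(build_contacts(s, "sidechain_3p5")$edges), 0L)
  # glycine contributes no side-chain atoms
  g <- structure_model(list(
    list(residue_number = 1L, ins = "", aa = "G",
         atoms = rbind(N = c(0, 5, 0), CA = c(0, 0, 0), C = c(0, -5, 0))),
    list(residue_number = 2L, ins = "", aa = "A",
         atoms = rbind(CA = c(1, 0, 0), CB = c(2, 0, 0)))))
  expect_equal(nrow(build_contacts(g, "sidechain_3p5")$edges), 0L)
  expect_equal(nrow(build_contacts(g, "allatom_3p5")$edges), 1L)
  # sequential-neighbor exclusion switch (peptide-bond C-N contacts dropped)
  tmp <- tempfile(fileext = ".pdb")
  h <- read_pdb(write_tiny_pdb(tmp, n_res = 4))
  n_all <- nrow(build_contacts(h, "allatom_3p5")$edges)
  n_noseq <- nrow(build_contacts(h, "allatom_3p5", exclude_sequential = TRUE)$edges)
  expect_lt(n_noseq, n_all)
})

test_that("ensemble contact frequency averages per-model adjacency", {
  base <- generate_toy_structure(12, "random_compact", seed = 53)
  set.seed(54)
  models <- lapply(1:4, function(i) {
    res <- base$residues
    for (k in seq_along(res))
      res[[k]]$atoms <- res[[k]]$atoms + matrix(rnorm(length(res[[k]]$atoms), 0, 0.4),
                                                nrow(res[[k]]$atoms), 3)
    structure_model(res)
  })
  ens <- ensemble_contact_frequency(models, "allatom_3p5")
  expect_true(all(ens$edges$E > 0 & ens$edges$E <= 1))
  # direct averaging oracle
  key_all <- lapply(models, function(m) {
    e <- build_contacts(m, "allatom_3p5")$edges
    paste(e$i, e$j)
  })
  for (k in seq_len(nrow(ens$edges))) {
    key <- paste(ens$edges$i[k], ens$edges$j[k])
    expect_equal(ens$edges$E[k], mean(vapply(key_all, function(ks) key %in% ks, TRUE)))
  }
  # single model: same edges as build_contacts, E = 1
  one <- ensemble_contact_frequency(models[1], "allatom_3p5")
  expect_equal(one$edges[, c("i", "j")], build_contacts(models[[1]], "allatom_3p5")$edges)
  expect_true(all(one$edges$E == 1))
  models[[2]]$residues[[1]]$residue_number <- 99L
  expect_error(ensemble_contact_frequency(models, "allatom_3p5"), "inconsistent")
})

test_that("contact comparison classifies gained/lost/conserved and reproduces worked fractions", {
  expect_equal(round(100 * pooled_rewired_fraction(16, 23, 118)), 25)
  expect_equal(round(100 * pooled_rewired_fraction(31, 36, 105)), 39)

  s <- generate_toy_structure(20, "random_compact", seed = 55)
  net <- build_contacts(s, "allatom_3p5")
  aln <- alignment_map(data.frame(site_a = 1:20, site_b = 1:20, ca_dist = 0))
  seqs <- rep("A", 20)
  cc <- compare_contacts(net, net, aln, seqs, seqs)
  expect_true(all(cc$per_site$f_r[!is.na(cc$per_site$f_r)] == 0))
  expect_equal(unname(cc$totals[c("G", "L")]), c(0L, 0L))
  expect_true(all(cc$per_site$site_class == "conserved_aa"))

  # hand-built nets: site 1 neighbors {2,3} in a, {3,4} in b -> 1 lost, 1
  # gained, 1 conserved, f_r = 2/3; f_r symmetric under swapping homologs
  na <- structure(list(nodes = 1:4,
                       edges = data.frame(i = c(1, 1), j = c(2, 3)),
                       dialect = "allatom_3p5", E = NULL), class = "ssap_contacts")
  nb <- structure(list(nodes = 1:4,
                       edges = data.frame(i = c(1, 1), j = c(3, 4)),
                       dialect = "allatom_3p5", E = NULL), class = "ssap_contacts")
  aln4 <- alignment_map(data.frame(site_a = 1:4, site_b = 1:4, ca_dist = 0))
  sq <- c("A", "C", "D", "E"); sq2 <- c("G", "C", "D", "E")
  cc1 <- compare_contacts(na, nb, aln4, sq, sq2)
  expect_equal(cc1$per_site$f_r[1], 2 / 3)
  expect_equal(cc1$per_site$site_class[1], "substituted")
  cc2 <- compare_contacts(nb, na, aln4, sq2, sq)
  expect_equal(cc2$per_site$f_r, cc1$per_site$f_r)
  expect_equal(cc2$per_site$n_gained, cc1$per_site$n_lost)

  # unaligned neighbor counted as lost under "count", dropped under "ignore"
  aln3 <- alignment_map(data.frame(site_a = c(1, 3, 4), site_b = c(1, 3, 4),
                                   ca_dist = 0))
  ccc <- compare_contacts(na, nb, aln3, sq, sq2)
  expect_equal(ccc$per_site$n_lost[1], 1L)  # neighbor 2 unaligned -> lost
  cci <- compare_contacts(na, nb, aln3, sq, sq2, unaligned = "ignore")
  expect_equal(cci$per_site$n_lost[1], 0L)
})

test_that("sequence divergence counts differing equivalent pairs", {
  aln <- alignment_map(data.frame(site_a = 1:10, site_b = 1:10, ca_dist = 0))
  a <- rep("A", 10); b <- a; b[c(2, 5, 9)] <- "W"
  expect_equal(sequence_divergence(aln, a, a), 0)
  expect_equal(sequence_divergence(aln, a, b), 0.3)
  expect_equal(sequence_divergence(aln, a, rep("Y", 10)), 1)
})

test_that("network proximity test: hand-countable paths and Dijkstra oracle", {
  # path graph 1-2-3-4-5
  path_net <- structure(list(nodes = 1:5,
                             edges = data.frame(i = 1:4, j = 2:5),
                             dialect = "allatom_3p5", E = NULL),
                        class = "ssap_contacts")
  set.seed(56)
  r <- network_proximity_test(path_net, query_sites = 1, anchor_sites = 5,
                              n_random = 200)
  expect_equal(r$observed, 4)
  r0 <- network_proximity_test(path_net, query_sites = 3, anchor_sites = c(3, 5),
                               n_random = 200)
  expect_equal(r0$observed, 0)
  expect_equal(r0$p_value, (sum(r0$null <= 0) + 1) / (length(r0$null) + 1))

  # weighted shortest paths vs exhaustive path enumeration on random graphs
  set.seed(57)
  for (trial in 1:10) {
    nn <- sample(5:8, 1)
    all_pairs <- t(combn(nn, 2))
    take <- sample(nrow(all_pairs), size = max(nn, rbinom(1, nrow(all_pairs), 0.5)))
    edges <- data.frame(i = all_pairs[take, 1], j = all_pairs[take, 2])
    E <- runif(nrow(edges), 0.05, 0.95)
    net <- structure(list(nodes = 1:nn,
                          edges = cbind(edges, E = E),
                          dialect = "allatom_3p5", E = E),
                     class = "ssap_contacts")
    from <- 1; to <- nn
    oracle <- oracle_shortest_path(edges, 1 - E + 1e-12, from, to, nn)
    res <- suppressWarnings(
      network_proximity_test(net, from, to, n_random = 10, weighted = TRUE))
    if (is.finite(oracle)) expect_equal(res$observed, oracle, tolerance = 1e-9)
    # unweighted hop count oracle too
    oracle_u <- oracle_shortest_path(edges, rep(1, nrow(edges)), from, to, nn)
    res_u <- suppressWarnings(
      network_proximity_test(net, from, to, n_random = 10))
    if (is.finite(oracle_u)) expect_equal(res_u$observed, oracle_u)
  }
  expect_error(network_proximity_test(path_net, 1:3, 3:5, 10), "exceed")
})

test_that("divergence-binned summary: degenerate bins and bootstrap coverage", {
  # constant values -> zero-width CI
  set.seed(58)
  out <- divergence_binned_summary(runif(30, 0, 0.1), rep(2.5, 30),
                                   breaks = c(0, 0.1), n_boot = 200)
  expect_equal(out$mean, 2.5)
  expect_equal(out$ci_lo, 2.5); expect_equal(out$ci_hi, 2.5)
  # single record bin: mean = value, degenerate CI; empty bin reported as NA
  out2 <- divergence_binned_summary(c(0.05, 0.35), c(1, 7),
                                    breaks = seq(0, 1, 0.1), n_boot = 100)
  expect_equal(out2$n, c(1L, 0L, 0L, 1L, rep(0L, 6)))
  expect_equal(out2$mean[4], 7); expect_equal(out2$ci_lo[4], 7)
  expect_true(is.na(out2$mean[2]))
  # divergence exactly at the top break lands in the last bin
  out3 <- divergence_binned_summary(1.0, 3, breaks = seq(0, 1, 0.5), n_boot = 10)
  expect_equal(out3$n, c(0L, 1L))
})

test_that("bootstrap confidence intervals cover the true mean about 95% of the time", {
  set.seed(59)
  trials <- 1000L
  hits <- 0L
  for (i in seq_len(trials)) {
    v <- rnorm(50, mean = 3, sd = 1)
    out <- divergence_binned_summary(rep(0.05, 50), v, breaks = c(0, 0.1),
                                     n_boot = 400)
    if (out$ci_lo <= 3 && 3 <= out$ci_hi) hits <- hits + 1L
  }
  expect_lt(abs(hits / trials - 0.95), 0.02)
})

test_that("site entropy: uniform, point mass, two-state rows", {
  v <- matrix(1 / 20, 1, 20)
  v <- rbind(v, c(1, rep(0, 19)), c(0.5, 0.5, rep(0, 18)))
  v <- v / rowSums(v)
  p <- preference_profile(v)
  expect_equal(site_entropy(p), c(log2(20), 0, 1), tolerance = 1e-12)
})
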