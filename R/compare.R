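#' Jensen-Shannon metric between two discrete distributions
#'
#' The square root of the Jensen-Shannon divergence with base-2 logarithms, a
#' true metric on the probability simplex bounded in \[0, 1\]: 0 iff p = q, 1
#' for distributions with disjoint support.
#'
#' @param p,q non-negative vectors of equal length, each summing to 1 within
#'   1e-6.
#' @return The JS distance (numeric scalar in \[0, 1\]).
#' @export
js_metric <- function(p, q) {
  if (length(p) != length(q)) stop("p and q have different lengths")
  if (any(p < 0) || any(q < 0)) stop("negative probability value(s)")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("inputs must sum to 1 within 1e-6")
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log2(a[i] / m[i]))
  }
  d2 <- 0.5 * kl(p) + 0.5 * kl(q)
  sqrt(max(d2, 0))
}

# all pairwise squared JS distances between the rows of X (k x 20);
# returns a vector aligned with combn(k, 2) column order
pairwise_js2 <- function(X) {
  k <- nrow(X)
  pr <- utils::combn(k, 2L)
  P <- X[pr[1L, ], , drop = FALSE]
  Q <- X[pr[2L, ], , drop = FALSE]
  M <- (P + Q) / 2
  t1 <- P * log2(P / M); t1[P == 0] <- 0
  t2 <- Q * log2(Q / M); t2[Q == 0] <- 0
  pmax(0.5 * rowSums(t1) + 0.5 * rowSums(t2), 0)
}

# relabeling machinery: all (or subsampled) assignments of n+m pooled
# replicates into groups of sizes n and m, as a within-pair indicator matrix.
# Returns list(W = n_pairs x R indicator, n_within, n_between, exact)
relabeling_masks <- function(n, m, max_permutations = 10000L) {
  k <- n + m
  total <- choose(k, n)
  exact <- total <= max_permutations
  if (exact) {
    sets <- utils::combn(k, n)
  } else {
    sets <- cbind(seq_len(n),
                  replicate(max_permutations - 1L, sort(sample.int(k, n))))
  }
  R <- ncol(sets)
  lab <- matrix(FALSE, k, R)
  lab[cbind(as.vector(sets), rep(seq_len(R), each = n))] <- TRUE
  pr <- utils::combn(k, 2L)
  W <- lab[pr[1L, ], , drop = FALSE] == lab[pr[2L, ], , drop = FALSE]
  storage.mode(W) <- "double"
  list(W = W, n_within = choose(n, 2) + choose(m, 2), n_between = n * m,
       n_pairs = ncol(pr), exact = exact, n_relabelings = R)
}

# core statistic for one or many sites: given d2 (n_pairs x L matrix of squared
# JS distances over pooled replicate pairs) and masks, return the R x L matrix
# of RMSD_corrected statistics (row 1 = identity labeling = observed)
rmsd_corrected_stats <- function(d2, masks) {
  d2 <- as.matrix(d2)
  tot <- colSums(d2)
  Sw <- crossprod(masks$W, d2)                 # R x L within sums
  Sb <- matrix(tot, nrow(Sw), ncol(Sw), byrow = TRUE) - Sw
  sqrt(Sb / masks$n_between) - sqrt(Sw / masks$n_within)
}

site_rows <- function(reps, site) {
  do.call(rbind, lapply(reps, function(p) p$values[site, ]))
}

#' Within/between replicate RMSD statistics at one site
#'
#' Given two sets of replicate profiles, computes at a site the
#' root-mean-square of JS distances over all within-set replicate pairs
#' (pooled from both sets: C(n,2) + C(m,2) pairs), over all n x m cross-set
#' pairs, and their difference `rmsd_corrected = rmsd_between - rmsd_within` —
#' the measurement-error-corrected distance whose permutation null defines
#' site significance.
#'
#' @param site site index (applied to both sets) or a length-2 vector
#'   `c(site_a, site_b)` for aligned sites.
#' @param reps_a,reps_b lists of `ssap_profile` replicates (>= 2 each).
#' @return Named numeric vector `rmsd_within`, `rmsd_between`, `rmsd_corrected`.
#' @export
rmsd_statistics <- function(site, reps_a, reps_b) {
  if (length(reps_a) < 2 || length(reps_b) < 2)
    stop("need >= 2 replicates in each set")
  site <- rep(site, length.out = 2L)
  X <- rbind(site_rows(reps_a, site[1]), site_rows(reps_b, site[2]))
  n <- length(reps_a); m <- length(reps_b)
  d2 <- pairwise_js2(X)
  pr <- utils::combn(n + m, 2L)
  within <- (pr[1, ] <= n) == (pr[2, ] <= n)
  rw <- sqrt(mean(d2[within]))
  rb <- sqrt(mean(d2[!within]))
  c(rmsd_within = rw, rmsd_between = rb, rmsd_corrected = rb - rw)
}

#' Exact permutation test for a site's SSAP difference
#'
#' Relabels the pooled n + m replicates into groups of sizes n and m in every
#' distinct way (exact when C(n+m, n) <= `max_permutations`, otherwise a
#' uniform random subsample that always includes the identity labeling) and
#' recomputes `rmsd_corrected` for each. The p-value is the fraction of
#' relabelings whose statistic is >= the observed one (ties counted, identity
#' included, so p >= 1 / n_relabelings > 0).
#'
#' @inheritParams rmsd_statistics
#' @param max_permutations cap on enumerated relabelings (default 10000).
#' @return p-value in (0, 1].
#' @export
permutation_test <- function(site, reps_a, reps_b, max_permutations = 10000L) {
  if (length(reps_a) < 2 || length(reps_b) < 2)
    stop("need >= 2 replicates in each set")
  site <- rep(site, length.out = 2L)
  n <- length(reps_a); m <- length(reps_b)
  X <- rbind(site_rows(reps_a, site[1]), site_rows(reps_b, site[2]))
  masks <- relabeling_masks(n, m, max_permutations)
  stats <- rmsd_corrected_stats(pairwise_js2(X), masks)[, 1L]
  mean(stats >= stats[1L] - 1e-12)
}

#' Benjamini-Hochberg q-values
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, the step-up false
#' discovery rate control applied across the sites of one pairwise comparison.
#'
#' @param p vector of p-values.
#' @return q-values, same length.
#' @export
bh_qvalues <- function(p) stats::p.adjust(p, method = "BH")

#' Compare two SSAP profiles site by site
#'
#' The replicate-aware comparison pipeline: calibrate the noise scale of each
#' profile so simulated replicates reach `target_r` mean Pearson correlation
#' with their source (unless `sigma_a`/`sigma_b` are supplied), simulate
#' `n_replicates` per profile, and for every equivalent-site pair compute the
#' point JS distance between the source rows, the within/between replicate
#' RMSD statistics, and the exact permutation p-value of `rmsd_corrected`;
#' finally control the FDR across sites with Benjamini-Hochberg at level
#' `alpha`.
#'
#' @param profile_a,profile_b `ssap_profile` objects.
#' @param alignment an `ssap_alignment` mapping sites of a to sites of b; by
#'   default the identity map (profiles must then have equal length).
#' @param target_r target mean replicate-to-source Pearson correlation
#'   (default 0.60).
#' @param alpha FDR significance level (default 0.05).
#' @param n_replicates replicates simulated per profile (default 6). With an
#'   even n = m split the statistic is invariant under swapping the two
#'   groups, so every relabeling ties with its complement and the smallest
#'   attainable p is 2 / C(2n, n): 1/462 at the default, coarse 1/3 in the
#'   minimal paired-replicate mode (`n_replicates = 2`), which is retained
#'   for compatibility with measured replicate pairs.
#' @param n_multinomial multinomial sample size of the noise model (default
#'   100).
#' @param max_permutations cap on enumerated relabelings per site.
#' @param sigma_a,sigma_b optional pre-calibrated noise scales (skip
#'   calibration).
#' @return An object of class `ssap_comparison`: list with `results` (one row
#'   per compared site: site_a, site_b, js, rmsd_within, rmsd_between,
#'   rmsd_corrected, p, q, significant), `summary` (n_sites, n_significant,
#'   fraction_significant, mean_js), and the sigmas used.
#' @export
compare_profiles <- function(profile_a, profile_b, alignment = NULL,
                             target_r = 0.60, alpha = 0.05,
                             n_replicates = 6L, n_multinomial = 100L,
                             max_permutations = 10000L,
                             sigma_a = NULL, sigma_b = NULL) {
  stopifnot(inherits(profile_a, "ssap_profile"),
            inherits(profile_b, "ssap_profile"))
  if (is.null(alignment)) {
    if (nrow(profile_a$values) != nrow(profile_b$values))
      stop("profiles differ in length; supply an alignment map")
    alignment <- alignment_map(
      data.frame(site_a = seq_len(nrow(profile_a$values)),
                 site_b = seq_len(nrow(profile_b$values)),
                 ca_dist = 0))
  }
  stopifnot(inherits(alignment, "ssap_alignment"))
  if (nrow(alignment$pairs) == 0) stop("empty alignment: nothing to compare")

  if (is.null(sigma_a))
    sigma_a <- calibrate_sigma(profile_a, target_r, n_multinomial)
  if (is.null(sigma_b))
    sigma_b <- calibrate_sigma(profile_b, target_r, n_multinomial)
  pa <- replicate_sim_params(n_multinomial, sigma_a, max(2L, n_replicates))
  pb <- replicate_sim_params(n_multinomial, sigma_b, max(2L, n_replicates))
  reps_a <- lapply(seq_len(pa$n_replicates), function(i)
    simulate_replicate(profile_a, pa))
  reps_b <- lapply(seq_len(pb$n_replicates), function(i)
    simulate_replicate(profile_b, pb))
  compare_replicate_sets(profile_a, profile_b, reps_a, reps_b, alignment,
                         alpha, max_permutations,
                         sigma_a = sigma_a, sigma_b = sigma_b)
}

#' Site-by-site comparison of two existing replicate sets
#'
#' The statistical core of [compare_profiles()], exposed for callers that
#' simulate (or measure) replicates themselves.
#'
#' @inheritParams compare_profiles
#' @param reps_a,reps_b lists of `ssap_profile` replicates (>= 2 each).
#' @param sigma_a,sigma_b recorded in the output for provenance (optional).
#' @return An `ssap_comparison` (see [compare_profiles()]).
#' @export
compare_replicate_sets <- function(profile_a, profile_b, reps_a, reps_b,
                                   alignment = NULL, alpha = 0.05,
                                   max_permutations = 10000L,
                                   sigma_a = NA_real_, sigma_b = NA_real_) {
  if (length(reps_a) < 2 || length(reps_b) < 2)
    stop("need >= 2 replicates in each set")
  if (is.null(alignment))
    alignment <- alignment_map(
      data.frame(site_a = seq_len(nrow(profile_a$values)),
                 site_b = seq_len(nrow(profile_b$values)),
                 ca_dist = 0))
  prs <- alignment$pairs
  if (nrow(prs) == 0) stop("empty alignment: nothing to compare")
  n <- length(reps_a); m <- length(reps_b)
  masks <- relabeling_masks(n, m, max_permutations)

  A <- lapply(reps_a, function(p) p$values)
  B <- lapply(reps_b, function(p) p$values)
  L <- nrow(prs)
  d2 <- matrix(0, masks$n_pairs, L)
  js <- numeric(L)
  for (i in seq_len(L)) {
    X <- rbind(do.call(rbind, lapply(A, function(v) v[prs$site_a[i], ])),
               do.call(rbind, lapply(B, function(v) v[prs$site_b[i], ])))
    d2[, i] <- pairwise_js2(X)
    js[i] <- js_metric(profile_a$values[prs$site_a[i], ],
                       profile_b$values[prs$site_b[i], ])
  }
  stats <- rmsd_corrected_stats(d2, masks)
  obs <- stats[1L, ]
  p <- colMeans(stats >= matrix(obs, nrow(stats), L, byrow = TRUE) - 1e-12)

  pr2 <- utils::combn(n + m, 2L)
  within <- (pr2[1, ] <= n) == (pr2[2, ] <= n)
  rw <- sqrt(colMeans(d2[within, , drop = FALSE]))
  rb <- sqrt(colMeans(d2[!within, , drop = FALSE]))

  q <- bh_qvalues(p)
  res <- data.frame(site_a = prs$site_a, site_b = prs$site_b, js = js,
                    rmsd_within = rw, rmsd_between = rb,
                    rmsd_corrected = rb - rw, p = p, q = q,
                    significant = q <= alpha)
  structure(list(
    results = res,
    summary = list(n_sites = L,
                   n_significant = sum(res$significant),
                   fraction_significant = mean(res$significant),
                   mean_js = mean(js)),
    alpha = alpha, sigma_a = sigma_a, sigma_b = sigma_b,
    n_replicates = c(a = n, b = m),
    exact = masks$exact, n_relabelings = masks$n_relabelings),
    class = "ssap_comparison")
}

#' @export
print.ssap_comparison <- function(x, ...) {
  cat(sprintf(
    "SSAP comparison: %d sites, %d significant (%.1f%%) at FDR %.2f; mean JS %.3f\n",
    x$summary$n_sites, x$summary$n_significant,
    100 * x$summary$fraction_significant, x$alpha, x$summary$mean_js))
  invisible(x)
}
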