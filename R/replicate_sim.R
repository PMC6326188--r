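#' Parameters of the replicate-profile noise simulator
#'
#' Replicates of an SSAP profile emulate experimental measurement error: per
#' site, a multinomial sample of size `n_multinomial` (default 100) is drawn
#' around the site's preferences, converted to fractions, perturbed with
#' Gaussian noise of scale `sigma`, clamped at 0 and renormalized over the 20
#' amino acids. Increasing `sigma` decreases the replicate-to-source Pearson
#' correlation, which is how a target correlation is dialed in
#' ([calibrate_sigma()]).
#'
#' @param n_multinomial multinomial sample size per site (>= 1; default 100).
#' @param sigma Gaussian noise standard deviation (>= 0).
#' @param n_replicates replicates per profile (>= 2; default 2).
#' @return An object of class `ssap_repsim_params`.
#' @export
replicate_sim_params <- function(n_multinomial = 100L, sigma = 0.05,
                                 n_replicates = 2L) {
  stopifnot(n_multinomial >= 1, sigma >= 0, n_replicates >= 2)
  structure(list(n_multinomial = as.integer(n_multinomial), sigma = sigma,
                 n_replicates = as.integer(n_replicates)),
            class = "ssap_repsim_params")
}

#' Simulate one replicate of an SSAP profile
#'
#' Uses the current RNG state; callers wanting reproducibility set the seed.
#' A site whose post-clamp row sums to zero has its noise resampled (up to 100
#' times, then an error is raised).
#'
#' @param profile an `ssap_profile`.
#' @param params a [replicate_sim_params()].
#' @return An `ssap_profile` replicate.
#' @export
simulate_replicate <- function(profile, params = replicate_sim_params()) {
  stopifnot(inherits(profile, "ssap_profile"),
            inherits(params, "ssap_repsim_params"))
  L <- nrow(profile$values)
  n <- params$n_multinomial
  out <- matrix(0, L, 20L)
  for (r in seq_len(L)) {
    m <- as.vector(stats::rmultinom(1L, n, prob = profile$values[r, ])) / n
    s <- 0
    for (try in seq_len(100L)) {
      v <- pmax(m + stats::rnorm(20L, 0, params$sigma), 0)
      s <- sum(v)
      if (s > 0) break
    }
    if (s == 0) stop("site ", r, ": row sums to 0 after 100 noise resamples")
    out[r, ] <- v / s
  }
  preference_profile(out, wildtype_aa = profile$sites$wt_aa,
                     residue_number = profile$sites$residue_number,
                     protein_id = paste0(profile$protein_id, "_rep"))
}

#' Pearson correlation between two SSAP profiles
#'
#' Computed over all L x 20 entries flattened (the convention used when
#' replicate correlations of mutational-scanning profiles are reported).
#'
#' @param a,b `ssap_profile` objects of equal dimensions.
#' @return Pearson r in \[-1, 1\].
#' @export
profile_correlation <- function(a, b) {
  stopifnot(inherits(a, "ssap_profile"), inherits(b, "ssap_profile"))
  if (!all(dim(a$values) == dim(b$values)))
    stop("profiles have different dimensions")
  x <- as.vector(a$values); y <- as.vector(b$values)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a flattened profile: correlation undefined")
  stats::cor(x, y)
}

# mean replicate-to-source correlation at a given sigma
mean_replicate_correlation <- function(profile, sigma, n_multinomial = 100L,
                                       n_reps = 20L) {
  params <- replicate_sim_params(n_multinomial, sigma, 2L)
  mean(vapply(seq_len(n_reps), function(i)
    profile_correlation(profile, simulate_replicate(profile, params)),
    0))
}

#' Calibrate the noise scale to a target replicate correlation
#'
#' Finds, by bisection, the `sigma` at which the mean replicate-to-source
#' Pearson correlation over `n_reps` simulated replicates is within `tol` of
#' `target_r`, exploiting the monotone decrease of correlation in `sigma`.
#' The achievable range is bounded above by the multinomial-only ceiling
#' (sigma = 0); a `target_r` outside the attainable range is an error that
#' reports the range.
#'
#' @param profile an `ssap_profile`.
#' @param target_r target mean Pearson correlation, in (0, 1).
#' @param n_multinomial multinomial sample size (default 100).
#' @param n_reps replicates per correlation estimate (default 20).
#' @param tol convergence tolerance on the correlation (default 0.01).
#' @param sigma_max upper bisection bound (default 1).
#' @param max_iter bisection iteration cap (default 40).
#' @return The calibrated sigma (numeric scalar).
#' @export
calibrate_sigma <- function(profile, target_r, n_multinomial = 100L,
                            n_reps = 20L, tol = 0.01, sigma_max = 1,
                            max_iter = 40L) {
  stopifnot(target_r > 0, target_r < 1)
  r_lo <- mean_replicate_correlation(profile, 0, n_multinomial, n_reps)
  if (target_r > r_lo + tol)
    stop(sprintf("target_r %.3f above the multinomial-only ceiling %.3f", target_r, r_lo))
  if (target_r >= r_lo - tol) return(0)
  r_hi <- mean_replicate_correlation(profile, sigma_max, n_multinomial, n_reps)
  if (target_r < r_hi - tol)
    stop(sprintf("target_r %.3f below reachable range [%.3f, %.3f] for sigma <= %g",
                 target_r, r_hi, r_lo, sigma_max))
  lo <- 0; hi <- sigma_max
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r_mid <- mean_replicate_correlation(profile, mid, n_multinomial, n_reps)
    if (abs(r_mid - target_r) <= tol / 2) return(mid)
    if (r_mid > target_r) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
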