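#' Specify a stability-to-fitness model
#'
#' Three biophysical models map a mutation's change in folding free energy
#' (ddG, kcal/mol) to the folding probability Pf used as the fitness proxy:
#'
#' * `threshold`: Pf = exp(-(ddG + dG_wt)/kT) / (1 + exp(-(ddG + dG_wt)/kT)),
#'   a sigmoid encoding a critical stability level below which fitness drops.
#'   `dG_wt` is the wildtype folding free energy; the common approximation
#'   dG_wt ~ 0 is the default but the parameter is exposed so its sensitivity
#'   can be probed (varying it shifts the sigmoid midpoint by -dG_wt).
#' * `maximum`: Pf = alpha * exp(-lambda * ddG) (exponent n = 1) — stabilizing
#'   mutations translate proportionally into a larger propensity to fold.
#' * `optimum`: Pf = alpha * exp(-lambda * ddG^2) (exponent n = 2) — a Gaussian
#'   around the wildtype stability; deviations in either direction are
#'   unfavorable.
#'
#' `alpha` cancels under the per-site preference normalization and is kept
#' only for completeness. `kT` defaults to 0.593 kcal/mol (approx. 298 K);
#' `lambda` defaults to 1 for the power models.
#'
#' @param model `"threshold"`, `"maximum"` or `"optimum"`.
#' @param kT thermal energy, kcal/mol (> 0).
#' @param lambda rate constant of the power models (> 0).
#' @param alpha positive scale constant (cancels in preferences).
#' @param dg_wt wildtype folding free energy, kcal/mol (threshold model only).
#' @return An object of class `ssap_fitness_model`.
#' @export
fitness_model_spec <- function(model = c("threshold", "maximum", "optimum"),
                               kT = 0.593, lambda = 1, alpha = 1, dg_wt = 0) {
  model <- match.arg(model)
  stopifnot(kT > 0, lambda > 0, alpha > 0, is.finite(dg_wt))
  n_exponent <- switch(model, maximum = 1L, optimum = 2L, NA_integer_)
  structure(list(model = model, kT = kT, lambda = lambda, alpha = alpha,
                 dg_wt = dg_wt, n_exponent = n_exponent),
            class = "ssap_fitness_model")
}

#' Folding probability under a stability-to-fitness model
#'
#' Vectorized over `ddg`. The threshold sigmoid is computed overflow-safely
#' (never 0 or NaN for finite input); the power models return
#' `alpha * exp(-lambda * ddg^n)`.
#'
#' @param ddg change(s) in folding free energy, kcal/mol; must be finite.
#' @param spec a [fitness_model_spec()].
#' @return Numeric vector of Pf values (> 0; <= 1 for the threshold model).
#' @export
folding_probability <- function(ddg, spec = fitness_model_spec()) {
  stopifnot(inherits(spec, "ssap_fitness_model"))
  if (!all(is.finite(ddg))) stop("non-finite ddG value(s)")
  exp(log_folding_probability(ddg, spec))
}

# log Pf, the numerically safe primitive every normalization goes through
log_folding_probability <- function(ddg, spec) {
  switch(spec$model,
    threshold = stats::plogis(-(ddg + spec$dg_wt) / spec$kT, log.p = TRUE),
    maximum = log(spec$alpha) - spec$lambda * ddg,
    optimum = log(spec$alpha) - spec$lambda * ddg^2
  )
}

#' Convert a ddG matrix to an SSAP profile
#'
#' Per site r and amino acid a the preference is
#' pi(r, a) = Pf(ddG(r, a)) / sum_j Pf(ddG(r, j)), normalized over the 20
#' amino acids. Rows are computed in log space with log-sum-exp so a site with
#' one large destabilizing outlier never flushes to zero; every output row
#' sums to 1, and the result is independent of `alpha`. For the maximum model
#' the row is exactly the softmax of `-lambda * ddg`.
#'
#' @param ddg a [ddg_matrix()].
#' @param spec a [fitness_model_spec()].
#' @return An `ssap_profile` with the same sites as `ddg`.
#' @export
ddg_to_preferences <- function(ddg, spec = fitness_model_spec()) {
  stopifnot(inherits(ddg, "ssap_ddg"))
  lp <- log_folding_probability(ddg$values, spec)
  mx <- apply(lp, 1L, max)
  w <- exp(lp - mx)
  pi <- w / rowSums(w)
  preference_profile(pi, wildtype_aa = ddg$sites$wt_aa,
                     residue_number = ddg$sites$residue_number,
                     protein_id = ddg$protein_id)
}
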