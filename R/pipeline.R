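#' Run the full divergence analysis on one homolog pair
#'
#' Chains the stages end to end for one pair: obtain ddG matrices (from files
#' or a synthetic spec), convert them to SSAP profiles under the chosen
#' stability-to-fitness model, obtain an equivalent-site alignment (from file,
#' by superposition of the structures, or the synthetic ground truth), run the
#' replicate-aware per-site comparison with FDR control, and measure sequence
#' divergence, sRMSD and (when structures are available) contact rewiring.
#'
#' `config` is a named list (or a YAML file read with [read_config()]) with:
#'
#' * `pair_id` — identifier (default "pair").
#' * either `synthetic` — an [synthetic_spec()] (or list of its arguments) —
#'   or `ddg_a`/`ddg_b` (paths or `ssap_ddg` objects) plus one of `alignment`
#'   (path or `ssap_alignment`) or `pdb_a`/`pdb_b` (paths or `ssap_structure`).
#' * `model` — a [fitness_model_spec()] or list of its arguments
#'   (default threshold model).
#' * `target_r` (0.60), `alpha` (0.05), `n_replicates` (5),
#'   `n_multinomial` (100), `contact_dialect` ("allatom_3p5"),
#'   `min_coverage` (0.95), `seed` (optional).
#' * `out_dir` — optional; per-site TSV and a summary row are written there.
#'
#' A pair whose alignment covers less than `min_coverage` of either structure
#' is rejected with an error (cohort runs skip it with a log message).
#'
#' @param config named list as above.
#' @return An object of class `ssap_pair_record`: list with `record` (one-row
#'   data.frame: pair_id, sequence_divergence, srmsd, n_sites_compared,
#'   n_significant, fraction_significant, mean_js, model), `comparison`
#'   (the `ssap_comparison`), `contacts` (an `ssap_contact_comparison` or
#'   NULL), `alignment`, `config`.
#' @export
run_pair <- function(config) {
  cfg <- config
  pair_id <- cfg$pair_id %||% "pair"
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  model <- as_model_spec(cfg$model)
  target_r <- cfg$target_r %||% 0.60
  alpha <- cfg$alpha %||% 0.05
  n_replicates <- cfg$n_replicates %||% 6L
  n_multinomial <- cfg$n_multinomial %||% 100L
  dialect <- cfg$contact_dialect %||% "allatom_3p5"
  min_coverage <- cfg$min_coverage %||% 0.95

  sa <- sb <- NULL
  if (!is.null(cfg$synthetic)) {
    spec <- if (inherits(cfg$synthetic, "ssap_synth_spec")) cfg$synthetic
            else do.call(synthetic_spec, cfg$synthetic)
    pair <- generate_homolog_pair(spec)
    ddg_a <- pair$ddg_a; ddg_b <- pair$ddg_b
    aln <- pair$alignment
    seq_a <- pair$seq_a; seq_b <- pair$seq_b
    sa <- pair$structure_a; sb <- pair$structure_b
  } else {
    ddg_a <- as_ddg(cfg$ddg_a); ddg_b <- as_ddg(cfg$ddg_b)
    seq_a <- ddg_a$sites$wt_aa; seq_b <- ddg_b$sites$wt_aa
    if (!is.null(cfg$pdb_a)) {
      sa <- as_structure(cfg$pdb_a, cfg$chain_a %||% "A")
      sb <- as_structure(cfg$pdb_b, cfg$chain_b %||% "A")
    }
    if (!is.null(cfg$alignment)) {
      aln <- if (inherits(cfg$alignment, "ssap_alignment")) cfg$alignment
             else read_alignment(cfg$alignment,
                                 n_sites_a = nrow(ddg_a$values),
                                 n_sites_b = nrow(ddg_b$values),
                                 seq_a = seq_a, seq_b = seq_b)
    } else if (!is.null(sa)) {
      aln <- superpose(sa, sb)$alignment
    } else stop("config needs 'alignment' or 'pdb_a'/'pdb_b' (or 'synthetic')")
  }
  if (!is.na(aln$coverage_a) &&
      (aln$coverage_a < min_coverage || aln$coverage_b < min_coverage))
    stop(sprintf("pair '%s': alignment coverage %.2f/%.2f below %.2f",
                 pair_id, aln$coverage_a, aln$coverage_b, min_coverage))

  prof_a <- ddg_to_preferences(ddg_a, model)
  prof_b <- ddg_to_preferences(ddg_b, model)
  cmp <- compare_profiles(prof_a, prof_b, aln, target_r = target_r,
                          alpha = alpha, n_replicates = n_replicates,
                          n_multinomial = n_multinomial)
  div <- sequence_divergence(aln, seq_a, seq_b)

  contacts <- NULL
  if (!is.null(sa)) {
    net_a <- build_contacts(sa, dialect)
    net_b <- build_contacts(sb, dialect)
    contacts <- compare_contacts(net_a, net_b, aln, seq_a, seq_b)
  }
  record <- data.frame(
    pair_id = pair_id,
    sequence_divergence = div,
    srmsd = srmsd(aln),
    n_sites_compared = cmp$summary$n_sites,
    n_significant = cmp$summary$n_significant,
    fraction_significant = cmp$summary$fraction_significant,
    mean_js = cmp$summary$mean_js,
    model = model$model,
    stringsAsFactors = FALSE)

  out <- structure(list(record = record, comparison = cmp, contacts = contacts,
                        alignment = aln, config = cfg),
                   class = "ssap_pair_record")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(cmp$results,
                       file.path(cfg$out_dir, paste0(pair_id, "_sites.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(record,
                       file.path(cfg$out_dir, paste0(pair_id, "_summary.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' @export
print.ssap_pair_record <- function(x, ...) {
  r <- x$record
  cat(sprintf(
    "Pair '%s': divergence %.2f, sRMSD %.2f A, %d/%d sites significant (%.1f%%)\n",
    r$pair_id, r$sequence_divergence, r$srmsd, r$n_significant,
    r$n_sites_compared, 100 * r$fraction_significant))
  invisible(x)
}

#' Run a cohort of pair analyses and summarize by sequence divergence
#'
#' Runs [run_pair()] on each config (continuing past single-pair failures with
#' a logged skip), aggregates the per-pair records, bins the fraction of
#' significant sites by sequence divergence with bootstrap confidence
#' intervals, and — when contact comparisons are available — pools per-site
#' rewired fractions, summarizes f_r by divergence split by site class
#' (substituted vs conserved amino acid), and reports a Wilcoxon rank-sum test
#' of f_r between the two classes.
#'
#' @param configs list of pair configs (see [run_pair()]).
#' @param breaks divergence bin breaks (default width 0.1 over \[0, 1\]).
#' @param n_boot bootstrap resamples for binned confidence intervals
#'   (default 10000).
#' @return An object of class `ssap_cohort`: `records` (data.frame),
#'   `binned_fraction` (divergence-binned fraction of significant sites),
#'   `site_rewiring` (per aligned site: divergence, f_r, site_class,
#'   significant), `binned_fr` (f_r binned by divergence and site class),
#'   `fr_class_test` (htest or NULL), `skipped` (character vector).
#' @export
run_cohort <- function(configs, breaks = seq(0, 1, 0.1), n_boot = 10000L) {
  stopifnot(length(configs) >= 1)
  records <- list(); rewiring <- list(); skipped <- character(0)
  for (i in seq_along(configs)) {
    res <- tryCatch(run_pair(configs[[i]]), error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- c(skipped, sprintf("config %d: %s", i, conditionMessage(res)))
      message("skipping pair config ", i, ": ", conditionMessage(res))
      next
    }
    records[[length(records) + 1L]] <- res$record
    if (!is.null(res$contacts)) {
      ps <- res$contacts$per_site
      sig <- res$comparison$results
      rewiring[[length(rewiring) + 1L]] <- data.frame(
        pair_id = res$record$pair_id,
        divergence = res$record$sequence_divergence,
        site_a = ps$site_a,
        f_r = ps$f_r,
        site_class = ps$site_class,
        significant = sig$significant[match(ps$site_a, sig$site_a)])
    }
  }
  if (!length(records)) stop("every pair in the cohort failed")
  records <- do.call(rbind, records)
  binned <- divergence_binned_summary(records$sequence_divergence,
                                      records$fraction_significant,
                                      breaks = breaks, n_boot = n_boot)
  site_rewiring <- if (length(rewiring)) do.call(rbind, rewiring) else NULL
  binned_fr <- NULL; fr_test <- NULL
  if (!is.null(site_rewiring)) {
    ok <- is.finite(site_rewiring$f_r)
    sr <- site_rewiring[ok, ]
    binned_fr <- do.call(rbind, lapply(split(sr, sr$site_class), function(d) {
      b <- divergence_binned_summary(d$divergence, d$f_r, breaks = breaks,
                                     n_boot = n_boot)
      b$site_class <- d$site_class[1]
      b
    }))
    rownames(binned_fr) <- NULL
    if (length(unique(sr$site_class)) == 2)
      fr_test <- suppressWarnings(stats::wilcox.test(f_r ~ site_class, data = sr))
  }
  structure(list(records = records, binned_fraction = binned,
                 site_rewiring = site_rewiring, binned_fr = binned_fr,
                 fr_class_test = fr_test, skipped = skipped),
            class = "ssap_cohort")
}

#' @export
print.ssap_cohort <- function(x, ...) {
  cat("Cohort: ", nrow(x$records), " pair(s) analyzed",
      if (length(x$skipped)) paste0(", ", length(x$skipped), " skipped"),
      "\n", sep = "")
  print(x$records[, c("pair_id", "sequence_divergence", "fraction_significant")])
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_model_spec <- function(m) {
  if (is.null(m)) return(fitness_model_spec())
  if (inherits(m, "ssap_fitness_model")) return(m)
  do.call(fitness_model_spec, as.list(m))
}

as_ddg <- function(x, dialect = "generic_tsv") {
  if (inherits(x, "ssap_ddg")) return(x)
  read_ddg_table(x, dialect)
}

as_structure <- function(x, chain = "A") {
  if (inherits(x, "ssap_structure")) return(x)
  read_pdb(x, chain)
}
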