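#' Read a ddG table
#'
#' Two dialects are supported.
#'
#' * `generic_tsv`: header `site`, `residue_number`, `wt_aa`, then the 20
#'   amino-acid columns `A` ... `Y` in alphabetical one-letter order; one row
#'   per site; values in kcal/mol, '.' decimal separator, UTF-8.
#' * `foldx_dif`: the per-mutation energy-difference dialect distilled from
#'   FoldX BuildModel output: two tab-separated columns `mutation` (code
#'   `<wt><residue_number><mut>`, e.g. `G41L`) and `ddG` (kcal/mol), one row
#'   per model build. Repeated rows for the same mutation are independent
#'   builds and are averaged (arithmetic mean); with >= 2 builds the per-entry
#'   standard error (sd/sqrt(k)) is recorded.
#'
#' Wildtype self-substitution entries are forced to 0 (with a warning if the
#' file claims otherwise). A site missing one or more of its 19 substitutions
#' in the `foldx_dif` dialect is a validation error listing the gaps.
#'
#' @param path file path.
#' @param dialect `"generic_tsv"` (default) or `"foldx_dif"`.
#' @param protein_id identifier for the returned object (default: file stem).
#' @return A [ddg_matrix()].
#' @export
read_ddg_table <- function(path, dialect = c("generic_tsv", "foldx_dif"),
                           protein_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(protein_id))
    protein_id <- sub("\\.[^.]*$", "", basename(path))
  if (dialect == "generic_tsv") read_ddg_generic(path, protein_id)
  else read_ddg_foldx(path, protein_id)
}

read_ddg_generic <- function(path, protein_id) {
  df <- tryCatch(
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e))
  )
  need <- c("site", "residue_number", "wt_aa", AA_ALPHABET)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  vals <- as.matrix(df[, AA_ALPHABET])
  if (!is.numeric(vals) || anyNA(vals)) {
    bad <- which(apply(df[, AA_ALPHABET], 1, function(r) anyNA(suppressWarnings(as.numeric(r)))))
    stop("malformed ddG row at line ", bad[1] + 1L, " of ", path)
  }
  ddg_matrix(vals, wildtype_aa = df$wt_aa,
             residue_number = df$residue_number,
             protein_id = protein_id, replicate_count = 1L)
}

read_ddg_foldx <- function(path, protein_id) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^mutation\\t", lines[1])) lines <- lines[-1]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_line <- seq_along(lines) + 1L  # header offset for messages
  mut <- vapply(parts, `[`, "", 1L)
  val <- suppressWarnings(as.numeric(vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, "")))
  ok <- grepl("^[A-Z][0-9]+[A-Z]$", mut)
  if (any(!ok | is.na(val))) {
    bad <- which(!ok | is.na(val))[1]
    stop("malformed row at line ", n_line[bad], " of ", path, ": '", lines[bad], "'")
  }
  wt <- substr(mut, 1L, 1L)
  ma <- substring(mut, nchar(mut))
  resno <- as.integer(substr(mut, 2L, nchar(mut) - 1L))
  bad_aa <- setdiff(unique(c(wt, ma)), AA_ALPHABET)
  if (length(bad_aa))
    stop("unknown amino-acid code(s) in ", path, ": ", paste(bad_aa, collapse = ", "))

  resnos <- sort(unique(resno))
  L <- length(resnos)
  ridx <- match(resno, resnos)
  cidx <- match(ma, AA_ALPHABET)
  wt_by_site <- vapply(resnos, function(rn) {
    w <- unique(wt[resno == rn])
    if (length(w) != 1) stop("conflicting wildtype codes at residue ", rn, " in ", path)
    w
  }, "")
  key <- (ridx - 1L) * 20L + cidx
  means <- tapply(val, key, mean)
  sds <- tapply(val, key, stats::sd)
  ks <- tapply(val, key, length)
  vals <- matrix(NA_real_, L, 20L)
  serr <- matrix(0, L, 20L)
  kk <- as.integer(names(means))
  vals[cbind((kk - 1L) %/% 20L + 1L, (kk - 1L) %% 20L + 1L)] <- means
  has2 <- !is.na(sds) & ks >= 2
  serr[cbind((kk - 1L) %/% 20L + 1L, (kk - 1L) %% 20L + 1L)[has2, , drop = FALSE]] <-
    (sds / sqrt(ks))[has2]
  wt_col <- match(wt_by_site, AA_ALPHABET)
  vals[cbind(seq_len(L), wt_col)] <- 0
  if (anyNA(vals)) {
    gaps <- which(is.na(vals), arr.ind = TRUE)
    msg <- paste0(wt_by_site[gaps[, 1]], resnos[gaps[, 1]],
                  AA_ALPHABET[gaps[, 2]])
    stop("missing mutation(s) in ", path, ": ",
         paste(utils::head(msg, 10), collapse = ", "),
         if (length(msg) > 10) sprintf(" (and %d more)", length(msg) - 10))
  }
  any_rep <- max(ks)
  ddg_matrix(vals, wildtype_aa = wt_by_site, residue_number = resnos,
             protein_id = protein_id, replicate_count = as.integer(any_rep),
             stderr = if (any(has2)) serr else NULL)
}

#' Write a ddG table in the generic TSV layout
#'
#' Inverse of [read_ddg_table()]'s `generic_tsv` dialect; full precision so a
#' write/read round trip reproduces the matrix to 1e-12 per entry.
#'
#' @param ddg a [ddg_matrix()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_ddg_table <- function(ddg, path) {
  stopifnot(inherits(ddg, "ssap_ddg"))
  df <- data.frame(site = ddg$sites$site,
                   residue_number = ddg$sites$residue_number,
                   wt_aa = ddg$sites$wt_aa, stringsAsFactors = FALSE)
  vals <- as.data.frame(ddg$values)
  df <- cbind(df, format(vals, digits = 17, scientific = TRUE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an SSAP profile as TSV
#'
#' Layout: header `site`, `wt_aa`, `pi_A` ... `pi_Y`; one row per site; full
#' precision so that a write/read round trip reproduces the profile to 1e-12
#' per entry. On read, rows must sum to 1 within 1e-6 (they are renormalized
#' exactly); a larger deviation or any negative entry is a validation error.
#'
#' @param profile an `ssap_profile`.
#' @param path file path.
#' @return `read_profile` returns an `ssap_profile`; `write_profile` returns
#'   `path` invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "ssap_profile"))
  df <- data.frame(site = profile$sites$site,
                   wt_aa = ifelse(is.na(profile$sites$wt_aa), "-", profile$sites$wt_aa),
                   stringsAsFactors = FALSE)
  vals <- as.data.frame(profile$values)
  names(vals) <- paste0("pi_", AA_ALPHABET)
  df <- cbind(df, format(vals, digits = 17, scientific = TRUE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @param protein_id identifier for the returned profile (default: file stem).
#' @export
read_profile <- function(path, protein_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(protein_id)) protein_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  cols <- paste0("pi_", AA_ALPHABET)
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("missing preference column(s) in ", path, ": ", paste(miss, collapse = ", "))
  vals <- as.matrix(df[, cols])
  wt <- if ("wt_aa" %in% names(df)) ifelse(df$wt_aa == "-", NA_character_, df$wt_aa) else NULL
  preference_profile(vals, wildtype_aa = wt, protein_id = protein_id)
}

#' Write / read an equivalent-site alignment map as TSV
#'
#' Layout: header `site_a`, `site_b`, `ca_dist`; one row per equivalent-site
#' pair; distances in angstrom.
#'
#' @param alignment an `ssap_alignment`.
#' @param path file path.
#' @inheritParams alignment_map
#' @return `read_alignment` returns an `ssap_alignment`.
#' @export
write_alignment <- function(alignment, path) {
  stopifnot(inherits(alignment, "ssap_alignment"))
  df <- alignment$pairs
  df$ca_dist <- format(df$ca_dist, digits = 17, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_alignment
#' @export
read_alignment <- function(path, n_sites_a = NA_integer_, n_sites_b = NA_integer_,
                           seq_a = NULL, seq_b = NULL, threshold = 3.5) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  alignment_map(df, n_sites_a = n_sites_a, n_sites_b = n_sites_b,
                seq_a = seq_a, seq_b = seq_b, threshold = threshold)
}

#' Read a YAML run configuration
#'
#' Convenience wrapper: a single YAML document mapped to a nested list, as
#' consumed by [run_pair()] / [run_cohort()].
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)
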