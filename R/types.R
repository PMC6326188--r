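#' The 20 proteinogenic amino acids, alphabetical one-letter order
#'
#' Fixed column order used by every ddG matrix and preference profile in the
#' package, removing any ordering ambiguity between modules.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

THREE_TO_ONE <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
  HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
  PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
  TRP = "W", TYR = "Y"
)

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Construct a per-site ddG matrix
#'
#' A `ddg_matrix` holds predicted changes in folding free energy
#' (ddG = dG(mutant) - dG(wildtype), kcal/mol) for every single amino acid
#' substitution at every site of a protein: one row per site, one column per
#' amino acid in the fixed order of [AA_ALPHABET]. Positive values are
#' destabilizing. The self-substitution entry (the wildtype amino acid of each
#' site) is identically zero by definition and is forced to zero, with a
#' warning, if the input claims otherwise.
#'
#' @param values numeric L x 20 matrix of ddG values (kcal/mol).
#' @param wildtype_aa character vector of one-letter wildtype codes, length L.
#' @param residue_number integer vector of author residue numbers (default
#'   `1:L`); retained for reporting, never used for matrix indexing.
#' @param protein_id identifier string.
#' @param replicate_count number of independent per-mutation model builds
#'   averaged into `values` (default 5).
#' @param stderr optional L x 20 matrix of per-entry standard errors.
#' @return An object of class `ssap_ddg` with elements `protein_id`, `sites`
#'   (data.frame: site, residue_number, wt_aa), `values`, `replicate_count`,
#'   `stderr`.
#' @export
ddg_matrix <- function(values, wildtype_aa, residue_number = seq_len(nrow(values)),
                       protein_id = "protein", replicate_count = 5L,
                       stderr = NULL) {
  values <- as.matrix(values)
  if (ncol(values) != 20L)
    stop("ddG matrix must have 20 columns (one per amino acid), got ", ncol(values))
  L <- nrow(values)
  if (length(wildtype_aa) != L)
    stop("wildtype_aa length (", length(wildtype_aa), ") != number of sites (", L, ")")
  bad <- setdiff(wildtype_aa, AA_ALPHABET)
  if (length(bad))
    stop("unknown amino-acid code(s): ", paste(unique(bad), collapse = ", "))
  if (!all(is.finite(values)))
    stop("ddG matrix contains non-finite values")
  if (length(residue_number) != L)
    stop("residue_number length != number of sites")
  colnames(values) <- AA_ALPHABET
  wt_col <- match(wildtype_aa, AA_ALPHABET)
  self <- values[cbind(seq_len(L), wt_col)]
  if (any(abs(self) > 1e-12)) {
    warning("wildtype self-substitution ddG not zero at ",
            sum(abs(self) > 1e-12), " site(s); forcing to 0")
  }
  values[cbind(seq_len(L), wt_col)] <- 0
  if (!is.null(stderr)) {
    stderr <- as.matrix(stderr)
    stopifnot(all(dim(stderr) == dim(values)), all(is.finite(stderr)))
    colnames(stderr) <- AA_ALPHABET
  }
  structure(
    list(protein_id = protein_id,
         sites = data.frame(site = seq_len(L),
                            residue_number = as.integer(residue_number),
                            wt_aa = wildtype_aa,
                            stringsAsFactors = FALSE),
         values = values,
         replicate_count = as.integer(replicate_count),
         stderr = stderr),
    class = "ssap_ddg"
  )
}

#' @export
print.ssap_ddg <- function(x, ...) {
  cat("ddG matrix '", x$protein_id, "': ", nrow(x$values),
      " sites x 20 amino acids (kcal/mol), ",
      x$replicate_count, " model build(s) averaged\n", sep = "")
  invisible(x)
}

#' Construct a site-specific amino acid preference (SSAP) profile
#'
#' An SSAP profile is a row-stochastic L x 20 matrix pi: `values[r, a]` is the
#' normalized propensity of site `r` to be occupied by amino acid `a`. Every
#' entry is non-negative and every row sums to 1 (tolerance 1e-9; rows are
#' renormalized exactly on construction when within 1e-6).
#'
#' @param values numeric L x 20 matrix of preferences.
#' @param wildtype_aa optional one-letter wildtype codes (length L).
#' @param residue_number author residue numbers (default `1:L`).
#' @param protein_id identifier string.
#' @return An object of class `ssap_profile`.
#' @export
preference_profile <- function(values, wildtype_aa = NULL,
                               residue_number = seq_len(nrow(values)),
                               protein_id = "protein") {
  values <- as.matrix(values)
  if (ncol(values) != 20L)
    stop("preference profile must have 20 columns, got ", ncol(values))
  if (any(values < 0))
    stop("negative preference value(s)")
  if (!all(is.finite(values)))
    stop("non-finite preference value(s)")
  rs <- rowSums(values)
  if (any(abs(rs - 1) > 1e-6))
    stop("profile row(s) ", paste(which(abs(rs - 1) > 1e-6), collapse = ", "),
         " do not sum to 1 (tolerance 1e-6)")
  values <- values / rs
  colnames(values) <- AA_ALPHABET
  L <- nrow(values)
  if (is.null(wildtype_aa)) wildtype_aa <- rep(NA_character_, L)
  structure(
    list(protein_id = protein_id,
         sites = data.frame(site = seq_len(L),
                            residue_number = as.integer(residue_number),
                            wt_aa = wildtype_aa,
                            stringsAsFactors = FALSE),
         values = values),
    class = "ssap_profile"
  )
}

#' @export
print.ssap_profile <- function(x, ...) {
  cat("SSAP profile '", x$protein_id, "': ", nrow(x$values),
      " sites x 20 amino acids\n", sep = "")
  invisible(x)
}

#' Construct an equivalent-site alignment map between two homologs
#'
#' Pairs of sites in two homologous structures are equivalent when their
#' C-alpha atoms lie within `threshold` angstrom (default 3.5) after optimal
#' superposition. The map is one-to-one; unpaired sites are listed separately.
#' Sequence divergence is the fraction of equivalent-site pairs whose amino
#' acids differ.
#'
#' @param pairs data.frame with columns `site_a`, `site_b`, `ca_dist` (angstrom).
#' @param n_sites_a,n_sites_b total site counts of the two proteins (needed for
#'   coverage; `NA` allowed).
#' @param seq_a,seq_b optional one-letter sequences (character vectors) used to
#'   compute sequence divergence.
#' @param threshold equivalence threshold in angstrom (default 3.5).
#' @return An object of class `ssap_alignment` with `pairs`, `unpaired_a`,
#'   `unpaired_b`, `sequence_divergence`, `coverage_a`, `coverage_b`,
#'   `threshold`.
#' @export
alignment_map <- function(pairs, n_sites_a = NA_integer_, n_sites_b = NA_integer_,
                          seq_a = NULL, seq_b = NULL, threshold = 3.5) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("site_a", "site_b", "ca_dist") %in% names(pairs)))
  if (anyDuplicated(pairs$site_a) || anyDuplicated(pairs$site_b))
    stop("alignment map is not one-to-one: duplicated site(s)")
  if (any(pairs$ca_dist > threshold + 1e-9))
    stop("pair(s) exceed the ", threshold, " angstrom equivalence threshold")
  div <- NA_real_
  if (!is.null(seq_a) && !is.null(seq_b) && nrow(pairs) > 0) {
    div <- mean(seq_a[pairs$site_a] != seq_b[pairs$site_b])
  }
  unpaired_a <- if (is.na(n_sites_a)) integer(0) else setdiff(seq_len(n_sites_a), pairs$site_a)
  unpaired_b <- if (is.na(n_sites_b)) integer(0) else setdiff(seq_len(n_sites_b), pairs$site_b)
  structure(
    list(pairs = pairs,
         unpaired_a = unpaired_a, unpaired_b = unpaired_b,
         sequence_divergence = div,
         coverage_a = if (is.na(n_sites_a)) NA_real_ else nrow(pairs) / n_sites_a,
         coverage_b = if (is.na(n_sites_b)) NA_real_ else nrow(pairs) / n_sites_b,
         threshold = threshold),
    class = "ssap_alignment"
  )
}

#' @export
print.ssap_alignment <- function(x, ...) {
  cat("Alignment map: ", nrow(x$pairs), " equivalent-site pairs",
      if (!is.na(x$sequence_divergence))
        sprintf(", sequence divergence %.3f", x$sequence_divergence),
      "\n", sep = "")
  invisible(x)
}
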