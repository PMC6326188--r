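#' Construct an in-memory structure model
#'
#' Minimal coordinate container used by the superposition and contact-network
#' code: an ordered list of residues, each carrying its author residue number,
#' one-letter amino acid and a named n x 3 matrix of heavy-atom coordinates in
#' angstrom (PDB convention). Residues used by downstream C-alpha operations
#' must have a `CA` atom.
#'
#' @param residues list of lists with elements `residue_number`, `ins`
#'   (insertion code, `""` if none), `aa` (one-letter), `atoms` (named matrix,
#'   rows = atom names, 3 columns x/y/z).
#' @param protein_id identifier.
#' @param chain chain identifier.
#' @param source path or description of origin.
#' @return An object of class `ssap_structure`.
#' @export
structure_model <- function(residues, protein_id = "protein", chain = "A",
                            source = "memory") {
  for (i in seq_along(residues)) {
    r <- residues[[i]]
    if (!all(c("residue_number", "aa", "atoms") %in% names(r)))
      stop("residue ", i, " lacks required fields")
    if (!all(is.finite(r$atoms)))
      stop("non-finite atom coordinates at residue ", i)
    if (is.null(residues[[i]]$ins)) residues[[i]]$ins <- ""
  }
  structure(list(protein_id = protein_id, chain = chain, source = source,
                 residues = residues),
            class = "ssap_structure")
}

#' @export
print.ssap_structure <- function(x, ...) {
  cat("Structure '", x$protein_id, "' chain ", x$chain, ": ",
      length(x$residues), " residues\n", sep = "")
  invisible(x)
}

#' Number of residues in a structure
#' @param s an `ssap_structure`.
#' @export
n_sites <- function(s) length(s$residues)

#' C-alpha coordinate matrix of a structure
#'
#' Residues lacking a CA atom are excluded with a warning; the `site`
#' attribute of the returned matrix maps rows back to residue indices.
#'
#' @param s an `ssap_structure`.
#' @return numeric matrix (n x 3) with attribute `site`.
#' @export
ca_coords <- function(s) {
  has_ca <- vapply(s$residues, function(r) "CA" %in% rownames(r$atoms), TRUE)
  if (any(!has_ca))
    warning(sum(!has_ca), " residue(s) lack a CA atom and are excluded")
  m <- do.call(rbind, lapply(s$residues[has_ca], function(r) r$atoms["CA", ]))
  attr(m, "site") <- which(has_ca)
  m
}

#' One-letter sequence of a structure
#' @param s an `ssap_structure`.
#' @export
structure_sequence <- function(s) vapply(s$residues, function(r) r$aa, "")

#' Read one chain of a PDB file
#'
#' Parses ATOM records of the named chain (HETATM ignored), first model only
#' for multi-model files, hydrogens excluded. Alternate locations are resolved
#' per atom by highest occupancy, ties broken alphabetically by altloc code.
#' Residues are ordered by (residue_number, insertion code).
#'
#' @param path PDB file path.
#' @param chain chain identifier (single character).
#' @return An `ssap_structure`.
#' @export
read_pdb <- function(path, chain = "A") {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) stop("chain '", chain, "' not found in ", path)
  # drop hydrogens (element symbol H, or names like H, 1H..., HB2)
  elesy <- if ("elesy" %in% names(at)) trimws(at$elesy) else ""
  is_h <- elesy == "H" | grepl("^[0-9]?H", trimws(at$elety))
  at <- at[!is_h, , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  # altloc resolution: per (residue, atom name) keep highest occupancy,
  # then alphabetical altloc
  key <- paste(at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]

  rkey <- paste(at$resno, at$insert, sep = "\r")
  res_order <- order(at$resno, at$insert)
  at <- at[res_order, , drop = FALSE]
  rkey <- rkey[res_order]
  residues <- lapply(split(seq_len(nrow(at)), factor(rkey, levels = unique(rkey))),
                     function(idx) {
    sub <- at[idx, , drop = FALSE]
    atoms <- cbind(sub$x, sub$y, sub$z)
    rownames(atoms) <- trimws(sub$elety)
    aa3 <- toupper(sub$resid[1])
    aa1 <- if (aa3 %in% names(THREE_TO_ONE)) THREE_TO_ONE[[aa3]] else "X"
    list(residue_number = sub$resno[1], ins = sub$insert[1], aa = aa1,
         atoms = atoms)
  })
  names(residues) <- NULL
  no_ca <- vapply(residues, function(r) !"CA" %in% rownames(r$atoms), TRUE)
  if (any(no_ca))
    warning(sum(no_ca), " residue(s) without CA in ", basename(path))
  structure_model(residues,
                  protein_id = sub("\\.[^.]*$", "", basename(path)),
                  chain = chain, source = path)
}
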