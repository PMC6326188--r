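#' Rigid-body superposition with iterated equivalent-site pairing
#'
#' Least-squares (Kabsch) superposition of structure `b` onto structure `a` on
#' the currently paired C-alpha atoms, iterated with re-pairing by mutual
#' nearest neighbors within the equivalence threshold (3.5 angstrom) until the
#' paired set is stable. Pairing initializes from `seed_pairs` when given
#' (e.g., from a sequence alignment), otherwise by residue order. This is a
#' pragmatic internal utility; externally produced alignment maps are accepted
#' everywhere as first-class input.
#'
#' @param a,b `ssap_structure` objects with >= 3 C-alpha atoms each.
#' @param seed_pairs optional 2-column matrix / data.frame of initial
#'   (site_a, site_b) pairs.
#' @param threshold equivalence threshold, angstrom (default 3.5).
#' @param max_iter re-pairing iteration cap (default 50).
#' @return An object of class `ssap_superposition`: `rotation` (3 x 3, det
#'   +1), `translation` (length 3; transform is `x %*% rotation + translation`
#'   applied to b), `alignment` (an `ssap_alignment` with per-pair C-alpha
#'   distances), `rmsd_paired`.
#' @export
superpose <- function(a, b, seed_pairs = NULL, threshold = 3.5, max_iter = 50L) {
  Xa <- ca_coords(a); Xb <- ca_coords(b)
  site_a <- attr(Xa, "site"); site_b <- attr(Xb, "site")
  if (nrow(Xa) < 3 || nrow(Xb) < 3) stop("need >= 3 CA atoms in each structure")
  if (is.null(seed_pairs)) {
    k <- min(nrow(Xa), nrow(Xb))
    ia <- seq_len(k); ib <- seq_len(k)
  } else {
    seed_pairs <- as.matrix(seed_pairs)
    ia <- match(seed_pairs[, 1], site_a); ib <- match(seed_pairs[, 2], site_b)
    keep <- !is.na(ia) & !is.na(ib)
    ia <- ia[keep]; ib <- ib[keep]
  }
  R <- diag(3); tr <- c(0, 0, 0)
  for (iter in seq_len(max_iter)) {
    if (length(ia) < 3) stop("no significant superposition: <3 pairs survive")
    P <- Xb[ib, , drop = FALSE]; Q <- Xa[ia, , drop = FALSE]
    cp <- colMeans(P); cq <- colMeans(Q)
    H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
    s <- svd(H)
    d <- sign(det(s$v %*% t(s$u)))
    R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
    tr <- cq - as.vector(cp %*% R)
    Bt <- Xb %*% R + matrix(tr, nrow(Xb), 3, byrow = TRUE)
    # mutual nearest neighbors within threshold
    D <- outer(rowSums(Xa^2), rowSums(Bt^2), `+`) - 2 * tcrossprod(Xa, Bt)
    D <- sqrt(pmax(D, 0))
    nn_a <- max.col(-D)                # for each a-row, closest b-row
    nn_b <- max.col(-t(D))             # for each b-row, closest a-row
    ia2 <- which(nn_b[nn_a] == seq_len(nrow(Xa)) &
                 D[cbind(seq_len(nrow(Xa)), nn_a)] <= threshold)
    ib2 <- nn_a[ia2]
    if (length(ia2) == length(ia) && all(ia2 == ia) && all(ib2 == ib)) break
    ia <- ia2; ib <- ib2
  }
  if (length(ia) < 3) stop("no significant superposition: <3 pairs survive")
  Bt <- Xb %*% R + matrix(tr, nrow(Xb), 3, byrow = TRUE)
  dist <- sqrt(rowSums((Xa[ia, , drop = FALSE] - Bt[ib, , drop = FALSE])^2))
  aln <- alignment_map(
    data.frame(site_a = site_a[ia], site_b = site_b[ib], ca_dist = dist),
    n_sites_a = n_sites(a), n_sites_b = n_sites(b),
    seq_a = structure_sequence(a), seq_b = structure_sequence(b),
    threshold = threshold)
  structure(list(rotation = R, translation = tr, alignment = aln,
                 rmsd_paired = sqrt(mean(dist^2))),
            class = "ssap_superposition")
}

#' Apply a superposition transform to coordinates
#' @param sup an `ssap_superposition`.
#' @param x n x 3 coordinate matrix (structure b frame).
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(sup, x)
  x %*% sup$rotation + matrix(sup$translation, nrow(x), 3, byrow = TRUE)

#' Structural deviation over equivalent sites (sRMSD)
#'
#' The per-pair structural deviation used throughout the package: the
#' arithmetic mean of the paired C-alpha distances, (1/n) * sum(d_i). Despite
#' the conventional name, this is a mean of distances, not a root-mean-square
#' (the naming follows the definition it implements; see the methods
#' vignette).
#'
#' @param alignment an `ssap_alignment` with >= 1 pair.
#' @return Mean paired C-alpha distance, angstrom.
#' @export
srmsd <- function(alignment) {
  stopifnot(inherits(alignment, "ssap_alignment"))
  if (nrow(alignment$pairs) == 0) stop("empty alignment")
  mean(alignment$pairs$ca_dist)
}

#' Build a residue contact network
#'
#' Two residues are in contact when the minimum distance between their atoms,
#' under the dialect's atom filter, is <= `cutoff` (3.5 angstrom):
#'
#' * `sidechain_3p5`: side-chain atoms only (backbone N, CA, C, O, OXT
#'   excluded; glycine contributes no side-chain atoms).
#' * `allatom_3p5`: all heavy atoms.
#'
#' Sequentially adjacent residues (|i - j| <= 1) are included by default;
#' `exclude_sequential = TRUE` drops them for contact-map conventions that do.
#'
#' @param s an `ssap_structure`.
#' @param dialect `"sidechain_3p5"` or `"allatom_3p5"`.
#' @param cutoff contact distance threshold, angstrom (default 3.5).
#' @param exclude_sequential drop |i-j| <= 1 edges (default FALSE).
#' @return An object of class `ssap_contacts`: `nodes`, `edges` (data.frame
#'   i, j with i < j), `dialect`, `E` (NULL unless an ensemble network).
#' @export
build_contacts <- function(s, dialect = c("sidechain_3p5", "allatom_3p5"),
                           cutoff = 3.5, exclude_sequential = FALSE) {
  dialect <- match.arg(dialect)
  L <- n_sites(s)
  coords <- list(); owner <- integer(0)
  for (i in seq_len(L)) {
    at <- s$residues[[i]]$atoms
    if (dialect == "sidechain_3p5")
      at <- at[!rownames(at) %in% BACKBONE_ATOMS, , drop = FALSE]
    if (nrow(at)) {
      coords[[length(coords) + 1L]] <- at
      owner <- c(owner, rep(i, nrow(at)))
    }
  }
  edges <- data.frame(i = integer(0), j = integer(0))
  if (length(coords)) {
    X <- do.call(rbind, coords)
    D2 <- outer(rowSums(X^2), rowSums(X^2), `+`) - 2 * tcrossprod(X)
    hit <- which(D2 <= cutoff^2 + 1e-9, arr.ind = TRUE)
    ri <- owner[hit[, 1]]; rj <- owner[hit[, 2]]
    keep <- ri < rj
    edges <- unique(data.frame(i = ri[keep], j = rj[keep]))
    if (exclude_sequential) edges <- edges[abs(edges$i - edges$j) > 1L, ]
    edges <- edges[order(edges$i, edges$j), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = seq_len(L), edges = edges, dialect = dialect,
                 E = NULL, cutoff = cutoff),
            class = "ssap_contacts")
}

#' @export
print.ssap_contacts <- function(x, ...) {
  cat("Contact network (", x$dialect, "): ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges",
      if (!is.null(x$E)) " (ensemble frequencies attached)", "\n", sep = "")
  invisible(x)
}

#' Ensemble contact frequency across structure models
#'
#' Builds the contact network of each model and attaches to every edge the
#' fraction of models E in which it is present; edges with E > 0 are retained.
#'
#' @param models list of `ssap_structure` objects with consistent residue
#'   numbering.
#' @inheritParams build_contacts
#' @return An `ssap_contacts` with column `E` on `edges` and field `E` set.
#' @export
ensemble_contact_frequency <- function(models, dialect = c("sidechain_3p5", "allatom_3p5"),
                                       cutoff = 3.5, exclude_sequential = FALSE) {
  dialect <- match.arg(dialect)
  stopifnot(length(models) >= 1)
  rn <- lapply(models, function(m)
    vapply(m$residues, function(r) r$residue_number, 0L))
  if (!all(vapply(rn, identical, TRUE, y = rn[[1]])))
    stop("inconsistent residue numbering across models")
  nets <- lapply(models, build_contacts, dialect = dialect, cutoff = cutoff,
                 exclude_sequential = exclude_sequential)
  keys <- unlist(lapply(nets, function(nw) paste(nw$edges$i, nw$edges$j)))
  tab <- table(keys) / length(models)
  ij <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
  edges <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                      E = as.numeric(tab))
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nets[[1]]$nodes, edges = edges, dialect = dialect,
                 E = edges$E, cutoff = cutoff),
            class = "ssap_contacts")
}

neighbor_sets <- function(net) {
  out <- rep(list(integer(0)), length(net$nodes))
  for (k in seq_len(nrow(net$edges))) {
    i <- net$edges$i[k]; j <- net$edges$j[k]
    out[[i]] <- c(out[[i]], j)
    out[[j]] <- c(out[[j]], i)
  }
  out
}

#' Pooled rewired-contact fraction from gained/lost/conserved counts
#'
#' `(G + L) / (G + L + C)` — one minus the Jaccard index of the two contact
#' sets, pooled over sites.
#'
#' @param gained,lost,conserved non-negative counts.
#' @return Fraction in \[0, 1\].
#' @export
pooled_rewired_fraction <- function(gained, lost, conserved) {
  tot <- gained + lost + conserved
  if (tot <= 0) stop("no contacts: rewired fraction undefined")
  (gained + lost) / tot
}

#' Classify contacts of aligned sites as conserved, gained or lost
#'
#' For each equivalent-site pair (r_a, r_b) the neighbor sets of the two
#' homologs are mapped into the index space of homolog a: conserved contacts
#' C_r appear in both, lost L_r only in a, gained G_r only in b. Contacts to
#' unaligned sites have no image in the other homolog and are counted as
#' lost/gained respectively (`unaligned = "count"`, default) or dropped
#' (`"ignore"`). The per-site rewired fraction is
#' f_r = (|G_r| + |L_r|) / (|G_r| + |L_r| + |C_r|), one minus the Jaccard
#' index of the neighbor sets. Sites are classed `substituted` or
#' `conserved_aa` by whether the aligned amino acids differ.
#'
#' @param net_a,net_b `ssap_contacts` networks of the two homologs.
#' @param alignment an `ssap_alignment` (non-empty).
#' @param seq_a,seq_b one-letter sequences of the two homologs.
#' @param unaligned `"count"` or `"ignore"`.
#' @return An object of class `ssap_contact_comparison`: `per_site`
#'   (data.frame: site_a, site_b, site_class, n_conserved, n_gained, n_lost,
#'   f_r), `totals` (named G, L, C), `pooled_rewired_fraction`.
#' @export
compare_contacts <- function(net_a, net_b, alignment, seq_a, seq_b,
                             unaligned = c("count", "ignore")) {
  unaligned <- match.arg(unaligned)
  stopifnot(inherits(alignment, "ssap_alignment"))
  prs <- alignment$pairs
  if (nrow(prs) == 0) stop("empty alignment")
  nb_a <- neighbor_sets(net_a)
  nb_b <- neighbor_sets(net_b)
  b_to_a <- rep(NA_integer_, length(net_b$nodes))
  b_to_a[prs$site_b] <- prs$site_a
  out <- data.frame(site_a = prs$site_a, site_b = prs$site_b,
                    site_class = NA_character_, n_conserved = 0L,
                    n_gained = 0L, n_lost = 0L, f_r = NA_real_)
  aligned_a <- prs$site_a
  for (k in seq_len(nrow(prs))) {
    ra <- prs$site_a[k]; rb <- prs$site_b[k]
    Ha <- nb_a[[ra]]
    Hb_raw <- nb_b[[rb]]
    Hb <- b_to_a[Hb_raw]                       # mapped into a-space; NA = unaligned
    if (unaligned == "ignore") {
      Ha <- Ha[Ha %in% aligned_a]
      Hb <- Hb[!is.na(Hb)]
    } else {
      # unaligned b-neighbors kept as out-of-a-space tokens (negative ids) so
      # they count as gained; unaligned a-neighbors stay in Ha and, having no
      # possible image in Hb, count as lost
      Hb[is.na(Hb)] <- -Hb_raw[is.na(Hb)]
    }
    C <- intersect(Ha, Hb)
    Ls <- setdiff(Ha, Hb)
    G <- setdiff(Hb, Ha)
    den <- length(C) + length(Ls) + length(G)
    out$n_conserved[k] <- length(C)
    out$n_gained[k] <- length(G)
    out$n_lost[k] <- length(Ls)
    out$f_r[k] <- if (den > 0) (length(G) + length(Ls)) / den else NA_real_
    out$site_class[k] <- if (seq_a[ra] != seq_b[rb]) "substituted" else "conserved_aa"
  }
  totals <- c(G = sum(out$n_gained), L = sum(out$n_lost), C = sum(out$n_conserved))
  structure(list(per_site = out, totals = totals,
                 pooled_rewired_fraction =
                   pooled_rewired_fraction(totals["G"], totals["L"], totals["C"])[[1]]),
            class = "ssap_contact_comparison")
}

#' @export
print.ssap_contact_comparison <- function(x, ...) {
  cat(sprintf(
    "Contact comparison: %d sites; totals G=%d L=%d C=%d; pooled rewired fraction %.3f\n",
    nrow(x$per_site), x$totals["G"], x$totals["L"], x$totals["C"],
    x$pooled_rewired_fraction))
  invisible(x)
}

#' Sequence divergence over equivalent sites
#'
#' Fraction of equivalent-site pairs whose one-letter amino acids differ.
#'
#' @param alignment a non-empty `ssap_alignment`.
#' @param seq_a,seq_b one-letter sequences.
#' @return Fraction in \[0, 1\].
#' @export
sequence_divergence <- function(alignment, seq_a, seq_b) {
  stopifnot(inherits(alignment, "ssap_alignment"))
  if (nrow(alignment$pairs) == 0) stop("empty alignment")
  mean(seq_a[alignment$pairs$site_a] != seq_b[alignment$pairs$site_b])
}

#' Network proximity of query sites to anchor sites
#'
#' Tests whether `query_sites` lie closer in the residue contact network to
#' `anchor_sites` than random site sets of the same size. The statistic is the
#' mean, over query sites, of the shortest-path length (Dijkstra; unweighted
#' hop counts by default, `weighted = TRUE` uses 1 - E edge weights) to the
#' nearest anchor. The null resamples `n_random` site sets uniformly from the
#' non-anchor nodes; p = (#{null <= observed} + 1) / (n_random + 1).
#' Query sites unreachable from every anchor are excluded with a warning.
#'
#' @param net an `ssap_contacts` network.
#' @param query_sites,anchor_sites site index vectors.
#' @param n_random null-set draws (default 1000).
#' @param weighted use 1 - E edge weights (requires an ensemble network).
#' @return List: `observed`, `null` (numeric vector), `p_value`.
#' @export
network_proximity_test <- function(net, query_sites, anchor_sites,
                                   n_random = 1000L, weighted = FALSE) {
  stopifnot(inherits(net, "ssap_contacts"))
  nn <- length(net$nodes)
  if (length(query_sites) + length(anchor_sites) > nn)
    stop("query + anchor sites exceed node count")
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$edges$i, to = net$edges$j),
    directed = FALSE,
    vertices = data.frame(name = net$nodes))
  w <- if (weighted) {
    if (is.null(net$edges$E)) stop("weighted = TRUE requires an ensemble network")
    1 - net$edges$E + 1e-12
  } else NULL
  D <- igraph::distances(g, v = as.character(seq_len(nn)),
                         to = as.character(anchor_sites), weights = w,
                         algorithm = if (is.null(w)) "unweighted" else "dijkstra")
  min_to_anchor <- apply(D, 1L, min)
  stat <- function(sites) {
    d <- min_to_anchor[sites]
    if (any(!is.finite(d))) {
      d <- d[is.finite(d)]
      if (!length(d)) return(NA_real_)
    }
    mean(d)
  }
  if (any(!is.finite(min_to_anchor[query_sites])))
    warning("query site(s) unreachable from all anchors: excluded")
  observed <- stat(query_sites)
  pool <- setdiff(seq_len(nn), anchor_sites)
  k <- length(query_sites)
  null <- vapply(seq_len(n_random), function(i) stat(sample(pool, k)), 0)
  null <- null[is.finite(null)]
  p <- (sum(null <= observed) + 1) / (length(null) + 1)
  list(observed = observed, null = null, p_value = p)
}

#' Divergence-binned means with bootstrap confidence intervals
#'
#' Bins records by divergence and reports, per bin, the mean of `value` with a
#' percentile bootstrap 95% confidence interval (2.5/97.5 percentiles of
#' `n_boot` resampled means). Empty bins are reported with NA, not errors.
#'
#' @param divergence numeric vector in \[0, 1\].
#' @param value numeric vector, same length.
#' @param breaks bin breaks (default `seq(0, 1, 0.1)`).
#' @param n_boot bootstrap resamples (default 10000).
#' @return data.frame: bin_lo, bin_hi, n, mean, ci_lo, ci_hi.
#' @export
divergence_binned_summary <- function(divergence, value,
                                      breaks = seq(0, 1, 0.1),
                                      n_boot = 10000L) {
  stopifnot(length(divergence) == length(value))
  bins <- cut(divergence, breaks = breaks, include.lowest = TRUE, right = FALSE)
  # right-open bins except the last, so divergence = max(breaks) is included
  bins[divergence == breaks[length(breaks)]] <- levels(bins)[nlevels(bins)]
  out <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                    n = 0L, mean = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_)
  for (b in seq_len(nlevels(bins))) {
    v <- value[which(as.integer(bins) == b)]
    v <- v[is.finite(v)]
    out$n[b] <- length(v)
    if (!length(v)) next
    out$mean[b] <- mean(v)
    if (length(v) == 1L) {
      out$ci_lo[b] <- out$ci_hi[b] <- v
    } else {
      bm <- vapply(seq_len(n_boot), function(i)
        mean(v[sample.int(length(v), replace = TRUE)]), 0)
      ci <- stats::quantile(bm, c(0.025, 0.975), names = FALSE)
      out$ci_lo[b] <- ci[1]; out$ci_hi[b] <- ci[2]
    }
  }
  out
}

#' Per-site Shannon entropy of an SSAP profile
#'
#' Base-2 entropy of each site's 20-amino-acid preference distribution
#' (0 log 0 = 0); ranges from 0 (point mass) to log2(20) ~ 4.32 bits
#' (uniform). Exposed sites typically show higher entropy (more uniform
#' preferences) than buried sites.
#'
#' @param profile an `ssap_profile`.
#' @return Numeric vector of per-site entropies, bits.
#' @export
site_entropy <- function(profile) {
  stopifnot(inherits(profile, "ssap_profile"))
  v <- profile$values
  t <- v * log2(v)
  t[v == 0] <- 0
  -rowSums(t)
}
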