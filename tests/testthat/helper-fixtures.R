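# fixture builders shared across test files

pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          alt = " ", occ = 1.00, icode = " ", element = NULL) {
  if (is.null(element)) element <- substr(trimws(name), 1, 1)
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name4, alt, resn, chain, resno, icode, x, y, z, occ, 0.0, element)
}

# minimal tri-residue PDB text (ALA backbone + CB), returns path
write_tiny_pdb <- function(path, n_res = 3, chain = "A", spacing = 3.8) {
  lines <- character(0)
  serial <- 0
  for (i in seq_len(n_res)) {
    x0 <- (i - 1) * spacing
    for (at in list(c("N", -1.0, 0.5, 0), c("CA", 0, 0, 0),
                    c("C", 1.0, 0.5, 0), c("O", 1.2, 1.6, 0),
                    c("CB", 0, -1.0, 1.1))) {
      serial <- serial + 1
      lines <- c(lines, pdb_atom_line(serial, at[1], "ALA", chain, i,
                                      x0 + as.numeric(at[2]),
                                      as.numeric(at[3]), as.numeric(at[4])))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# uniform-ish valid random profile
random_profile <- function(L = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- matrix(rexp(L * 20), L, 20)
  preference_profile(v / rowSums(v))
}

random_simplex <- function(k = 20) {
  v <- rexp(k)
  v / sum(v)
}

# independent textbook JS divergence (natural definition, base-2 logs)
oracle_js <- function(p, q) {
  m <- (p + q) / 2
  term <- function(a) {
    s <- 0
    for (i in seq_along(a)) if (a[i] > 0) s <- s + a[i] * log(a[i] / m[i], base = 2)
    s
  }
  sqrt(0.5 * term(p) + 0.5 * term(q))
}

# independent BH step-up oracle
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# brute-force shortest path by enumerating all simple paths (tiny graphs)
oracle_shortest_path <- function(edges, weights, from, to, n_nodes) {
  adj <- vector("list", n_nodes)
  for (k in seq_len(nrow(edges))) {
    i <- edges$i[k]; j <- edges$j[k]; w <- weights[k]
    adj[[i]] <- rbind(adj[[i]], c(j, w))
    adj[[j]] <- rbind(adj[[j]], c(i, w))
  }
  best <- Inf
  walk <- function(node, visited, cost) {
    if (cost >= best) return()
    if (node == to) { best <<- cost; return() }
    nb <- adj[[node]]
    if (is.null(nb)) return()
    for (r in seq_len(nrow(nb)))
      if (!nb[r, 1] %in% visited)
        walk(nb[r, 1], c(visited, nb[r, 1]), cost + nb[r, 2])
  }
  walk(from, from, 0)
  best
}

# list of n simulated replicates of a profile at a given sigma
make_replicates <- function(profile, n, sigma, n_multinomial = 100L) {
  params <- replicate_sim_params(n_multinomial, sigma, max(2L, n))
  lapply(seq_len(n), function(i) simulate_replicate(profile, params))
}

# profile pair with disjoint point masses planted at given sites
plant_point_masses <- function(profile, sites, offset = 5L) {
  va <- profile$values; vb <- profile$values
  for (r in sites) {
    a <- rep(0, 20); a[(r %% 20) + 1] <- 1
    b <- rep(0, 20); b[((r + offset) %% 20) + 1] <- 1
    va[r, ] <- a; vb[r, ] <- b
  }
  list(a = preference_profile(va), b = preference_profile(vb))
}
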