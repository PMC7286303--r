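# Brute-force oracles and fixture builders shared across test files.
# All oracles are deliberately naive (scalar loops, direct formula
# evaluation) and independent of the package's vectorized code paths.

random_connectome <- function(n, p_edge = 0.5, weighted = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  on <- runif(length(ut)) < p_edge
  w[ut[on]] <- if (weighted) runif(sum(on), 0.05, 1) else 1
  w <- w + t(w)
  connectome(w, sprintf("r%02d", seq_len(n)),
             if (weighted) "fa_w" else "struct_binary")
}

# scalar triple-loop all-pairs shortest paths on a length matrix
oracle_apsp <- function(L) {
  n <- nrow(L)
  D <- L
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_lengths <- function(w, binary) {
  L <- matrix(Inf, nrow(w), ncol(w))
  for (i in seq_len(nrow(w)))
    for (j in seq_len(ncol(w)))
      if (i == j) L[i, j] <- 0
      else if (w[i, j] != 0) L[i, j] <- if (binary) 1 else 1 / w[i, j]
  L
}

oracle_global_eff <- function(w, binary) {
  n <- nrow(w)
  if (n < 2) return(0)
  D <- oracle_apsp(oracle_lengths(w, binary))
  tot <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (i != j && is.finite(D[i, j])) tot <- tot + 1 / D[i, j]
  tot / (n * (n - 1))
}

oracle_local_eff <- function(w, binary) {
  n <- nrow(w)
  vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] != 0)
    if (length(nb) < 2) return(0)
    oracle_global_eff(w[nb, nb, drop = FALSE], binary)
  }, numeric(1))
}

# direct triangle enumeration
oracle_clustering <- function(w, binary) {
  n <- nrow(w)
  mx <- max(w)
  vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] != 0)
    k <- length(nb)
    if (k < 2) return(0)
    tot <- 0
    for (a in seq_len(k - 1))
      for (b in (a + 1):k) {
        j1 <- nb[a]; j2 <- nb[b]
        if (w[j1, j2] != 0) {
          tot <- tot + if (binary) 1
          else ((w[i, j1] / mx) * (w[i, j2] / mx) * (w[j1, j2] / mx))^(1 / 3)
        }
      }
    2 * tot / (k * (k - 1))
  }, numeric(1))
}

# small helper: symmetric matrix from upper-triangle edge list
sym_from_edges <- function(n, edges, weights = 1) {
  w <- matrix(0, n, n)
  weights <- rep_len(weights, nrow(edges))
  for (e in seq_len(nrow(edges))) {
    w[edges[e, 1], edges[e, 2]] <- weights[e]
    w[edges[e, 2], edges[e, 1]] <- weights[e]
  }
  w
}

tiny_atlas <- function(n = 10, n_gm = 6, seed = 42) generate_atlas(n, n_gm, seed)

# null two-group stacks of random symmetric "connectomes"
null_stack <- function(n_nodes, n_subj, sd = 1, mean = 0) {
  arr <- array(0, c(n_nodes, n_nodes, n_subj))
  for (s in seq_len(n_subj)) {
    m <- matrix(0, n_nodes, n_nodes)
    m[upper.tri(m)] <- rnorm(n_nodes * (n_nodes - 1) / 2, mean, sd)
    arr[, , s] <- m + t(m)
  }
  arr
}
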