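# Independent brute-force oracles, deliberately written with different
# algorithms than the package implementation.

# Permutations of 1..n by successive insertion (contrast with the
# first-element recursion used in the package).
oracle_perms <- function(n) {
  out <- matrix(1L, 1L, 1L)
  for (k in 2:n) {
    grown <- vector("list", k)
    for (pos in seq_len(k)) {
      grown[[pos]] <- cbind(out[, seq_len(pos - 1L), drop = FALSE], k,
                            out[, seq(pos, k - 1L)[seq_len(k - pos)],
                                drop = FALSE])
    }
    out <- do.call(rbind, grown)
  }
  unname(out)
}

# Exact two-sided Spearman permutation p-value: permute raw y, recompute
# rho with stats::cor(method = "spearman") each time.
oracle_spearman_p <- function(x, y) {
  n <- length(x)
  rho_obs <- stats::cor(x, y, method = "spearman")
  P <- oracle_perms(n)
  rho_perm <- apply(P, 1L, function(idx)
    stats::cor(x, y[idx], method = "spearman"))
  mean(abs(rho_perm) >= abs(rho_obs) - 1e-9)
}

# All-pairs shortest paths by Floyd-Warshall over lengths 1/W.
oracle_floyd_warshall <- function(W) {
  n <- ncol(W)
  D <- matrix(Inf, n, n)
  D[W > 0] <- 1 / W[W > 0]
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_global_efficiency <- function(W) {
  n <- ncol(W)
  D <- oracle_floyd_warshall(W)
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && is.finite(D[i, j])) total <- total + 1 / D[i, j]
  total / (n * (n - 1))
}

# Onnela clustering by explicit triple enumeration.
oracle_clustering <- function(W) {
  n <- ncol(W)
  mx <- max(W)
  if (mx == 0) return(rep(0, n))
  Wn <- W / mx
  out <- numeric(n)
  for (i in seq_len(n)) {
    k_i <- sum(W[i, ] > 0)
    if (k_i < 2) next
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n))
      if (j != i && h != i && j != h)
        acc <- acc + (Wn[i, j] * Wn[i, h] * Wn[j, h])^(1 / 3)
    out[i] <- acc / (k_i * (k_i - 1))
  }
  out
}

# Random symmetric non-negative weight matrix with zero diagonal.
random_weight_matrix <- function(n, p_edge = 0.5) {
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  vals <- ifelse(stats::runif(sum(ut)) < p_edge, stats::runif(sum(ut)), 0)
  W[ut] <- vals
  W + t(W)
}
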