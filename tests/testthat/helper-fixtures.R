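# Shared helpers: independent oracles and small generators used across tests.

# Direct plug-in entropy, written independently of the package internals.
oracle_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

# Degree of node i in a 0/1 adjacency matrix by explicit edge enumeration.
oracle_degree <- function(adj) {
  p <- nrow(adj)
  vapply(seq_len(p), function(i) {
    sum(vapply(seq_len(p), function(j) j != i && adj[i, j] != 0, TRUE))
  }, 0L)
}

# Joint count table of two label vectors via table() (independent of the
# tabulate-based fast path).
oracle_joint <- function(lx, ly, nbx, nby) {
  as.matrix(table(factor(lx, levels = seq_len(nbx)),
                  factor(ly, levels = seq_len(nby))))
}

random_counts <- function(max_bins = 8, max_total = 60) {
  m <- sample(2:max_bins, 1)
  counts <- stats::rmultinom(1, sample(5:max_total, 1), rep(1 / m, m))[, 1]
  if (sum(counts > 0) == 0) counts[1] <- 1
  counts
}

gaussian_pair <- function(n, rho) {
  z <- stats::rnorm(n)
  x <- z
  y <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
  cbind(x, y)
}
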