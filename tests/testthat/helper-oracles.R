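# Independent oracles and fixture builders used across the suite.

# Spearman rho by the rank-difference formula (valid without ties):
# 1 - 6 sum(d^2) / (n (n^2 - 1)).
spearman_rank_formula <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Density by brute-force pair enumeration: count pairs (i < j) flagged as
# edges in a logical adjacency matrix, divide by the enumerated pair count.
density_enumeration <- function(adj) {
  n <- nrow(adj)
  pairs <- 0
  edges <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pairs <- pairs + 1
      if (adj[i, j]) edges <- edges + 1
    }
  }
  edges / pairs
}

# Pearson chi-square on a 2x2 by the closed form N (ad - bc)^2 / (r1 r2 c1 c2).
chisq_2x2_closed_form <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Forge a bootstrap ensemble with fully controlled rho/p matrices, to test
# edge filtering in isolation. `edge_rho`/`edge_p` are vectors of length B
# for the (1,2) pair of a G-node ensemble; all other pairs stay null.
fake_ensemble <- function(edge_rho, edge_p, G = 3) {
  B <- length(edge_rho)
  groups <- paste0("g", seq_len(G))
  mats <- lapply(seq_len(B), function(b) {
    rho <- diag(G)
    p <- matrix(1, G, G)
    diag(p) <- 0
    rho[1, 2] <- rho[2, 1] <- edge_rho[b]
    p[1, 2] <- p[2, 1] <- edge_p[b]
    dimnames(rho) <- dimnames(p) <- list(groups, groups)
    structure(list(rho = rho, p = p, n = 100,
                   degenerate = matrix(FALSE, G, G)),
              class = "nutrinet_cormat")
  })
  structure(
    list(matrices = mats, indices = vector("list", B), n = 100,
         groups = groups, B = B, seed = 0L),
    class = "nutrinet_ensemble"
  )
}

# Small deterministic intake tibble.
toy_intake <- function() {
  tibble::tibble(
    subject_id = 1:3,
    a = c(100, 50, 10),
    b = c(300, 50, 90)
  )
}
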