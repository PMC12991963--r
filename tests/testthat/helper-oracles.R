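# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the package's own computational paths.

# Brute-force multiple-site partition: enumerate every unordered plot pair,
# accumulate the shared-abundance and surplus component sums explicitly.
oracle_multisite <- function(mat) {
  n <- nrow(mat)
  SA <- Smin <- Smax <- 0
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      x <- mat[j, ]; y <- mat[k, ]
      A <- sum(pmin(x, y))
      B <- sum(x) - A
      C <- sum(y) - A
      SA <- SA + A
      Smin <- Smin + min(B, C)
      Smax <- Smax + max(B, C)
    }
  }
  total <- (Smin + Smax) / (2 * SA + Smin + Smax)
  balanced <- Smin / (Smin + SA)
  c(total = total, balanced = balanced, gradient = total - balanced)
}

# Incidence-based multiple-site Sorensen family, coded with species-set
# operations on a presence/absence matrix: Sorensen dissimilarity, Simpson
# turnover, nestedness-resultant component.
oracle_incidence <- function(mat01) {
  n <- nrow(mat01)
  sets <- apply(mat01 > 0, 1, which, simplify = FALSE)
  Sa <- Sb <- Sc <- 0
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      shared <- length(intersect(sets[[j]], sets[[k]]))
      bj <- length(setdiff(sets[[j]], sets[[k]]))
      ck <- length(setdiff(sets[[k]], sets[[j]]))
      Sa <- Sa + shared
      Sb <- Sb + min(bj, ck)
      Sc <- Sc + max(bj, ck)
    }
  }
  sor <- (Sb + Sc) / (2 * Sa + Sb + Sc)
  sim <- Sb / (Sa + Sb)
  c(total = sor, balanced = sim, gradient = sor - sim)
}

# Hand evaluation of the alpha indices on a single abundance row, on
# Hellinger proportions when transformed.
oracle_alpha_row <- function(x, transformed = TRUE) {
  h <- if (transformed) sqrt(x / sum(x)) else x
  p <- h[h > 0] / sum(h)
  c(richness = sum(x > 0),
    shannon = -sum(p * log(p)),
    inv_simpson = 1 / sum(p^2))
}

# Random integer community matrix (may contain zero cells, never an
# all-zero row unless asked for).
rand_count_matrix <- function(n_plots, n_species, lambda = 3,
                              zero_prob = 0.3) {
  m <- matrix(rpois(n_plots * n_species, lambda) *
                (runif(n_plots * n_species) > zero_prob),
              nrow = n_plots,
              dimnames = list(sprintf("p%02d", seq_len(n_plots)),
                              sprintf("s%02d", seq_len(n_species))))
  empty <- rowSums(m) == 0
  m[empty, 1] <- 1
  m
}

# Small, fast simulation configurations reused across tests.
tiny_null_cfg <- function(...) {
  scenario_preset("null", n_sites = 1, n_pairs = 3, months = c(0, 6, 12),
                  pool_size = 25, richness0 = 10, ...)
}

small_null_cfg <- function(...) {
  scenario_preset("null", n_sites = 1, n_pairs = 5,
                  months = seq(0, 42, by = 6), pool_size = 30,
                  richness0 = 10, ...)
}
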