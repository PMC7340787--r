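# Shared fixtures, built in code at test time.

# random symmetric adjacency with unit diagonal, entries in [0, 1]
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  a
}

# brute-force O(n^3) topological overlap, straight from the definition
tom_oracle <- function(a) {
  n <- nrow(a)
  w <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i])
    kj <- sum(a[j, -j])
    w[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  dimnames(w) <- dimnames(a)
  w
}

# expression matrix with named dimnames from a plain numeric matrix
as_expr <- function(m, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%03d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  m
}

# small planted design used by several module-level tests
small_design <- function(seed, ...) {
  synthetic_design(n_genes = 120L, n_samples = 150L,
                   module_sizes = c(40L, 30L), seed = seed, ...)
}
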