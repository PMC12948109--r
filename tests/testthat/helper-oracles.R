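# Brute-force Haseman-Elston oracle: enumerate every unordered pair of
# distinct individuals, average the two orientations of the trait product
# when both are observed, and fit the regression with lm().  Independent of
# the package's sufficient-statistic implementation.
brute_he <- function(M, N, K) {
  pairs <- list()
  for (i in names(M)) {
    for (j in names(N)) {
      if (i == j) next
      key <- paste(sort(c(i, j)), collapse = "|")
      pairs[[key]] <- c(pairs[[key]], unname(M[i] * N[j]))
    }
  }
  y <- vapply(pairs, mean, numeric(1))
  x <- vapply(names(pairs), function(k) {
    ij <- strsplit(k, "|", fixed = TRUE)[[1]]
    K[ij[1], ij[2]]
  }, numeric(1))
  s <- summary(stats::lm(y ~ x))$coefficients
  list(beta = s[2, 1], se = s[2, 2], p = s[2, 4], n_pairs = length(y))
}

# Random symmetric kinship-like matrix for toy examples.
toy_kinship <- function(n, seed) {
  set.seed(seed)
  K <- matrix(stats::rnorm(n * n, 0.25, 0.06), n, n)
  K <- (K + t(K)) / 2
  diag(K) <- 0.5
  ids <- sprintf("i%02d", seq_len(n))
  dimnames(K) <- list(ids, ids)
  K
}

named_rnorm <- function(n, ids = sprintf("i%02d", seq_len(n))) {
  stats::setNames(stats::rnorm(length(ids)), ids)
}
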