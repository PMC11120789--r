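# Shared fixture builders: all test data are generated in code.

random_positive_table <- function(n_samples, n_features, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::runif(n_samples * n_features, 0.1, 10),
              n_samples, n_features,
              dimnames = list(paste0("S", seq_len(n_samples)),
                              paste0("F", seq_len(n_features))))
  m
}

random_orthogonal <- function(d, seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# 99% binomial band around a nominal rejection level
binom_band <- function(level, replicates) {
  half <- stats::qnorm(0.995) * sqrt(level * (1 - level) / replicates)
  c(level - half, level + half)
}
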