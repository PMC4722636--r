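# Small in-code fixtures shared across test files.

rand_net <- function(n_drugs, n_targets, density = 0.3, seed = 1) {
  withr::with_seed(seed, {
    Y <- matrix(rbinom(n_drugs * n_targets, 1, density), n_targets, n_drugs)
    if (sum(Y) == 0) Y[1, 1] <- 1
    if (sum(Y) == length(Y)) Y[1, 1] <- 0
    dti_network(Y, sprintf("d%02d", seq_len(n_drugs)),
                sprintf("t%02d", seq_len(n_targets)))
  })
}

# strictly positive definite random kernel with unit-ish scale
rand_pd <- function(n, seed = 1, jitter = 0.5) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * (n + 2)), n)
    K <- tcrossprod(X) / (n + 2)
    K + jitter * diag(n)
  })
}

# independent O(n^2) average-precision oracle: for each positive, the
# precision over everything scoring at least as high (tie groups share
# their end-of-group precision).
aupr_rank_walk <- function(scores, labels) {
  pos <- which(labels == 1)
  mean(vapply(pos, function(i) {
    ge <- scores >= scores[i]
    sum(labels[ge]) / sum(ge)
  }, numeric(1)))
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
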