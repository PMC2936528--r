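# Monte-Carlo oracle for the M1 exceptionality score: refit the first-order
# chain from the reference sequence, resimulate, and take the empirical sd
# of N(word) - Ehat(word) across replicates.  Counting and expectation here
# are computed directly on integer matrices, independent of the package's
# count/variance path.
mc_oracle_z <- function(word, ref_seq, n_rep = 10000, seed = 1) {
  bases <- c("A", "C", "G", "T")
  ref <- match(strsplit(ref_seq, "")[[1]], bases)
  L <- length(ref)
  # empirical transition matrix from consecutive pairs
  Pm <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4)
    Pm[i, j] <- sum(ref[-L] == i & ref[-1] == j)
  Pm <- Pm / rowSums(Pm)
  X <- simulate_m1(n_rep, L, Pm, seed = seed, as_matrix = TRUE)

  idx <- match(strsplit(word, "")[[1]], bases)
  h <- length(idx)
  count_word <- function(M, w) {
    hits <- matrix(TRUE, nrow(M), ncol(M) - length(w) + 1)
    for (j in seq_along(w))
      hits <- hits & (M[, j:(ncol(M) - length(w) + j), drop = FALSE] == w[j])
    rowSums(hits)
  }
  Nw <- count_word(X, idx)
  pair_counts <- vapply(seq_len(h - 1), function(i)
    count_word(X, idx[i:(i + 1)]), numeric(n_rep))
  int_counts <- vapply(seq(2, h - 1), function(i)
    rowSums(X == idx[i]), numeric(n_rep))
  Ehat <- apply(pair_counts, 1, prod) / apply(int_counts, 1, prod)
  d <- Nw - Ehat

  ref_mat <- matrix(ref, nrow = 1)
  obs <- count_word(ref_mat, idx)
  e_ref <- prod(vapply(seq_len(h - 1), function(i)
    count_word(ref_mat, idx[i:(i + 1)]), numeric(1))) /
    prod(vapply(seq(2, h - 1), function(i) sum(ref == idx[i]), numeric(1)))
  (obs - e_ref) / stats::sd(d)
}
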