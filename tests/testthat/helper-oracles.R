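# Independent oracles kept deliberately naive: they share no code with the
# implementation they check.

# minimum path cost over an explicit enumeration of all monotone warping
# paths (steps down, right, or diagonal) through a local-cost matrix
dtw_brute_force <- function(C) {
  J <- nrow(C)
  I <- ncol(C)
  best <- Inf
  recurse <- function(j, i, acc) {
    acc <- acc + C[j, i]
    if (j == J && i == I) {
      if (acc < best) best <<- acc
      return(invisible(NULL))
    }
    if (j < J && i < I) recurse(j + 1, i + 1, acc)
    if (j < J) recurse(j + 1, i, acc)
    if (i < I) recurse(j, i + 1, acc)
    invisible(NULL)
  }
  recurse(1L, 1L, 0)
  best
}

# squared-distance cost matrix by explicit double loop
cost_matrix_loops <- function(X, M) {
  out <- matrix(0, nrow(X), nrow(M))
  for (j in seq_len(nrow(X))) {
    for (i in seq_len(nrow(M))) {
      out[j, i] <- sum((X[j, ] - M[i, ])^2)
    }
  }
  out
}
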