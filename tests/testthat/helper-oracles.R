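# Independent brute-force oracles used to cross-check the implementation.

# Spearman's rho via explicit rank construction (midranks by hand).
oracleSpearman <- function(x, y) {
  # rank = average position of equal values in the sorted vector (midranks)
  midrank <- function(v) sapply(v, function(vi) mean(which(sort(v) == vi)))
  rx <- midrank(x); ry <- midrank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# All-pairs distance scan for searchlight neighborhoods.
oracleNeighbors <- function(xyz, radius) {
  n <- nrow(xyz)
  lapply(seq_len(n), function(i) {
    which(sapply(seq_len(n), function(j)
      sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= radius))
  })
}

# Benjamini-Hochberg step-up applied literally to sorted p-values.
oracleBH <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= seq_len(m) / m * alpha)
  sig <- logical(m)
  if (length(below)) sig[o[seq_len(max(below))]] <- TRUE
  sig
}

# Exact permutation p for Spearman's rho by full enumeration (n <= 6).
oraclePermP <- function(x, y, twoSided = TRUE) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  rho <- cor(x, y, method = "spearman")
  stat <- if (twoSided) abs else identity
  vals <- sapply(perms(y), function(yy) cor(x, yy, method = "spearman"))
  mean(stat(vals) >= stat(rho) - 1e-12)
}
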