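# Independent brute-force oracles used to cross-check the implementation.

# Sample entropy by exhaustive template-pair enumeration over embedding
# matrices (no shared code with the package's counting kernel).
brute_sampen <- function(x, m = 2, r_frac = 0.2) {
  n <- length(x)
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) return(list(value = 0, A = NA, B = NA, degenerate = TRUE))
  r <- r_frac * s
  nt <- n - m
  emb <- function(width) vapply(0:(width - 1), function(k) x[(1:nt) + k],
                                numeric(nt))
  count_pairs <- function(M) {
    cnt <- 0L
    for (i in 1:(nrow(M) - 1)) {
      d <- abs(M[(i + 1):nrow(M), , drop = FALSE] -
                 matrix(M[i, ], nrow(M) - i, ncol(M), byrow = TRUE))
      cheb <- do.call(pmax, lapply(seq_len(ncol(d)), function(j) d[, j]))
      cnt <- cnt + sum(cheb <= r)
    }
    cnt
  }
  B <- count_pairs(emb(m))
  A <- count_pairs(emb(m + 1))
  if (B == 0 || A == 0)
    list(value = NA_real_, A = A, B = B, degenerate = TRUE)
  else list(value = -log(A / B), A = A, B = B, degenerate = FALSE)
}

# Closed-form OLS slope/intercept via normal equations.
brute_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# Closed-form pooled two-sample t.
brute_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}
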