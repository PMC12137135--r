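# Independent brute-force oracles used to cross-check the implementation.

# sliding median with truncated windows, naive loop
oracle_sliding_median <- function(x, order) {
  half <- (order - 1L) %/% 2L
  n <- length(x)
  sapply(seq_len(n), function(i) {
    w <- x[max(1L, i - half):min(n, i + half)]
    stats::median(w[!is.na(w)])
  })
}

# per-window OLS slope via lm(), percent per minute
oracle_moving_slope <- function(x, t, window) {
  lo <- (window - 1L) %/% 2L
  hi <- window %/% 2L
  n <- length(x)
  sapply(seq_len(n), function(i) {
    j <- max(1L, i - lo):min(n, i + hi)
    unname(stats::coef(stats::lm(x[j] ~ I(t[j] / 60)))[2L])
  })
}

# 3x3 neighborhood median with nearest-edge replication, naive loop
oracle_median3x3 <- function(m) {
  d <- dim(m)
  out <- m
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) {
    ri <- pmin(d[1L], pmax(1L, (i - 1L):(i + 1L)))
    ci <- pmin(d[2L], pmax(1L, (j - 1L):(j + 1L)))
    out[i, j] <- stats::median(m[ri, ci])
  }
  out
}

# dense grid search for the non-negative 2-chromophore least squares;
# returns the grid minimizer and objective values
oracle_grid_nnls <- function(m, ext, n_grid = 1001L, c_max = NULL) {
  E <- cbind(ext$eps_hbo, ext$eps_hbd)
  G <- crossprod(E)
  B <- as.numeric(crossprod(E, m))
  if (is.null(c_max)) {
    cu <- solve(G, B)
    c_max <- max(1e-6, 2 * max(abs(cu)))
  }
  g <- seq(0, c_max, length.out = n_grid)
  a1 <- G[1, 1] * g^2 - 2 * B[1] * g
  a2 <- G[2, 2] * g^2 - 2 * B[2] * g
  f <- outer(a1, a2, "+") + 2 * G[1, 2] * outer(g, g)
  k <- arrayInd(which.min(f), dim(f))
  list(c = c(g[k[1]], g[k[2]]),
       objective = min(f) + sum(m^2),
       resolution = g[2] - g[1])
}

# residual objective ||E c - m||^2
nnls_objective <- function(c, m, ext) {
  E <- cbind(ext$eps_hbo, ext$eps_hbd)
  sum((E %*% c - m)^2)
}
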