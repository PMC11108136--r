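# Independent oracles, coded separately from the production paths.

# Natural cubic spline via the textbook tridiagonal system for the
# second derivatives (M_1 = M_n = 0), with linear extrapolation beyond
# the boundary knots. Deliberately does not use stats::spline*.
natural_spline_oracle <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  M <- numeric(n)
  if (n > 2) {
    A <- matrix(0, n - 2, n - 2)
    b <- numeric(n - 2)
    for (r in seq_len(n - 2)) {
      i <- r + 1
      if (r > 1) A[r, r - 1] <- h[i - 1]
      A[r, r] <- 2 * (h[i - 1] + h[i])
      if (r < n - 2) A[r, r + 1] <- h[i]
      b[r] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
    }
    M[2:(n - 1)] <- solve(A, b)
  }
  eval1 <- function(z) {
    if (z <= x[1]) {
      slope <- (y[2] - y[1]) / h[1] - h[1] * M[2] / 6
      return(y[1] + slope * (z - x[1]))
    }
    if (z >= x[n]) {
      slope <- (y[n] - y[n - 1]) / h[n - 1] + h[n - 1] * M[n - 1] / 6
      return(y[n] + slope * (z - x[n]))
    }
    i <- findInterval(z, x, rightmost.closed = TRUE)
    hi <- h[i]
    M[i] * (x[i + 1] - z)^3 / (6 * hi) + M[i + 1] * (z - x[i])^3 / (6 * hi) +
      (y[i] / hi - M[i] * hi / 6) * (x[i + 1] - z) +
      (y[i + 1] / hi - M[i + 1] * hi / 6) * (z - x[i])
  }
  vapply(xout, eval1, 0)
}

# Brute-force life-table expectancy: explicit survival products and
# person-years sums, naive double loop, no cumprod/cumsum.
life_table_ex_oracle <- function(qx, ax = 0.5, terminal_mx = NULL, at = 0) {
  K <- length(qx)
  ax <- rep_len(ax, K)
  surv <- function(y) {  # P(alive at exact age y), ages 0-based
    p <- 1
    if (y > 0) for (k in 1:y) p <- p * (1 - qx[k])
    p
  }
  L <- numeric(0)
  for (y in 1:K) {
    ly <- surv(y - 1); ly1 <- surv(y)
    L[y] <- ly1 + ax[y] * (ly - ly1)
  }
  if (!is.null(terminal_mx)) L <- c(L, surv(K) / terminal_mx)
  total <- 0
  for (y in (at + 1):length(L)) total <- total + L[y]
  total / surv(at)
}

# Direct tally of transition frequencies from a panel, independent of
# count_transitions()/estimate_group_matrices().
brute_force_phat <- function(records, sex, group, i, j,
                             scheme = age_group_scheme()) {
  lo <- scheme$breaks[group]
  hi <- scheme$upper[group]
  in_cell <- records$sex == sex & records$age >= lo & records$age < hi &
    records$state_t == i
  if (!sum(in_cell)) return(NA_real_)
  sum(in_cell & records$state_t1 == j) / sum(in_cell)
}
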