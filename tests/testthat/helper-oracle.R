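# Independent exhaustive-search oracle for small windowed fits: enumerates
# every ordered sequence of up to `max_segments` candidate lines whose
# consecutive intersections fall strictly increasing inside the window,
# assigns probes by position, and returns the minimum of
# SSE + penalty * (#segments - 1). Shares nothing with the DP implementation.
oracle_objective <- function(x, y, candidates, penalty,
                             max_segments = 3, anchor = NULL) {
  m <- candidates$slope
  b <- candidates$intercept
  K <- length(m)
  n <- length(x)
  line_val <- function(j, xx) b[j] + m[j] * (xx - x[1])
  sse_between <- function(j, lo, hi) {
    if (hi < lo) return(0)
    sum((y[lo:hi] - line_val(j, x[lo:hi]))^2)
  }
  anchor_cost <- function(j) {
    if (is.null(anchor)) return(0)
    4 * (anchor$value - line_val(j, anchor$pos))^2
  }
  xint <- function(j, k) {
    if (m[j] == m[k]) return(NA_real_)
    x[1] + (b[k] - b[j]) / (m[j] - m[k])
  }

  best <- Inf
  # one segment
  for (j in 1:K) {
    best <- min(best, sse_between(j, 1, n) + anchor_cost(j))
  }
  if (max_segments >= 2) {
    for (j in 1:K) for (k in 1:K) {
      if (k == j) next
      t1 <- xint(j, k)
      if (is.na(t1) || t1 <= x[1] || t1 >= x[n]) next
      g1 <- findInterval(t1, x)
      obj <- anchor_cost(j) + sse_between(j, 1, g1) +
        sse_between(k, g1 + 1, n) + penalty
      best <- min(best, obj)
      if (max_segments >= 3) {
        for (l in 1:K) {
          if (l == k) next
          t2 <- xint(k, l)
          if (is.na(t2) || t2 <= t1 || t2 >= x[n]) next
          g2 <- findInterval(t2, x)
          if (g2 <= g1) next
          obj3 <- anchor_cost(j) + sse_between(j, 1, g1) +
            sse_between(k, g1 + 1, g2) + sse_between(l, g2 + 1, n) +
            2 * penalty
          best <- min(best, obj3)
        }
      }
    }
  }
  best
}
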