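# Independent brute-force transcriptions of the enrichment statistics,
# kept deliberately naive (explicit loops, no shared code with the package)
# so they can serve as oracles.

oracle_fc <- function(expt, ctrl) {
  n <- length(expt)
  se <- 0
  for (j in 1:n) se <- se + expt[j] + 1
  sc <- 0
  for (k in 1:n) sc <- sc + ctrl[k] + 1
  out <- numeric(n)
  for (i in 1:n) out[i] <- log2(((expt[i] + 1) / se) / ((ctrl[i] + 1) / sc))
  out
}

oracle_z <- function(expt, ctrl) {
  Te <- 0
  for (j in seq_along(expt)) Te <- Te + expt[j]
  Tc <- 0
  for (j in seq_along(ctrl)) Tc <- Tc + ctrl[j]
  out <- numeric(length(expt))
  for (i in seq_along(expt)) {
    fcomb <- (expt[i] + ctrl[i]) / (Te + Tc)
    den <- sqrt(fcomb * (1 - fcomb) / Te + fcomb * (1 - fcomb) / Tc)
    out[i] <- if (den == 0) 0 else (expt[i] / Te - ctrl[i] / Tc) / den
  }
  out
}

# Upper-tail standard-normal probability through the incomplete-gamma
# route, independent of pnorm.
oracle_p <- function(z) {
  ifelse(z >= 0,
         0.5 * stats::pgamma(z^2 / 2, 0.5, lower.tail = FALSE),
         1 - 0.5 * stats::pgamma(z^2 / 2, 0.5, lower.tail = FALSE))
}

# BH step-up by literal definition: q_(i) = min_{j >= i} min(1, p_(j) m / j).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, min(1, p[o[j]] * m / j))
    q[o[i]] <- best
  }
  q
}

# All count vectors of length n with sum between 1 and total_max.
enumerate_counts <- function(n, total_max) {
  g <- as.matrix(do.call(expand.grid, rep(list(0:total_max), n)))
  dimnames(g) <- NULL
  g[rowSums(g) >= 1 & rowSums(g) <= total_max, , drop = FALSE]
}
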