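# Independent brute-force oracles used to cross-check the package
# implementations. These deliberately share no code with the package.

# mean resultant length by explicit complex vector summation
oracle_resultant <- function(angles_deg, axial = TRUE) {
  m <- if (axial) 2 else 1
  z <- sum(exp(1i * m * angles_deg * pi / 180)) / length(angles_deg)
  Mod(z)
}

# hand product-limit estimator
oracle_km <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  out <- data.frame(time = ut, surv = NA_real_)
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d / at_risk)
    out$surv[i] <- s
  }
  out
}

# two-group log-rank chi-square from the hypergeometric O-E/V sums
oracle_logrank <- function(times, events, group) {
  g <- as.integer(as.factor(group)) - 1L
  ut <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (t in ut) {
    n <- sum(times >= t)
    n1 <- sum(times >= t & g == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# exact two-sided Fisher p by enumeration of all tables with fixed margins
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  prob <- function(a) dhyper(a, r1, r2, c1)
  p_obs <- prob(tab[1, 1])
  a_range <- max(0, c1 - r2):min(r1, c1)
  sum(vapply(a_range, prob, numeric(1))[vapply(a_range, prob, numeric(1)) <= p_obs * (1 + 1e-7)])
}

# Cox partial log-likelihood for a single covariate (Efron ties)
oracle_cox_loglik <- function(beta, x, times, events) {
  ll <- 0
  for (t in unique(times[events == 1])) {
    D <- which(times == t & events == 1)
    R <- which(times >= t)
    d <- length(D)
    sr <- sum(exp(beta * x[R]))
    sd <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1) ll <- ll - log(sr - l / d * sd)
  }
  ll
}

oracle_cox_beta <- function(x, times, events, lo = -5, hi = 5) {
  optimize(function(b) oracle_cox_loglik(b, x, times, events),
           c(lo, hi), maximum = TRUE, tol = 1e-9)$maximum
}

# Spearman rho via midranks then Pearson
oracle_spearman <- function(x, y) cor(rank(x), rank(y))

# joint-histogram MI computed independently (nested loops, natural counts)
oracle_mi <- function(a, b, bins) {
  cut_bin <- function(v) {
    r <- range(v)
    pmin(pmax(floor((v - r[1]) / diff(r) * bins) + 1, 1), bins)
  }
  ia <- cut_bin(as.vector(a)); ib <- cut_bin(as.vector(b))
  J <- matrix(0, bins, bins)
  for (k in seq_along(ia)) J[ia[k], ib[k]] <- J[ia[k], ib[k]] + 1
  P <- J / sum(J)
  mi <- 0
  for (i in 1:bins) for (j in 1:bins)
    if (P[i, j] > 0) mi <- mi + P[i, j] * log2(P[i, j] / (sum(P[i, ]) * sum(P[, j])))
  mi
}

# maximum corner/parameter discrepancy between two affine transforms over a box
transform_point_error <- function(a, b, pts) {
  max(sqrt(rowSums((affine_apply(a, pts) - affine_apply(b, pts))^2)))
}
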