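# Independent fixed-step classical RK4 integrator, used as the
# cross-integrator oracle against the adaptive solver.
rk4_integrate <- function(rhs, y0, times, parms) {
  n <- length(times)
  out <- matrix(NA_real_, n, length(y0))
  out[1, ] <- y0
  y <- y0
  for (i in 2:n) {
    h <- times[i] - times[i - 1]
    t <- times[i - 1]
    k1 <- unlist(rhs(t, y, parms))
    k2 <- unlist(rhs(t + h / 2, y + h / 2 * k1, parms))
    k3 <- unlist(rhs(t + h / 2, y + h / 2 * k2, parms))
    k4 <- unlist(rhs(t + h, y + h * k3, parms))
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i, ] <- y
  }
  out
}

# Brute-force double-loop version of the normalized squared-error cost.
naive_cost_se <- function(x, s, gene_max) {
  gene_max <- unname(gene_max)
  total <- 0
  for (j in seq_len(nrow(x))) {
    for (i in seq_len(ncol(x))) {
      total <- total + ((x[j, i] - s[j, i]) / gene_max[j])^2
    }
  }
  unname(total)
}

# Brute-force LASSO penalty sum.
naive_lasso <- function(cost_se, p, pwt, lambda, n_par) {
  pen <- 0
  for (i in seq_along(p)) {
    if (abs(pwt[i]) > 1e-9) pen <- pen + abs((p[i] - pwt[i]) / pwt[i])
  }
  cost_se + lambda * pen / n_par
}

# Cosinor regression oracle: recover mesor/amplitude/phase of a ~24 h
# cosine by linear regression on cos/sin terms.
cosinor_fit <- function(t, x, period = 24) {
  X <- cbind(1, cos(2 * pi * t / period), sin(2 * pi * t / period))
  b <- solve(crossprod(X), crossprod(X, x))
  mesor <- b[1]
  amp <- sqrt(b[2]^2 + b[3]^2)
  phase <- (atan2(b[3], b[2]) * period / (2 * pi)) %% period
  list(mesor = mesor, amplitude = amp, phase = phase)
}
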