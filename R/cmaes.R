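#' Covariance matrix adaptation evolution strategy (CMA-ES)
#'
#' Minimizes a black-box objective with the standard (mu/mu_w, lambda)
#' CMA-ES: weighted recombination, cumulative step-size adaptation and
#' rank-one plus rank-mu covariance updates. Box constraints are handled
#' by evaluating the objective at the coordinate-wise projection onto the
#' box and adding a quadratic penalty on the projection distance, which
#' keeps the search signal smooth near the boundary.
#'
#' @param fn objective function of a numeric vector, returning a scalar.
#' @param x0 numeric start vector.
#' @param sigma0 initial global step size (in the units of `x0`).
#' @param lower,upper numeric bounds (recycled); default unbounded.
#' @param popsize lambda; default `4 + floor(3 * log(d))`.
#' @param max_evals evaluation budget; the best-so-far solution is
#'   returned when it is exhausted. `0` returns `x0` with its cost.
#' @param seed integer seed; the run is reproducible for a fixed seed.
#' @param stop_tol stop early when the range of the population's objective
#'   values falls below this (default 1e-12).
#' @return list with `par` (best point, projected into the box), `value`,
#'   `evals`, `trace` (best value per generation), `seed`.
#' @export
cma_es <- function(fn, x0, sigma0 = 0.3, lower = -Inf, upper = Inf,
                   popsize = NULL, max_evals = 5000, seed = 1L,
                   stop_tol = 1e-12) {
  d <- length(x0)
  lower <- rep_len(lower, d)
  upper <- rep_len(upper, d)
  if (any(lower > upper)) stop("infeasible bounds: lower > upper")
  project <- function(x) pmin(pmax(x, lower), upper)
  eval_pen <- function(x) {
    xp <- project(x)
    fn(xp) + 1e4 * sum((x - xp)^2)
  }

  x0p <- project(x0)
  if (max_evals <= 0) {
    return(list(par = x0p, value = fn(x0p), evals = 1L,
                trace = numeric(0), seed = seed))
  }
  set.seed(seed)

  lambda <- popsize %||% (4L + floor(3 * log(d)))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)

  cc <- (4 + mueff / d) / (d + 4 + 2 * mueff / d)
  cs <- (mueff + 2) / (d + mueff + 5)
  c1 <- 2 / ((d + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((d + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (d + 1)) - 1) + cs
  chiN <- sqrt(d) * (1 - 1 / (4 * d) + 1 / (21 * d^2))

  xmean <- x0
  sigma <- sigma0
  pc <- ps <- numeric(d)
  B <- diag(d); D <- rep(1, d); C <- diag(d)
  inv_sqrt_C <- diag(d)
  eigeneval <- 0L

  best <- list(par = x0p, value = eval_pen(x0))
  evals <- 1L
  trace <- numeric(0)
  gen <- 0L

  while (evals < max_evals) {
    gen <- gen + 1L
    Z <- matrix(stats::rnorm(d * lambda), d, lambda)
    Y <- B %*% (D * Z)
    X <- xmean + sigma * Y
    fvals <- apply(X, 2, eval_pen)
    evals <- evals + lambda
    ord <- order(fvals)
    if (fvals[ord[1]] < best$value) {
      best <- list(par = project(X[, ord[1]]), value = fvals[ord[1]])
    }
    trace <- c(trace, fvals[ord[1]])

    sel <- ord[seq_len(mu)]
    xold <- xmean
    xmean <- as.numeric(X[, sel, drop = FALSE] %*% w)
    ymean <- (xmean - xold) / sigma

    ps <- (1 - cs) * ps +
      sqrt(cs * (2 - cs) * mueff) * as.numeric(inv_sqrt_C %*% ymean)
    hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * gen)) / chiN <
      1.4 + 2 / (d + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * ymean

    artmp <- (X[, sel, drop = FALSE] - xold) / sigma
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * artmp %*% (w * t(artmp))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    sigma <- min(sigma, 1e4)

    if (evals - eigeneval > lambda / (c1 + cmu) / d / 10) {
      eigeneval <- evals
      C <- (C + t(C)) / 2
      eg <- eigen(C, symmetric = TRUE)
      D <- sqrt(pmax(eg$values, 1e-20))
      B <- eg$vectors
      inv_sqrt_C <- B %*% (t(B) / D)
    }
    if (diff(range(fvals)) < stop_tol) break
  }
  list(par = best$par, value = best$value, evals = evals,
       trace = trace, seed = seed)
}
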