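#' Fit configuration
#'
#' Settings shared by the wild-type, knock-out and PK-PD fits.
#'
#' @param free character vector of free parameter names (subset of the
#'   network or PK-PD parameter names). Optimization runs in log-space.
#' @param base_params full parameter vector supplying the non-free values
#'   and the initial guess for the free ones.
#' @param lower,upper named (or scalar) multiplicative bounds on each free
#'   parameter relative to its initial value; defaults span 0.01x-100x.
#' @param sigma0 initial CMA-ES step size in log-units (default 0.3).
#' @param popsize CMA-ES population size (default: library rule for the
#'   dimension).
#' @param max_evals evaluation budget per restart (desk preset 5000).
#' @param restarts number of CMA-ES restarts (default 3).
#' @param seed integer random seed recorded in all outputs.
#' @param amplitude_threshold minimum relative amplitude demanded of every
#'   fitted mRNA trajectory (default 0.05).
#' @param amplitude_exempt genes exempt from the amplitude constraint
#'   (e.g. UGT1A1 for HCT116-like lines).
#' @param amplitude_penalty weight of the additive constraint penalty.
#' @param divergence_threshold relative deviation above which a parameter
#'   counts as divergent from the wild type (default 0.05).
#' @param sim_dt trajectory output step used during fitting (h).
#' @param init_state optional full initial state vector used for every
#'   candidate simulation; by default the state is assembled from the
#'   first data timepoint (fitted mRNAs) plus small positive constants.
#' @return object of class `fit_config`.
#' @export
fit_config <- function(free, base_params = default_clock_parameters(),
                       lower = 0.01, upper = 100, sigma0 = 0.3,
                       popsize = NULL, max_evals = 5000, restarts = 3,
                       seed = 1L, amplitude_threshold = 0.05,
                       amplitude_exempt = character(0),
                       amplitude_penalty = 1e3,
                       divergence_threshold = 0.05, sim_dt = 0.25,
                       init_state = NULL) {
  stopifnot(length(free) >= 1, all(free %in% names(base_params)))
  if (any(lower > upper)) stop("infeasible bounds: lower > upper")
  if (any(lower <= 0)) stop("bounds must be positive multipliers")
  structure(
    list(
      free = free, base_params = base_params,
      lower = lower, upper = upper, sigma0 = sigma0, popsize = popsize,
      max_evals = max_evals, restarts = restarts, seed = as.integer(seed),
      amplitude_threshold = amplitude_threshold,
      amplitude_exempt = amplitude_exempt,
      amplitude_penalty = amplitude_penalty,
      divergence_threshold = divergence_threshold, sim_dt = sim_dt,
      init_state = init_state
    ),
    class = "fit_config"
  )
}

#' Squared-error cost between data and simulation
#'
#' `sum_{i,j} ((x_i^j - s^j(t_i)) / max_k x_k^j)^2` over all genes `j`
#' present both in the dataset and (as `M_<gene>`) in the trajectory,
#' evaluated at the data sampling times. The per-gene normalization by the
#' data maximum gives every mRNA equal weight regardless of its
#' expression level.
#'
#' @param data an [expression_dataset()].
#' @param sim a `clock_trajectory` covering the data window.
#' @param zero_exempt genes with all-zero data to skip (otherwise an
#'   all-zero normalizer is an error).
#' @return scalar cost.
#' @export
cost_squared_error <- function(data, sim, zero_exempt = character(0)) {
  genes <- intersect(data$genes, sub("^M_", "", grep("^M_", colnames(sim$values), value = TRUE)))
  if (length(genes) == 0) stop("no genes shared between data and simulation")
  total <- 0
  for (g in genes) {
    mx <- data$gene_max[[g]]
    if (mx <= 0) {
      if (g %in% zero_exempt) next
      stop(sprintf("gene '%s' has all-zero data; normalizer undefined", g))
    }
    s <- interp_species(sim, paste0("M_", g), data$times)
    total <- total + sum(((data$values[g, ] - s) / mx)^2)
  }
  total
}

#' LASSO-regularized cost
#'
#' `cost_SE + lambda * (1/n_par) * sum_i |(p_i - p_i^WT) / p_i^WT|`.
#' Parameters whose wild-type value is below 1e-9 in magnitude are
#' excluded from the sum (their relative deviation is undefined).
#'
#' @param cost_se squared-error cost of the candidate fit.
#' @param params named candidate parameter vector (the fitted subset).
#' @param wt_params wild-type values, aligned with `params`.
#' @param lambda penalty term (>= 0).
#' @param n_par number of fitted parameters (defaults to
#'   `length(params)`; must be positive).
#' @return scalar regularized cost.
#' @export
lasso_cost <- function(cost_se, params, wt_params, lambda,
                       n_par = length(params)) {
  if (n_par == 0) stop("n_par must be positive")
  stopifnot(length(params) == length(wt_params))
  ok <- abs(wt_params) > 1e-9
  pen <- sum(abs((params[ok] - wt_params[ok]) / wt_params[ok]))
  cost_se + lambda * pen / n_par
}

#' Oscillation amplitude constraint
#'
#' Checks per gene whether the simulated mRNA trajectory oscillates with
#' relative amplitude `(max - min)/max` above the threshold over the
#' fitted window. Exempt genes always pass; a non-exempt gene with zero
#' maximum fails.
#'
#' @param sim a `clock_trajectory`.
#' @param genes genes to check (without the `M_` prefix).
#' @param threshold minimum relative amplitude (default 0.05).
#' @param exempt genes that pass regardless.
#' @param window optional `c(t0, t1)` restricting the check.
#' @return named logical vector; attribute `"amplitude"` carries the
#'   measured relative amplitudes.
#' @export
amplitude_constraint <- function(sim, genes, threshold = 0.05,
                                 exempt = character(0), window = NULL) {
  keep <- rep(TRUE, length(sim$time))
  if (!is.null(window)) keep <- sim$time >= window[1] & sim$time <= window[2]
  ra <- vapply(genes, function(g) {
    relative_amplitude(sim$values[keep, paste0("M_", g)])
  }, numeric(1))
  pass <- ra > threshold
  pass[genes %in% exempt] <- TRUE
  names(pass) <- genes
  attr(pass, "amplitude") <- ra
  pass
}

#' Pooled coefficient of determination
#'
#' `1 - SS_res / SS_tot` over all gene series, each normalized by its data
#' maximum (the same scaling as the fitting cost). Values can be negative
#' when the simulation fits worse than the per-gene mean (e.g. comparing
#' a knock-out fit against wild-type data).
#'
#' @param data an [expression_dataset()].
#' @param sim a `clock_trajectory` covering the data window.
#' @param zero_exempt genes with all-zero data to skip.
#' @return scalar R squared.
#' @export
coefficient_of_determination <- function(data, sim,
                                         zero_exempt = character(0)) {
  genes <- intersect(data$genes, sub("^M_", "", grep("^M_", colnames(sim$values), value = TRUE)))
  ss_res <- 0
  ss_tot <- 0
  for (g in genes) {
    mx <- data$gene_max[[g]]
    if (mx <= 0) {
      if (g %in% zero_exempt) next
      stop(sprintf("gene '%s' has all-zero data", g))
    }
    x <- data$values[g, ] / mx
    s <- interp_species(sim, paste0("M_", g), data$times) / mx
    ss_res <- ss_res + sum((x - s)^2)
    ss_tot <- ss_tot + sum((x - mean(x))^2)
  }
  if (ss_tot <= 0) stop("zero total variance; R squared undefined")
  1 - ss_res / ss_tot
}

#' Parameters diverging from the wild type
#'
#' Names and relative deviations of parameters with
#' `|p / p_WT - 1| > threshold`. Entries whose wild-type value is below
#' 1e-9 in magnitude are excluded (relative deviation undefined).
#'
#' @param fit_params,wt_params named, aligned parameter vectors.
#' @param threshold relative-deviation threshold (default 0.05).
#' @return named numeric vector of deviations of the divergent parameters.
#' @export
divergent_parameters <- function(fit_params, wt_params, threshold = 0.05) {
  if (!identical(sort(names(fit_params)), sort(names(wt_params)))) {
    stop("parameter sets do not match")
  }
  wt <- wt_params[names(fit_params)]
  ok <- abs(wt) > 1e-9
  dev <- abs(fit_params[ok] / wt[ok] - 1)
  dev[dev > threshold]
}

# Internal: objective closure for clock fitting.
make_clock_objective <- function(data, network, config, lambda = 0,
                                 wt_params = NULL) {
  free <- config$free
  base <- config$base_params
  init <- config$init_state %||% initial_state(
    network,
    mrna_init = stats::setNames(
      data$values[intersect(data$genes, network$genes), 1],
      intersect(data$genes, network$genes)
    )
  )
  tspan <- range(data$times)
  genes <- intersect(data$genes, network$genes)
  wt_free <- if (!is.null(wt_params)) wt_params[free] else NULL
  function(logx) {
    p <- base
    p[free] <- exp(logx)
    traj <- try(
      simulate_clock(network, p, init_state = init, t_span = tspan,
                     schedule = NULL, dt = config$sim_dt),
      silent = TRUE
    )
    if (inherits(traj, "try-error")) return(1e8)
    cost <- try(
      cost_squared_error(data, traj, zero_exempt = config$amplitude_exempt),
      silent = TRUE
    )
    if (inherits(cost, "try-error") || !is.finite(cost)) return(1e8)
    ok <- amplitude_constraint(traj, genes, config$amplitude_threshold,
                               config$amplitude_exempt)
    ra <- attr(ok, "amplitude")
    viol <- pmax(0, config$amplitude_threshold - ra[!ok]) /
      config$amplitude_threshold
    cost <- cost + config$amplitude_penalty * sum(viol)
    if (lambda > 0) {
      cost <- lasso_cost(cost, p[free], wt_free, lambda, length(free))
    }
    cost
  }
}

# Internal: shared CMA-ES driver with restarts in log-space.
run_fit <- function(objective, config) {
  x0 <- log(config$base_params[config$free])
  lo <- x0 + log(rep_len(config$lower, length(x0)))
  hi <- x0 + log(rep_len(config$upper, length(x0)))
  best <- NULL
  for (r in seq_len(max(1, config$restarts))) {
    res <- cma_es(
      objective, x0 = as.numeric(x0), sigma0 = config$sigma0,
      lower = as.numeric(lo), upper = as.numeric(hi),
      popsize = config$popsize, max_evals = config$max_evals,
      seed = config$seed + (r - 1L) * 1000L
    )
    if (is.null(best) || res$value < best$value) best <- res
    if (config$max_evals <= 0) break
  }
  best
}

#' Fit the clock network to wild-type expression data
#'
#' Minimizes the normalized squared-error cost with CMA-ES (log-space,
#' multiplicative bounds, restarts) subject to the minimum-amplitude
#' constraint, which is enforced as a large additive penalty so the
#' optimizer retains a search signal near the boundary.
#'
#' @param data an [expression_dataset()] with paralogs already lumped.
#' @param network a [build_network()] system.
#' @param config a [fit_config()].
#' @return object of class `fit_result`: full parameter vector, `cost_se`,
#'   `r2`, `feasible` (amplitude constraint satisfied), convergence
#'   `trace`, `seed`, `evals`.
#' @export
fit_wildtype <- function(data, network, config) {
  stopifnot(inherits(data, "expression_dataset"),
            inherits(config, "fit_config"))
  obj <- make_clock_objective(data, network, config)
  best <- run_fit(obj, config)
  finalize_clock_fit(best, data, network, config)
}

# Internal: evaluate a finished run into a fit_result.
finalize_clock_fit <- function(best, data, network, config,
                               lambda = 0, wt_params = NULL) {
  p <- config$base_params
  p[config$free] <- exp(best$par)
  init <- config$init_state %||% initial_state(
    network,
    mrna_init = stats::setNames(
      data$values[intersect(data$genes, network$genes), 1],
      intersect(data$genes, network$genes)
    )
  )
  traj <- simulate_clock(
    network, p, init_state = init,
    t_span = range(data$times), dt = config$sim_dt
  )
  genes <- intersect(data$genes, network$genes)
  cost_se <- cost_squared_error(data, traj, config$amplitude_exempt)
  feasible <- all(amplitude_constraint(
    traj, genes, config$amplitude_threshold, config$amplitude_exempt
  ))
  res <- list(
    params = p, free = config$free,
    cost_se = cost_se,
    cost_lasso = if (lambda > 0) {
      lasso_cost(cost_se, p[config$free], wt_params[config$free],
                 lambda, length(config$free))
    } else NULL,
    lambda = lambda,
    r2 = coefficient_of_determination(data, traj, config$amplitude_exempt),
    feasible = feasible,
    divergent = if (!is.null(wt_params)) {
      divergent_parameters(p[config$free], wt_params[config$free],
                           config$divergence_threshold)
    } else NULL,
    trajectory = traj,
    trace = best$trace, evals = best$evals, seed = config$seed
  )
  if (!feasible) {
    warning("no amplitude-feasible solution found within budget")
  }
  structure(res, class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "fit_result: cost_SE %.4g, R^2 %.3f, %d free parameters%s%s (seed %d)\n",
    x$cost_se, x$r2, length(x$free),
    if (!is.null(x$lambda) && x$lambda > 0) {
      sprintf(", lambda %.3g, %d divergent", x$lambda, length(x$divergent))
    } else "",
    if (x$feasible) "" else " [INFEASIBLE]", x$seed
  ))
  invisible(x)
}

#' Fit a knock-out cell line with LASSO regularization
#'
#' Starts from the wild-type fit and minimizes the LASSO-regularized cost,
#' which penalizes the mean absolute relative divergence of the fitted
#' parameters from their wild-type values so that only few parameters
#' move far. Reports the divergent parameters at the configured threshold.
#'
#' @param data knock-out [expression_dataset()] (lumped; the knocked-out
#'   paralog's contribution is removed from the family sum on the data
#'   side).
#' @param network a [build_network()] system.
#' @param wt_result the wild-type [fit_wildtype()] result.
#' @param lambda LASSO penalty term (>= 0).
#' @param config a [fit_config()]; its `base_params` are overridden by the
#'   wild-type fit so the search starts at the wild-type optimum.
#' @return a `fit_result` with `cost_lasso` and `divergent` filled in.
#' @export
fit_knockout <- function(data, network, wt_result, lambda, config) {
  stopifnot(inherits(wt_result, "fit_result"), lambda >= 0)
  config$base_params <- wt_result$params
  obj <- make_clock_objective(data, network, config, lambda = lambda,
                              wt_params = wt_result$params)
  best <- run_fit(obj, config)
  finalize_clock_fit(best, data, network, config, lambda = lambda,
                     wt_params = wt_result$params)
}

#' Penalty sweep for the knock-out regularization
#'
#' Runs one knock-out fit per penalty value with the same seed (so the
#' penalty effect is isolated from sampling noise) and tabulates fit
#' quality and the number of divergent parameters.
#'
#' @param data,network,wt_result,config as in [fit_knockout()].
#' @param lambda_grid non-empty vector of penalties (>= 0).
#' @return data.frame with columns lambda, cost_se, r2, n_divergent;
#'   attribute `"fits"` holds the individual `fit_result`s.
#' @export
penalty_sweep <- function(data, network, wt_result, lambda_grid, config) {
  if (length(lambda_grid) == 0) stop("lambda grid is empty")
  if (any(lambda_grid < 0)) stop("lambda must be non-negative")
  fits <- lapply(lambda_grid, function(l) {
    fit_knockout(data, network, wt_result, l, config)
  })
  out <- data.frame(
    lambda = lambda_grid,
    cost_se = vapply(fits, function(f) f$cost_se, numeric(1)),
    r2 = vapply(fits, function(f) f$r2, numeric(1)),
    n_divergent = vapply(fits, function(f) length(f$divergent), integer(1))
  )
  attr(out, "fits") <- fits
  out
}

#' Fit the PK-PD part to cytotoxicity curves
#'
#' Fits the dead-cell variable of the PK-PD model to experimental (or
#' synthetic) cytotoxicity time courses: one curve per treatment time
#' plus an untreated control. Treated curves are first rescaled to start
#' at the control's starting value, so the fit sees temporal development
#' rather than offsets at treatment onset. The free parameters (per
#' `config$free`, defaulting to the death-rate and living/dead-cell
#' equation parameters plus the UGT sigmoid) are estimated with CMA-ES.
#'
#' @param curves data.frame with columns `treatment_time` (NA for the
#'   control), `time` (measurement time in hours after treatment start),
#'   `value` (cytotoxicity signal). Every treatment time must share the
#'   control's measurement grid.
#' @param proteins rescaled `protein_trajectory` driving the PK layer.
#' @param config list with `params` (base [pkpd_parameters()]), `free`
#'   (character; names of scalar PK-PD parameters to fit), optional
#'   `lower`/`upper` multiplicative bounds, `dose`, `exposure`,
#'   `max_evals`, `popsize`, `sigma0`, `seed`.
#' @return object of class `pkpd_fit`: fitted `pkpd_parameters`, `cost`,
#'   `trace`, `seed`.
#' @export
fit_pkpd <- function(curves, proteins, config) {
  req <- c("treatment_time", "time", "value")
  if (!all(req %in% names(curves))) {
    stop("curves must have columns treatment_time, time, value")
  }
  ctrl <- curves[is.na(curves$treatment_time), ]
  if (nrow(ctrl) == 0) stop("curves must include a control condition")
  trt_times <- sort(unique(curves$treatment_time[!is.na(curves$treatment_time)]))
  grid <- sort(unique(ctrl$time))
  for (T0 in trt_times) {
    tt <- sort(curves$time[!is.na(curves$treatment_time) &
                             curves$treatment_time == T0])
    if (!isTRUE(all.equal(tt, grid))) {
      stop(sprintf("treatment time %g is missing timepoints", T0))
    }
  }
  # rescale treated curves to start at the control's starting value
  c0 <- ctrl$value[which.min(ctrl$time)]
  curves_rs <- curves
  for (T0 in trt_times) {
    sel <- !is.na(curves$treatment_time) & curves$treatment_time == T0
    v <- curves$value[sel][order(curves$time[sel])]
    if (v[1] > 0) {
      curves_rs$value[sel] <- curves$value[sel] * (c0 / v[1])
    }
  }

  base <- config$params
  free <- config$free %||%
    c("death_base", "death_amp", "death_phase", "alpha_A", "alpha_tau",
      "k_kill", "growth", "M_UGT")
  dose <- config$dose %||% 1
  exposure <- config$exposure %||% 4
  horizon <- max(grid)
  seed <- as.integer(config$seed %||% 1L)

  apply_free <- function(logx) {
    p <- base
    for (i in seq_along(free)) p[[free[i]]] <- exp(logx[i])
    # k_UGT is a signed slope; fitted on its magnitude with fixed sign
    if ("k_UGT" %in% free) p$k_UGT <- -abs(p$k_UGT)
    p
  }
  sim_dt <- config$sim_dt %||% 1
  sim_curves <- function(p) {
    out <- list()
    for (T0 in trt_times) {
      prot <- treatment_protocol(T0, dose, exposure, horizon)
      s <- simulate_treatment(proteins, p, prot, dt = sim_dt,
                              rtol = 1e-4, atol = 1e-6)
      out[[as.character(T0)]] <-
        stats::approx(s$time - T0, s$values[, "D"], xout = grid, rule = 2)$y
    }
    prot0 <- treatment_protocol(0, 0, exposure, horizon)
    s0 <- simulate_treatment(proteins, p, prot0, dt = sim_dt,
                             rtol = 1e-4, atol = 1e-6)
    out[["control"]] <- stats::approx(s0$time, s0$values[, "D"],
                                      xout = grid, rule = 2)$y
    out
  }
  target <- list()
  for (T0 in trt_times) {
    sel <- !is.na(curves_rs$treatment_time) & curves_rs$treatment_time == T0
    target[[as.character(T0)]] <-
      curves_rs$value[sel][order(curves_rs$time[sel])]
  }
  target[["control"]] <- ctrl$value[order(ctrl$time)]

  objective <- function(logx) {
    p <- try(apply_free(logx), silent = TRUE)
    if (inherits(p, "try-error")) return(1e8)
    sims <- try(sim_curves(p), silent = TRUE)
    if (inherits(sims, "try-error")) return(1e8)
    tot <- 0
    for (nm in names(target)) tot <- tot + sum((sims[[nm]] - target[[nm]])^2)
    if (!is.finite(tot)) 1e8 else tot
  }

  x0 <- log(abs(vapply(free, function(nm) as.numeric(base[[nm]][1]), numeric(1))))
  lo <- x0 + log(rep_len(config$lower %||% 0.05, length(x0)))
  hi <- x0 + log(rep_len(config$upper %||% 20, length(x0)))
  res <- cma_es(objective, x0 = as.numeric(x0), sigma0 = config$sigma0 %||% 0.2,
                lower = as.numeric(lo), upper = as.numeric(hi),
                popsize = config$popsize, max_evals = config$max_evals %||% 2000,
                seed = seed)
  fitted <- apply_free(res$par)
  structure(
    list(params = fitted, free = free, cost = res$value,
         trace = res$trace, evals = res$evals, seed = seed),
    class = "pkpd_fit"
  )
}
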