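test_that("squared-error cost matches the formula and a double-loop oracle", {
  # one gene, x=[2,4], s=[2,2]: (0/4)^2 + (2/4)^2 = 0.25
  ds <- toy_dataset(rbind(ARNTL = c(2, 4)), times = c(0, 3))
  sim <- structure(
    list(time = c(0, 3), values = cbind(M_ARNTL = c(2, 2))),
    class = "clock_trajectory"
  )
  expect_equal(cost_squared_error(ds, sim), 0.25)
  # sim identical to data gives zero cost
  sim2 <- structure(
    list(time = c(0, 3), values = cbind(M_ARNTL = c(2, 4))),
    class = "clock_trajectory"
  )
  expect_equal(cost_squared_error(ds, sim2), 0)
  # random multi-gene toys agree with the naive double loop
  set.seed(101)
  for (rep in 1:20) {
    ng <- sample(2:5, 1); nt <- sample(3:8, 1)
    genes <- c("ARNTL", "PER", "CRY", "NR1D", "CES2")[seq_len(ng)]
    x <- matrix(runif(ng * nt, 0.5, 10), ng, nt,
                dimnames = list(genes, NULL))
    s <- matrix(runif(ng * nt, 0.5, 10), ng, nt)
    tt <- seq(0, by = 2, length.out = nt)
    ds <- toy_dataset(x, times = tt)
    sim <- structure(
      list(time = tt,
           values = matrix(t(s), nt, ng,
                           dimnames = list(NULL, paste0("M_", genes)))),
      class = "clock_trajectory"
    )
    expect_equal(cost_squared_error(ds, sim),
                 naive_cost_se(x, s, apply(x, 1, max)))
  }
  # all-zero gene is an error unless exempt
  dz <- toy_dataset(rbind(ARNTL = c(1, 2), UGT1A1 = c(0, 0)),
                    times = c(0, 3))
  simz <- structure(
    list(time = c(0, 3),
         values = cbind(M_ARNTL = c(1, 2), M_UGT1A1 = c(0, 0))),
    class = "clock_trajectory"
  )
  expect_error(cost_squared_error(dz, simz), "all-zero")
  expect_equal(cost_squared_error(dz, simz, zero_exempt = "UGT1A1"), 0)
})

test_that("LASSO cost implements the mean absolute relative divergence penalty", {
  # params = wt or lambda = 0 reduce to the squared error
  p <- c(a = 1, b = 2, c = 3, d = 4)
  expect_equal(lasso_cost(1.5, p, p, lambda = 8), 1.5)
  expect_equal(lasso_cost(1.5, p * 2, p, lambda = 0), 1.5)
  # n_par = 4, one parameter at 2x WT, lambda = 8: cost + 8 * (1/4) * 1
  p2 <- p; p2["b"] <- 4
  expect_equal(lasso_cost(1.5, p2, p, lambda = 8), 1.5 + 2)
  expect_error(lasso_cost(1, p, p, 1, n_par = 0), "n_par")
  # random toys vs naive loop; near-zero WT entries are excluded
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    pwt <- runif(n, 0.5, 3)
    if (rep %% 3 == 0) pwt[1] <- 1e-12
    pp <- pwt * exp(rnorm(n, 0, 0.3))
    l <- runif(1, 0, 10)
    expect_equal(lasso_cost(0.7, pp, pwt, l, n),
                 naive_lasso(0.7, pp, pwt, l, n))
  }
})

test_that("amplitude constraint applies the 5% rule with exemptions", {
  tt <- seq(0, 45, by = 0.5)
  vals <- cbind(
    M_ARNTL = 1 - 0.06 * (1 + cos(2 * pi * tt / 24)) / 2,  # rel amp 0.06
    M_PER = rep(2, length(tt)),                            # constant
    M_UGT1A1 = rep(0, length(tt))                          # silent
  )
  sim <- structure(list(time = tt, values = vals), class = "clock_trajectory")
  ok <- amplitude_constraint(sim, c("ARNTL", "PER", "UGT1A1"),
                             exempt = "UGT1A1")
  expect_true(ok[["ARNTL"]])   # 0.06 > 0.05
  expect_false(ok[["PER"]])    # constant trajectory fails
  expect_true(ok[["UGT1A1"]])  # exempt passes despite zero maximum
  ok2 <- amplitude_constraint(sim, "UGT1A1")
  expect_false(ok2[["UGT1A1"]])
})

test_that("pooled R squared matches its definition on toy cases", {
  tt <- c(0, 3, 6)
  x <- rbind(A = c(1, 2, 3), B = c(4, 6, 8))
  ds <- toy_dataset(x, times = tt)
  make_sim <- function(s) structure(
    list(time = tt, values = matrix(t(s), 3, 2,
                                    dimnames = list(NULL, c("M_A", "M_B")))),
    class = "clock_trajectory"
  )
  expect_equal(coefficient_of_determination(ds, make_sim(x)), 1)
  means <- rbind(A = rep(2, 3), B = rep(6, 3))
  expect_equal(coefficient_of_determination(ds, make_sim(means)), 0)
  # hand-computed pooled value for an arbitrary simulation
  s <- rbind(A = c(1.5, 2, 2.5), B = c(5, 6, 7))
  xn <- x / c(3, 8); sn <- s / c(3, 8)
  expected <- 1 - sum((xn - sn)^2) /
    sum((xn - rowMeans(xn))^2)
  expect_equal(coefficient_of_determination(ds, make_sim(s)), expected)
})

test_that("divergent parameters are selected at the threshold", {
  wt <- c(a = 1, b = 2, c = 3)
  expect_length(divergent_parameters(wt, wt), 0)
  p <- wt; p["a"] <- 1.04
  expect_length(divergent_parameters(p, wt), 0)
  p["b"] <- 2 * 1.10
  d <- divergent_parameters(p, wt)
  expect_named(d, "b")
  expect_equal(unname(d), 0.10, tolerance = 1e-12)
  expect_error(divergent_parameters(c(a = 1), wt), "do not match")
})

test_that("CMA-ES minimizes smooth test functions reproducibly", {
  sphere <- function(x) sum((x - c(1, -2, 3))^2)
  r1 <- cma_es(sphere, x0 = rep(0, 3), sigma0 = 0.5, max_evals = 1500,
               seed = 4)
  expect_lt(r1$value, 1e-8)
  r2 <- cma_es(sphere, x0 = rep(0, 3), sigma0 = 0.5, max_evals = 1500,
               seed = 4)
  expect_identical(r1$par, r2$par)
  # bounds are respected
  rb <- cma_es(sphere, x0 = rep(0, 3), sigma0 = 0.5, max_evals = 1500,
               seed = 4, lower = rep(-1, 3), upper = rep(1, 3))
  expect_true(all(rb$par >= -1 & rb$par <= 1))
  expect_error(cma_es(sphere, rep(0, 3), lower = 1, upper = -1),
               "infeasible")
  # rosenbrock in 2d
  rosen <- function(x) 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2
  rr <- cma_es(rosen, c(-1, 1), sigma0 = 0.3, max_evals = 4000, seed = 9)
  expect_lt(rr$value, 1e-6)
})

test_that("budget-0 fits return the initial guess and bad bounds error", {
  spec <- synthetic_spec(seed = 5)
  ds <- lump_paralogs(generate_clock_expression(spec))
  net <- fix_network()
  cfg <- fit_config(free = c("vmax_PER", "dm_PER"), max_evals = 0,
                    restarts = 1, amplitude_exempt = "UGT1A1")
  suppressWarnings(res <- fit_wildtype(ds, net, cfg))
  expect_s3_class(res, "fit_result")
  expect_equal(res$params[["vmax_PER"]],
               default_clock_parameters()[["vmax_PER"]])
  expect_error(fit_config(free = "vmax_PER", lower = 2, upper = 0.5),
               "infeasible")
})

test_that("penalty sweep validates its grid", {
  spec <- synthetic_spec(seed = 5)
  ds <- lump_paralogs(generate_clock_expression(spec))
  net <- fix_network()
  cfg <- fit_config(free = "vmax_PER", max_evals = 0, restarts = 1,
                    amplitude_exempt = "UGT1A1")
  suppressWarnings(wt <- fit_wildtype(ds, net, cfg))
  expect_error(penalty_sweep(ds, net, wt, numeric(0), cfg), "empty")
  expect_error(penalty_sweep(ds, net, wt, c(-1, 0), cfg), "non-negative")
  suppressWarnings(sw <- penalty_sweep(ds, net, wt, 0, cfg))
  expect_equal(nrow(sw), 1)
  expect_equal(sw$lambda, 0)
})

test_that("PK-PD fitting rejects malformed cytotoxicity curves", {
  prot <- fix_proteins()
  grid <- seq(0, 72, length.out = 7)
  curves <- rbind(
    data.frame(treatment_time = 240, time = grid, value = 1),
    data.frame(treatment_time = NA, time = grid, value = 1)
  )
  cfg <- list(params = pkpd_parameters(), free = "death_base",
              max_evals = 0, seed = 1)
  # control present and grids aligned: runs
  expect_s3_class(fit_pkpd(curves, prot, cfg), "pkpd_fit")
  # missing control
  expect_error(fit_pkpd(curves[!is.na(curves$treatment_time), ], prot, cfg),
               "control")
  # missing timepoints in a treated curve
  broken <- curves[-2, ]
  expect_error(fit_pkpd(broken, prot, cfg), "missing timepoints")
  expect_error(fit_pkpd(data.frame(a = 1), prot, cfg), "columns")
})
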