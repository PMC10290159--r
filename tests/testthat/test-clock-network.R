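test_that("network construction validates topology and carries the refined edges", {
  net <- fix_network()
  ed <- net$edges
  # PPARa inhibits CES2; NFIL3 acts on CES2 only indirectly (via NR1D)
  expect_true(any(ed$from == "PPARA" & ed$to == "CES2" & ed$type == "inhibit"))
  expect_true(any(ed$from == "NR1D" & ed$to == "CES2" & ed$type == "inhibit"))
  expect_false(any(ed$from == "NFIL3" & ed$to == "CES2"))
  expect_true(any(ed$from == "NFIL3" & ed$to == "PER" & ed$type == "inhibit"))
  expect_true(any(ed$from == "NFIL3" & ed$to == "NR1D"))
  # NFIL3 and PAR/DBP compete on both ABC transporters
  for (g in c("ABCB", "ABCC")) {
    expect_true(any(ed$from == "DBP" & ed$to == g & ed$type == "activate"))
    expect_true(any(ed$from == "NFIL3" & ed$to == g &
                      ed$type == "inhibit_compete"))
  }
  # TOP1 is not part of the transcription network
  expect_false("TOP1" %in% net$genes)

  topo <- default_topology()
  topo$species <- c(topo$species, "PER")
  expect_error(build_network(topo), "duplicated species")
  topo2 <- default_topology()
  topo2$edges$type[1] <- "mystery"
  expect_error(build_network(topo2), "unknown interaction type")
  topo3 <- default_topology()
  topo3$edges$from[1] <- "NOTAGENE"
  expect_error(build_network(topo3), "NOTAGENE")
})

test_that("zeroed production rates leave a pure-decay right-hand side", {
  net <- fix_network()
  p <- fix_params()
  p[grep("^(vmax|ktl|kim)_", names(p))] <- 0
  p["kf_cplx"] <- 0
  p["kb_cplx"] <- 0
  y <- setNames(runif(length(net$species), 0.1, 2), net$species)
  d <- unlist(net$rhs(0, unname(y), c(unname(p[net$param_names]), 1, 1)))
  expect_true(all(d <= 0))
})

test_that("light switching follows the on/off rule with pulse replacement", {
  base <- 2.0
  expect_equal(effective_transcription_rate(base, NULL, 10), base)
  sch <- zeitgeber_schedule(f_light = 1.07)
  # ZT 3: lights on -> f * V1max; ZT 15: lights off -> V1max
  expect_equal(effective_transcription_rate(base, sch, 3), 1.07 * base)
  expect_equal(effective_transcription_rate(base, sch, 15), base)
  # pulse window [3, 4): replaces the LD factor while active
  schp <- zeitgeber_schedule(f_light = 1.07,
                             pulses = list(pulse_spec(3, 1, 3)))
  expect_equal(effective_transcription_rate(base, schp, 3.5), 3 * base)
  expect_equal(effective_transcription_rate(base, schp, 4.5), 1.07 * base)
  expect_error(effective_transcription_rate(-1, sch, 0), "non-negative")
  # a schedule with f = 1 everywhere is equivalent to no schedule
  sch1 <- zeitgeber_schedule(f_light = 1)
  tr_a <- simulate_clock(fix_network(), fix_params(), t_span = c(0, 48))
  tr_b <- simulate_clock(fix_network(), fix_params(), t_span = c(0, 48),
                         schedule = sch1)
  expect_equal(tr_a$values, tr_b$values, tolerance = 1e-10)
})

test_that("single-species decay submodel matches the closed form", {
  net <- fix_network()
  p <- fix_params()
  p[grep("^(vmax|ktl)_", names(p))] <- 0
  p["kf_cplx"] <- 0
  d <- unname(p["dm_ARNTL"])
  y0 <- initial_state(net)
  y0[] <- 0
  y0["M_ARNTL"] <- 2.5
  tr <- simulate_clock(net, p, init_state = y0, t_span = c(0, 24),
                       dt = 0.5, rtol = 1e-8, atol = 1e-14)
  expected <- 2.5 * exp(-d * tr$time)
  expect_equal(tr$values[, "M_ARNTL"], expected, tolerance = 1e-6)
})

test_that("adaptive trajectories agree with an independent RK4 integrator", {
  net <- fix_network()
  p <- fix_params()
  y0 <- unname(fix_free_lc()$state)
  tr <- simulate_clock(net, p, init_state = setNames(y0, net$species),
                       t_span = c(0, 48), dt = 0.1)
  parms <- c(unname(p[net$param_names]), 1, 1)
  fine <- seq(0, 48, by = 0.005)
  orc <- rk4_integrate(net$rhs, y0, fine, parms)
  idx <- match(round(tr$time, 6), round(fine, 6))
  keep <- !is.na(idx)
  scale <- apply(orc, 2, max)
  rel <- abs(tr$values[keep, ] - orc[idx[keep], ]) /
    rep(pmax(scale, 1e-8), each = sum(keep))
  expect_lt(max(rel), 1e-3)
})

test_that("simulation is deterministic and stays non-negative over 10 days", {
  net <- fix_network()
  p <- fix_params()
  a <- simulate_clock(net, p, t_span = c(0, 240), dt = 0.5)
  b <- simulate_clock(net, p, t_span = c(0, 240), dt = 0.5)
  expect_identical(a$values, b$values)
  expect_true(all(a$values >= 0))
  expect_true(all(diff(a$time) > 0))
})

test_that("limit cycle detection measures period and flags damped systems", {
  # constructed oracle: forced harmonic system with known 24 h period
  net <- fix_network()
  lc <- fix_free_lc()
  expect_equal(lc$period, 23.8, tolerance = 0.01)
  expect_gt(lc$amplitude, 0.05)
  # a parameter set driving the system to a fixed point is reported damped
  p_dead <- fix_params()
  p_dead["vmax_PER"] <- 0.001
  expect_error(
    limit_cycle(net, p_dead, transient = 120, horizon = 72),
    "damped|maxima"
  )
})

test_that("harmonic test signal gives a 24 h period from peak detection", {
  t <- seq(0, 120, by = 0.05)
  x <- 5 + 2 * cos(2 * pi * (t - 7) / 24)
  pk <- find_peaks(t, x)
  expect_equal(median(diff(pk$time)), 24, tolerance = 0.05)
  expect_equal(pk$time[1] %% 24, 7, tolerance = 0.05)
})

test_that("paralog lumping sums families and conserves expression mass", {
  vals <- rbind(
    PER1 = c(1, 2), PER2 = c(3, 4), PER3 = c(0, 1),
    CRY1 = c(2, 2), CRY2 = c(1, 0),
    NR1D1 = c(5, 1), NR1D2 = c(1, 1),
    ARNTL = c(9, 9)
  )
  ds <- toy_dataset(vals)
  lumped <- lump_paralogs(ds)
  expect_equal(unname(lumped$values["PER", ]), c(4, 7))
  expect_equal(unname(lumped$values["CRY", ]), c(3, 2))
  expect_equal(unname(lumped$values["ARNTL", ]), c(9, 9))
  # mass conservation per timepoint
  expect_equal(colSums(lumped$values), colSums(vals))
  # identity mapping leaves the dataset unchanged
  ident <- lump_paralogs(ds, mapping = list())
  expect_equal(ident$values[rownames(vals), ], ds$values)
  # a paralog in two lumps is rejected
  expect_error(
    lump_paralogs(ds, mapping = list(A = "PER1", B = c("PER1", "PER2"))),
    "more than one lump"
  )
  # absent paralog without KO flag is rejected; with flag it is allowed
  ds2 <- toy_dataset(vals[rownames(vals) != "PER2", ])
  expect_error(lump_paralogs(ds2), "not flagged")
  ok <- lump_paralogs(ds2, knocked_out = "PER2")
  expect_equal(unname(ok$values["PER", ]), c(1, 3))
})
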