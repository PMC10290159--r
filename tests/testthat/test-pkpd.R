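test_that("translation reaches the closed-form steady state for constant mRNA", {
  tt <- seq(0, 200, by = 0.25)
  m <- 3
  vals <- matrix(m, length(tt), 4,
                 dimnames = list(NULL, paste0("M_", c("CES2", "ABCB",
                                                     "ABCC", "UGT1A1"))))
  traj <- structure(list(time = tt, values = vals), class = "clock_trajectory")
  pk <- pkpd_parameters(pdeg_amp = 0)
  prot <- translate_proteins(traj, pk)
  expected <- pk$ktl[["CES2"]] * m / pk$pdeg_base[["CES2"]]
  expect_equal(unname(prot$values[length(tt), "CES2"]), unname(expected),
               tolerance = 1e-4)
  # zero mRNA: protein decays monotonically towards zero
  vals0 <- vals; vals0[] <- 0
  traj0 <- structure(list(time = tt, values = vals0),
                     class = "clock_trajectory")
  prot0 <- translate_proteins(traj0, pk)
  expect_true(all(diff(prot0$values[, "ABCB"]) <= 1e-12))
})

test_that("circadian-degradation translation matches a fine explicit-Euler oracle", {
  tt <- seq(0, 96, by = 0.25)
  m_of_t <- function(t) 2 + sin(2 * pi * t / 24)
  vals <- matrix(m_of_t(tt), length(tt), 4,
                 dimnames = list(NULL, paste0("M_", c("CES2", "ABCB",
                                                     "ABCC", "UGT1A1"))))
  traj <- structure(list(time = tt, values = vals), class = "clock_trajectory")
  pk <- pkpd_parameters()
  prot <- translate_proteins(traj, pk)
  # independent fixed-grid explicit Euler at 0.001 h
  h <- 0.001
  tg <- seq(0, 96, by = h)
  g <- "CES2"
  y <- pk$ktl[[g]] * m_of_t(0) / pk$pdeg_base[[g]]
  yout <- numeric(length(tt)); yout[1] <- y
  j <- 2
  for (i in 2:length(tg)) {
    t0 <- tg[i - 1]
    dr <- pk$pdeg_base[[g]] *
      (1 + pk$pdeg_amp[[g]] * cos(2 * pi * (t0 - pk$pdeg_phase[[g]]) / 24))
    y <- y + h * (pk$ktl[[g]] * m_of_t(t0) - dr * y)
    while (j <= length(tt) && abs(tg[i] - tt[j]) < h / 2) {
      yout[j] <- y; j <- j + 1
    }
  }
  rel <- abs(prot$values[, g] - yout) / max(yout)
  expect_lt(max(rel), 1e-3)
})

test_that("protein rescaling sets maxima, preserves shape, and handles UGT-null lines", {
  tt <- seq(0, 48, by = 0.5)
  vals <- cbind(CES2 = 5 * (1 + 0.3 * sin(tt / 4)), ABCB = rep(1, length(tt)),
                ABCC = rep(2, length(tt)), UGT1A1 = rep(0, length(tt)))
  traj <- structure(list(time = tt, values = vals),
                    class = "protein_trajectory")
  tmax <- c(CES2 = 2, ABCB = 2, ABCC = 2, UGT1A1 = 2)
  out <- rescale_protein(traj, tmax, zero_ok = "UGT1A1")
  expect_equal(max(out$values[, "CES2"]), 2)
  # shape preserved: pointwise proportional
  ratio <- out$values[, "CES2"] / vals[, "CES2"]
  expect_lt(diff(range(ratio)), 1e-12)
  # HCT116-like: 10-fold UGT reduction via scale factor
  vals2 <- vals; vals2[, "UGT1A1"] <- 1 + 0.1 * cos(tt / 5)
  traj2 <- structure(list(time = tt, values = vals2),
                     class = "protein_trajectory")
  out2 <- rescale_protein(traj2, tmax, scale_factor = c(UGT1A1 = 0.1))
  expect_equal(max(out2$values[, "UGT1A1"]), 0.2)
  # zero UGT passes through as zero without error
  expect_equal(max(out$values[, "UGT1A1"]), 0)
  # but a zero non-exempt protein is an error
  vals3 <- vals; vals3[, "ABCB"] <- 0
  traj3 <- structure(list(time = tt, values = vals3),
                     class = "protein_trajectory")
  expect_error(rescale_protein(traj3, tmax, zero_ok = "UGT1A1"), "ABCB")
})

test_that("post-treatment UGT sigmoid has the printed midpoint and asymptotes", {
  # zero magnitude: multiplier is identically 1
  expect_equal(ugt_treatment_factor(c(-5, 0, 7, 100), 0, -0.3),
               rep(1, 4))
  # midpoint where k*t + 4 = 0 gives 1 + M/2
  M <- 1.8; k <- -0.25
  expect_equal(ugt_treatment_factor(-4 / k, M, k), 1 + M / 2)
  # negative slope: asymptote 1 + M as t grows
  expect_equal(ugt_treatment_factor(1e4, M, k), 1 + M, tolerance = 1e-8)
  expect_equal(ugt_treatment_factor(-1e4, M, k), 1, tolerance = 1e-8)
  # monotone increasing for k < 0
  tt <- seq(-20, 60, by = 1)
  expect_true(all(diff(ugt_treatment_factor(tt, M, k)) > 0))
})

test_that("death rate combines baseline, circadian modulation and alpha transient", {
  pk <- pkpd_parameters(death_amp = 0, alpha_A = 0)
  prot <- treatment_protocol(t_start = 10)
  expect_equal(death_rate(c(0, 5, 30), pk, prot),
               rep(pk$death_base, 3))
  # alpha transient peaks at s = tau with height A above the baseline
  pk2 <- pkpd_parameters(death_amp = 0, alpha_A = 0.04, alpha_tau = 5)
  s <- seq(0, 40, by = 0.01)
  r <- death_rate(10 + s, pk2, prot) - pk2$death_base
  expect_equal(s[which.max(r)], 5, tolerance = 0.02)
  expect_equal(max(r), 0.04, tolerance = 1e-6)
  # before treatment start there is no transient
  expect_equal(death_rate(9.99, pk2, prot), pk2$death_base)
  expect_error(death_rate(0, pkpd_parameters(alpha_tau = 0), prot),
               "alpha_tau")
})

test_that("dose zero reproduces the untreated control exactly", {
  prot <- fix_proteins()
  pk <- pkpd_parameters()
  a <- simulate_treatment(prot, pk, treatment_protocol(240, dose = 0))
  b <- simulate_treatment(prot, pk, treatment_protocol(240, dose = 0))
  expect_identical(a$values, b$values)
  # no drug: CPT-11, SN-38 and damage stay at zero; D only from baseline
  expect_equal(max(a$values[, "CPT11"]), 0)
  expect_equal(max(a$values[, "SN38"]), 0)
  expect_error(simulate_treatment(prot, pk, treatment_protocol(240, dose = -1)),
               "non-negative")
})

test_that("treated dynamics agree with a tighter-tolerance oracle run", {
  prot <- fix_proteins()
  pk <- pkpd_parameters()
  protocol <- treatment_protocol(246, dose = 1)
  a <- simulate_treatment(prot, pk, protocol)
  # oracle: same model integrated with much tighter tolerances via ode
  pf <- lapply(colnames(prot$values), function(g) {
    approxfun(prot$time, prot$values[, g], rule = 2)
  })
  names(pf) <- colnames(prot$values)
  rhs <- function(t, y, parms) {
    ces <- pf$CES2(t)
    ugt <- pf$UGT1A1(t) * pk$ugt_scale *
      ugt_treatment_factor(t - 246, pk$M_UGT, pk$k_UGT)
    Ce <- if (t >= 246 && t < 246 + protocol$exposure) protocol$dose else 0
    dCi <- pk$k_upt * Ce - (pk$k_eff_abcb * pf$ABCB(t) + pk$k_act * ces) * y[1]
    dS <- pk$k_act * ces * y[1] -
      (pk$k_deact * ugt + pk$k_eff_abcc * pf$ABCC(t)) * y[2]
    dDNA <- pk$k_dmg * pk$top1 * y[2] - pk$d_dmg * y[3]
    dtot <- death_rate(t, pk, protocol) + pk$k_kill * y[3]
    list(c(dCi, dS, dDNA, (pk$growth - dtot) * y[4], dtot * y[4]))
  }
  seg <- sort(unique(c(a$time, 246 + protocol$exposure)))
  orc <- deSolve::lsoda(c(0, 0, 0, pk$L0, pk$D0), seg, rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  oD <- orc[match(round(a$time, 8), round(orc[, 1], 8)), 6]
  rel <- abs(a$values[, "D"] - oD) / max(oD)
  expect_lt(max(rel), 1e-3)
})

test_that("lower UGT scale increases normalized toxicity", {
  prot <- fix_proteins()
  times <- seq(240, 261, by = 3)
  prof_full <- toxicity_profile(pkpd_model(prot, pkpd_parameters()), times)
  prof_low <- toxicity_profile(
    pkpd_model(prot, pkpd_parameters(ugt_scale = 0.1)), times
  )
  expect_true(all(prof_low$profile$auc_ratio >
                    prof_full$profile$auc_ratio))
})

test_that("toxicity profile is normalized, ratio-invariant and control-flat", {
  prot <- fix_proteins()
  times <- seq(240, 261, by = 3)
  # dose 0 at every treatment time: profile identically 1
  prof0 <- toxicity_profile(pkpd_model(prot, pkpd_parameters(), dose = 0),
                            times)
  expect_equal(prof0$profile$auc_ratio, rep(1, length(times)),
               tolerance = 1e-9)
  # joint rescaling of D (via L0 and D0) leaves the ratio unchanged
  prof_a <- toxicity_profile(pkpd_model(prot, pkpd_parameters(), dose = 1),
                             times)
  prof_b <- toxicity_profile(
    pkpd_model(prot, pkpd_parameters(L0 = 2, D0 = 0.04), dose = 1), times
  )
  expect_equal(prof_a$profile$auc_ratio, prof_b$profile$auc_ratio,
               tolerance = 1e-6)
  expect_error(toxicity_profile(pkpd_model(prot, pkpd_parameters()),
                                seq(240, 249, 3)),
               "span")
})

test_that("toxicity is a non-decreasing function of dose", {
  prot <- fix_proteins()
  times <- seq(240, 261, by = 3)
  aucs <- sapply(c(0.5, 1, 2), function(d) {
    mean(toxicity_profile(pkpd_model(prot, pkpd_parameters(), dose = d),
                          times)$profile$auc_ratio)
  })
  expect_true(all(diff(aucs) > 0))
})

test_that("phase adaptation shifts all circadian phases modulo 24 and nothing else", {
  pk <- pkpd_parameters()
  expect_equal(phase_adapt(pk, 0), pk)
  p24 <- phase_adapt(pk, 24)
  expect_equal(p24$pdeg_phase, pk$pdeg_phase %% 24)
  expect_equal(p24$death_phase, pk$death_phase %% 24)
  p3 <- phase_adapt(pk, 3)
  expect_equal(p3$pdeg_phase, (pk$pdeg_phase + 3) %% 24)
  expect_equal(p3$death_phase, (pk$death_phase + 3) %% 24)
  same <- setdiff(names(pk), c("pdeg_phase", "death_phase"))
  expect_equal(p3[same], pk[same])
  # simulated protein degradation minima shift by the adapted phase
  tt <- seq(0, 340, by = 0.25)
  vals <- matrix(2, length(tt), 4,
                 dimnames = list(NULL, paste0("M_", c("CES2", "ABCB",
                                                     "ABCC", "UGT1A1"))))
  traj <- structure(list(time = tt, values = vals),
                    class = "clock_trajectory")
  pr_a <- translate_proteins(traj, pk)
  pr_b <- translate_proteins(traj, p3)
  k <- tt >= 240
  pk_a <- find_peaks(tt[k], -pr_a$values[k, "CES2"])
  pk_b <- find_peaks(tt[k], -pr_b$values[k, "CES2"])
  d <- (pk_b$time[1] - pk_a$time[1]) %% 24
  expect_equal(d, 3, tolerance = 0.1)
})
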