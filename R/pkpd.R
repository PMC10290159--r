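PKPD_PROTEINS <- c("CES2", "ABCB", "ABCC", "UGT1A1")

#' Irinotecan PK-PD parameter set
#'
#' Rates of cellular irinotecan pharmacokinetics (CPT-11 uptake, CES2-
#' mediated activation to SN-38, UGT1A1-mediated deactivation, ABCB/ABCC
#' efflux), DNA-damage dynamics with constant TOP1, and the cell-death
#' pharmacodynamics: a baseline death rate with treatment-independent
#' circadian modulation plus a transient treatment-induced increase
#' (alpha function), and the sigmoidal post-treatment UGT increase with
#' magnitude `M_UGT` and slope `k_UGT`.
#'
#' @param ... named overrides of any default field.
#' @return object of class `pkpd_parameters` (a named list).
#' @export
pkpd_parameters <- function(...) {
  p <- list(
    # pharmacokinetics (1/h per unit protein where protein-mediated)
    k_upt = 0.4,         # CPT-11 uptake
    k_act = 0.15,        # CES2-mediated CPT-11 -> SN-38
    k_deact = 0.25,      # UGT1A1-mediated SN-38 inactivation
    k_eff_abcb = 0.12,   # ABCB efflux of CPT-11
    k_eff_abcc = 0.12,   # ABCC efflux of SN-38
    top1 = 1.0,          # constant TOP1 protein level
    k_dmg = 0.4,         # TOP1-SN38-DNA complex formation
    d_dmg = 0.25,        # damage repair/turnover
    # pharmacodynamics
    k_kill = 0.25,       # death rate per unit DNA damage
    death_base = 0.010,  # baseline death rate (1/h)
    death_amp = 0.006,   # circadian death modulation amplitude (1/h)
    death_phase = 12,    # circadian death modulation phase (h)
    alpha_A = 0.03,      # transient death-rate peak height (1/h)
    alpha_tau = 6,       # transient death-rate time constant (h)
    growth = 0.015,      # living-cell growth rate (1/h)
    L0 = 1, D0 = 0.02,   # initial living/dead cells (assay units)
    # treatment-induced UGT sigmoid
    M_UGT = 2, k_UGT = -0.25,
    # translation and circadian protein degradation of the four
    # drug-metabolism proteins
    ktl = c(CES2 = 0.5, ABCB = 0.5, ABCC = 0.5, UGT1A1 = 0.5),
    pdeg_base = c(CES2 = 0.15, ABCB = 0.15, ABCC = 0.15, UGT1A1 = 0.15),
    pdeg_amp = c(CES2 = 0.5, ABCB = 0.5, ABCC = 0.5, UGT1A1 = 0.5),
    pdeg_phase = c(CES2 = 4, ABCB = 8, ABCC = 8, UGT1A1 = 6),
    # protein rescaling maxima (concentration units of the PK layer)
    target_max = c(CES2 = 2, ABCB = 2, ABCC = 2, UGT1A1 = 2),
    ugt_scale = 1.0      # cell-line UGT scale factor (0.1 for HCT116-like)
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad) > 0) stop(sprintf("unknown PK-PD parameter '%s'", bad[1]))
  for (nm in names(ov)) {
    if (length(p[[nm]]) > 1) {
      v <- ov[[nm]]
      if (is.null(names(v))) {
        p[[nm]][] <- v
      } else {
        p[[nm]][names(v)] <- v
      }
    } else {
      p[[nm]] <- ov[[nm]]
    }
  }
  scalars <- c(
    "k_upt", "k_act", "k_deact", "k_eff_abcb", "k_eff_abcc", "top1",
    "k_dmg", "d_dmg", "k_kill", "death_base", "death_amp", "alpha_A",
    "alpha_tau", "growth", "L0", "D0", "M_UGT"
  )
  if (any(unlist(p[scalars]) < 0)) stop("PK-PD rates must be non-negative")
  if (p$ugt_scale <= 0 || p$ugt_scale > 1) stop("ugt_scale must be in (0, 1]")
  structure(p, class = "pkpd_parameters")
}

#' Treatment protocol
#'
#' @param t_start treatment start time in circadian/Zeitgeber hours.
#' @param dose extracellular CPT-11 concentration during exposure (>= 0).
#' @param exposure exposure duration in hours.
#' @param horizon observation horizon after treatment start in hours.
#' @return object of class `treatment_protocol`.
#' @export
treatment_protocol <- function(t_start = 0, dose = 1, exposure = 4,
                               horizon = 72) {
  if (dose < 0) stop("dose must be non-negative")
  if (horizon <= 0) stop("horizon must be positive")
  structure(
    list(t_start = t_start, dose = dose, exposure = exposure,
         horizon = horizon),
    class = "treatment_protocol"
  )
}

#' Translate drug-metabolism mRNAs into proteins
#'
#' Integrates translation-degradation dynamics for CES2, ABCB, ABCC and
#' UGT1A1 with circadian protein degradation
#' `d(t) = d0 * (1 + a * cos(2*pi*(t - phase)/24))`, driven by the mRNA
#' trajectory of the clock network.
#'
#' @param mrna_traj a `clock_trajectory` containing the `M_*` species.
#' @param params a [pkpd_parameters()] object.
#' @param clock_phase additional phase shift in hours applied to all
#'   degradation phases (used for cell-line phase adaptation).
#' @param proteins subset of proteins to translate.
#' @return trajectory object with one column per protein.
#' @export
translate_proteins <- function(mrna_traj, params, clock_phase = 0,
                               proteins = PKPD_PROTEINS) {
  tgrid <- mrna_traj$time
  mfun <- lapply(proteins, function(g) {
    col <- paste0("M_", g)
    if (!col %in% colnames(mrna_traj$values)) {
      stop(sprintf("mRNA trajectory lacks species '%s'", col))
    }
    stats::approxfun(tgrid, mrna_traj$values[, col], rule = 2)
  })
  names(mfun) <- proteins
  ktl <- params$ktl[proteins]
  d0 <- params$pdeg_base[proteins]
  am <- params$pdeg_amp[proteins]
  ph <- params$pdeg_phase[proteins] + clock_phase
  rhs <- function(t, y, parms) {
    m <- vapply(proteins, function(g) mfun[[g]](t), numeric(1))
    dr <- d0 * (1 + am * cos(2 * pi * (t - ph) / 24))
    list(ktl * m - dr * y)
  }
  m0 <- vapply(proteins, function(g) mfun[[g]](tgrid[1]), numeric(1))
  y0 <- ktl * m0 / d0
  sol <- deSolve::lsoda(y = unname(y0), times = tgrid, func = rhs,
                        parms = NULL, rtol = 1e-6, atol = 1e-10)
  vals <- sol[, -1, drop = FALSE]
  vals[vals < 0] <- 0
  colnames(vals) <- proteins
  structure(
    list(time = tgrid, values = vals, species = proteins),
    class = "protein_trajectory"
  )
}

#' Rescale protein trajectories to reference maxima
#'
#' Each protein series is scaled so its maximum equals
#' `target_max * scale_factor`, preserving the shape. An all-zero series
#' passes through unchanged only for proteins listed in `zero_ok`
#' (UGT1A1 in UGT-null cell lines); otherwise it is an error.
#'
#' @param traj a `protein_trajectory`.
#' @param target_max named vector of target maxima per protein.
#' @param scale_factor named or scalar multiplier on the target (e.g. the
#'   0.1 UGT reduction of HCT116-like lines).
#' @param zero_ok proteins allowed to be identically zero.
#' @return rescaled `protein_trajectory`.
#' @export
rescale_protein <- function(traj, target_max, scale_factor = 1,
                            zero_ok = character(0)) {
  vals <- traj$values
  proteins <- colnames(vals)
  sf <- if (length(scale_factor) == 1 && is.null(names(scale_factor))) {
    stats::setNames(rep(scale_factor, length(proteins)), proteins)
  } else {
    out <- stats::setNames(rep(1, length(proteins)), proteins)
    out[names(scale_factor)] <- scale_factor
    out
  }
  for (g in proteins) {
    mx <- max(vals[, g])
    tgt <- target_max[[g]] * sf[[g]]
    if (mx <= 0) {
      if (tgt > 0 && !(g %in% zero_ok)) {
        stop(sprintf("all-zero trajectory for '%s' with nonzero target", g))
      }
      next
    }
    vals[, g] <- vals[, g] * (tgt / mx)
  }
  traj$values <- vals
  traj
}

#' Sigmoidal post-treatment UGT increase
#'
#' Multiplier `1 + M_UGT / (1 + exp(k_UGT * t + 4))` applied to the UGT
#' protein from treatment onset; `t` is time after treatment in hours.
#' With negative slope `k_UGT` the multiplier rises sigmoidally from ~1
#' towards `1 + M_UGT`.
#'
#' @param t time after treatment (h); vectorized.
#' @param M_UGT magnitude (>= 0 for an increase).
#' @param k_UGT slope (1/h).
#' @return multiplier, same length as `t`.
#' @export
ugt_treatment_factor <- function(t, M_UGT, k_UGT) {
  1 + M_UGT / (1 + exp(k_UGT * t + 4))
}

#' Cell death rate
#'
#' Baseline plus treatment-independent circadian modulation plus, after
#' treatment start, a transient alpha-function increase
#' `A * (s/tau) * exp(1 - s/tau)` (unit-peak scaling: the transient peaks
#' at `s = tau` with value `A`). The total is clipped at zero.
#'
#' @param t time (h); vectorized.
#' @param params a [pkpd_parameters()].
#' @param protocol a [treatment_protocol()]; its `t_start` anchors the
#'   transient. Use `NULL` for an untreated run (no transient).
#' @return death rate in 1/h.
#' @export
death_rate <- function(t, params, protocol = NULL) {
  if (params$alpha_tau <= 0) stop("alpha_tau must be positive")
  r <- params$death_base +
    params$death_amp * cos(2 * pi * (t - params$death_phase) / 24)
  if (!is.null(protocol)) {
    s <- t - protocol$t_start
    a <- ifelse(s >= 0,
                params$alpha_A * (s / params$alpha_tau) *
                  exp(1 - s / params$alpha_tau), 0)
    r <- r + a
  }
  pmax(r, 0)
}

#' Simulate irinotecan treatment of a cell population
#'
#' Integrates intracellular CPT-11, SN-38, DNA damage and living/dead
#' cells over the protocol horizon, driven by the (rescaled) protein
#' trajectories. The UGT protein is additionally multiplied by the
#' sigmoidal post-treatment factor and by the cell-line `ugt_scale`.
#' SN-38 is shared between nucleus and cytoplasm (a single pool).
#'
#' @param protein_trajs `protein_trajectory` covering the horizon.
#' @param params a [pkpd_parameters()].
#' @param protocol a [treatment_protocol()].
#' @param dt output step (h).
#' @param rtol,atol solver tolerances (absolute tolerance within the
#'   1e-3 to 1e-7 range customary for these cell-count equations; a loose
#'   setting is used inside fitting loops).
#' @return list of class `cell_population_trajectory` with `time`, and
#'   `values` columns CPT11, SN38, DNA, L (living), D (dead).
#' @export
simulate_treatment <- function(protein_trajs, params, protocol, dt = 0.1,
                               rtol = 1e-6, atol = 1e-9) {
  if (protocol$dose < 0) stop("dose must be non-negative")
  t0 <- protocol$t_start
  t1 <- t0 + protocol$horizon
  if (min(protein_trajs$time) > t0 || max(protein_trajs$time) < t1) {
    stop("protein trajectories do not cover the protocol horizon")
  }
  pf <- lapply(colnames(protein_trajs$values), function(g) {
    stats::approxfun(protein_trajs$time, protein_trajs$values[, g], rule = 2)
  })
  names(pf) <- colnames(protein_trajs$values)

  rhs <- function(t, y, parms) {
    Ci <- y[1]; S <- y[2]; DNA <- y[3]; L <- y[4]
    ces <- pf$CES2(t)
    ugt <- pf$UGT1A1(t) * params$ugt_scale *
      ugt_treatment_factor(t - t0, params$M_UGT, params$k_UGT)
    abcb <- pf$ABCB(t); abcc <- pf$ABCC(t)
    Ce <- if (t >= t0 && t < t0 + protocol$exposure) protocol$dose else 0
    dCi <- params$k_upt * Ce -
      (params$k_eff_abcb * abcb + params$k_act * ces) * Ci
    dS <- params$k_act * ces * Ci -
      (params$k_deact * ugt + params$k_eff_abcc * abcc) * S
    dDNA <- params$k_dmg * params$top1 * S - params$d_dmg * DNA
    dtot <- death_rate(t, params, protocol) + params$k_kill * DNA
    dL <- (params$growth - dtot) * L
    dD <- dtot * L
    list(c(dCi, dS, dDNA, dL, dD))
  }
  bounds <- unique(c(t0, t0 + protocol$exposure, t1))
  bounds <- sort(bounds[bounds >= t0 & bounds <= t1])
  times <- unique(sort(c(seq(t0, t1, by = dt), bounds)))
  y <- c(0, 0, 0, params$L0, params$D0)
  rows <- list(); tacc <- list()
  for (s in seq_len(length(bounds) - 1)) {
    seg <- times[times >= bounds[s] & times <= bounds[s + 1]]
    if (seg[1] > bounds[s]) seg <- c(bounds[s], seg)
    if (seg[length(seg)] < bounds[s + 1]) seg <- c(seg, bounds[s + 1])
    sol <- deSolve::lsoda(y = y, times = seg, func = rhs, parms = NULL,
                          rtol = rtol, atol = atol)
    y <- sol[nrow(sol), -1]
    keep <- if (s == 1) seq_len(nrow(sol)) else -1L
    rows[[s]] <- sol[keep, -1, drop = FALSE]
    tacc[[s]] <- sol[keep, 1]
  }
  vals <- do.call(rbind, rows)
  vals[vals < 0] <- 0
  colnames(vals) <- c("CPT11", "SN38", "DNA", "L", "D")
  structure(
    list(time = unlist(tacc), values = vals, protocol = protocol),
    class = "cell_population_trajectory"
  )
}

#' Bundle a parameterized PK-PD model for profile computation
#'
#' @param proteins rescaled `protein_trajectory` covering all intended
#'   treatment windows.
#' @param params a [pkpd_parameters()].
#' @param dose,exposure,horizon protocol template shared by all treatment
#'   times.
#' @return list of class `pkpd_model`.
#' @export
pkpd_model <- function(proteins, params, dose = 1, exposure = 4,
                       horizon = 72) {
  structure(
    list(proteins = proteins, params = params, dose = dose,
         exposure = exposure, horizon = horizon),
    class = "pkpd_model"
  )
}

#' Circadian toxicity profile
#'
#' For each treatment time, the area under the dead-cell curve of the
#' treated run divided by that of the untreated control started at the
#' same time (trapezoidal rule on a uniform 0.1 h grid). The peak time is
#' refined by quadratic interpolation around the discrete maximum on the
#' periodic treatment-time grid; ties break towards the earliest time.
#'
#' @param model a [pkpd_model()].
#' @param treatment_times vector of treatment start times (h) spanning a
#'   circadian cycle.
#' @return object of class `toxicity_profile`: data.frame `profile`
#'   (treatment_time, auc_ratio) plus `peak_time`, `peak_value`.
#' @export
toxicity_profile <- function(model, treatment_times = seq(0, 21, by = 3)) {
  if (diff(range(treatment_times)) < 21 - 1e-9) {
    stop("treatment times must span a circadian cycle (>= 21 h grid span)")
  }
  ratio <- vapply(treatment_times, function(T0) {
    prot_t <- treatment_protocol(T0, model$dose, model$exposure, model$horizon)
    prot_c <- treatment_protocol(T0, 0, model$exposure, model$horizon)
    trt <- simulate_treatment(model$proteins, model$params, prot_t)
    ctl <- simulate_treatment(model$proteins, model$params, prot_c)
    a_t <- auc_trapezoid(trt$time, trt$values[, "D"])
    a_c <- auc_trapezoid(ctl$time, ctl$values[, "D"])
    if (a_c <= 0) stop("control AUC is zero; cannot normalize")
    a_t / a_c
  }, numeric(1))
  pk <- profile_peak(treatment_times, ratio, period = 24)
  structure(
    list(
      profile = data.frame(treatment_time = treatment_times,
                           auc_ratio = ratio),
      peak_time = pk$time, peak_value = pk$value
    ),
    class = "toxicity_profile"
  )
}

# Quadratic peak refinement on a periodic grid.
profile_peak <- function(times, values, period = 24) {
  i <- which.max(values)  # which.max takes the earliest on ties
  n <- length(values)
  im <- if (i == 1) n else i - 1
  ip <- if (i == n) 1 else i + 1
  t0 <- times[i]
  tm <- times[im]; tp <- times[ip]
  # unwrap neighbours around the maximum
  if (tm > t0) tm <- tm - period
  if (tp < t0) tp <- tp + period
  y <- c(values[im], values[i], values[ip])
  x <- c(tm, t0, tp)
  denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
  if (abs(denom) < .Machine$double.eps) {
    return(list(time = t0 %% period, value = values[i]))
  }
  a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) + x[1] * (y[3] - y[2])) / denom
  b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) + x[1]^2 * (y[2] - y[3])) / denom
  if (a >= 0) return(list(time = t0 %% period, value = values[i]))
  tv <- -b / (2 * a)
  if (tv < x[1] || tv > x[3]) return(list(time = t0 %% period, value = values[i]))
  c0 <- y[1] - a * x[1]^2 - b * x[1]
  list(time = tv %% period, value = a * tv^2 + b * tv + c0)
}

#' @export
print.toxicity_profile <- function(x, ...) {
  cat(sprintf(
    "toxicity_profile: %d treatment times, peak %.3f at %.2f h\n",
    nrow(x$profile), x$peak_value, x$peak_time
  ))
  invisible(x)
}

#' Shift circadian phases of a PK-PD parameter set
#'
#' Shifts all circadian protein-degradation phases and the death-rate
#' modulation phase by `delta_phase` hours (modulo 24), leaving every
#' other parameter untouched. Used to adapt a fitted model to a cell line
#' whose clock phase (read off ARNTL expression) differs from the
#' reference line.
#'
#' @param params a [pkpd_parameters()].
#' @param delta_phase phase difference in hours (finite).
#' @return shifted `pkpd_parameters`.
#' @export
phase_adapt <- function(params, delta_phase) {
  stopifnot(is.finite(delta_phase))
  params$pdeg_phase <- (params$pdeg_phase + delta_phase) %% 24
  params$death_phase <- (params$death_phase + delta_phase) %% 24
  params
}
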