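#' Entrain the clock to a light-dark cycle
#'
#' Simulates the network under an LD schedule past a transient and checks
#' the entrainment criterion: a 24 h period (within `period_tol`) and a
#' relative amplitude over a 64 h window at least as strong as the
#' free-running amplitude (within `amplitude_tol`).
#'
#' @param network,params as in [simulate_clock()].
#' @param schedule a [zeitgeber_schedule()] with `f_light` > 1.
#' @param transient hours discarded before judging (default 480; locking
#'   near threshold is slow).
#' @param reference species for period/amplitude measurement.
#' @param period_tol tolerance on the 24 h period (default 0.1 h).
#' @param amplitude_tol allowed fractional amplitude loss vs free-running
#'   (default 0.05).
#' @param free_reference optional precomputed free-running [limit_cycle()]
#'   result, reused across repeated calls (e.g. a strength scan).
#' @return list with `trajectory` (entrained window), `entrained`
#'   (logical verdict), `period`, `amplitude`, `free_amplitude`, `state`
#'   (final state, at a lights-on boundary).
#' @export
entrain <- function(network, params, schedule, transient = 480,
                    reference = "M_ARNTL", period_tol = 0.1,
                    amplitude_tol = 0.05, free_reference = NULL) {
  free_lc <- free_reference %||%
    limit_cycle(network, params, schedule = NULL,
                transient = 240, horizon = 130,
                reference = reference)
  horizon <- 96  # multiple of 24 so the final state sits at lights-on
  lc <- limit_cycle(network, params, schedule = schedule,
                    transient = transient, horizon = horizon,
                    reference = reference)
  # relative amplitude over a 64 h window
  w <- lc$trajectory$time <= min(lc$trajectory$time) + 64
  amp64 <- relative_amplitude(lc$trajectory$values[w, reference])
  verdict <- abs(lc$period - 24) <= period_tol &&
    amp64 >= free_lc$amplitude * (1 - amplitude_tol)
  list(
    trajectory = lc$trajectory, entrained = verdict, period = lc$period,
    amplitude = amp64, free_amplitude = free_lc$amplitude,
    free_period = free_lc$period, state = lc$state
  )
}

#' Minimal entraining light strength
#'
#' Scans an ascending grid of light factors and returns the smallest one
#' whose LD cycle entrains the oscillator, or `NA` if none does.
#'
#' @param network,params as in [simulate_clock()].
#' @param f_grid ascending grid of light factors starting at 1.
#' @param ... passed to [entrain()].
#' @return list with `f_star` (NA if no grid value entrains) and `table`
#'   (f, entrained, period, amplitude).
#' @export
minimal_entrainment_strength <- function(network, params,
                                         f_grid = seq(1, 2, by = 0.05),
                                         ...) {
  if (length(f_grid) == 0) stop("f grid is empty")
  if (is.unsorted(f_grid)) stop("f grid must be ascending")
  free_lc <- limit_cycle(network, params, schedule = NULL,
                         transient = 240, horizon = 130)
  rows <- list()
  f_star <- NA_real_
  for (f in f_grid) {
    if (f <= 1) {
      # f = 1 is no forcing; a detuned free-runner cannot be entrained
      ent <- abs(free_lc$period - 24) <= 0.1
      rows[[length(rows) + 1]] <- data.frame(
        f = f, entrained = ent, period = free_lc$period,
        amplitude = free_lc$amplitude
      )
      if (ent) { f_star <- f; break }
      next
    }
    e <- entrain(network, params, zeitgeber_schedule(f_light = f),
                 free_reference = free_lc, ...)
    rows[[length(rows) + 1]] <- data.frame(
      f = f, entrained = e$entrained, period = e$period,
      amplitude = e$amplitude
    )
    if (e$entrained) { f_star <- f; break }
  }
  list(f_star = f_star, table = do.call(rbind, rows))
}

#' Phase shift in response to a single Zeitgeber pulse
#'
#' From an entrained state, simulates a reference run (LD only) and a
#' pulsed run (LD plus one pulse) and measures the phase shift as the
#' time difference of the reference gene's second maximum after the pulse
#' (reference minus pulsed). Sign convention: positive shift = phase
#' advance (the pulsed peak occurs earlier than the reference peak).
#'
#' @param network,params as in [simulate_clock()].
#' @param schedule the entrained LD [zeitgeber_schedule()] (no pulses).
#' @param pulse a [pulse_spec()]; `t_pulse` is interpreted as Zeitgeber
#'   time in the first simulated cycle (negative values wrap to the
#'   previous day).
#' @param entrained_state state vector at lights-on from [entrain()]; if
#'   NULL it is computed.
#' @param cycles number of post-pulse cycles to simulate (default 6).
#' @param reference species used for the shift measurement (default
#'   ARNTL mRNA).
#' @param ref_traj optional precomputed unpulsed trajectory (from the
#'   same entrained state and schedule) reused across a scan.
#' @return object of class `phase_shift`: `shift` (h), `pulse`,
#'   `reference` gene, `peaks_ref`/`peaks_pulse`, and `relaxation`
#'   (per-cycle peak-time differences).
#' @export
pulse_response <- function(network, params, schedule, pulse,
                           entrained_state = NULL, reference = "M_ARNTL",
                           cycles = 6, ref_traj = NULL) {
  if (is.null(entrained_state)) {
    entrained_state <- entrain(network, params, schedule)$state
  }
  t_pulse_abs <- pulse$t_pulse %% schedule$period + schedule$period
  pulse_abs <- pulse_spec(t_pulse_abs, pulse$dur_pulse, pulse$f, pulse$target)
  t_end <- t_pulse_abs + pulse$dur_pulse + cycles * schedule$period
  sch_ref <- schedule
  sch_pulse <- schedule
  sch_pulse$pulses <- c(schedule$pulses, list(pulse_abs))
  ref <- if (!is.null(ref_traj) && max(ref_traj$time) >= t_end) {
    ref_traj
  } else {
    simulate_clock(network, params, init_state = entrained_state,
                   t_span = c(0, t_end), schedule = sch_ref, dt = 0.05)
  }
  per <- simulate_clock(network, params, init_state = entrained_state,
                        t_span = c(0, t_end), schedule = sch_pulse, dt = 0.05)
  t_off <- t_pulse_abs + pulse$dur_pulse
  pk_r <- find_peaks(ref$time[ref$time > t_off],
                     ref$values[ref$time > t_off, reference])
  pk_p <- find_peaks(per$time[per$time > t_off],
                     per$values[per$time > t_off, reference])
  n <- min(nrow(pk_r), nrow(pk_p))
  if (n < 2) stop("fewer than two post-pulse maxima; extend the window")
  diffs <- pk_r$time[seq_len(n)] - pk_p$time[seq_len(n)]
  shift <- diffs[2]
  # report modulo the cycle, in (-T/2, T/2]
  shift <- ((shift + schedule$period / 2) %% schedule$period) -
    schedule$period / 2
  structure(
    list(
      shift = shift, pulse = pulse, reference = reference,
      peaks_ref = pk_r[seq_len(n), ], peaks_pulse = pk_p[seq_len(n), ],
      relaxation = diffs
    ),
    class = "phase_shift"
  )
}

#' Phase-response scan over pulse timing, strength and duration
#'
#' Evaluates [pulse_response()] on the full grid; individual failures are
#' recorded as NA cells rather than aborting the scan.
#'
#' @param network,params,schedule,entrained_state as in
#'   [pulse_response()].
#' @param t_pulse_grid Zeitgeber times of pulse onset (h).
#' @param strengths pulse strength factors.
#' @param durations pulse durations (h).
#' @param target `"PER"` or `"NR1D"`.
#' @return object of class `prc_table`: data.frame (t_pulse, strength,
#'   duration, target, shift) plus `max_shift_time` (Zeitgeber time of
#'   the largest absolute shift).
#' @export
prc_scan <- function(network, params, schedule,
                     t_pulse_grid = seq(0, 21, by = 3), strengths = 1.75,
                     durations = 1, target = "PER",
                     entrained_state = NULL) {
  target <- match.arg(target, c("PER", "NR1D"))
  if (is.null(entrained_state)) {
    entrained_state <- entrain(network, params, schedule)$state
  }
  grid <- expand.grid(t_pulse = t_pulse_grid, strength = strengths,
                      duration = durations)
  grid$target <- target
  grid$shift <- NA_real_
  # shared unpulsed reference covering the longest pulse window
  t_end_max <- max(grid$t_pulse %% schedule$period) + schedule$period +
    max(grid$duration) + 6 * schedule$period
  ref_traj <- simulate_clock(network, params, init_state = entrained_state,
                             t_span = c(0, t_end_max), schedule = schedule,
                             dt = 0.05)
  for (i in seq_len(nrow(grid))) {
    if (grid$strength[i] == 1) { grid$shift[i] <- 0; next }
    ps <- pulse_spec(grid$t_pulse[i], grid$duration[i], grid$strength[i],
                     target)
    r <- try(pulse_response(network, params, schedule, ps,
                            entrained_state = entrained_state,
                            ref_traj = ref_traj),
             silent = TRUE)
    if (!inherits(r, "try-error")) grid$shift[i] <- r$shift
  }
  ok <- !is.na(grid$shift)
  max_row <- if (any(ok)) grid[ok, ][which.max(abs(grid$shift[ok])), ] else NULL
  structure(
    list(table = grid,
         max_shift_time = if (is.null(max_row)) NA_real_ else max_row$t_pulse,
         max_shift = if (is.null(max_row)) NA_real_ else max_row$shift),
    class = "prc_table"
  )
}

#' @export
print.prc_table <- function(x, ...) {
  cat(sprintf(
    "prc_table: %d cells, largest |shift| %.2f h at ZT %.1f\n",
    nrow(x$table), x$max_shift, x$max_shift_time
  ))
  invisible(x)
}

#' Cycles until a pulse perturbation decays to half
#'
#' Measures, per gene, the per-cycle peak-time deviation between pulsed
#' and reference runs and reports the number of cycles until the
#' deviation first falls below half of its initial value. Core-clock
#' genes typically relax faster than clock-controlled output genes.
#'
#' @param network,params,schedule,pulse,entrained_state as in
#'   [pulse_response()].
#' @param genes genes to track (default PER and CES2).
#' @param cycles post-pulse cycles simulated.
#' @return named numeric vector of cycles-to-half-deviation (NA if the
#'   deviation never halves within the window).
#' @export
pulse_relaxation <- function(network, params, schedule, pulse,
                             genes = c("PER", "CES2"),
                             entrained_state = NULL, cycles = 8) {
  out <- stats::setNames(rep(NA_real_, length(genes)), genes)
  for (g in genes) {
    r <- pulse_response(network, params, schedule, pulse,
                        entrained_state = entrained_state,
                        reference = paste0("M_", g), cycles = cycles)
    dev <- abs(r$relaxation)
    if (dev[1] <= 0) { out[g] <- 0; next }
    below <- which(dev <= dev[1] / 2)
    if (length(below) > 0) out[g] <- below[1] - 1
  }
  out
}

#' Toxicity profile under a Zeitgeber pulse
#'
#' Computes the circadian toxicity profile from pulse-perturbed clock
#' trajectories and compares its peak time with the unpulsed profile.
#'
#' @param network,params clock model.
#' @param schedule entrained LD schedule.
#' @param pulse a [pulse_spec()] or NULL for the unpulsed reference.
#' @param pkpd a [pkpd_parameters()] object for the cell line.
#' @param treatment_times treatment grid (Zeitgeber hours of one cycle).
#' @param entrained_state optional precomputed entrained state.
#' @param dose,exposure,horizon protocol template.
#' @return list with `profile` (a `toxicity_profile`), `peak_time`, and
#'   `proteins` used.
#' @export
toxicity_under_pulse <- function(network, params, schedule, pulse, pkpd,
                                 treatment_times = seq(0, 21, by = 3),
                                 entrained_state = NULL, dose = 1,
                                 exposure = 4, horizon = 72) {
  if (is.null(entrained_state)) {
    entrained_state <- entrain(network, params, schedule)$state
  }
  sch <- schedule
  if (!is.null(pulse)) {
    t_abs <- pulse$t_pulse %% schedule$period + schedule$period
    sch$pulses <- c(sch$pulses,
                    list(pulse_spec(t_abs, pulse$dur_pulse, pulse$f,
                                    pulse$target)))
  }
  t_end <- max(treatment_times) + horizon + 2 * schedule$period
  traj <- simulate_clock(network, params, init_state = entrained_state,
                         t_span = c(0, t_end), schedule = sch, dt = 0.1)
  prot <- translate_proteins(traj, pkpd)
  prot <- rescale_protein(prot, pkpd$target_max,
                          scale_factor = c(UGT1A1 = pkpd$ugt_scale),
                          zero_ok = "UGT1A1")
  model <- pkpd_model(prot, pkpd, dose = dose, exposure = exposure,
                      horizon = horizon)
  # treatments are delivered in the cycle following the pulse day
  prof <- toxicity_profile(model, treatment_times + 2 * schedule$period)
  list(profile = prof, peak_time = prof$peak_time, proteins = prot)
}
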