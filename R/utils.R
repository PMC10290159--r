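#' Locate local maxima of a sampled signal
#'
#' Finds strict local maxima of `x` over `time` and refines each peak
#' position by fitting a quadratic through the three samples around the
#' discrete maximum. Ties are broken towards the earliest time.
#'
#' @param time numeric vector of strictly increasing times (hours).
#' @param x numeric vector of signal values, same length as `time`.
#' @param refine logical; apply quadratic sub-grid refinement (default TRUE).
#' @param min_prominence minimum height of a peak above the lower of its two
#'   neighbouring minima, as a fraction of the signal range. Peaks shallower
#'   than this are discarded. Default 0.01.
#' @return data.frame with columns `time` and `value`, one row per peak,
#'   ordered by time. Zero rows if no peak is found.
#' @export
find_peaks <- function(time, x, refine = TRUE, min_prominence = 0.01) {
  stopifnot(length(time) == length(x), length(time) >= 3)
  n <- length(x)
  core <- 2:(n - 1)
  is_max <- x[core] > x[core - 1] & x[core] >= x[core + 1]
  idx <- core[is_max]
  if (length(idx) == 0L) {
    return(data.frame(time = numeric(0), value = numeric(0)))
  }
  rng <- diff(range(x))
  if (rng > 0 && min_prominence > 0) {
    keep <- vapply(idx, function(i) {
      left <- min(x[max(1, i - 200):i])
      right <- min(x[i:min(n, i + 200)])
      (x[i] - max(left, right)) / rng >= min_prominence
    }, logical(1))
    idx <- idx[keep]
  }
  if (length(idx) == 0L) {
    return(data.frame(time = numeric(0), value = numeric(0)))
  }
  tt <- time[idx]
  vv <- x[idx]
  if (refine) {
    for (k in seq_along(idx)) {
      i <- idx[k]
      t3 <- time[(i - 1):(i + 1)]
      y3 <- x[(i - 1):(i + 1)]
      # quadratic through three points; vertex is the refined peak
      denom <- (t3[1] - t3[2]) * (t3[1] - t3[3]) * (t3[2] - t3[3])
      if (abs(denom) > .Machine$double.eps) {
        a <- (t3[3] * (y3[2] - y3[1]) + t3[2] * (y3[1] - y3[3]) +
                t3[1] * (y3[3] - y3[2])) / denom
        b <- (t3[3]^2 * (y3[1] - y3[2]) + t3[2]^2 * (y3[3] - y3[1]) +
                t3[1]^2 * (y3[2] - y3[3])) / denom
        if (a < 0) {
          tv <- -b / (2 * a)
          if (tv >= t3[1] && tv <= t3[3]) {
            c0 <- y3[1] - a * t3[1]^2 - b * t3[1]
            tt[k] <- tv
            vv[k] <- a * tv^2 + b * tv + c0
          }
        }
      }
    }
  }
  data.frame(time = tt, value = vv)
}

#' Trapezoidal area under a sampled curve
#'
#' Resamples the curve to a uniform grid by linear interpolation and applies
#' the trapezoidal rule.
#'
#' @param time sampling times (hours), strictly increasing.
#' @param x values.
#' @param dt resampling step in hours (default 0.1).
#' @return scalar AUC.
#' @export
auc_trapezoid <- function(time, x, dt = 0.1) {
  stopifnot(length(time) == length(x), length(time) >= 2)
  grid <- seq(time[1], time[length(time)], by = dt)
  if (grid[length(grid)] < time[length(time)]) {
    grid <- c(grid, time[length(time)])
  }
  xi <- stats::approx(time, x, xout = grid, rule = 2)$y
  pracma::trapz(grid, xi)
}

#' Relative oscillation amplitude
#'
#' (max - min) / max of a series; the criterion used to force fitted mRNA
#' trajectories to oscillate. Returns 0 for an all-zero series.
#'
#' @param x numeric vector.
#' @return scalar in [0, 1].
#' @export
relative_amplitude <- function(x) {
  mx <- max(x)
  if (mx <= 0) return(0)
  (mx - min(x)) / mx
}

# Interpolate trajectory species at arbitrary times (rule = 2: clamp ends).
interp_species <- function(traj, species, times) {
  stopifnot(species %in% colnames(traj$values))
  stats::approx(traj$time, traj$values[, species], xout = times, rule = 2)$y
}

# Small helper: a %||% b
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Provenance record for an analysis artifact
#'
#' @param config any serializable configuration object (hashed into the record).
#' @param seed integer seed used for the run, or NA.
#' @return list with package version, timestamp, seed and a config digest.
#' @export
provenance_record <- function(config = NULL, seed = NA_integer_) {
  digest <- if (is.null(config)) {
    NA_character_
  } else {
    # cheap structural digest: sum of char codes of the serialized config
    s <- paste(utils::capture.output(utils::str(config)), collapse = "")
    sprintf("%08x", sum(utf8ToInt(s)) %% .Machine$integer.max)
  }
  list(
    package = "chronotox",
    version = as.character(utils::packageVersion("chronotox")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_digest = digest
  )
}
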