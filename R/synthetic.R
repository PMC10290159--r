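#' Specification for synthetic circadian expression data
#'
#' Describes the generative model for synthetic gene-expression time
#' series: a cosinor oscillation per gene (mesor, relative amplitude,
#' peak phase, ~24 h period) with an additive linear drift — mimicking
#' the consistent linear trends seen on top of oscillations in RNA-seq
#' time courses — and multiplicative log-normal noise (CPM-like
#' heteroscedasticity). Paralog families carry compensation rules used by
#' the knock-out generator.
#'
#' @param genes data.frame with columns `gene`, `mesor` (> 0 except for
#'   deliberately silent genes), `amplitude` (relative, in [0, 1)),
#'   `phase` (h), `period` (h, ~24), `drift` (units/h).
#' @param noise_sd log-normal sigma of the multiplicative noise
#'   (0 = noiseless).
#' @param t_start,t_step,t_end sampling grid in hours (default every 3 h
#'   over 0-45 h, mimicking the study's sampling).
#' @param families named list of paralog families with compensation rule:
#'   each element `list(members=..., rule="compensate"|"co_reduce")`.
#' @param seed mandatory integer seed.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(genes = default_synthetic_genes(),
                           noise_sd = 0, t_start = 0, t_step = 3,
                           t_end = 45,
                           families = default_synthetic_families(),
                           seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(is.data.frame(genes),
            all(c("gene", "mesor", "amplitude", "phase", "period",
                  "drift") %in% names(genes)))
  if (any(genes$mesor < 0)) stop("mesor must be non-negative")
  if (any(genes$amplitude < 0 | genes$amplitude >= 1)) {
    stop("relative amplitudes must lie in [0, 1)")
  }
  if (t_end - t_start < 24) stop("sampling must cover at least 24 h")
  structure(
    list(genes = genes, noise_sd = noise_sd,
         times = seq(t_start, t_end, by = t_step),
         families = families, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Default synthetic gene panel
#'
#' Core-clock paralogs plus drug-metabolism genes with phases spread over
#' the cycle, moderate relative amplitudes, and mild linear drifts for
#' the genes that show pronounced trends in RNA-seq time courses (ROR,
#' PPARA, CES2). UGT1A1 is near-silent, as in HCT116-like lines.
#'
#' @param hct116_like logical; if TRUE (default) UGT1A1 mesor is set to a
#'   near-zero value.
#' @return data.frame usable as `genes` in [synthetic_spec()].
#' @export
default_synthetic_genes <- function(hct116_like = TRUE) {
  g <- rbind(
    data.frame(gene = "ARNTL",  mesor = 60, amplitude = 0.45, phase = 20),
    data.frame(gene = "CLOCK",  mesor = 45, amplitude = 0.15, phase = 22),
    data.frame(gene = "PER1",   mesor = 30, amplitude = 0.40, phase = 9),
    data.frame(gene = "PER2",   mesor = 50, amplitude = 0.45, phase = 10),
    data.frame(gene = "PER3",   mesor = 8,  amplitude = 0.35, phase = 11),
    data.frame(gene = "CRY1",   mesor = 35, amplitude = 0.30, phase = 12),
    data.frame(gene = "CRY2",   mesor = 28, amplitude = 0.25, phase = 14),
    data.frame(gene = "NR1D1",  mesor = 40, amplitude = 0.55, phase = 6),
    data.frame(gene = "NR1D2",  mesor = 32, amplitude = 0.45, phase = 7),
    data.frame(gene = "ROR",    mesor = 25, amplitude = 0.25, phase = 16),
    data.frame(gene = "DBP",    mesor = 20, amplitude = 0.50, phase = 8),
    data.frame(gene = "NFIL3",  mesor = 15, amplitude = 0.30, phase = 18),
    data.frame(gene = "PPARA",  mesor = 22, amplitude = 0.20, phase = 15),
    data.frame(gene = "CES2",   mesor = 55, amplitude = 0.25, phase = 7),
    data.frame(gene = "ABCB",   mesor = 18, amplitude = 0.20, phase = 13),
    data.frame(gene = "ABCC",   mesor = 48, amplitude = 0.20, phase = 11),
    data.frame(gene = "UGT1A1", mesor = if (hct116_like) 0.05 else 12,
               amplitude = 0.2, phase = 9)
  )
  g$period <- 24
  g$drift <- 0
  g$drift[g$gene %in% c("ROR", "PPARA", "CES2")] <- c(0.25, -0.15, 0.4)
  g
}

#' Default paralog families and compensation rules
#'
#' PER and NR1D families compensate (the family sum is preserved after a
#' single-member knock-out); the ARNTL family co-reduces (ARNTL2 drops
#' when ARNTL is knocked out). ARNTL2 is not part of the default panel's
#' fitted genes but is included here for knock-out emulation.
#'
#' @return named list of family definitions.
#' @export
default_synthetic_families <- function() {
  list(
    PER = list(members = c("PER1", "PER2", "PER3"), rule = "compensate"),
    NR1D = list(members = c("NR1D1", "NR1D2"), rule = "compensate"),
    CRY = list(members = c("CRY1", "CRY2"), rule = "compensate"),
    ARNTL = list(members = c("ARNTL", "ARNTL2"), rule = "co_reduce")
  )
}

# Internal: noiseless cosinor + drift matrix for a spec.
cosinor_matrix <- function(spec) {
  tt <- spec$times
  g <- spec$genes
  vals <- matrix(0, nrow(g), length(tt), dimnames = list(g$gene, NULL))
  for (i in seq_len(nrow(g))) {
    vals[i, ] <- g$mesor[i] *
      (1 + g$amplitude[i] * cos(2 * pi * (tt - g$phase[i]) / g$period[i])) +
      g$drift[i] * tt
  }
  vals
}

#' Generate synthetic circadian expression data
#'
#' `x_g(t) = (mesor * (1 + amp * cos(2*pi*(t - phase)/period)) +
#' drift * t) * noise`, with log-normal multiplicative noise of sigma
#' `noise_sd`. Values are clipped at zero to stay on the CPM scale.
#' Bit-for-bit reproducible for a fixed seed.
#'
#' @param spec a [synthetic_spec()].
#' @param cell_line label attached to the dataset.
#' @return an [expression_dataset()].
#' @export
generate_clock_expression <- function(spec, cell_line = "synthetic_WT") {
  stopifnot(inherits(spec, "synthetic_spec"))
  vals <- cosinor_matrix(spec)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    noise <- matrix(
      stats::rlnorm(length(vals), meanlog = -spec$noise_sd^2 / 2,
                    sdlog = spec$noise_sd),
      nrow(vals), ncol(vals)
    )
    vals <- vals * noise
  }
  vals[vals < 0] <- 0
  expression_dataset(vals, spec$times, cell_line)
}

#' Generate a synthetic knock-out dataset
#'
#' Sets the knocked-out gene's series to a residual level (1e-3 of the
#' family mesor, avoiding degenerate normalizers) and applies the
#' family's compensation rule: `compensate` raises the remaining
#' paralogs proportionally so the per-timepoint family sum is preserved;
#' `co_reduce` scales the remaining paralogs down (positive regulation
#' by the knocked-out member), as seen for ARNTL2 after ARNTL knock-out.
#'
#' @param spec a [synthetic_spec()].
#' @param ko_gene gene to knock out; must belong to a declared family.
#' @param co_reduce_factor factor applied to remaining members under the
#'   `co_reduce` rule (default 0.4).
#' @return an [expression_dataset()] labelled `synthetic_<gene>KO`.
#' @export
generate_knockout <- function(spec, ko_gene, co_reduce_factor = 0.4) {
  stopifnot(inherits(spec, "synthetic_spec"))
  fam <- NULL
  for (f in spec$families) if (ko_gene %in% f$members) { fam <- f; break }
  if (is.null(fam)) {
    stop(sprintf("gene '%s' has no declared paralog family/compensation rule",
                 ko_gene))
  }
  wt <- generate_clock_expression(spec, cell_line = "synthetic_WT")
  vals <- wt$values
  if (!ko_gene %in% rownames(vals)) {
    stop(sprintf("gene '%s' not in the synthetic panel", ko_gene))
  }
  others <- intersect(setdiff(fam$members, ko_gene), rownames(vals))
  fam_mesor <- mean(spec$genes$mesor[spec$genes$gene %in% fam$members])
  residual <- 1e-3 * fam_mesor
  ko_series <- vals[ko_gene, ]
  vals[ko_gene, ] <- residual
  if (fam$rule == "compensate" && length(others) > 0) {
    # redistribute the lost expression proportionally to current levels
    for (j in seq_len(ncol(vals))) {
      tot <- sum(vals[others, j])
      lost <- ko_series[j] - residual
      if (tot > 0 && lost > 0) {
        vals[others, j] <- vals[others, j] * (1 + lost / tot)
      }
    }
  } else if (fam$rule == "co_reduce" && length(others) > 0) {
    vals[others, ] <- vals[others, ] * co_reduce_factor
  }
  expression_dataset(vals, spec$times,
                     cell_line = sprintf("synthetic_%sKO", ko_gene))
}

#' Generate synthetic cytotoxicity curves
#'
#' Forward-simulates the PK-PD model per treatment time plus an untreated
#' control, adds multiplicative log-normal noise, and attaches the
#' ground-truth normalized-AUC toxicity profile computed from the
#' noiseless curves.
#'
#' @param pkpd_truth a [pkpd_parameters()] (ground truth).
#' @param proteins rescaled `protein_trajectory` covering all windows.
#' @param treatment_times non-empty vector of treatment start times (h).
#' @param noise_sd log-normal sigma (0 = noiseless).
#' @param seed integer seed.
#' @param dose,exposure,horizon protocol template.
#' @param n_points measurement timepoints per curve (default 13).
#' @return list with `curves` (data.frame treatment_time/time/value,
#'   control rows have NA treatment_time), `truth_profile` (a
#'   `toxicity_profile`), `truth_params`.
#' @export
generate_cytotoxicity <- function(pkpd_truth, proteins, treatment_times,
                                  noise_sd = 0, seed = 1L, dose = 1,
                                  exposure = 4, horizon = 72,
                                  n_points = 13) {
  if (length(treatment_times) == 0) stop("treatment grid is empty")
  grid <- seq(0, horizon, length.out = n_points)
  rows <- list()
  for (T0 in treatment_times) {
    s <- simulate_treatment(proteins, pkpd_truth,
                            treatment_protocol(T0, dose, exposure, horizon))
    rows[[length(rows) + 1]] <- data.frame(
      treatment_time = T0, time = grid,
      value = stats::approx(s$time - T0, s$values[, "D"], xout = grid,
                            rule = 2)$y
    )
  }
  s0 <- simulate_treatment(proteins, pkpd_truth,
                           treatment_protocol(0, 0, exposure, horizon))
  rows[[length(rows) + 1]] <- data.frame(
    treatment_time = NA_real_, time = grid,
    value = stats::approx(s0$time, s0$values[, "D"], xout = grid,
                          rule = 2)$y
  )
  curves <- do.call(rbind, rows)
  if (noise_sd > 0) {
    set.seed(seed)
    curves$value <- curves$value *
      stats::rlnorm(nrow(curves), -noise_sd^2 / 2, noise_sd)
  }
  truth <- toxicity_profile(
    pkpd_model(proteins, pkpd_truth, dose, exposure, horizon),
    treatment_times
  )
  list(curves = curves, truth_profile = truth, truth_params = pkpd_truth)
}
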