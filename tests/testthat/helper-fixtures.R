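# Shared fixtures, computed lazily and cached for the whole test run.
.fix <- new.env(parent = emptyenv())

fix_network <- function() {
  if (is.null(.fix$network)) .fix$network <- build_network()
  .fix$network
}

fix_params <- function() default_clock_parameters()

# Free-running limit cycle of the default model.
fix_free_lc <- function() {
  if (is.null(.fix$free_lc)) {
    .fix$free_lc <- limit_cycle(fix_network(), fix_params(),
                                transient = 240, horizon = 130)
  }
  .fix$free_lc
}

# Entrained state under 12:12 LD at f_light = 1.5 (the package's
# operating point for pulse experiments).
fix_entrained <- function() {
  if (is.null(.fix$entrained)) {
    .fix$entrained <- entrain(fix_network(), fix_params(),
                              zeitgeber_schedule(f_light = 1.5),
                              free_reference = fix_free_lc())
  }
  .fix$entrained
}

fix_schedule <- function() zeitgeber_schedule(f_light = 1.5)

# Long clock trajectory + rescaled proteins for PK-PD tests.
fix_proteins <- function() {
  if (is.null(.fix$proteins)) {
    traj <- simulate_clock(fix_network(), fix_params(),
                           t_span = c(0, 340), dt = 0.25)
    pk <- pkpd_parameters()
    prot <- translate_proteins(traj, pk)
    .fix$proteins <- rescale_protein(prot, pk$target_max,
                                     zero_ok = "UGT1A1")
  }
  .fix$proteins
}

# Small synthetic expression dataset builder.
toy_dataset <- function(values, times = NULL) {
  if (is.null(times)) times <- seq(0, by = 3, length.out = ncol(values))
  expression_dataset(values, times)
}
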