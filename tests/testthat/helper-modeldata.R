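# Model-generated expression datasets for self-consistency/recovery tests.

# Sample the mRNAs of a parameterization on its own limit cycle.
model_dataset <- function(params, label, t_step = 3, t_end = 45) {
  net <- fix_network()
  lc <- limit_cycle(net, params, transient = 240, horizon = 60, dt = 0.05)
  state0 <- setNames(lc$state, net$species)
  traj <- simulate_clock(net, params, init_state = state0,
                         t_span = c(0, t_end), dt = 0.25)
  tt <- seq(0, t_end, by = t_step)
  vals <- t(sapply(net$genes, function(g) {
    approx(traj$time, traj$values[, paste0("M_", g)], xout = tt)$y
  }))
  rownames(vals) <- net$genes
  list(data = expression_dataset(vals, tt, label), state = state0)
}

# Normalized total variance of a dataset (the SS_tot of the fitting cost).
dataset_variance <- function(ds) {
  sum(sapply(ds$genes, function(g) {
    x <- ds$values[g, ] / max(ds$values[g, ])
    sum((x - mean(x))^2)
  }))
}

# The planted knock-out perturbation used by the regularization tests.
planted_ko_factors <- function() {
  c(ki_NR1D_ARNTL = 1.6, dn_PER = 1.5, vmax_NR1D = 0.6)
}
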