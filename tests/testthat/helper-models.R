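# shared fixtures, built once per test run
coupled_pars <- default_parameters("coupled")
core_pars <- default_parameters("core")

# coarse sweep grid: enough to resolve every fold of the calibrated models
sweep_grid <- seq(0, 5e5, length.out = 101)

# memoised sweeps (several test files need them)
.sweep_cache <- new.env()
cached_sweep <- function(which = c("coupled", "core")) {
  which <- match.arg(which)
  if (is.null(.sweep_cache[[which]])) {
    p <- if (which == "coupled") coupled_pars else core_pars
    .sweep_cache[[which]] <- sweep_bifurcation(p, sweep_grid, seed = 1)
  }
  .sweep_cache[[which]]
}

random_state <- function(params, seed) {
  drop(random_initial_states(params, 1, seed))
}

# memoised residence-time/landscape analyses shared by the stochastic
# acceptance checks (3 seeds, shortened horizon: the tested orderings are
# separated by one to two orders of magnitude)
.mrt_cache <- new.env()
cached_mrt <- function(which, S) {
  key <- paste0(which, "_", S)
  if (is.null(.mrt_cache[[key]])) {
    p <- if (which == "coupled") coupled_pars else core_pars
    .mrt_cache[[key]] <- mrt_analysis(p, S, seeds = 1:3, hours = 8e3)
  }
  .mrt_cache[[key]]
}
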