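# Shared fixtures: a desk-scale parameter set (smaller landscape, capacity
# and development time than the reference values, same ratios) used by the
# slower metapopulation tests, and tiny settings for unit tests.

scaled_params <- function(...) {
  args <- list(M = 20, K = 1000, tau = 200, max_cycles = 300)
  args[names(list(...))] <- list(...)
  do.call(sim_params, args)
}

tiny_params <- function(...) {
  args <- list(M = 5, K = 200, tau = 50, D = 20, H0 = 20, max_cycles = 50)
  args[names(list(...))] <- list(...)
  do.call(sim_params, args)
}

fig_growth <- function(...) growth_params(c = 0.15, K = 1e4, ...)
fig_decay <- function(...) decay_params(delta_K = 0.1, delta_s = 0.1, ...)
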