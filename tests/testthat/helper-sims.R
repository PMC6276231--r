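# Shared converged simulations, computed once per test session.
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, maker) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- maker()
  .sim_cache[[key]]
}

healthy_sim <- function() cached_sim("healthy", function()
  run_to_steady_state(default_params("healthy")))

hf_sim <- function() cached_sim("hf", function()
  run_to_steady_state(default_params("hf")))

# HF with constant-speed series pump at a mid support level
supported_sim <- function(omega = 100) cached_sim(paste0("sup", omega),
  function() {
    p <- default_params("hf")
    p$pump$attach <- "series"
    p$control$omega_mean <- omega
    run_to_steady_state(p, init = hf_sim()$state0)
  })
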