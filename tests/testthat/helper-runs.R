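# shared simulation runs, computed once per test session
.run_cache <- new.env(parent = emptyenv())

cache_get <- function(key, fn) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- fn()
  .run_cache[[key]]
}

healthy_sweep <- function() cache_get("healthy_sweep", function() {
  steady_state_response(healthy_parameters(),
                        c(0, 20, 30, 40, 50, 60, 70, 80), settle = 100)
})

healthy_pair <- function() cache_get("healthy_pair", function() {
  steady_state_response(healthy_parameters(), c(0, 80), settle = 120)
})

hf_pair <- function() cache_get("hf_pair", function() {
  steady_state_response(scenario_heart_failure(healthy_parameters()),
                        c(0, 80), settle = 150)
})

supine_sim <- function() cache_get("supine_sim", function() {
  simulate_cvs(healthy_parameters(), tilt_protocol(0, 60), record = TRUE)
})

# fast settings for estimation tests
est_settle <- 40
est_dt <- 1e-3
est_angles <- c(0, 40, 80)
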