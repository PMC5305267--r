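# Shared small fixtures, built once per test run.

p64 <- polar_params(N = 64)
g64 <- make_disk(p64)
rested64 <- rested_state(g64, p64)

# a quick polarized run reused by several tests (front state at t = 120)
polar_run <- function(params = p64, geometry = g64, amp = 0.003,
                      t_end = 120, ...) {
  simulate(rested_state(geometry, params), geometry, params,
           stimulus_protocol("graded", ks_amp = amp, ks_dur = 20),
           solver_config(t_end = t_end, ...))
}

# synthetic trace with a prescribed max_u series (for detector tests)
fake_trace <- function(t, max_u, params = p64) {
  structure(list(metrics = tibble::tibble(t = t, max_u = max_u),
                 events = tibble::tibble(onset = 0, offset = 1),
                 params = params),
            class = "polar_trace")
}

# lazily computed, cached heavy runs shared across acceptance blocks
.memo <- new.env()
memo_get <- function(key, compute) {
  if (!exists(key, .memo)) assign(key, compute(), .memo)
  get(key, .memo)
}
aspiration_pf <- function() memo_get("asp_pf", function() aspiration_release(p64))
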