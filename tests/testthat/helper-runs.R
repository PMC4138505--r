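# Long simulations shared between acceptance blocks, computed once per
# test session.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .run_cache)) assign(key, fn(), envir = .run_cache)
  get(key, envir = .run_cache)
}

trimodal_trace <- function(k = 0.1, seed = 1) {
  key <- paste0("trimodal_k", k)
  cached(key, function()
    simulate_protocol(quiet_protocol(45000, k = k), default_config(), seed))
}

pf_trace <- function(seed, rate = 100, duration = 25000) {
  cached(paste0("pf_", rate, "_", seed, "_", duration), function()
    simulate_protocol(
      protocol_spec("pf", duration = duration,
                    cf = list(on = FALSE, freq = 1),
                    pf = list(on = TRUE, rate = rate, seed = NULL),
                    overrides = list()),
      default_config(), seed))
}

cf_trace <- function(g_sk, duration = 15000, g_ih = NULL, pf = FALSE, seed = 1) {
  key <- paste0("cf_", g_sk, "_", duration, "_",
                if (is.null(g_ih)) "d" else g_ih, "_", pf, "_", seed)
  cached(key, function() {
    ov <- list(g_sk = g_sk)
    if (!is.null(g_ih)) ov$g_ih_soma <- g_ih
    simulate_protocol(
      protocol_spec("cf", duration = duration,
                    cf = list(on = TRUE, freq = 1),
                    pf = list(on = pf, rate = 100, seed = NULL),
                    overrides = ov),
      default_config(), seed)
  })
}

# pooled tonic rate of a trace (NA if no tonic interval)
trace_tonic_rate <- function(tr) {
  suppressWarnings(analyze_trace(tr)$summary$tonic_rate_hz)
}
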