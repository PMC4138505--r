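# Shared builders: reduced cables and passive membranes for oracle tests.

tiny_config <- function(n_sm = 1, n_sp = 1, sm = c(1, 0.1), sp = c(1, 0.1)) {
  default_config(geometry = list(
    smooth = list(n = n_sm, length = sm[1], diam = sm[2]),
    spiny = list(n = n_sp, length = sp[1], diam = sp[2])))
}

# all active conductances off; leak only
passive_config <- function(...) {
  cfg <- default_config(...)
  cfg$densities$soma[] <- 0
  cfg$densities$soma[["leak"]] <- 0.1
  cfg$densities$dend[] <- 0
  cfg$densities$dend[["leak"]] <- 0.38
  cfg
}

quiet_protocol <- function(duration, ...) {
  protocol_spec("quiet", duration = duration,
                cf = list(on = FALSE, freq = 1),
                pf = list(on = FALSE, rate = 0, seed = NULL),
                overrides = list(...))
}

cf_protocol <- function(duration, g_sk = 0.72, freq = 1, ...) {
  protocol_spec("cf", duration = duration,
                cf = list(on = TRUE, freq = freq),
                pf = list(on = FALSE, rate = 0, seed = NULL),
                overrides = list(g_sk = g_sk, ...))
}
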