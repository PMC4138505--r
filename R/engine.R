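# Simulation driver: translates a configuration + protocol into the flat
# parameter list the compiled core consumes, manages state initialisation
# and chaining, and wraps recorded output into a `purksim_trace`.

# mM/ms of shell-concentration change per mA/cm2 of (inward) Ca current.
# Two readings of the somatic influx term are supported: "area" divides by
# the somatic membrane area in um2 (the printed per-area form, which makes
# the influx negligible so the shell rides its 100 nM floor), "shell" is
# the 1e4/(2 F depth) form shared with the dendritic shells.
soma_influx_coef <- function(config) {
  ca <- config$calcium$soma
  mode <- if (is.null(ca$influx_mode)) "area" else ca$influx_mode
  F <- config$constants$F
  if (mode == "area") {
    area_um2 <- pi * config$geometry$soma$diam * config$geometry$soma$length
    100 / (2 * F * ca$depth * area_um2)
  } else 1e4 / (2 * F * ca$depth)
}

build_engine_pars <- function(config, protocol = NULL, seed = 1) {
  topo <- build_default_topology(config)
  comp <- topo$compartments
  n <- nrow(comp)
  zone_i <- match(comp$zone, c("soma", "smooth", "spiny")) - 1L

  # densities: mS/cm2 -> S/cm2, per compartment, zone-masked
  zero <- numeric(n)
  dmask <- function(val, zones) { x <- zero; x[comp$zone %in% zones] <- val / 1000; x }
  ds <- config$densities$soma; dd <- config$densities$dend
  dens <- list(
    na_r = dmask(ds[["na_r"]], "soma"),
    ca_p_s = dmask(ds[["ca_p"]], "soma"),
    k_fast = dmask(ds[["k_fast"]], "soma"),
    k_mid = dmask(ds[["k_mid"]], "soma"),
    k_slow = dmask(ds[["k_slow"]], "soma"),
    bk_s = dmask(ds[["bk"]], "soma"),
    ih_s = dmask(ds[["ih"]], "soma"),
    leak_s = dmask(ds[["leak"]], "soma"),
    ca_t = dmask(dd[["ca_t"]], c("smooth", "spiny")),
    ca_e = dmask(dd[["ca_e"]], c("smooth", "spiny")),
    ca_p_d = dmask(dd[["ca_p"]], c("smooth", "spiny")),
    k_a = dmask(dd[["k_a"]], c("smooth", "spiny")),
    k_d = dmask(dd[["k_d"]], c("smooth", "spiny")),
    k_m = dmask(dd[["k_m"]], c("smooth", "spiny")),
    k_dr = dmask(dd[["k_dr"]], c("smooth", "spiny")),
    bk_d = dmask(dd[["bk"]], c("smooth", "spiny")),
    k2 = dmask(dd[["k2"]], c("smooth", "spiny")),
    ih_d = dmask(dd[["ih"]], c("smooth", "spiny")),
    leak_d = dmask(dd[["leak"]], c("smooth", "spiny")))

  # axial coupling coefficients: current into i from parent/child per mV,
  # as a density (mA/cm2 per mV)
  cpar <- numeric(n); cchild <- numeric(n)
  for (k in seq_len(nrow(topo$edges))) {
    a <- topo$edges$a[k] + 1L; b <- topo$edges$b[k] + 1L
    r <- topo$edges$r_mohm[k]
    cchild[a] <- 1e-6 / (r * comp$area[a])
    cpar[b] <- 1e-6 / (r * comp$area[b])
  }

  # synapse trains from the protocol
  cf_comps <- integer(0); cf_times <- numeric(0)
  pf_comps <- integer(0); pf_times <- list()
  dur <- if (is.null(protocol)) 0 else protocol$duration
  smooth_ids <- comp$id[comp$zone == "smooth"]
  spiny_ids <- comp$id[comp$zone == "spiny"]
  if (!is.null(protocol) && isTRUE(protocol$cf$on)) {
    cfg_cf <- config$synapses$cf
    trains <- make_cf_trains(protocol$cf$freq, t_start = 0, t_end = dur,
                             n_contacts = min(cfg_cf$n, length(smooth_ids)),
                             smooth_ids = smooth_ids, g_syn = cfg_cf$g)
    cf_comps <- vapply(trains, `[[`, integer(1), "compartment")
    cf_times <- trains[[1]]$times
  }
  if (!is.null(protocol) && isTRUE(protocol$pf$on)) {
    cfg_pf <- config$synapses$pf
    pf_seed <- if (is.null(protocol$pf$seed)) seed else protocol$pf$seed
    trains <- make_pf_trains(protocol$pf$rate, t_end = dur, seed = pf_seed,
                             spiny_ids = spiny_ids, g_syn = cfg_pf$g)
    pf_comps <- vapply(trains, `[[`, integer(1), "compartment")
    pf_times <- lapply(trains, `[[`, "times")
  }

  ci <- config$integration
  list(
    n = n, zone = zone_i, area = comp$area, cm = comp$cm, diam = comp$diam,
    cpar = cpar, cchild = cchild, dens = dens,
    dt = ci$dt, T = config$constants$T, F = config$constants$F,
    Rgas = config$constants$Rgas,
    ek_soma = config$reversals$ek_soma, ek_dend = config$reversals$ek_dend,
    ena = config$reversals$ena,
    el_soma = config$reversals$el_soma, el_dend = config$reversals$el_dend,
    eh_soma = config$reversals$eh_soma, eh_dend = config$reversals$eh_dend,
    eca_dend = config$reversals$eca_dend,
    k_kd = config$kinetics$k_kd,
    calcium = list(
      soma_depth = config$calcium$soma$depth,
      soma_beta = config$calcium$soma$beta,
      soma_floor = config$calcium$soma$floor,
      soma_ca_init = config$calcium$soma$ca_init,
      soma_influx_coef = soma_influx_coef(config),
      spiny_kt = config$calcium$spiny$kt, spiny_kd = config$calcium$spiny$kd,
      spiny_tau_r = config$calcium$spiny$tau_r, spiny_y = config$calcium$spiny$y,
      spiny_depth = config$calcium$spiny$depth,
      spiny_ca_init = config$calcium$spiny$ca_init,
      smooth_kt = config$calcium$smooth$kt, smooth_kd = config$calcium$smooth$kd,
      smooth_tau_r = config$calcium$smooth$tau_r,
      smooth_depth = config$calcium$smooth$depth,
      smooth_z = config$calcium$smooth$z,
      f = config$calcium$smooth$f, s = config$calcium$smooth$s,
      w_threshold = config$calcium$smooth$w_threshold,
      r_threshold = config$calcium$smooth$r_threshold,
      g_fast = config$calcium$smooth$g_fast,
      tau_m_fast = config$calcium$smooth$tau_m_fast,
      g_slow = config$calcium$smooth$g_slow,
      tau_m_slow = config$calcium$smooth$tau_m_slow,
      gsk_off = config$calcium$smooth$gsk_off,
      gsk_on = config$calcium$smooth$gsk_on,
      smooth_ca_init = config$calcium$smooth$ca_init),
    pump = list(density = config$pump$density, tau = config$pump$tau,
                na_floor = config$pump$na_floor, na_init = config$pump$na_init,
                ena_floor = config$pump$ena_floor, na_out = config$pump$na_out),
    synapses = list(
      cf_g = config$synapses$cf$g, cf_tau1 = config$synapses$cf$tau1,
      cf_tau2 = config$synapses$cf$tau2,
      pf_g = config$synapses$pf$g, pf_tau1 = config$synapses$pf$tau1,
      pf_tau2 = config$synapses$pf$tau2,
      cf_comps = as.integer(cf_comps), cf_times = cf_times,
      pf_comps = as.integer(pf_comps), pf_times = pf_times),
    monitor_smooth = if (length(smooth_ids))
      smooth_ids[min(ci$monitor_smooth, length(smooth_ids))] else 0L,
    spike_thresh = ci$spike_threshold,
    dspike_thresh = ci$dend_spike_threshold,
    v_init = ci$v_init)
}

#' Initialise the full simulation state
#'
#' Voltage at the initial value (-65 mV) everywhere, gates at their steady
#' state for that voltage, all Markov occupancy in C1, calcium at the
#' per-zone initial concentrations, w = r = 0, internal sodium at 10 mM,
#' and an unprimed delay buffer (primed quasi-stationarily on first use).
#'
#' @param config configuration list.
#' @param protocol optional protocol (only synapse bookkeeping sizes depend
#'   on it).
#' @param seed integer seed (PF train generation).
#' @return engine state list.
#' @export
init_state <- function(config = default_config(), protocol = NULL, seed = 1) {
  cpp_init_state(build_engine_pars(config, protocol, seed))
}

#' Advance a simulation state
#'
#' Runs the per-step update loop for `n_steps` steps of the configured dt:
#' synaptic conductances, exponential-Euler gates, implicit Markov step,
#' backward-Euler cable solve, then calcium / switch / pump updates.
#'
#' @param state engine state (from [init_state()] or a previous call).
#' @param config,protocol,seed as in [simulate_protocol()].
#' @param n_steps number of steps to take.
#' @param record_stride sampling stride in steps (0 = no recording).
#' @return list with `trace` fields and the final `state`.
#' @export
advance <- function(state, config = default_config(), protocol = NULL,
                    seed = 1, n_steps = 1, record_stride = 0) {
  pars <- build_engine_pars(config, protocol, seed)
  cpp_run(pars, state, n_steps, settle_steps = 0,
          record_stride = record_stride)
}

#' Run a protocol and return a trace
#'
#' Settles the model for `config$integration$settle` ms (no synaptic
#' input, no recording), then runs the protocol window recording sampled
#' voltage (soma, the monitored smooth compartment, the first spiny
#' compartment), the monitored smooth compartment's calcium system
#' (ca, y, w, r, live gsk), internal sodium and pump current, plus
#' full-rate somatic spike times and dendritic Ca-spike times.
#' Deterministic given config, protocol and seed.
#'
#' @param protocol a protocol from [protocol_spec()] or a preset name from
#'   [protocol_presets()].
#' @param config configuration list (protocol overrides are applied).
#' @param seed integer seed for the PF streams.
#' @param record_all_v record voltage for all compartments.
#' @return object of class `purksim_trace`.
#' @export
simulate_protocol <- function(protocol, config = default_config(), seed = 1,
                              record_all_v = FALSE) {
  if (is.character(protocol)) protocol <- protocol_spec(protocol)
  config <- apply_protocol_overrides(config, protocol)
  pars <- build_engine_pars(config, protocol, seed)
  st <- cpp_init_state(pars)
  dt <- config$integration$dt
  settle_steps <- round(config$integration$settle / dt)
  n_steps <- round(protocol$duration / dt)
  out <- cpp_run(pars, st, n_steps, settle_steps = settle_steps,
                 record_stride = config$integration$record_stride,
                 record_all_v = record_all_v)
  sm <- out$smooth
  colnames(sm) <- c("ca", "y", "w", "r", "gsk_live", "na_i", "i_pump")
  vcols <- if (record_all_v) paste0("c", seq_len(ncol(out$v)) - 1L)
           else c("soma", "smooth", "spiny")
  colnames(out$v) <- vcols
  structure(list(
    t = out$t, v = out$v, smooth = sm,
    spikes = out$spikes, dend_spikes = out$dend_spikes,
    cf_events = pars$synapses$cf_times,
    state = out$state,
    clamp_ca = out$clamp_ca, clamp_na = out$clamp_na,
    protocol = protocol, seed = seed,
    dt = dt, stride = config$integration$record_stride),
    class = "purksim_trace")
}

#' @export
print.purksim_trace <- function(x, ...) {
  cat("purksim trace:", x$protocol$name, "\n")
  cat("  duration:", if (length(x$t)) max(x$t) / 1000 else 0, "s,",
      length(x$spikes), "somatic spikes,",
      length(x$dend_spikes), "dendritic Ca spikes\n")
  invisible(x)
}

#' Write a trace as CSV with a JSON sidecar
#'
#' Wide CSV of the sampled channels; the sidecar records protocol, seed and
#' package version for provenance.
#'
#' @param trace a `purksim_trace`.
#' @param path CSV path (the sidecar gets `.json` appended).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(t = trace$t, trace$v, trace$smooth, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(protocol = unclass(trace$protocol), seed = trace$seed,
               dt = trace$dt,
               package_version = as.character(utils::packageVersion("purksim")),
               spikes = trace$spikes, dend_spikes = trace$dend_spikes,
               cf_events = trace$cf_events)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
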