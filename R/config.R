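#' Default model configuration
#'
#' Returns the full parameter set of the 41-compartment Purkinje cell model
#' as a nested list: geometry, passive properties, physical constants,
#' reversal potentials, maximal conductance densities, channel kinetics,
#' the three intracellular calcium systems, the somatic Na+/K+ pump, the
#' climbing-fiber (CF) and parallel-fiber (PF) synapse parameters, and the
#' integration settings.
#'
#' Conductance densities are in mS/cm2 and match the published per-zone
#' table; dendritic values already include the surface-area correction
#' factor \code{C_d}, which is therefore applied only to membrane
#' capacitance (\code{cm_smooth = 0.8 * C_d}, \code{cm_spiny = 1.5 * C_d}
#' uF/cm2). The dendritic compartment geometry is not part of the published
#' description (it descends from an equivalent-cable reduction); it is a
#' calibration surface exposed here with shipped defaults.
#'
#' @param ... named overrides applied on top of the defaults with
#'   \code{modifyList} semantics, e.g. \code{default_config(pump =
#'   list(density = 0.05))}.
#' @return A nested configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    geometry = list(
      soma   = list(length = 22, diam = 22),
      smooth = list(n = 20, length = 20, diam = 1.3),
      spiny  = list(n = 20, length = 10, diam = 0.35)
    ),
    passive = list(
      cm_soma = 0.8,          # uF/cm2
      cd = 3.80,              # dendrite surface-correction factor
      cm_smooth_factor = 0.8, # cm_smooth = factor * cd
      cm_spiny_factor = 1.5,
      ra = 35.4               # Ohm cm
    ),
    constants = list(T = 36, F = 96485.332, Rgas = 8.314462),
    reversals = list(
      ek_soma = -88, ek_dend = -77, ena = 70,
      el_soma = -70, el_dend = -80,
      eh_soma = -30, eh_dend = -32.9, eca_dend = 135
    ),
    densities = list(      # mS/cm2
      soma = c(na_r = 156, ca_p = 0.52, k_fast = 41.6, k_mid = 20.8,
               k_slow = 41.6, bk = 72.8, ih = 1.04, leak = 0.1),
      dend = c(ca_t = 2.28, ca_e = 12.16, ca_p = 6.1, k_a = 121.6,
               k_d = 136.8, k_m = 0.0152, k_dr = 0.912, bk = 228,
               k2 = 0.608, ih = 1.4, leak = 0.38)
    ),
    kinetics = list(k_kd = 0.1),  # D-type inactivation slowing factor
    calcium = list(
      soma   = list(depth = 0.1, beta = 1, floor = 1e-4, ca_init = 5e-5,
                    influx_mode = "area"),
      spiny  = list(kt = 4e-5, kd = 4e-5, tau_r = 2, y = 4e-5,
                    depth = 0.1, ca_init = 4e-5),
      smooth = list(kt = 1e-4, kd = 1e-4, tau_r = 2, depth = 0.1,
                    z = 2.4e-4, f = 100, s = 1000,
                    w_threshold = 0.06,   # mA/cm2, Ca-influx magnitude
                    r_threshold = 3,      # nA, CF synaptic current magnitude
                    g_fast = 1e5, tau_m_fast = 100,
                    g_slow = 1e4, tau_m_slow = 1000,
                    gsk_off = 1e-7, gsk_on = 0.72,  # S/cm2
                    ca_init = 4e-5)
    ),
    pump = list(density = 0.04, tau = 5000, na_floor = 10, na_init = 10,
                ena_floor = 70, na_out = 138.4, diffusion = FALSE),
    synapses = list(
      cf = list(n = 17, g = 1, tau1 = 0.5, tau2 = 1.2, e = 0, freq = 1),
      pf = list(g = 5e-4, tau1 = 0.5, tau2 = 1.2, e = 0, rate = 100)
    ),
    integration = list(dt = 0.025, settle = 2000, record_stride = 40,
                       v_init = -65, monitor_smooth = 10,
                       spike_threshold = -20, dend_spike_threshold = -30)
  )
  ov <- list(...)
  if (length(ov)) cfg <- utils::modifyList(cfg, ov)
  validate_config(cfg)
  cfg
}

#' Validate a model configuration
#'
#' Checks positivity of geometry, capacitance and axial resistivity, and
#' non-negativity of all conductance densities.
#'
#' @param cfg a configuration list as returned by [default_config()].
#' @return `cfg`, invisibly; errors on invalid input.
#' @export
validate_config <- function(cfg) {
  g <- cfg$geometry
  dims <- c(g$soma$length, g$soma$diam, g$smooth$length, g$smooth$diam,
            g$spiny$length, g$spiny$diam)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("configuration error: compartment dimensions must be positive")
  if (g$smooth$n < 1 || g$spiny$n < 1)
    stop("configuration error: need at least one smooth and one spiny compartment")
  if (cfg$passive$ra <= 0) stop("configuration error: ra must be positive")
  if (cfg$passive$cm_soma <= 0 || cfg$passive$cd <= 0)
    stop("configuration error: capacitance parameters must be positive")
  if (any(cfg$densities$soma < 0) || any(cfg$densities$dend < 0))
    stop("configuration error: conductance densities must be non-negative")
  if (cfg$integration$dt <= 0) stop("configuration error: dt must be positive")
  invisible(cfg)
}

#' Read / write a model configuration as YAML
#'
#' The YAML round trip is value-exact for the numeric payload
#' (\code{yaml} preserves doubles at full precision).
#'
#' @param path file path.
#' @param cfg a configuration list.
#' @return `read_config` returns the configuration list; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # yaml drops names on scalar vectors; restore the density name order
  for (zone in names(cfg$densities))
    cfg$densities[[zone]] <- unlist(cfg$densities[[zone]])
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  out <- cfg
  # named vectors serialise as YAML maps (atomic vectors would lose names)
  out$densities <- lapply(cfg$densities, as.list)
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}
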