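# Named experiment protocols: which synaptic inputs are on and which
# model parameters deviate from the defaults (k, g_sk, somatic g_ih,
# pump density).

#' Protocol specification
#'
#' @param name protocol name (free text or a preset name).
#' @param duration protocol window, ms.
#' @param cf list `(on, freq)`: synchronous climbing-fiber input, Hz.
#' @param pf list `(on, rate, seed)`: Poisson parallel-fiber input, Hz.
#' @param overrides named list of parameter overrides; recognised names:
#'   `k` (D-type inactivation factor), `g_sk` (S/cm2, the r-switched SK
#'   conductance), `g_ih_soma` (mS/cm2), `pump_density` (mA/cm2).
#' @return list of class `protocol_spec`.
#' @export
protocol_spec <- function(name, duration = 25000,
                          cf = list(on = FALSE, freq = 1),
                          pf = list(on = FALSE, rate = 100, seed = NULL),
                          overrides = list()) {
  if (length(name) == 1 && name %in% names(.presets) &&
      missing(duration) && missing(cf) && missing(pf) && missing(overrides))
    return(.presets[[name]])
  structure(list(name = name, duration = duration, cf = cf, pf = pf,
                 overrides = overrides), class = "protocol_spec")
}

.mk <- function(name, duration, cf_on = FALSE, cf_freq = 1, pf_on = FALSE,
                pf_rate = 100, ...)
  structure(list(name = name, duration = duration,
                 cf = list(on = cf_on, freq = cf_freq),
                 pf = list(on = pf_on, rate = pf_rate, seed = NULL),
                 overrides = list(...)), class = "protocol_spec")

.presets <- list(
  trimodal      = .mk("trimodal", 25000),
  trimodal_k02  = .mk("trimodal_k02", 25000, k = 0.2),
  pf_only       = .mk("pf_only", 25000, pf_on = TRUE),
  cf_toggle     = .mk("cf_toggle", 40000, cf_on = TRUE, g_sk = 0.72),
  cf_pause      = .mk("cf_pause", 15000, cf_on = TRUE, g_sk = 0.62),
  cf_pf_gain    = .mk("cf_pf_gain", 15000, cf_on = TRUE, pf_on = TRUE,
                      g_sk = 0.62),
  ih_block      = .mk("ih_block", 15000, cf_on = TRUE, g_sk = 0.72,
                      g_ih_soma = 0),
  ih_mask       = .mk("ih_mask", 15000, cf_on = TRUE, g_sk = 0.72,
                      g_ih_soma = 5),
  ih_rescue_085 = .mk("ih_rescue_085", 15000, cf_on = TRUE, g_sk = 0.85,
                      g_ih_soma = 5),
  ih_rescue_088 = .mk("ih_rescue_088", 15000, cf_on = TRUE, g_sk = 0.88,
                      g_ih_soma = 5))

#' Protocol presets
#'
#' The named experiment set: the intrinsic trimodal pattern (default
#' k = 0.1 and the k = 0.2 variant), PF input only, CF toggling
#' (g_sk = 0.72), CF tonic+pause (g_sk = 0.62), CF+PF gain, and the
#' somatic I_h experiments (block g_ih = 0; mask g_ih = 5 mS/cm2; SK
#' rescue at g_sk = 0.85 and 0.88 S/cm2).
#'
#' @return named list of `protocol_spec` objects.
#' @export
protocol_presets <- function() .presets

#' Apply protocol parameter overrides to a configuration
#'
#' @param config configuration list.
#' @param protocol `protocol_spec`.
#' @return modified configuration.
#' @export
apply_protocol_overrides <- function(config, protocol) {
  ov <- protocol$overrides
  if (!is.null(ov$k)) config$kinetics$k_kd <- ov$k
  if (!is.null(ov$g_sk)) config$calcium$smooth$gsk_on <- ov$g_sk
  if (!is.null(ov$g_ih_soma)) config$densities$soma[["ih"]] <- ov$g_ih_soma
  if (!is.null(ov$pump_density)) config$pump$density <- ov$pump_density
  config
}

#' Run a named experiment and summarise it
#'
#' Simulates the preset protocol and produces the measurement report:
#' spike-train summary, mode segmentation, and the headline numbers
#' (pooled tonic rate, trimodal repeat and firing lengths, toggle flip
#' fraction, up/down durations, post-complex-spike pause lengths, pump
#' silences).
#'
#' @param name preset name (see [protocol_presets()]).
#' @param config configuration list.
#' @param seed integer seed.
#' @param duration optional duration override, ms.
#' @return list report (machine-readable; serialise with
#'   `jsonlite::write_json`).
#' @export
run_experiment <- function(name, config = default_config(), seed = 1,
                           duration = NULL) {
  if (!name %in% names(.presets)) stop("unknown preset: ", name)
  proto <- .presets[[name]]
  if (!is.null(duration)) proto$duration <- duration
  tr <- simulate_protocol(proto, config, seed)
  analyze_trace(tr)
}

#' Full analysis of a simulated trace
#'
#' @param tr a `purksim_trace`.
#' @return report list: `summary` (rates and lengths), `segments` (mode
#'   segmentation data frame), `toggle` (toggle statistics when CF input
#'   is present).
#' @export
analyze_trace <- function(tr) {
  window <- c(0, max(tr$t, 0))
  cs <- detect_complex_spikes(tr$spikes, tr$dend_spikes, tr$cf_events)
  seg <- segment_modes(tr$spikes, tr$dend_spikes, window,
                       complex_spikes = cs)
  tf <- tonic_frequency(seg)
  rep_len <- trimodal_repeat_length(seg)
  tog <- if (length(tr$cf_events))
    toggle_statistics(tr$spikes, tr$cf_events) else NULL
  list(
    protocol = tr$protocol$name, seed = tr$seed,
    summary = list(
      n_spikes = length(tr$spikes),
      n_dend_ca_spikes = length(tr$dend_spikes),
      n_complex_spikes = length(cs),
      tonic_rate_hz = tf,
      firing_length_ms = rep_len$firing_length,
      repeat_length_ms = rep_len$repeat_length,
      flip_fraction = if (!is.null(tog)) tog$flip_fraction else NA_real_,
      median_up_ms = if (!is.null(tog)) tog$median_up else NA_real_,
      median_down_ms = if (!is.null(tog)) tog$median_down else NA_real_,
      pump_silences = if (!is.null(tog)) nrow(tog$pump_silences) else
        NA_integer_,
      median_cf_pause_ms = if (length(cs))
        cf_pause_lengths(tr$spikes, cs, median = TRUE) else NA_real_),
    segments = seg, toggle = tog, complex_spikes = cs)
}
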