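# Hodgkin-Huxley channel catalogue: reference (pure-R) implementations of
# every gate law in the model. The compiled engine carries the same
# expressions; the test suite sweeps both and asserts agreement, so a
# transcription slip in either copy is caught.
#
# Conventions:
#  * somatic laws are (inf, tau) pairs with tau printed in seconds
#    (converted to ms here); steady states are Boltzmann sigmoids.
#  * dendritic laws are alpha/beta pairs in 1/ms combined via
#    inf = a/(a+b), tau = 1/((a+b) * mt * rate_scale) with
#    mt = 3^((T-37)/10); rate_scale carries the printed channel-specific
#    update factors (E-type Ca m: 4, h: 10; D-type K m: 10, h: k = 0.1).
#  * Ca-gated laws take the bulk shell [Ca2+] in mM.

.sigm <- function(x) 1 / (1 + exp(x))

# Each entry: function(v, ca, T, k_kd) -> list(inf, tau [ms], rate_scale)
.gate_catalog <- list(
  k_fast.m = function(v, ca, T, k) {
    ts <- ifelse(v < -35, 0.000103 + 0.0149 * exp(0.035 * v),
                 0.000129 + 1 / (exp((v + 100.7) / 12.9) + exp((v - 56) / -23.1)))
    list(inf = .sigm(-(v + 24) / 15.4), tau = 1000 * ts, rate_scale = 1)
  },
  k_fast.h = function(v, ca, T, k) {
    ts <- ifelse(v <= 0, 1.22e-5 + 0.012 * exp(-((v + 56.3) / 49.6)^2),
                 0.0012 + 0.0023 * exp(-0.141 * v))
    list(inf = 0.31 + 0.69 * .sigm((v + 5.8) / 11.2), tau = 1000 * ts,
         rate_scale = 1)
  },
  k_mid.m = function(v, ca, T, k) {
    ts <- ifelse(v < -20,
                 0.000688 + 1 / (exp((v + 64.2) / 6.5) + exp((v - 141.5) / -34.8)),
                 0.00016 + 0.0008 * exp(-0.0267 * v))
    list(inf = .sigm(-(v + 24) / 20.4), tau = 1000 * ts, rate_scale = 1)
  },
  k_slow.m = function(v, ca, T, k) {
    ts <- 0.000796 + 1 / (exp((v + 73.2) / 11.7) + exp((v - 306.7) / -74.2))
    list(inf = .sigm(-(v + 16.5) / 18.4), tau = 1000 * ts, rate_scale = 1)
  },
  ca_p_s.m = function(v, ca, T, k) {
    ts <- ifelse(v <= -50, 0.000264 + 0.128 * exp(0.103 * v),
                 0.000191 + 0.00376 * exp(-((v + 11.9) / 27.8)^2))
    list(inf = .sigm(-(v + 19) / 5.5), tau = 1000 * ts, rate_scale = 1)
  },
  ih_s.m = function(v, ca, T, k) {
    list(inf = .sigm((v + 90.1) / 9.9),
         tau = 1000 * (0.19 + 0.72 * exp(-((v + 81.5) / 11.9)^2)),
         rate_scale = 1)
  },
  bk_s.m = function(v, ca, T, k) {
    ts <- 0.000505 + 1 / (exp((v + 86.4) / 10.1) + exp((v - 33.3) / -10))
    list(inf = .sigm(-(v + 28.9) / 6.2), tau = 1000 * ts, rate_scale = 1)
  },
  bk_s.h = function(v, ca, T, k) {
    ts <- 0.0019 + 1 / (exp((v + 48.5) / 5.2) + exp((v - 54.2) / -12.9))
    list(inf = 0.085 + 0.915 * .sigm((v + 32) / 5.8), tau = 1000 * ts,
         rate_scale = 1)
  },
  bk_s.z = function(v, ca, T, k)
    list(inf = rep(1 / (1 + 0.001 / ca), length(v)),
         tau = rep(1, length(v)), rate_scale = 1),

  ca_t.m = function(v, ca, T, k)
    .ab_law(2.6 / (1 + exp((v + 21) / -8)), 0.18 / (1 + exp((v + 40) / 4)), T, 1),
  ca_t.h = function(v, ca, T, k)
    .ab_law(0.0025 / (1 + exp((v + 40) / 8)), 0.19 / (1 + exp((v + 50) / -10)), T, 1),
  ca_e.m = function(v, ca, T, k)
    .ab_law(2.6 / (1 + exp((v + 7) / -8)), 0.18 / (1 + exp((v + 26) / 4)), T, 4),
  ca_e.h = function(v, ca, T, k)
    .ab_law(0.0025 / (1 + exp((v + 32) / 8)), 0.19 / (1 + exp((v + 42) / -10)), T, 10),
  ca_p_d.m = function(v, ca, T, k)
    .ab_law(8.5 / (1 + exp((v - 8) / -12.5)), 35 / (1 + exp((v + 74) / 14.5)), T, 1),
  ih_d.m = function(v, ca, T, k)
    list(inf = .sigm((v + 84.1) / 10.2),
         tau = 1 / (exp(-17.9 - 0.116 * v) + exp(-1.84 + 0.09 * v)) + 100,
         rate_scale = 1),
  k_a.m = function(v, ca, T, k)
    .ab_law(1.4 / (1 + exp((v + 27) / -12)), 0.49 / (1 + exp((v + 30) / 4)), T, 1),
  k_a.h = function(v, ca, T, k)
    .ab_law(0.00175 / (1 + exp((v + 50) / 8)), 0.49 / (1 + exp((v + 13) / -10)), T, 1),
  k_m.m = function(v, ca, T, k) {
    ft <- 2.3^((T - 36) / 10)
    list(inf = .sigm(-(v + 35) / 10),
         tau = (1000 / ft) / (3.3 * (exp((v + 35) / 40) + exp(-(v + 35) / 20))),
         rate_scale = 1)
  },
  k_d.m = function(v, ca, T, k)
    .ab_law(8.5 / (1 + exp((v + 17) / -12.5)), 35 / (1 + exp((v + 99) / 14.5)), T, 10),
  k_d.h = function(v, ca, T, k)
    .ab_law(0.0015 / (1 + exp((v + 89) / 8)), 0.0055 / (1 + exp((v + 83) / -8)), T, k),
  k_dr.m = function(v, ca, T, k)
    .ab_law(0.1 * vtrap_dr(v), 0.125 * exp(-(v + 65) / 80), T, 1),
  bk_d.m = function(v, ca, T, k)
    .ab_law(rep(7.5, length(v)), 0.11 / exp((v - 35) / 14.9), T, 1, use_mt = FALSE),
  bk_d.z = function(v, ca, T, k)
    list(inf = rep(1 / (1 + (400 / (1000 * ca)) / 1), length(v)),
         tau = rep(10, length(v)), rate_scale = 1),
  k2.m = function(v, ca, T, k)
    .ab_law(rep(25, length(v)), 0.075 / exp((v + 5) / 10), T, 1, use_mt = FALSE),
  k2.z = function(v, ca, T, k)
    list(inf = rep(1 / (1 + (20 / (1000 * ca)) / 1), length(v)),
         tau = rep(10, length(v)), rate_scale = 1),
  sk.m = function(v, ca, T, k) {
    ab <- sk_rates(v, ca, T)
    list(inf = ab$alpha / (ab$alpha + ab$beta),
         tau = 1 / (ab$alpha + ab$beta), rate_scale = 1)
  }
)

.ab_law <- function(a, b, T, rate_scale, use_mt = TRUE) {
  mt <- if (use_mt) 3^((T - 37) / 10) else 1
  list(inf = a / (a + b), tau = 1 / ((a + b) * mt * rate_scale),
       rate_scale = rate_scale)
}

#' Singularity-protected HH rate term of the delayed rectifier
#'
#' \eqn{x/(e^x - 1)}-type activation rate with a first-order series branch
#' taken when the exponent magnitude falls below 1e-6.
#'
#' @param v membrane potential, mV.
#' @return rate term, dimensionless.
#' @export
vtrap_dr <- function(v) {
  x <- -(v + 55) / 10
  ifelse(abs(x) < 1e-6, 10 * (1 - x / 2), -(v + 55) / (exp(x) - 1))
}

#' SK channel opening/closing rates (Moczydlowski-Latorre)
#'
#' Voltage- and calcium-dependent alpha/beta (1/ms) of the small-conductance
#' Ca2+-activated K+ channel. The voltage enters through Boltzmann factors
#' \eqn{\exp(-2 \delta F V / RT)} with the absolute temperature
#' \eqn{R (T + 273.15)}, T in degrees C.
#'
#' @param v membrane potential, mV.
#' @param ca intracellular calcium, mM.
#' @param T temperature, degrees C.
#' @param F,Rgas Faraday and gas constants.
#' @return list with `alpha` and `beta`, 1/ms.
#' @export
sk_rates <- function(v, ca, T = 36, F = 96485.332, Rgas = 8.314462) {
  RT <- Rgas * (T + 273.15)
  list(alpha = 0.48 / (1 + 0.18 * exp(-2 * 0.84 * F * (v * 1e-3) / RT) / ca),
       beta = 0.28 / (1 + ca / (0.011 * exp(-2 * 1 * F * (v * 1e-3) / RT))))
}

#' Gate catalogue
#'
#' One row per Hodgkin-Huxley gate of the model: channel, gate name, zone,
#' exponent in the current product, and the rate-scale factor carried in
#' the update exponent.
#'
#' @return data frame describing every gate law.
#' @export
gate_catalog <- function() {
  data.frame(
    channel = c("k_fast", "k_fast", "k_mid", "k_slow", "ca_p_s", "ih_s",
                "bk_s", "bk_s", "bk_s",
                "ca_t", "ca_t", "ca_e", "ca_e", "ca_p_d", "ih_d",
                "k_a", "k_a", "k_m", "k_d", "k_d", "k_dr",
                "bk_d", "bk_d", "k2", "k2", "sk"),
    gate = c("m", "h", "m", "m", "m", "m", "m", "h", "z",
             "m", "h", "m", "h", "m", "m",
             "m", "h", "m", "m", "h", "m",
             "m", "z", "m", "z", "m"),
    zone = c(rep("soma", 9), rep("dendrite", 16), "smooth"),
    exponent = c(3, 1, 4, 4, 1, 1, 3, 1, 2,
                 1, 1, 1, 1, 1, 1,
                 4, 1, 1, 1, 1, 4,
                 1, 2, 1, 2, 1),
    rate_scale = c(rep(1, 9),
                   1, 1,        # ca_t m, h
                   4, 10,       # ca_e m, h (printed update factors)
                   1, 1,        # ca_p_d, ih_d
                   1, 1, 1,     # k_a m, h; k_m
                   10, 0.1,     # k_d m, h (k = 0.1)
                   1,           # k_dr
                   1, 1, 1, 1,  # bk_d m, z; k2 m, z
                   1),          # sk

    ca_dependent = c(rep(FALSE, 8), TRUE, rep(FALSE, 12),
                     FALSE, TRUE,   # bk_d m, z
                     FALSE, TRUE,   # k2 m, z
                     TRUE),         # sk
    stringsAsFactors = FALSE)
}

#' Steady state and time constant of a gate law
#'
#' Evaluates the voltage (and, for Ca-gated laws, calcium) dependence of a
#' named gate: the steady-state open fraction and the effective time
#' constant in ms (for alpha/beta laws this already folds in the
#' temperature factor and the printed rate-scale factor, so that
#' [gate_update()] with `rate_scale = 1` reproduces the printed update).
#'
#' @param channel,gate names as in [gate_catalog()].
#' @param v membrane potential(s), mV.
#' @param ca shell calcium, mM (used by Ca-gated laws).
#' @param T temperature, degrees C.
#' @param k_kd the D-type K+ inactivation slowing factor (default 0.1).
#' @return list with vectors `inf` and `tau` (ms).
#' @export
gate_steady_and_tau <- function(channel, gate = "m", v, ca = 1e-4, T = 36,
                                k_kd = 0.1) {
  key <- paste(channel, gate, sep = ".")
  fn <- .gate_catalog[[key]]
  if (is.null(fn)) stop("unknown channel/gate: ", key)
  if (any(!is.finite(v))) stop("v must be finite")
  out <- fn(v, ca, T, k_kd)
  list(inf = out$inf, tau = out$tau)
}

#' Exponential-Euler gate update
#'
#' Advances a first-order gate exactly for frozen rates over one step:
#' \deqn{x' = x + (x_\infty - x)(1 - e^{-dt \cdot s/\tau})}
#' where `s` is an optional extra rate scale. The update is monotone toward
#' `inf` and contractive for any positive `dt`.
#'
#' @param state current gate value in `[0, 1]`.
#' @param inf steady-state target.
#' @param tau time constant, ms.
#' @param dt step, ms.
#' @param rate_scale extra dimensionless rate multiplier (default 1).
#' @return updated gate value.
#' @export
gate_update <- function(state, inf, tau, dt, rate_scale = 1) {
  stopifnot(dt > 0)
  state + (inf - state) * (1 - exp(-dt * rate_scale / tau))
}

#' GHK flux of the somatic P-type calcium current
#'
#' Goldman-Hodgkin-Katz current density for Ca2+ with the fixed constants
#' the somatic P-type current sees: permeability 5e-5 cm/s,
#' internal 100 nM, external 2 mM, T = 295 K. The changing shell calcium is
#' deliberately not read by this expression. The v -> 0 singularity is
#' removed with the usual expm1 limit form.
#'
#' @param v membrane potential, mV (vectorised).
#' @return current density, mA/cm2 (negative = inward).
#' @export
ghk_flux <- function(v) {
  F <- 96485.332; Rg <- 8.314462; Tk <- 295
  P <- 5e-5; ci <- 1e-10; co <- 2e-6; z <- 2
  u <- z * F * (v * 1e-3) / (Rg * Tk)
  ratio <- ifelse(abs(u) < 1e-9, 1, u / (-expm1(-u)))
  1000 * P * z * F * ratio * (ci - co * exp(-u))
}

#' Ionic current of a channel from its gates
#'
#' Ohmic currents return \eqn{g_{max} \prod x_i^{e_i} (v - E)} in mA/cm2
#' with `gmax` in S/cm2; the somatic P-type Ca current instead returns
#' \eqn{g_{max,raw} \cdot m \cdot \Phi_{GHK}(v)} where `gmax_raw` is the
#' printed table value and the GHK flux uses its fixed concentrations.
#'
#' @param channel channel name as in [gate_catalog()].
#' @param gates named numeric vector of gate values (e.g. `c(m = .2, h = .9)`).
#' @param v membrane potential, mV.
#' @param gmax maximal conductance, mS/cm2 (table units).
#' @param reversal reversal potential, mV (ignored by the GHK branch).
#' @return current density, mA/cm2.
#' @export
channel_current <- function(channel, gates, v, gmax, reversal = NULL) {
  cat_ <- gate_catalog()
  rows <- cat_[cat_$channel == channel, , drop = FALSE]
  if (nrow(rows) == 0) stop("unknown channel: ", channel)
  if (channel == "ca_p_s")
    return(gmax * gates[["m"]] * ghk_flux(v))
  prod_g <- 1
  for (i in seq_len(nrow(rows)))
    prod_g <- prod_g * gates[[rows$gate[i]]]^rows$exponent[i]
  (gmax / 1000) * prod_g * (v - reversal)
}
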