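# Climbing-fiber and parallel-fiber inputs: event trains plus the
# dual-exponential conductance synapse. A single event is normalised to
# peak at exactly g_syn (the Exp2Syn convention), which makes the printed
# 1 uS (CF) and 0.0005 uS (PF) magnitudes meaningful.

#' Synapse specification
#'
#' @param target_compartment 0-based compartment id.
#' @param g_syn peak conductance of one event, uS.
#' @param e_rev reversal potential, mV.
#' @param tau1,tau2 rise and decay time constants, ms (tau2 > tau1 > 0).
#' @return list of class `synapse_spec`.
#' @export
synapse_spec <- function(target_compartment, g_syn, e_rev = 0,
                         tau1 = 0.5, tau2 = 1.2) {
  stopifnot(tau1 > 0, tau2 > tau1, g_syn > 0)
  structure(list(target_compartment = target_compartment, g_syn = g_syn,
                 e_rev = e_rev, tau1 = tau1, tau2 = tau2),
            class = "synapse_spec")
}

#' Peak time and normalisation of the dual-exponential conductance
#'
#' A lone event's conductance \eqn{e^{-t/\tau_2} - e^{-t/\tau_1}} peaks at
#' \eqn{t_p = \tau_1\tau_2/(\tau_2-\tau_1)\,\ln(\tau_2/\tau_1)} (about
#' 0.750 ms for 0.5/1.2 ms); the normalisation factor scales that peak to 1.
#'
#' @param tau1,tau2 time constants, ms.
#' @return list with `t_peak` (ms) and `norm`.
#' @export
dual_exp_peak <- function(tau1 = 0.5, tau2 = 1.2) {
  tp <- tau1 * tau2 / (tau2 - tau1) * log(tau2 / tau1)
  list(t_peak = tp, norm = 1 / (exp(-tp / tau2) - exp(-tp / tau1)))
}

#' Synchronous climbing-fiber trains
#'
#' 17 identical periodic event trains (one per contacted proximal smooth
#' compartment), each with peak conductance 1 uS. All trains share the
#' same event times (the CF fires synchronously at all contacts).
#'
#' @param freq firing frequency, Hz.
#' @param t_start,t_end window, ms; the first event is at `t_start`.
#' @param n_contacts number of contacts (default 17).
#' @param smooth_ids available smooth compartment ids, most proximal first.
#' @param g_syn peak conductance, uS.
#' @return list of event trains; each has `compartment`, `times` (ms),
#'   `source = "CF"`, and the synapse spec.
#' @export
make_cf_trains <- function(freq, t_start = 0, t_end, n_contacts = 17,
                           smooth_ids = 1:20, g_syn = 1) {
  stopifnot(freq > 0)
  if (length(smooth_ids) < n_contacts)
    stop("configuration error: fewer smooth compartments (",
         length(smooth_ids), ") than CF contacts (", n_contacts, ")")
  times <- seq(t_start, t_end, by = 1000 / freq)
  times <- times[times < t_end]
  lapply(smooth_ids[seq_len(n_contacts)], function(id)
    list(compartment = id, times = times, source = "CF",
         spec = synapse_spec(id, g_syn)))
}

#' Asynchronous Poisson parallel-fiber trains
#'
#' One homogeneous Poisson train per spiny compartment, mean rate `rate`,
#' each with peak conductance 0.0005 uS. Per-synapse streams are derived
#' from the master seed so trains are independent yet reproducible.
#'
#' @param rate mean firing rate, Hz (0 gives empty trains).
#' @param t_end window length, ms.
#' @param seed master integer seed.
#' @param spiny_ids spiny compartment ids.
#' @param g_syn peak conductance, uS.
#' @return list of event trains as in [make_cf_trains()], `source = "PF"`.
#' @export
make_pf_trains <- function(rate, t_end, seed, spiny_ids = 21:40,
                           g_syn = 5e-4) {
  stopifnot(rate >= 0)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  lapply(seq_along(spiny_ids), function(k) {
    set.seed((seed * 1009L + k) %% .Machine$integer.max)
    times <- if (rate == 0) numeric(0) else {
      n_exp <- rate * t_end / 1000
      gaps <- stats::rexp(ceiling(n_exp + 6 * sqrt(n_exp) + 25), rate / 1000)
      tt <- cumsum(gaps)
      while (sum(tt) < t_end && tt[length(tt)] < t_end) {  # top up if short
        gaps <- stats::rexp(50, rate / 1000)
        tt <- c(tt, tt[length(tt)] + cumsum(gaps))
      }
      tt[tt < t_end]
    }
    list(compartment = spiny_ids[k], times = times, source = "PF",
         spec = synapse_spec(spiny_ids[k], g_syn))
  })
}

#' Dual-exponential synaptic conductance and current
#'
#' Sums the peak-normalised dual-exponential kernels of all past events:
#' \deqn{g(t) = g_{syn} \cdot N \sum_{t_e \le t}
#'       (e^{-(t-t_e)/\tau_2} - e^{-(t-t_e)/\tau_1})}
#' and returns both the conductance and the current
#' \eqn{i = g (v - e_{rev})} (uS * mV = nA), so the CF r-switch can read
#' the current directly.
#'
#' @param spec a [synapse_spec()].
#' @param events event time vector, ms (or a train list with `$times`).
#' @param t evaluation time(s), ms.
#' @param v membrane potential at the target, mV.
#' @return list with `g` (uS) and `i` (nA), vectorised over `t`.
#' @export
synaptic_current <- function(spec, events, t, v) {
  if (is.list(events)) events <- events$times
  pk <- dual_exp_peak(spec$tau1, spec$tau2)
  g <- vapply(t, function(tt) {
    el <- events[events <= tt]
    if (!length(el)) return(0)
    dt <- tt - el
    spec$g_syn * pk$norm * sum(exp(-dt / spec$tau2) - exp(-dt / spec$tau1))
  }, numeric(1))
  list(g = g, i = g * (v - spec$e_rev))
}

#' Export / import event trains as two-column text
#'
#' Plain text replay format: synapse (compartment) id and event time in ms.
#'
#' @param trains list of event trains.
#' @param path file path.
#' @return `read_event_trains` returns a data frame (id, time_ms).
#' @export
write_event_trains <- function(trains, path) {
  df <- do.call(rbind, lapply(trains, function(tr)
    if (length(tr$times)) data.frame(id = tr$compartment, time_ms = tr$times)))
  if (is.null(df)) df <- data.frame(id = integer(0), time_ms = numeric(0))
  utils::write.table(df, path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_event_trains
#' @export
read_event_trains <- function(path)
  utils::read.table(path, header = TRUE, sep = "\t")
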