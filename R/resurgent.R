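# 13-state Markov model of the somatic resurgent Na+ current.
#
# States: C1..C5 (sequential closed), O (open), OB (open-channel block),
# I1..I6 (inactivated). The activation chain carries statistical factors
# {4a, 3a, 2a, a, gamma} forward and {b, 2b, 3b, 4b, delta} backward; the
# closed<->inactivated rungs use Con*a^(i-1) / Coff*b^(i-1); the
# inactivated chain mirrors the closed chain scaled by a (forward) and
# b (backward); O pairs with OB (epsilon/zeta) and I6 (Oon/Ooff).

.markov_states <- c("C1", "C2", "C3", "C4", "C5", "O", "OB",
                    "I1", "I2", "I3", "I4", "I5", "I6")

#' Voltage-dependent rate constants of the resurgent Na+ scheme
#'
#' alpha = 150 exp(v/20), beta = 3 exp(-v/20), zeta = 0.03 exp(-v/25)
#' (1/ms); gamma = 150, delta = 40, epsilon = 1.75, Con = 0.005,
#' Coff = 0.5, Oon = 0.75, Ooff = 0.005. The chain-scaling factors are
#' a = (Oon/Con)^(1/4) and b = (Ooff/Coff)^(1/4).
#'
#' @param v membrane potential, mV.
#' @return named list of rates (1/ms) and factors.
#' @export
markov_rates <- function(v) {
  list(alpha = 150 * exp(v / 20), beta = 3 * exp(-v / 20),
       gamma = 150, delta = 40, epsilon = 1.75, zeta = 0.03 * exp(-v / 25),
       Con = 0.005, Coff = 0.5, Oon = 0.75, Ooff = 0.005,
       a = (0.75 / 0.005)^(1 / 4), b = (0.005 / 0.5)^(1 / 4))
}

#' Edge list of the resurgent Na+ Markov scheme
#'
#' The scheme's connectivity as data (auditable against the published
#' state diagram): one row per directed transition with a symbolic rate
#' expression in terms of the rate constants of [markov_rates()].
#'
#' @return data frame with columns `from`, `to`, `rate` (expression text).
#' @export
markov_edges <- function() {
  e <- rbind(
    c("C1", "C2", "4*alpha"), c("C2", "C1", "beta"),
    c("C2", "C3", "3*alpha"), c("C3", "C2", "2*beta"),
    c("C3", "C4", "2*alpha"), c("C4", "C3", "3*beta"),
    c("C4", "C5", "alpha"),   c("C5", "C4", "4*beta"),
    c("C5", "O", "gamma"),    c("O", "C5", "delta"),
    c("O", "OB", "epsilon"),  c("OB", "O", "zeta"),
    c("O", "I6", "Oon"),      c("I6", "O", "Ooff"),
    c("C1", "I1", "Con"),           c("I1", "C1", "Coff"),
    c("C2", "I2", "Con*a"),         c("I2", "C2", "Coff*b"),
    c("C3", "I3", "Con*a^2"),       c("I3", "C3", "Coff*b^2"),
    c("C4", "I4", "Con*a^3"),       c("I4", "C4", "Coff*b^3"),
    c("C5", "I5", "Con*a^4"),       c("I5", "C5", "Coff*b^4"),
    c("I1", "I2", "4*alpha*a"), c("I2", "I1", "beta*b"),
    c("I2", "I3", "3*alpha*a"), c("I3", "I2", "2*beta*b"),
    c("I3", "I4", "2*alpha*a"), c("I4", "I3", "3*beta*b"),
    c("I4", "I5", "alpha*a"),   c("I5", "I4", "4*beta*b"),
    c("I5", "I6", "gamma*a"),   c("I6", "I5", "delta*b"))
  data.frame(from = e[, 1], to = e[, 2], rate = e[, 3],
             stringsAsFactors = FALSE)
}

#' Transition-rate generator of the resurgent Na+ channel
#'
#' Builds the 13 x 13 generator matrix Q at a fixed voltage from the edge
#' list: Q[i, j] is the rate from state i to state j (1/ms), the diagonal
#' the negative row sum, so occupancy evolves as dp/dt = t(Q) p.
#'
#' @param v membrane potential, mV.
#' @return 13 x 13 matrix with state dimnames.
#' @export
build_transition_matrix <- function(v) {
  stopifnot(is.finite(v))
  rates <- markov_rates(v)
  ed <- markov_edges()
  Q <- matrix(0, 13, 13, dimnames = list(.markov_states, .markov_states))
  for (k in seq_len(nrow(ed)))
    Q[ed$from[k], ed$to[k]] <- eval(parse(text = ed$rate[k]), rates)
  diag(Q) <- -rowSums(Q)
  Q
}

#' Advance the Markov occupancy by one implicit step
#'
#' Backward-Euler solve of dp/dt = t(Q) p at fixed voltage: solves
#' (I - dt t(Q)) p' = p. The solve conserves total occupancy to round-off
#' (column sums of the system matrix are 1) and preserves non-negativity
#' (M-matrix structure).
#'
#' @param occ occupancy vector over the 13 states (sums to 1).
#' @param v membrane potential, mV.
#' @param dt step, ms (0 returns `occ` unchanged).
#' @return updated occupancy vector.
#' @export
step_occupancy <- function(occ, v, dt) {
  stopifnot(length(occ) == 13)
  if (dt == 0) return(occ)
  Q <- build_transition_matrix(v)
  as.numeric(solve(diag(13) - dt * t(Q), occ))
}

#' Stationary occupancy at fixed voltage
#'
#' Null-space equilibrium of the generator, computed by eigen decomposition
#' of t(Q); used as the independent oracle for long implicit relaxations.
#'
#' @param v membrane potential, mV.
#' @return equilibrium occupancy vector (sums to 1).
#' @export
markov_equilibrium <- function(v) {
  A <- t(build_transition_matrix(v))
  e <- eigen(A)
  k <- which.min(abs(e$values))
  p <- Re(e$vectors[, k])
  p / sum(p)
}

#' Resurgent Na+ current
#'
#' \eqn{I = g_{max} \cdot O \cdot (v - E_{Na})} with `gmax` in mS/cm2
#' (156 at the soma by default) and O the open-state occupancy.
#'
#' @param occ occupancy vector (O is state 6) or a scalar open fraction.
#' @param v membrane potential, mV.
#' @param e_na sodium reversal potential, mV.
#' @param gmax maximal conductance, mS/cm2.
#' @return current density, mA/cm2.
#' @export
resurgent_current <- function(occ, v, e_na = 70, gmax = 156) {
  o <- if (length(occ) == 13) occ[6] else occ
  (gmax / 1000) * o * (v - e_na)
}
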