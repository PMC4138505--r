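#' Build the 41-compartment cable topology
#'
#' Constructs the unbranched chain soma -> 20 smooth -> 20 spiny used by the
#' model: the soma is a 22 x 22 um cylinder; dendritic compartments take
#' their (configurable) lengths and diameters from the configuration.
#' Membrane area is the open-cylinder lateral area pi * d * L (end caps
#' ignored, the NEURON convention). Membrane capacitance is 0.8 uF/cm2 at
#' the soma and \code{0.8 * C_d} / \code{1.5 * C_d} uF/cm2 for smooth and
#' spiny compartments.
#'
#' @param config configuration list from [default_config()].
#' @return A list of class `cable_topology` with elements
#'   \describe{
#'     \item{compartments}{data frame: id (0-based, soma = 0), zone,
#'       length and diam (um), area (cm2), cm (uF/cm2)}
#'     \item{edges}{data frame of adjacent compartment id pairs (a, b) with
#'       the axial resistance r_mohm between their centres}
#'     \item{ra}{specific axial resistivity, Ohm cm}
#'   }
#' @export
build_default_topology <- function(config = default_config()) {
  validate_config(config)
  g <- config$geometry; p <- config$passive
  n_sm <- g$smooth$n; n_sp <- g$spiny$n
  zone <- c("soma", rep("smooth", n_sm), rep("spiny", n_sp))
  # scalar = uniform segments; vectors allow tapered dendrites
  len <- c(g$soma$length, rep(g$smooth$length, length.out = n_sm),
           rep(g$spiny$length, length.out = n_sp))
  diam <- c(g$soma$diam, rep(g$smooth$diam, length.out = n_sm),
            rep(g$spiny$diam, length.out = n_sp))
  cm <- c(p$cm_soma, rep(p$cm_smooth_factor * p$cd, n_sm),
          rep(p$cm_spiny_factor * p$cd, n_sp))
  n <- length(zone)
  comp <- data.frame(
    id = seq_len(n) - 1L, zone = zone, length = len, diam = diam,
    area = pi * diam * len * 1e-8,   # um2 -> cm2
    cm = cm, stringsAsFactors = FALSE)
  edges <- data.frame(a = 0:(n - 2), b = 1:(n - 1))
  edges$r_mohm <- vapply(seq_len(nrow(edges)), function(k) {
    i <- edges$a[k] + 1L; j <- edges$b[k] + 1L
    axial_resistance(comp[i, ], comp[j, ], p$ra)
  }, numeric(1))
  structure(list(compartments = comp, edges = edges, ra = p$ra),
            class = "cable_topology")
}

#' Axial resistance between two adjacent compartments
#'
#' Series resistance of the two half-cylinders between compartment centres:
#' \deqn{R = Ra \cdot (L_a/2)/(\pi r_a^2) + Ra \cdot (L_b/2)/(\pi r_b^2)}
#' with lengths and radii in um and Ra in Ohm cm; the result is in MOhm.
#'
#' @param a,b compartment rows (lists with `length` and `diam` in um).
#' @param ra specific axial resistivity, Ohm cm.
#' @return Axial resistance in MOhm.
#' @export
axial_resistance <- function(a, b, ra = 35.4) {
  if (a$diam <= 0 || b$diam <= 0)
    stop("configuration error: zero compartment radius")
  half <- function(L_um, d_um) {
    r_cm <- d_um / 2 * 1e-4
    ra * (L_um / 2 * 1e-4) / (pi * r_cm^2)   # Ohm
  }
  (half(a$length, a$diam) + half(b$length, b$diam)) * 1e-6
}

#' Axial transfer current density
#'
#' Current entering compartment `a` from its neighbour `b`,
#' \eqn{(v_b - v_a)/r_{ab}} in nA, normalised by the membrane area of `a`
#' to a density in mA/cm2. Antisymmetric with the current entering `b` up
#' to the area normalisation, so total charge is conserved across the edge.
#'
#' @param v_a,v_b membrane potentials, mV.
#' @param r_ab axial resistance, MOhm.
#' @param area_a membrane area of the receiving compartment, cm2.
#' @return Signed current density entering `a`, mA/cm2.
#' @export
transfer_current <- function(v_a, v_b, r_ab, area_a) {
  if (any(r_ab <= 0)) stop("configuration error: axial resistance must be positive")
  i_na <- (v_b - v_a) / r_ab          # mV / MOhm = nA
  i_na * 1e-6 / area_a                # mA/cm2
}

#' Per-zone maximal conductance table
#'
#' The default channel density table of the model (mS/cm2), one row per
#' current, columns soma / smooth / spiny. Smooth and spiny zones share the
#' dendritic density set except that SK is present only in smooth
#' compartments (its live conductance is switch-controlled, see
#' [step_smooth_ca()]).
#'
#' @param config configuration list.
#' @return data frame of densities by zone.
#' @export
density_table <- function(config = default_config()) {
  s <- config$densities$soma; d <- config$densities$dend
  data.frame(
    current = c("na_r", "ca_p", "ca_t", "ca_e", "k_fast", "k_mid", "k_slow",
                "k_a", "k_d", "k_m", "k_dr", "bk", "k2", "ih", "leak"),
    soma = c(s[["na_r"]], s[["ca_p"]], 0, 0, s[["k_fast"]], s[["k_mid"]],
             s[["k_slow"]], 0, 0, 0, 0, s[["bk"]], 0, s[["ih"]], s[["leak"]]),
    smooth = c(0, d[["ca_p"]], d[["ca_t"]], d[["ca_e"]], 0, 0, 0,
               d[["k_a"]], d[["k_d"]], d[["k_m"]], d[["k_dr"]], d[["bk"]],
               d[["k2"]], d[["ih"]], d[["leak"]]),
    spiny = c(0, d[["ca_p"]], d[["ca_t"]], d[["ca_e"]], 0, 0, 0,
              d[["k_a"]], d[["k_d"]], d[["k_m"]], d[["k_dr"]], d[["bk"]],
              d[["k2"]], d[["ih"]], d[["leak"]]),
    stringsAsFactors = FALSE)
}
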