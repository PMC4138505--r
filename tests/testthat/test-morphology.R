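test_that("default cable has 41 compartments in a 40-edge chain with the printed zones", {
  topo <- build_default_topology()
  comp <- topo$compartments
  expect_equal(nrow(comp), 41)
  expect_equal(nrow(topo$edges), 40)
  expect_equal(sum(comp$zone == "soma"), 1)
  expect_equal(sum(comp$zone == "smooth"), 20)
  expect_equal(sum(comp$zone == "spiny"), 20)
  expect_equal(comp$id[comp$zone == "soma"], 0)            # soma at index 0
  expect_true(all(which(comp$zone == "smooth") <
                  which(comp$zone == "spiny")))            # smooth proximal
  expect_equal(comp$length[1], 22)
  expect_equal(comp$diam[1], 22)
  expect_equal(comp$cm[1], 0.8)
  expect_equal(unique(comp$cm[comp$zone == "smooth"]), 0.8 * 3.8)
  expect_equal(unique(comp$cm[comp$zone == "spiny"]), 1.5 * 3.8)
  expect_equal(topo$ra, 35.4)
  # membrane area is the lateral cylinder area
  expect_equal(comp$area[1], pi * 22 * 22 * 1e-8)
})

test_that("reduced builds and invalid geometry behave as specified", {
  topo <- build_default_topology(tiny_config())
  expect_equal(nrow(topo$compartments), 3)
  expect_equal(nrow(topo$edges), 2)
  expect_error(default_config(geometry = list(smooth = list(diam = -1))),
               "configuration error")
  expect_error(axial_resistance(list(length = 10, diam = 0),
                                list(length = 10, diam = 1)),
               "configuration error")
})

test_that("per-zone density table matches the published maximal conductances", {
  dt <- density_table()
  get <- function(cur, zone) dt[dt$current == cur, zone]
  expect_equal(get("na_r", "soma"), 156)
  expect_equal(get("na_r", "smooth"), 0)
  expect_equal(get("ca_p", "soma"), 0.52)
  expect_equal(get("ca_p", "smooth"), 6.1)
  expect_equal(get("ca_t", "soma"), 0)     # no T/E-type Ca at the soma
  expect_equal(get("ca_t", "spiny"), 2.28)
  expect_equal(get("ca_e", "soma"), 0)
  expect_equal(get("ca_e", "smooth"), 12.16)
  expect_equal(get("k_fast", "soma"), 41.6)
  expect_equal(get("k_mid", "soma"), 20.8)
  expect_equal(get("k_slow", "soma"), 41.6)
  expect_equal(get("k_a", "smooth"), 121.6)
  expect_equal(get("k_d", "smooth"), 136.8)
  expect_equal(get("k_m", "smooth"), 0.0152)
  expect_equal(get("k_dr", "smooth"), 0.912)
  expect_equal(get("bk", "soma"), 72.8)
  expect_equal(get("bk", "smooth"), 228)
  expect_equal(get("k2", "smooth"), 0.608)
  expect_equal(get("ih", "soma"), 1.04)
  expect_equal(get("ih", "smooth"), 1.4)
  expect_equal(get("leak", "soma"), 0.1)
  expect_equal(get("leak", "spiny"), 0.38)
  expect_identical(dt$smooth, dt$spiny)    # zones share the dendritic set
})

test_that("axial resistance follows the two-half-cylinder formula", {
  soma <- list(length = 22, diam = 22)
  # hand unit conversion: 35.4 Ohm cm * 22 um / (pi * (11 um)^2), in MOhm
  hand <- 35.4 * (22e-4) / (pi * (11e-4)^2) * 1e-6
  expect_equal(axial_resistance(soma, soma, 35.4), hand, tolerance = 1e-12)
  # symmetry: two identical cylinders L, r give ra*L/(pi r^2)
  cyl <- list(length = 10, diam = 4)
  r1 <- axial_resistance(cyl, cyl, 35.4)
  expect_equal(r1, 35.4 * 10e-4 / (pi * (2e-4)^2) * 1e-6)
  # doubling both lengths doubles R
  cyl2 <- list(length = 20, diam = 4)
  expect_equal(axial_resistance(cyl2, cyl2, 35.4), 2 * r1)
})

test_that("transfer current is a unit-correct, charge-conserving density", {
  expect_equal(transfer_current(-60, -60, 5, 1e-5), 0)
  # 10 mV across 10 MOhm = 1 nA into a known area
  area <- 1521e-8
  expect_equal(transfer_current(-70, -60, 10, area), 1e-6 / area)
  # Kirchhoff: absolute charge conserved across each edge of the cable
  topo <- build_default_topology()
  comp <- topo$compartments
  set.seed(42)
  v <- runif(41, -80, 0)
  for (k in sample(nrow(topo$edges), 10)) {
    a <- topo$edges$a[k] + 1; b <- topo$edges$b[k] + 1
    r <- topo$edges$r_mohm[k]
    ia <- transfer_current(v[a], v[b], r, comp$area[a]) * comp$area[a]
    ib <- transfer_current(v[b], v[a], r, comp$area[b]) * comp$area[b]
    expect_equal(ia + ib, 0, tolerance = 1e-15)
  }
})

test_that("config round-trips through YAML value-exactly", {
  cfg <- default_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$densities$soma, cfg$densities$soma)
  expect_equal(cfg2$geometry, cfg$geometry, ignore_attr = TRUE)
  expect_equal(cfg2$calcium$smooth$z, cfg$calcium$smooth$z)
  expect_equal(cfg2$pump$density, cfg$pump$density)
})
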