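# Synthetic spike-train fixtures for the measurement layer.

synth_trace <- function(spike_times, t_end = 1000, dt = 0.1, base = -65,
                        peak = 40) {
  t <- seq(0, t_end, by = dt)
  v <- rep(base, length(t))
  for (s in spike_times) {
    w <- which(abs(t - s) <= 0.5)
    v[w] <- base + (peak - base) * exp(-((t[w] - s) / 0.2)^2)
  }
  list(t = t, v = matrix(v, ncol = 1, dimnames = list(NULL, "soma")))
}

test_that("spike detection: threshold crossings, peak alignment, refractory", {
  flat <- synth_trace(numeric(0))
  expect_length(detect_spikes(flat), 0)
  set.seed(11)
  times <- sort(runif(100, 5, 995))
  times <- times[c(TRUE, diff(times) > 5)]
  tr <- synth_trace(times)
  det <- detect_spikes(tr)
  expect_length(det, length(times))
  expect_lt(max(abs(det - times)), 0.1)
  # subthreshold oscillation peaking at -30 mV is ignored
  sub <- synth_trace(c(200, 400), peak = -30)
  expect_length(detect_spikes(sub), 0)
})

test_that("complex-spike detection requires CF gating and a dendritic Ca spike", {
  spikes <- c(seq(100, 900, by = 10), 1001, 1004)
  dend <- c(1002)
  expect_length(detect_complex_spikes(spikes, dend, numeric(0)), 0)  # no CF
  cs <- detect_complex_spikes(spikes, dend, cf_events = 1000)
  expect_equal(cs, 1001)
  # bursts without a CF event are excluded even with Ca spikes
  cs2 <- detect_complex_spikes(spikes, c(500), cf_events = 1000)
  expect_length(cs2, 0)          # Ca spike not coincident with the CF event
})

test_that("mode segmentation labels a constructed tonic/burst/quiescent train", {
  # 5 s tonic at 100 Hz, 3 s of bursting with Ca spikes, 10 s silence
  tonic <- seq(0, 4990, by = 10)
  burst <- as.vector(outer(c(0, 5, 10), seq(5000, 7800, by = 400), "+"))
  ca <- seq(5000, 7800, by = 400)
  spikes <- sort(c(tonic, burst))
  seg <- segment_modes(spikes, ca, c(0, 18000))
  expect_equal(seg$label, c("tonic", "burst", "quiescent"))
  expect_equal(seg$start[1], 0)
  expect_equal(seg$end[3], 18000)
  # boundaries within one inter-event bin of the construction
  expect_equal(seg$end[1], 5000, tolerance = 0.1)   # relative: +-500 ms
  expect_equal(seg$start[3], 7810, tolerance = 0.1)
  # a pure periodic train with no Ca spikes is a single tonic interval
  seg2 <- segment_modes(seq(0, 9990, 10), numeric(0), c(0, 10000))
  expect_equal(seg2$label, "tonic")
  expect_equal(seg2$n_spikes, 1000)
})

test_that("segmentation is idempotent under 1 ms time-origin shifts", {
  tonic <- seq(0, 4990, by = 10)
  ca <- seq(5000, 7800, by = 400)
  burst <- as.vector(outer(c(0, 5, 10), ca, "+"))
  spikes <- sort(c(tonic, burst))
  s0 <- segment_modes(spikes, ca, c(0, 18000))
  s1 <- segment_modes(spikes + 1, ca + 1, c(1, 18001))
  expect_equal(s1$label, s0$label)
  expect_equal(s1$start - 1, s0$start, tolerance = 1e-9)
  expect_equal(s1$n_spikes, s0$n_spikes)
})

test_that("tonic frequency pools spike counts over tonic time", {
  seg <- data.frame(start = c(0, 1000, 2000), end = c(1000, 2000, 3000),
                    label = c("tonic", "quiescent", "tonic"),
                    n_spikes = c(90, 0, 110))
  expect_equal(tonic_frequency(seg), 100)           # weighted pooling
  seg1 <- data.frame(start = 0, end = 1000, label = "tonic", n_spikes = 100)
  expect_equal(tonic_frequency(seg1), 100)
  expect_warning(v <- tonic_frequency(seg[2, ]), "no tonic")
  expect_true(is.na(v))
})

test_that("toggle statistics: strict alternation, continuous firing, pump silences", {
  cf <- seq(0, 20000, by = 1000)
  # strict alternation: firing only in even intervals
  up_iv <- seq(1, 20, by = 2)
  spikes <- sort(unlist(lapply(up_iv, function(k)
    seq(cf[k] + 150, cf[k + 1] - 10, by = 10))))
  tog <- toggle_statistics(spikes, cf)
  expect_equal(tog$flip_fraction, 1.0)
  expect_equal(tog$median_up, 1000)
  expect_equal(tog$median_down, 1000)
  expect_equal(nrow(tog$pump_silences), 0)
  # continuous firing with only short pauses: no down states at all
  allup <- seq(100, 19900, by = 10)
  tog2 <- toggle_statistics(allup, cf)
  expect_equal(tog2$flip_fraction, 0)
  expect_length(tog2$down_durations, 0)
  # one 12 s silence among alternations is flagged exactly once
  cf3 <- seq(0, 30000, by = 1000)
  firing <- c(seq(150, 7990, by = 10), seq(20150, 29990, by = 10))
  # alternation outside the silence:
  firing <- firing[!(firing > 1000 & firing < 2000) &
                   !(firing > 3000 & firing < 4000) &
                   !(firing > 21000 & firing < 22000)]
  tog3 <- toggle_statistics(firing, cf3)
  expect_equal(nrow(tog3$pump_silences), 1)
  expect_equal(tog3$pump_silences$duration, 12000)
})

test_that("post-complex-spike pauses are measured from the last spikelet", {
  spikes <- c(seq(0, 990, 10), 1001, 1003, 1025, seq(1035, 2000, 10))
  cs <- 1001
  expect_equal(cf_pause_lengths(spikes, cs), 22)      # 1025 - 1003
  expect_equal(cf_pause_lengths(spikes, cs, median = FALSE), 22)
})
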