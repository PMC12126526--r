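# Transient detection, the dS/dt fluorescence-rate statistic and the
# weight-sensitivity classification.

test_that("flat and all-zero traces yield no transients", {
  expect_warning(out <- detect_transients(rep(0, 100), 10), "flat trace")
  expect_equal(nrow(out), 0)
})

test_that("a rectangular pulse is measured as its geometry", {
  # height 0.8 for 2 s on a zero baseline; dense sampling so the
  # interpolated crossings pin the edges to within one frame
  fx <- rect_pulse_trace(h = 0.8, dur_s = 2, fps = 100)
  out <- detect_transients(fx$trace, fx$fps, min_duration_s = 0.5)
  expect_equal(nrow(out), 1)
  expect_equal(out$area, 1.6, tolerance = 2 / fx$fps)
  expect_equal(out$duration, 2, tolerance = 2 / fx$fps)
  expect_equal(out$rate, 0.8, tolerance = 0.01)
})

test_that("triangular pulse area converges to h*b/2 at O(dt^2)", {
  errs <- vapply(c(25, 100), function(fps) {
    fx <- tri_pulse_trace(h = 1, b = 4, fps = fps)
    out <- detect_transients(fx$trace, fx$fps, min_duration_s = 0.5)
    abs(out$area[1] - 2)  # h*b/2 = 2, minus the sub-threshold sliver
  }, numeric(1))
  # both resolutions near-exact; error shrinks with dt
  expect_lt(errs[2], 0.02)
  expect_lte(errs[2], errs[1] + 1e-12)
})

test_that("peak rate is area over duration and scales linearly", {
  expect_equal(peak_rate(1.6, 2), 0.8)
  expect_equal(peak_rate(0, 3), 0)

  fx <- rect_pulse_trace(h = 0.5, dur_s = 3, fps = 50)
  r1 <- detect_transients(fx$trace, fx$fps)$rate
  r3 <- detect_transients(3 * fx$trace, fx$fps)$rate
  expect_equal(r3, 3 * r1, tolerance = 1e-9)
})

test_that("overall rate is the unweighted mean of peak rates", {
  tr <- tibble::tibble(onset = c(0, 5), offset = c(2, 6),
                       duration = c(2, 1), area = c(1.6, 0.4),
                       rate = c(0.8, 0.4))
  expect_equal(overall_rate(tr)$rate, 0.6)
  expect_equal(overall_rate(tr[1, ])$rate, 0.8)
  expect_true(is.na(overall_rate(tr[0, ])$rate))
  expect_equal(overall_rate(tr[0, ])$n_peaks, 0)

  # brute-force oracle on random peaks
  set.seed(3)
  n <- 25
  areas <- runif(n, 0.1, 3)
  durs <- runif(n, 0.5, 4)
  tr <- tibble::tibble(onset = seq_len(n), offset = seq_len(n) + durs,
                       duration = durs, area = areas, rate = areas / durs)
  expect_equal(overall_rate(tr)$rate, sum(areas / durs) / n)
})

test_that("rates are invariant to appending quiet flat segments", {
  fx <- rect_pulse_trace(h = 0.8, dur_s = 2, total_s = 20, fps = 50)
  longer <- c(fx$trace, rep(0, 600))
  r1 <- detect_transients(fx$trace, fx$fps)
  r2 <- detect_transients(longer, fx$fps)
  expect_equal(nrow(r1), nrow(r2))
  expect_equal(r1$rate, r2$rate, tolerance = 1e-9)
})

test_that("overlapping events separated by a deep valley are split", {
  fps <- 20
  t <- seq(0, 30, by = 1 / fps)
  set.seed(2)
  two <- 0.8 * ca_kernel(t - 5, 0.1, 1.0) + 0.8 * ca_kernel(t - 7, 0.1, 1.0) +
    rnorm(length(t), 0, 0.01)
  out <- detect_transients(two, fps, min_duration_s = 0.3)
  expect_equal(nrow(out), 2)
  out_ns <- detect_transients(two, fps, min_duration_s = 0.3,
                              split_dip_frac = 0)
  expect_equal(nrow(out_ns), 1)
})

test_that("the classification rule follows the three 20% inequalities", {
  # 0.1 < 0.2, 0.3 > 0.2, 0.4 > 0.22: suppressed
  expect_equal(classify_weight_sensitivity(1.0, 1.1, 0.7)$label,
               "suppressed")
  # all equal: strict inequalities fail
  expect_equal(classify_weight_sensitivity(1.0, 1.0, 1.0)$label,
               "unclassified")
  # 0.05 < 0.2, 0.5 > 0.2, 0.45 > 0.21: enhanced
  expect_equal(classify_weight_sensitivity(1.0, 1.05, 1.5)$label,
               "enhanced")
  # exact ties at the 20% boundary stay unclassified
  expect_equal(classify_weight_sensitivity(1.0, 1.0, 0.8)$label,
               "unclassified")
  # missing rates are flagged
  out <- classify_weight_sensitivity(1.0, NA, 0.5)
  expect_equal(out$label, "unclassified")
  expect_equal(out$reason, "missing rate")
})

test_that("classification is scale invariant", {
  set.seed(5)
  for (i in 1:50) {
    r <- runif(3, 0.05, 2)
    c1 <- classify_weight_sensitivity(r[1], r[2], r[3])$label
    s <- runif(1, 0.01, 100)
    c2 <- classify_weight_sensitivity(s * r[1], s * r[2], s * r[3])$label
    expect_equal(c1, c2)
  }
})

test_that("cohort classification reduces to the per-neuron rule", {
  mk <- function(rates, cond) {
    tibble::tibble(neuron_id = as.character(seq_along(rates)),
                   condition = cond, rate = rates,
                   n_peaks = rep(5L, length(rates)))
  }
  # identical rates across conditions: nothing called
  r <- runif(10, 0.2, 1)
  cls <- cohort_classification(mk(r, "probe_only"), mk(r, "balloon_weight"),
                               mk(r, "weight"))
  expect_equal(unname(cls$counts["suppressed"]), 0L)
  expect_equal(unname(cls$counts["enhanced"]), 0L)

  # single neuron reproduces classify_weight_sensitivity
  cls1 <- cohort_classification(mk(1.0, "probe_only"),
                                mk(1.1, "balloon_weight"),
                                mk(0.7, "weight"))
  expect_equal(cls1$calls$label, "suppressed")

  # mismatched id sets are rejected with the difference listed
  bad <- mk(r[1:9], "weight")
  expect_error(cohort_classification(mk(r, "probe_only"),
                                     mk(r, "balloon_weight"), bad),
               "differ across conditions.*10")
})

test_that("neuron rates run per row of a trace set", {
  fps <- 10
  fx1 <- rect_pulse_trace(h = 0.8, dur_s = 2, total_s = 50, fps = fps)
  fx2 <- rect_pulse_trace(h = 0.4, dur_s = 2, total_s = 50, fps = fps)
  ts <- trace_set(rbind(fx1$trace, fx2$trace, 0), frame_rate = fps,
                  neuron_ids = c("a", "b", "c"), condition = "probe_only")
  out <- neuron_rates(ts)
  expect_equal(out$neuron_id, c("a", "b", "c"))
  expect_equal(out$rate[1] / out$rate[2], 2, tolerance = 0.01)
  expect_true(is.na(out$rate[3]))
  expect_equal(out$n_peaks, c(1L, 1L, 0L))
})

test_that("trace set validation enforces its invariants", {
  expect_error(trace_set(matrix(c(1, NA), 1, 2)), "missing frames")
  expect_error(trace_set(matrix(0, 2, 5), neuron_ids = c("a", "a")),
               "unique")
  expect_error(trace_set(matrix(0, 1, 5), frame_rate = 0), "> 0")
})
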