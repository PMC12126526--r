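# Fluorescence-rate statistic on dF/F calcium traces and the three-condition
# weight-sensitivity classification.
#
# The per-peak statistic is the area under a firing peak of the dF/F trace
# divided by the peak duration (dS/dt); a neuron's overall rate is the
# unweighted mean over its peaks. A neuron is weight-suppressed when its rate
# is stable (within 20%, relative) between the probe-only and
# balloon+weight conditions but drops by more than 20% under the
# uncompensated weight; weight-enhanced is the mirrored increase.

#' Construct a trace set
#'
#' A dF/F matrix (neurons x frames) with a frame clock and stable neuron
#' identifiers, plus session metadata.
#'
#' @param dff Numeric matrix, rows = neurons, columns = frames.
#' @param frame_rate Imaging rate in frames per second (> 0).
#' @param neuron_ids Unique identifiers, one per row; defaults to row
#'   numbers.
#' @param animal_id,condition,experiment Session metadata.
#' @return An object of class `trace_set`.
#' @export
trace_set <- function(dff, frame_rate = 3,
                      neuron_ids = NULL,
                      animal_id = NA_character_,
                      condition = NA_character_,
                      experiment = NA_integer_) {
  dff <- as.matrix(dff)
  if (!is.numeric(dff) || anyNA(dff)) {
    stop("dff must be a numeric matrix without missing frames", call. = FALSE)
  }
  if (!is.finite(frame_rate) || frame_rate <= 0) {
    stop("frame_rate must be > 0", call. = FALSE)
  }
  if (is.null(neuron_ids)) neuron_ids <- as.character(seq_len(nrow(dff)))
  neuron_ids <- as.character(neuron_ids)
  if (length(neuron_ids) != nrow(dff) || anyDuplicated(neuron_ids)) {
    stop("neuron_ids must be unique, one per trace row", call. = FALSE)
  }
  structure(list(dff = dff, frame_rate = frame_rate,
                 neuron_ids = neuron_ids,
                 animal_id = animal_id, condition = condition,
                 experiment = experiment),
            class = "trace_set")
}

# linear-interpolated time at which the piecewise-linear trace crosses
# `level` between samples i and i+1
cross_time <- function(times, v, i, level) {
  f <- (level - v[i]) / (v[i + 1] - v[i])
  times[i] + f * (times[i + 1] - times[i])
}

# trapezoidal integral of piecewise-linear (v - baseline) over [t0, t1],
# with explicit endpoint values v0, v1 (threshold at interpolated crossings,
# the raw sample value when a transient is clipped by the recording edge)
trapz_between <- function(times, v, t0, t1, v0, v1, baseline) {
  inside <- which(times > t0 & times < t1)
  tt <- c(t0, times[inside], t1)
  vv <- c(v0, v[inside], v1) - baseline
  sum(diff(tt) * (head_(vv) + tail_(vv)) / 2)
}
head_ <- function(x) x[-length(x)]
tail_ <- function(x) x[-1]

# recursively split [lo, hi] (frame indices of one supra-threshold run) at
# interior valleys; a valley qualifies when its height above baseline falls
# below split_dip_frac times the smaller of the two flanking peak heights.
# Splits at the deepest qualifying local minimum, then recurses both sides.
# Returns boundary indices.
split_at_valleys <- function(v, lo, hi, baseline, split_dip_frac) {
  if (split_dip_frac <= 0 || hi - lo < 2) return(integer())
  interior <- (lo + 1):(hi - 1)
  is_min <- vapply(interior, function(i) {
    v[i] <= v[i - 1] && v[i] < v[i + 1]
  }, logical(1))
  cand <- interior[is_min]
  if (length(cand) == 0) return(integer())
  qualifies <- vapply(cand, function(m) {
    left_peak <- max(v[lo:m]) - baseline
    right_peak <- max(v[m:hi]) - baseline
    (v[m] - baseline) < split_dip_frac * min(left_peak, right_peak)
  }, logical(1))
  cand <- cand[qualifies]
  if (length(cand) == 0) return(integer())
  mi <- cand[which.min(v[cand])]
  c(split_at_valleys(v, lo, mi, baseline, split_dip_frac), mi,
    split_at_valleys(v, mi, hi, baseline, split_dip_frac))
}

#' Detect calcium transients in one dF/F trace
#'
#' Baseline is a low percentile of the trace; the detection threshold is the
#' baseline plus `k_mad` robust standard deviations of the noise. The noise
#' scale is estimated from the median absolute successive difference of the
#' trace (divided by `sqrt(2)`), which uses every frame and is insensitive
#' to the slow transients themselves; when that is degenerate the MAD of the
#' below-baseline residuals is used instead.
#' A transient is a maximal supra-threshold run lasting at least
#' `min_duration_s`; onset and offset are the linearly interpolated threshold
#' crossings, the area is the trapezoidal integral of the baseline-subtracted
#' trace between them, and the rate is area / duration.
#'
#' Runs containing a deep interior valley are split there into separate
#' peaks: a local minimum whose height above baseline falls below
#' `split_dip_frac` times the smaller flanking peak height marks a boundary
#' between two overlapping events (set `split_dip_frac = 0` to disable
#' splitting).
#'
#' @param trace Numeric dF/F vector for one neuron.
#' @param frame_rate Frames per second.
#' @param baseline_percentile Percentile (0-100) defining the baseline,
#'   default 20.
#' @param k_mad Threshold height in robust SDs above baseline, default 3.
#' @param min_duration_s Minimum transient duration in seconds; default
#'   0.66 (two frames at 3 fps).
#' @param split_dip_frac Valley depth (fraction of the smaller flanking peak
#'   height above baseline) below which a supra-threshold run is split into
#'   separate peaks; default 0.5.
#' @return A tibble with one row per transient: `onset`, `offset`,
#'   `duration`, `area`, `rate`.
#' @export
detect_transients <- function(trace, frame_rate = 3,
                              baseline_percentile = 20,
                              k_mad = 3, min_duration_s = 0.66,
                              split_dip_frac = 0.5) {
  stopifnot(is.numeric(trace), length(trace) >= 2, frame_rate > 0)
  empty <- tibble::tibble(onset = numeric(), offset = numeric(),
                          duration = numeric(), area = numeric(),
                          rate = numeric())
  times <- (seq_along(trace) - 1) / frame_rate
  baseline <- as.numeric(stats::quantile(trace, baseline_percentile / 100))

  sigma <- stats::mad(diff(trace), center = 0) / sqrt(2)
  if (!is.finite(sigma) || sigma == 0) {
    # degenerate derivative (e.g. piecewise-constant trace): fall back to
    # the below-baseline residual scale, then to a global robust scale
    below <- trace[trace <= baseline] - baseline
    sigma <- stats::mad(below, center = 0)
  }
  if (!is.finite(sigma) || sigma == 0) {
    sigma <- stats::mad(trace - baseline, center = 0)
  }
  if (!is.finite(sigma) || sigma == 0) {
    if (diff(range(trace)) == 0) {
      warning("flat trace: no transients detected", call. = FALSE)
      return(empty)
    }
    # structured but noiseless trace: any excursion above baseline counts
    sigma <- .Machine$double.eps
  }
  threshold <- baseline + k_mad * sigma

  above <- trace > threshold
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)

  out <- lapply(runs, function(k) {
    i0 <- starts[k]
    i1 <- ends[k]
    bnd <- split_at_valleys(trace, i0, i1, baseline, split_dip_frac)
    seg_lo <- c(i0, bnd)
    seg_hi <- c(bnd, i1)
    segs <- lapply(seq_along(seg_lo), function(s) {
      lo <- seg_lo[s]
      hi <- seg_hi[s]
      first <- s == 1
      last <- s == length(seg_lo)
      clip0 <- first && lo == 1
      clip1 <- last && hi == length(trace)
      onset <- if (!first || clip0) times[lo] else
        cross_time(times, trace, lo - 1, threshold)
      offset <- if (!last || clip1) times[hi] else
        cross_time(times, trace, hi, threshold)
      v0 <- if (first && !clip0) threshold else trace[lo]
      v1 <- if (last && !clip1) threshold else trace[hi]
      area <- trapz_between(times, trace, onset, offset, v0, v1, baseline)
      data.frame(onset = onset, offset = offset,
                 duration = offset - onset, area = area)
    })
    do.call(rbind, segs)
  })
  out <- do.call(rbind, out)
  out <- out[out$duration >= min_duration_s & out$duration > 0, ,
             drop = FALSE]
  if (nrow(out) == 0) return(empty)
  tibble::tibble(onset = out$onset, offset = out$offset,
                 duration = out$duration, area = out$area,
                 rate = out$area / out$duration)
}

#' Fluorescence rate of a single peak
#'
#' The area under the peak divided by its duration (dS/dt).
#'
#' @param area Peak area (dF/F x s).
#' @param duration Peak duration (s), > 0.
#' @return Rate in dF/F units per second.
#' @export
peak_rate <- function(area, duration) {
  stopifnot(all(duration > 0))
  area / duration
}

#' Overall fluorescence rate of a neuron
#'
#' Unweighted mean of the per-peak rates across a session,
#' `(sum_i dS_i/dt_i) / n`. `NA` when no peaks were detected.
#'
#' @param transients Output of [detect_transients()] for one neuron/session.
#' @return A list with `rate` and `n_peaks`.
#' @export
overall_rate <- function(transients) {
  n <- nrow(transients)
  list(rate = if (n == 0) NA_real_ else mean(transients$rate), n_peaks = n)
}

#' Per-neuron overall rates for a trace set
#'
#' Runs [detect_transients()] and [overall_rate()] on each neuron.
#'
#' @param ts A [trace_set()].
#' @param ... Detection parameters passed to [detect_transients()].
#' @return A tibble: `neuron_id`, `condition`, `rate`, `n_peaks`.
#' @export
neuron_rates <- function(ts, ...) {
  stopifnot(inherits(ts, "trace_set"))
  res <- lapply(seq_len(nrow(ts$dff)), function(i) {
    tr <- suppressWarnings(
      detect_transients(ts$dff[i, ], frame_rate = ts$frame_rate, ...))
    overall_rate(tr)
  })
  tibble::tibble(neuron_id = ts$neuron_ids,
                 condition = ts$condition,
                 rate = vapply(res, `[[`, numeric(1), "rate"),
                 n_peaks = vapply(res, `[[`, integer(1), "n_peaks"))
}

#' Classify one neuron's weight sensitivity
#'
#' With overall rates `r_p` (probe-only), `r_bw` (balloon + weight) and
#' `r_w` (weight), the neuron is
#' * `suppressed` when `|r_bw - r_p| < tol * r_p`, `r_p - r_w > tol * r_p`
#'   and `r_bw - r_w > tol * r_bw`;
#' * `enhanced` when `|r_bw - r_p| < tol * r_p`, `r_w - r_p > tol * r_p`
#'   and `r_w - r_bw > tol * r_bw`;
#' * `unclassified` otherwise.
#' All inequalities are strict; exact ties at the threshold are
#' unclassified. Any missing rate gives `unclassified` with a reason.
#'
#' @param r_p,r_bw,r_w Overall rates under the three conditions.
#' @param tol Relative threshold, default 0.20.
#' @return A list: `label`, `reason` (`NA` unless rates were missing), and
#'   the three rates.
#' @export
classify_weight_sensitivity <- function(r_p, r_bw, r_w, tol = 0.20) {
  stopifnot(tol > 0)
  rates <- c(r_p = r_p, r_bw = r_bw, r_w = r_w)
  if (anyNA(rates) || any(!is.finite(rates))) {
    return(list(label = "unclassified", reason = "missing rate",
                r_p = r_p, r_bw = r_bw, r_w = r_w))
  }
  stable_pb <- abs(r_bw - r_p) < tol * r_p
  suppressed <- stable_pb && (r_p - r_w > tol * r_p) &&
    (r_bw - r_w > tol * r_bw)
  enhanced <- stable_pb && (r_w - r_p > tol * r_p) &&
    (r_w - r_bw > tol * r_bw)
  label <- if (suppressed) "suppressed" else if (enhanced) "enhanced"
           else "unclassified"
  list(label = label, reason = NA_character_,
       r_p = r_p, r_bw = r_bw, r_w = r_w)
}

#' Classify a cohort of neurons across the three conditions
#'
#' Applies [classify_weight_sensitivity()] to every neuron of one experiment,
#' given the per-condition rate tables from [neuron_rates()]. Neuron identity
#' sets must agree across conditions (cross-session registration is an input
#' contract, not performed here).
#'
#' @param rates_p,rates_bw,rates_w Rate tibbles for the probe-only,
#'   balloon+weight and weight sessions.
#' @param tol Relative threshold, default 0.20.
#' @return A list with `calls` (tibble: `neuron_id`, `r_p`, `r_bw`, `r_w`,
#'   `label`, `reason`) and `counts` (named counts of suppressed, enhanced,
#'   unclassified).
#' @export
cohort_classification <- function(rates_p, rates_bw, rates_w, tol = 0.20) {
  ids <- rates_p$neuron_id
  for (other in list(rates_bw$neuron_id, rates_w$neuron_id)) {
    if (!setequal(ids, other)) {
      diffs <- union(setdiff(ids, other), setdiff(other, ids))
      stop("neuron id sets differ across conditions: ",
           paste(diffs, collapse = ", "), call. = FALSE)
    }
  }
  bw <- rates_bw$rate[match(ids, rates_bw$neuron_id)]
  w <- rates_w$rate[match(ids, rates_w$neuron_id)]
  calls <- lapply(seq_along(ids), function(i) {
    classify_weight_sensitivity(rates_p$rate[i], bw[i], w[i], tol = tol)
  })
  calls_tbl <- tibble::tibble(
    neuron_id = ids,
    r_p = rates_p$rate, r_bw = bw, r_w = w,
    label = vapply(calls, `[[`, character(1), "label"),
    reason = vapply(calls, `[[`, character(1), "reason")
  )
  counts <- c(suppressed = sum(calls_tbl$label == "suppressed"),
              enhanced = sum(calls_tbl$label == "enhanced"),
              unclassified = sum(calls_tbl$label == "unclassified"))
  list(calls = calls_tbl, counts = counts)
}
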