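#' Names of the 17 spike-train features
#' @return character vector of length 17
#' @export
spike_feature_names <- function() {
  c("voltage_base", "steady_state_voltage", "mean_frequency",
    "time_to_first_spike", "burst_isi", "isi_cv", "adaptation_index",
    "ap_height", "ap_begin_voltage", "ahp_depth", "ahp_time_from_peak",
    "spike_half_width",
    paste0("norm_if_", c(75, 125, 150, 200, 300)))
}

# spike bookkeeping: peaks of excursions above the 0 mV detection threshold
.find_spikes <- function(t, v, threshold = 0) {
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold)
  if (!length(up)) return(NULL)
  down <- which(v[-1] < threshold & v[-length(v)] >= threshold)
  peaks <- vapply(up, function(i) {
    j <- down[down >= i]
    j <- if (length(j)) j[1] else length(v)
    (i:j)[which.max(v[i:j])]
  }, integer(1))
  data.frame(idx = peaks, t = t[peaks], v = v[peaks])
}

#' Extract the 17 spike-train features from a somatic trace
#'
#' Spike bookkeeping uses a 0 mV peak threshold; the AP begin point is where
#' dV/dt last crosses 20 mV/ms upward before the peak. The half-width is
#' measured at half height between the AP begin voltage and the peak.
#' The ISI coefficient of variance follows the printed convention
#' ISI_mean / ISI_SD (switchable to the conventional SD/mean). The five
#' normalised I-F features are read from the supplied reference curve at 75,
#' 125, 150, 200 and 300% of the normalised input whose curve frequency
#' matches the trace's mean frequency. With fewer than two spikes the
#' ISI-based features are returned as NA (flagged undefined, not fabricated).
#'
#' @param trace data.frame `t_ms`, `v_mv` covering the stimulus
#' @param stim_onset,stim_offset stimulus window, ms
#' @param if_reference a normalised I-F curve from [normalize_if_curve()]
#'   (NULL: the five I-F features are NA)
#' @param isi_cv_form `"mean_over_sd"` (printed definition, default) or
#'   `"sd_over_mean"`
#' @param dvdt_threshold AP-begin slope criterion, mV/ms (default 20)
#' @return named numeric vector of length 17
#' @export
extract_features <- function(trace, stim_onset, stim_offset,
                             if_reference = NULL,
                             isi_cv_form = c("mean_over_sd", "sd_over_mean"),
                             dvdt_threshold = 20) {
  isi_cv_form <- match.arg(isi_cv_form)
  t <- trace$t_ms; v <- trace$v_mv
  f <- setNames(rep(NA_real_, 17L), spike_feature_names())
  f["voltage_base"] <- mean(v[t < stim_onset])
  end_win <- t >= stim_offset - 0.1 * (stim_offset - stim_onset) & t <= stim_offset
  f["steady_state_voltage"] <- mean(v[end_win])
  sp <- .find_spikes(t, v, 0)
  sp <- if (is.null(sp)) sp else sp[sp$t >= stim_onset & sp$t <= stim_offset, ]
  nsp <- if (is.null(sp)) 0L else nrow(sp)
  f["mean_frequency"] <- nsp / ((stim_offset - stim_onset) / 1000)
  if (nsp >= 1L) f["time_to_first_spike"] <- sp$t[1] - stim_onset
  if (nsp >= 2L) {
    isi <- diff(sp$t)
    f["burst_isi"] <- isi[1]
    if (length(isi) >= 2L && sd(isi) > 0) {
      f["isi_cv"] <- if (isi_cv_form == "mean_over_sd") {
        mean(isi) / sd(isi)
      } else sd(isi) / mean(isi)
    }
    if (length(isi) >= 2L) {
      f["adaptation_index"] <- mean(diff(isi) / (isi[-1] + isi[-length(isi)]))
    }
  }
  if (nsp >= 1L) {
    f["ap_height"] <- mean(sp$v)
    dvdt <- c(NA, diff(v) / diff(t))
    begin_v <- begin_i <- rep(NA_real_, nsp)
    for (k in seq_len(nsp)) {
      lo <- if (k == 1L) which(t >= stim_onset)[1] else sp$idx[k - 1L]
      seg <- lo:sp$idx[k]
      cr <- seg[which(dvdt[seg] >= dvdt_threshold)]
      if (length(cr)) {
        # last upward crossing of the slope criterion before the peak
        runs <- cr[c(TRUE, diff(cr) > 1)]
        begin_i[k] <- runs[length(runs)]
        begin_v[k] <- v[runs[length(runs)]]
      }
    }
    f["ap_begin_voltage"] <- mean(begin_v, na.rm = TRUE)
    # AHP between consecutive spikes (and after the last spike within stim)
    if (nsp >= 2L) {
      depth <- tfp <- numeric(nsp - 1L)
      for (k in seq_len(nsp - 1L)) {
        seg <- sp$idx[k]:sp$idx[k + 1L]
        depth[k] <- min(v[seg])
        tfp[k] <- t[seg[which.min(v[seg])]] - sp$t[k]
      }
      f["ahp_depth"] <- mean(depth)
      f["ahp_time_from_peak"] <- mean(tfp)
    }
    hw <- rep(NA_real_, nsp)
    for (k in seq_len(nsp)) {
      if (is.na(begin_i[k])) next
      half <- (sp$v[k] + begin_v[k]) / 2
      i0 <- begin_i[k]:sp$idx[k]
      iup <- i0[which(v[i0] >= half)[1]]
      after <- sp$idx[k]:min(length(v), sp$idx[k] + round(5 / (t[2] - t[1])))
      dn <- after[which(v[after] < half)[1]]
      if (!is.na(iup) && !is.na(dn)) {
        tu <- .cross_time(t[(iup - 1):iup], v[(iup - 1):iup] - half, 0)
        td <- .cross_time(t[(dn - 1):dn], half - v[(dn - 1):dn], 0)
        hw[k] <- td - tu
      }
    }
    f["spike_half_width"] <- mean(hw, na.rm = TRUE)
  }
  if (!is.null(if_reference) && nsp >= 1L) {
    x <- if_input_at_rate(if_reference, f[["mean_frequency"]])
    for (pct in c(75, 125, 150, 200, 300)) {
      f[paste0("norm_if_", pct)] <- if_rate_at_input(if_reference, x * pct / 100)
    }
  }
  f
}

#' Normalise an I-F curve by the 10 Hz input current
#'
#' Neighbouring points are connected by straight lines; the current
#' producing 10 Hz is found by inverse linear interpolation and all currents
#' are rescaled by it.
#'
#' @param points data.frame with columns `current` and `rate` (Hz), at least
#'   two points whose rates bracket 10 Hz
#' @return list of class `if_curve` with `input` (normalised), `rate` and
#'   `i_10hz` (in the input units)
#' @export
normalize_if_curve <- function(points) {
  stopifnot(nrow(points) >= 2)
  points <- points[order(points$current), ]
  if (min(points$rate) > 10 || max(points$rate) < 10) {
    stop("normalization error: 10 Hz outside the curve's rate range")
  }
  i10 <- approx(points$rate, points$current, xout = 10, ties = mean)$y
  structure(list(input = points$current / i10, rate = points$rate,
                 i_10hz = i10), class = "if_curve")
}

#' Firing rate of a normalised I-F curve at a given input
#'
#' Piecewise-linear between points, extended linearly from the end segments.
#' @param curve an `if_curve`
#' @param x normalised input (1 corresponds to the 10 Hz current)
#' @return rate, Hz (floored at 0)
#' @export
if_rate_at_input <- function(curve, x) {
  xs <- curve$input; ys <- curve$rate
  y <- vapply(x, function(xi) {
    if (xi <= xs[1]) {
      ys[1] + (ys[2] - ys[1]) / (xs[2] - xs[1]) * (xi - xs[1])
    } else if (xi >= xs[length(xs)]) {
      n <- length(xs)
      ys[n] + (ys[n] - ys[n - 1]) / (xs[n] - xs[n - 1]) * (xi - xs[n])
    } else approx(xs, ys, xout = xi, ties = mean)$y
  }, 0)
  pmax(y, 0)
}

#' Normalised input producing a given rate on an I-F curve
#' @param curve an `if_curve`
#' @param rate firing rate, Hz
#' @return normalised input (inverse linear interpolation, end segments
#'   extended)
#' @export
if_input_at_rate <- function(curve, rate) {
  xs <- curve$input; ys <- curve$rate
  if (rate <= ys[1]) {
    xs[1] + (xs[2] - xs[1]) / (ys[2] - ys[1]) * (rate - ys[1])
  } else if (rate >= ys[length(ys)]) {
    n <- length(ys)
    xs[n] + (xs[n] - xs[n - 1]) / (ys[n] - ys[n - 1]) * (rate - ys[n])
  } else approx(ys, xs, xout = rate, ties = mean)$y
}

#' Simulate an I-F curve for an active model
#'
#' @param model an active `cable_model` (after [apply_active_params()])
#' @param amps step-current amplitudes, nA
#' @param stim_onset,stim_offset stimulus window, ms
#' @param dt time step, ms
#' @return data.frame with `current` (nA) and `rate` (Hz)
#' @export
compute_if_curve <- function(model, amps, stim_onset = 100, stim_offset = 1100,
                             dt = 0.025) {
  rate <- vapply(amps, function(a) {
    sim <- simulate_model(model, stim_offset + 100, dt,
                          stimuli = data.frame(comp = 1, onset = stim_onset,
                                               offset = stim_offset, amp = a))
    tr <- get_trace(sim)
    sp <- .find_spikes(tr$t_ms, tr$v_mv, 0)
    n <- if (is.null(sp)) 0L else sum(sp$t >= stim_onset & sp$t <= stim_offset)
    n / ((stim_offset - stim_onset) / 1000)
  }, 0)
  data.frame(current = amps, rate = rate)
}
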