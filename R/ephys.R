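#' Evoked-current metrics from a trace
#'
#' Extracts the standard evoked-response parameters from a voltage-clamp
#' current trace: baseline, signed peak amplitude, 10-90% rise time,
#' mono-exponential decay tau (least-squares fit over a configurable
#' window on the falling phase), and charge (trapezoidal integral of the
#' baseline-subtracted current). A configurable blanking window after the
#' stimulus excludes the stimulation artifact from the peak search. Inward
#' currents are negative; amplitude and charge are reported signed.
#'
#' @param trace data.frame with columns `time_s` and `current_nA`.
#' @param stim_time stimulus onset, s.
#' @param baseline_window `c(t0, t1)` in s, before `stim_time`.
#' @param integration_window `c(t0, t1)` in s for charge and peak search;
#'   default `stim_time` to end of trace.
#' @param blank_ms artifact blanking window after the stimulus, ms
#'   (excluded from the peak search only).
#' @param decay_from,decay_to fractions of the peak deviation bounding the
#'   decay-fit window on the falling phase (defaults 0.7 and 0.1: the fit
#'   runs from 70% recovery, where the rising exponential no longer
#'   contaminates the decay, down to 10%).
#' @return an `evoked_metrics` list: `baseline_nA`, `amplitude_nA`,
#'   `rise_time_10_90_ms`, `decay_tau_ms`, `charge_pC`, `peak_time_s`.
#' @export
evoked_metrics <- function(trace, stim_time, baseline_window = NULL,
                           integration_window = NULL, blank_ms = 1,
                           decay_from = 0.7, decay_to = 0.1) {
  t <- trace$time_s; i <- trace$current_nA
  if (is.null(baseline_window)) baseline_window <- c(min(t), stim_time)
  if (baseline_window[2] > stim_time) stop("baseline window must precede the stimulus")
  bl_idx <- t >= baseline_window[1] & t <= baseline_window[2]
  if (sum(bl_idx) < 2) stop("baseline window too short")
  baseline <- mean(i[bl_idx])
  noise_sd <- stats::sd(i[bl_idx])
  if (is.null(integration_window)) integration_window <- c(stim_time, max(t))
  win <- t >= integration_window[1] & t <= integration_window[2]
  tw <- t[win]
  dev <- i[win] - baseline
  if (length(dev) < 3) stop("integration window too short")
  searchable <- tw >= stim_time + blank_ms / 1000
  if (!any(searchable)) stop("integration window too short")
  # peak search and no-response gate on a 3-sample running mean: the raw
  # per-sample maximum of pure noise exceeds 3 SD at these sampling rates
  sm <- as.numeric(stats::filter(dev, rep(1 / 3, 3), sides = 2))
  sm[is.na(sm)] <- 0
  pk_rel <- which(searchable)[which.max(abs(sm[searchable]))]
  amp <- sm[pk_rel]
  if (abs(amp) <= 3 * max(noise_sd, .Machine$double.eps))
    stop("no response: extremum within 3 SD of baseline noise")
  peak_time <- tw[pk_rel]
  # 10-90% rise time by linear interpolation on the rising limb (from the
  # stimulus; the blanking window applies to the peak search only)
  rise_idx <- which(tw <= peak_time & tw >= stim_time)
  rise_t <- tw[rise_idx]; rise_v <- dev[rise_idx] / amp  # normalized 0..1
  t_at <- function(frac) {
    above <- which(rise_v >= frac)
    if (!length(above)) return(NA_real_)
    k <- above[1]
    if (k == 1) return(rise_t[1])
    t0 <- rise_t[k - 1]; t1 <- rise_t[k]
    v0 <- rise_v[k - 1]; v1 <- rise_v[k]
    t0 + (frac - v0) / (v1 - v0) * (t1 - t0)
  }
  rise_ms <- (t_at(0.9) - t_at(0.1)) * 1000
  # decay fit on the falling phase, decay_from -> decay_to of the peak;
  # window anchors from the smoothed trace, the fit on raw samples
  post <- seq(pk_rel, length(dev))
  frac_v <- sm[post] / amp
  start_rel <- which(frac_v <= decay_from)
  start_k <- if (length(start_rel)) post[start_rel[1]] else pk_rel
  end_rel <- which(frac_v <= decay_to)
  end_k <- if (length(end_rel)) post[end_rel[1]] else length(dev)
  fit_idx <- seq(start_k, end_k)
  decay_tau <- fit_decay_tau(tw[fit_idx] - tw[start_k], dev[fit_idx], dev[start_k])
  charge <- trapz(tw, dev) * 1000  # nA·s = nC; x1000 -> pC
  structure(list(baseline_nA = baseline, amplitude_nA = amp,
                 rise_time_10_90_ms = rise_ms, decay_tau_ms = decay_tau,
                 charge_pC = charge, peak_time_s = peak_time),
            class = "evoked_metrics")
}

# Least-squares mono-exponential fit dev ~ A * exp(-t/tau); t from the peak.
# Log-linear start values refined by nonlinear least squares.
fit_decay_tau <- function(t_rel, dev, amp) {
  pos <- dev / amp > 0.01
  tt <- t_rel[pos]; vv <- dev[pos] / amp  # normalized, positive
  if (length(tt) < 3) stop("non-convergent decay fit: too few points")
  lf <- stats::lm(log(vv) ~ tt)
  tau0 <- unname(-1 / stats::coef(lf)[2])
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(tt) / 3
  fit <- try(minpack.lm::nlsLM(vv ~ A * exp(-tt / tau),
                               start = list(A = 1, tau = tau0),
                               control = minpack.lm::nls.lm.control(maxiter = 200)),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("non-convergent decay fit: ", attr(fit, "condition")$message)
  unname(stats::coef(fit)["tau"]) * 1000
}

#' @export
print.evoked_metrics <- function(x, ...) {
  cat(sprintf(paste0("<evoked_metrics> amplitude %.2f nA, rise(10-90) %.2f ms, ",
                     "tau %.2f ms, charge %.2f pC\n"),
              x$amplitude_nA, x$rise_time_10_90_ms, x$decay_tau_ms, x$charge_pC))
  invisible(x)
}

#' Paired-pulse ratio
#'
#' Amplitude of the second response divided by the first. By default the
#' second amplitude is corrected for the residual decay of the first
#' response: the first response's fitted mono-exponential is extrapolated
#' to the second peak time and subtracted (`correction = "extrapolate"`).
#' Alternative: subtract the current immediately before the second
#' stimulus (`correction = "pre_pulse"`).
#'
#' @param trace data.frame with `time_s`, `current_nA`.
#' @param stim1,stim2 stimulus times, s (`stim2 > stim1`).
#' @param baseline_window as in [evoked_metrics()].
#' @param blank_ms artifact blanking, ms.
#' @param correction `"extrapolate"` or `"pre_pulse"`.
#' @return list with `ratio` (on magnitudes), `A1_nA`, `A2_nA`, and the
#'   two [evoked_metrics()]-style peak times.
#' @export
pp_ratio <- function(trace, stim1, stim2, baseline_window = NULL,
                     blank_ms = 1, correction = c("extrapolate", "pre_pulse")) {
  correction <- match.arg(correction)
  if (stim2 <= stim1) stop("stim2 must be after stim1")
  m1 <- evoked_metrics(trace, stim1, baseline_window,
                       integration_window = c(stim1, stim2), blank_ms = blank_ms)
  t <- trace$time_s; i <- trace$current_nA
  win2 <- t >= stim2 + blank_ms / 1000 & t <= stim2 + (stim2 - stim1) +
    20 * m1$decay_tau_ms / 1000
  if (!any(win2)) stop("trace too short for second response")
  dev2 <- i[win2] - m1$baseline_nA
  pk2 <- which.max(abs(dev2))
  t2 <- t[win2][pk2]
  raw2 <- dev2[pk2]
  if (correction == "extrapolate") {
    resid1 <- m1$amplitude_nA * exp(-(t2 - m1$peak_time_s) / (m1$decay_tau_ms / 1000))
    A2 <- raw2 - resid1
  } else {
    pre2 <- i[max(which(t < stim2))] - m1$baseline_nA
    A2 <- raw2 - pre2
  }
  if (abs(m1$amplitude_nA) == 0) stop("first response absent")
  list(ratio = abs(A2) / abs(m1$amplitude_nA),
       A1_nA = m1$amplitude_nA, A2_nA = A2,
       peak1_time_s = m1$peak_time_s, peak2_time_s = t2)
}
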