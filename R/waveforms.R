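#' Piecewise-constant dose-rate waveforms
#'
#' A dose-rate waveform is an ordered set of non-overlapping beam-on
#' segments, each with a constant instantaneous dose rate; the dose rate is
#' zero between segments (gaps are implicit). `dose_waveform()` validates
#' and classes a segment table.
#'
#' @param t_start,t_end Segment start/end times, seconds.
#' @param rate Segment dose rates, Gy/s.
#' @return A data frame of class `dose_waveform` with columns `t_start`,
#'   `t_end`, `rate`.
#' @export
dose_waveform <- function(t_start, t_end, rate) {
  wf <- data.frame(t_start = as.numeric(t_start),
                   t_end = as.numeric(t_end),
                   rate = as.numeric(rate))
  wf <- wf[order(wf$t_start), , drop = FALSE]
  rownames(wf) <- NULL
  if (nrow(wf)) {
    if (any(wf$t_end <= wf$t_start)) stop("segment with t_end <= t_start")
    if (any(wf$rate < 0)) stop("negative dose rate")
    if (nrow(wf) > 1 &&
        any(wf$t_start[-1] < wf$t_end[-nrow(wf)] - 1e-12))
      stop("overlapping waveform segments")
  }
  class(wf) <- c("dose_waveform", class(wf))
  wf
}

#' Total dose delivered by a waveform
#' @param wf A `dose_waveform`.
#' @return Dose in Gy (the time-integral of the dose rate).
#' @export
total_dose <- function(wf) {
  if (!nrow(wf)) return(0)
  sum((wf$t_end - wf$t_start) * wf$rate)
}

#' Beam-off time of a waveform
#' @param wf A `dose_waveform`.
#' @return End time of the last beam-on segment, seconds.
#' @export
beam_off_time <- function(wf) if (nrow(wf)) max(wf$t_end) else 0

#' @export
print.dose_waveform <- function(x, ...) {
  cat("<dose_waveform> ", nrow(x), " segment(s), total dose ",
      signif(total_dose(x), 8), " Gy, beam off at ",
      signif(beam_off_time(x), 8), " s\n", sep = "")
  invisible(x)
}

#' Constant-rate waveform
#'
#' Single beam-on segment delivering `dose` at a fixed `rate`, as for a
#' uniform scattered field.
#'
#' @param dose Total dose, Gy (> 0).
#' @param rate Dose rate, Gy/s (> 0).
#' @return A `dose_waveform` with one segment of duration `dose/rate`.
#' @export
constant_waveform <- function(dose, rate) {
  if (dose <= 0) stop("non-positive dose")
  if (rate <= 0) stop("non-positive rate")
  dose_waveform(0, dose / rate, rate)
}

#' Pulsed-beam waveform
#'
#' Train of rectangular pulses as delivered by a pulsed electron linac:
#' pulses of width `pulse_width` at repetition `frequency`, each delivering
#' `dose_per_pulse` (rate = dose_per_pulse / pulse_width), until
#' `total_dose` is reached. The pulse count is `floor(total/DPP)` full
#' pulses plus one trimmed final pulse (same rate, shorter width) so the
#' delivered dose is exact.
#'
#' @param dose_per_pulse Gy per pulse (> 0, <= `total_dose`).
#' @param pulse_width Pulse duration, s.
#' @param frequency Pulse repetition frequency, Hz.
#' @param total_dose Total delivered dose, Gy.
#' @return A `dose_waveform`.
#' @export
pulse_train_waveform <- function(dose_per_pulse, pulse_width, frequency,
                                 total_dose) {
  if (dose_per_pulse <= 0) stop("non-positive dose per pulse")
  if (dose_per_pulse > total_dose) stop("dose per pulse exceeds total dose")
  period <- 1 / frequency
  if (pulse_width >= period) stop("pulse width >= pulse period")
  rate <- dose_per_pulse / pulse_width
  n_full <- floor(total_dose / dose_per_pulse + 1e-9)
  rem <- total_dose - n_full * dose_per_pulse
  if (rem < 1e-12 * total_dose) rem <- 0
  starts <- (seq_len(n_full) - 1) * period
  widths <- rep(pulse_width, n_full)
  doses <- rep(dose_per_pulse, n_full)
  if (rem > 0) {
    starts <- c(starts, n_full * period)
    widths <- c(widths, rem / rate)
    doses <- c(doses, rem)
  }
  ends <- starts + widths
  # per-segment rates are recomputed from the realised segment lengths so
  # the summed dose is exact: at large time offsets t_start + width loses
  # the low-order bits of the microsecond pulse width
  dose_waveform(starts, ends, doses / (ends - starts))
}

#' Concatenate a multi-beam schedule into one waveform
#'
#' Time-shifts a sequence of sub-delivery waveforms so that each one starts
#' `gap_after` seconds after the previous one ends. Gaps are represented
#' implicitly (no zero-rate segments): the kinetics integrator coasts
#' through them with zero dose rate. The beam-off time of the result is the
#' end of the final sub-delivery, which anchors the post-irradiation
#' equilibration window.
#'
#' @param waveforms List of `dose_waveform` sub-deliveries (>= 1).
#' @param gaps Gap after each sub-delivery, seconds (length
#'   `length(waveforms) - 1`, or a single value recycled; >= 0).
#' @return A `dose_waveform` whose total dose is the sum of the parts.
#' @export
concat_schedule <- function(waveforms, gaps = 0) {
  n <- length(waveforms)
  if (n < 1) stop("empty schedule")
  if (n == 1) return(waveforms[[1]])
  gaps <- rep_len(gaps, n - 1)
  if (any(gaps < 0)) stop("negative inter-beam gap")
  out <- waveforms[[1]]
  t0 <- beam_off_time(out)
  for (i in 2:n) {
    wf <- waveforms[[i]]
    shift <- t0 + gaps[i - 1]
    wf$t_start <- wf$t_start + shift
    wf$t_end <- wf$t_end + shift
    out <- rbind(as.data.frame(out), as.data.frame(wf))
    t0 <- max(wf$t_end)
  }
  dose_waveform(out$t_start, out$t_end, out$rate)
}

#' Read/write waveforms as CSV
#'
#' Round-trip stable representation with columns `t_start`, `t_end`,
#' `rate_Gy_per_s`.
#' @param wf A `dose_waveform`.
#' @param path File path.
#' @return `read_waveform()` returns a `dose_waveform`;
#'   `write_waveform()` returns `path` invisibly.
#' @export
write_waveform <- function(wf, path) {
  out <- data.frame(t_start = wf$t_start, t_end = wf$t_end,
                    rate_Gy_per_s = wf$rate)
  utils::write.csv(format(out, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  d <- utils::read.csv(path)
  dose_waveform(d$t_start, d$t_end, d$rate_Gy_per_s)
}
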