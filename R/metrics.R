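#' Average dose rate (ADR)
#'
#' Voxel dose divided by the total field delivery time.
#'
#' @param voxel_dose_Gy Voxel dose, Gy.
#' @param field_time_s Field delivery time, s (> 0).
#' @return Gy/s.
#' @export
adr <- function(voxel_dose_Gy, field_time_s) {
  if (any(field_time_s <= 0)) stop("zero or negative field time")
  voxel_dose_Gy / field_time_s
}

#' Dose-averaged dose rate (DADR)
#'
#' Dose-weighted mean of the instantaneous per-spot dose rates seen by a
#' voxel: `(1/D) * sum(d_j * ddot_j)`.
#'
#' @param spot_doses_Gy Per-spot doses to the voxel, Gy.
#' @param spot_rates_Gy_s Matching per-spot instantaneous dose rates, Gy/s.
#' @return Gy/s.
#' @export
dadr <- function(spot_doses_Gy, spot_rates_Gy_s) {
  if (length(spot_doses_Gy) != length(spot_rates_Gy_s))
    stop("spot dose and rate vectors differ in length")
  D <- sum(spot_doses_Gy)
  if (D <= 0) stop("zero total dose")
  sum(spot_doses_Gy * spot_rates_Gy_s) / D
}

#' PBS dose rate (PBSDR)
#'
#' `(D - 2 d) / T` with `d = 0.01 * D` and `T` the time between the
#' cumulative dose crossing `d` and `D - d`. Crossing times are found by
#' linear interpolation inside the piecewise-constant-rate segments of the
#' voxel waveform.
#'
#' @param wf The voxel's [dose_waveform()].
#' @param D Reference dose, Gy; defaults to the waveform's total dose.
#' @return Gy/s.
#' @export
pbsdr <- function(wf, D = total_dose(wf)) {
  if (!nrow(wf)) stop("empty waveform")
  dd <- 0.01 * D
  cum <- cumsum((wf$t_end - wf$t_start) * wf$rate)
  cum0 <- c(0, cum[-length(cum)])
  crossing <- function(level) {
    s <- which(cum >= level - 1e-15)[1]
    if (is.na(s)) stop("trace never reaches the requested dose level")
    wf$t_start[s] + (level - cum0[s]) / wf$rate[s]
  }
  t1 <- crossing(dd)
  t2 <- crossing(D - dd)
  (D - 2 * dd) / (t2 - t1)
}

#' ROS-volume histogram (RVH)
#'
#' Survival-style cumulative histogram over equal-volume voxels: for each
#' ROOH level, the fraction of the region volume with at least that value.
#'
#' @param rooh_uM Per-voxel ROOH values, micromolar (or an
#'   `ros_field_result`).
#' @return Data frame of class `rvh_curve` with columns `rooh_uM` (sorted
#'   ascending) and `volume_fraction` (non-increasing, from 1 to 1/N).
#' @export
rvh <- function(rooh_uM) {
  if (inherits(rooh_uM, "ros_field_result")) rooh_uM <- rooh_uM$voxels$rooh_uM
  if (!length(rooh_uM)) stop("empty ROS map")
  x <- sort(rooh_uM)
  n <- length(x)
  out <- data.frame(rooh_uM = x, volume_fraction = (n:1) / n)
  class(out) <- c("rvh_curve", class(out))
  out
}

#' ROOH value exceeded by a given volume fraction
#'
#' DVH-style statistic: `rooh_at_volume(x, 50)` is the volume median (the
#' ROOH level reached or exceeded in 50% of the region).
#'
#' @param rooh_uM Per-voxel ROOH values (or an `ros_field_result`).
#' @param v Volume percentage (0-100).
#' @return ROOH in micromolar.
#' @export
rooh_at_volume <- function(rooh_uM, v = 50) {
  if (inherits(rooh_uM, "ros_field_result")) rooh_uM <- rooh_uM$voxels$rooh_uM
  stopifnot(v > 0, v < 100 || v == 100)
  unname(stats::quantile(rooh_uM, probs = 1 - v / 100, names = FALSE))
}

#' FLASH sparing of the volume-median ROOH
#'
#' Difference of the ROOH[v%] statistic between a conventional-current and
#' an ultra-high-current delivery of the same field, reported positive when
#' the UHDR arm produces less ROOH (sparing).
#'
#' @param conv,uhdr Per-voxel ROOH vectors (or `ros_field_result`s) for the
#'   CONV and UHDR arms; must cover the same geometry.
#' @param v Volume percentage; 50 gives the volume median.
#' @return Sparing in micromolar (CONV minus UHDR).
#' @export
delta_rooh <- function(conv, uhdr, v = 50) {
  cv <- if (inherits(conv, "ros_field_result")) conv$voxels$rooh_uM else conv
  uv <- if (inherits(uhdr, "ros_field_result")) uhdr$voxels$rooh_uM else uhdr
  if (length(cv) != length(uv)) stop("mismatched region volumes")
  rooh_at_volume(cv, v) - rooh_at_volume(uv, v)
}

#' Dose-response curve of mean regional ROOH
#'
#' Monotone piecewise-cubic (Hyman-filtered spline) interpolant through
#' simulated (dose, mean ROOH) pairs for one beam current.
#'
#' @param dose_Gy Simulated nominal doses, Gy.
#' @param mean_rooh_uM Matching mean regional ROOH, micromolar (strictly
#'   increasing with dose).
#' @return A function mapping dose (Gy) to mean ROOH (uM), with the input
#'   table attached as attribute `points`.
#' @export
dose_response <- function(dose_Gy, mean_rooh_uM) {
  o <- order(dose_Gy)
  dose_Gy <- dose_Gy[o]; mean_rooh_uM <- mean_rooh_uM[o]
  if (any(diff(mean_rooh_uM) <= 0))
    stop("mean ROOH must be strictly increasing with dose")
  f <- stats::splinefun(dose_Gy, mean_rooh_uM, method = "hyman")
  attr(f, "points") <- data.frame(dose_Gy, mean_rooh_uM)
  attr(f, "range") <- range(dose_Gy)
  f
}

#' Iso-ROOH equivalent dose and FLASH dose-modifying factor
#'
#' Finds the conventional-delivery dose whose mean regional ROOH equals
#' that of a given UHDR dose, by root-finding on the two dose-response
#' interpolants, and the dose-modifying factor `DMF = uhdr_dose /
#' conv_dose`.
#'
#' @param conv_curve,uhdr_curve [dose_response()] interpolants for the CONV
#'   and UHDR arms.
#' @param uhdr_dose UHDR dose, Gy (inside both interpolation ranges).
#' @return List with `conv_dose_Gy`, `dmf` and the matched `rooh_uM`.
#' @export
iso_rooh_equivalent <- function(conv_curve, uhdr_curve, uhdr_dose) {
  rng <- attr(uhdr_curve, "range")
  if (uhdr_dose < rng[1] || uhdr_dose > rng[2])
    stop("UHDR dose outside interpolation range")
  target <- uhdr_curve(uhdr_dose)
  rngc <- attr(conv_curve, "range")
  f <- function(d) conv_curve(d) - target
  if (f(rngc[1]) > 0 || f(rngc[2]) < 0)
    stop("no iso-ROOH root inside the CONV interpolation range")
  conv_dose <- stats::uniroot(f, rngc, tol = 1e-10)$root
  list(conv_dose_Gy = conv_dose, dmf = uhdr_dose / conv_dose,
       rooh_uM = target)
}

#' Fraction of the region below an ROOH threshold
#'
#' @param rooh_uM Per-voxel ROOH values (or an `ros_field_result`).
#' @param threshold_uM ROOH threshold, micromolar (> 0).
#' @return Percentage of voxels with ROOH strictly below the threshold.
#' @export
fraction_below <- function(rooh_uM, threshold_uM) {
  if (inherits(rooh_uM, "ros_field_result")) rooh_uM <- rooh_uM$voxels$rooh_uM
  if (!length(rooh_uM)) stop("empty ROS map")
  stopifnot(threshold_uM > 0)
  100 * mean(rooh_uM < threshold_uM)
}
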