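# Occupancy-driven tumor growth inhibition: a Hill kill function moves
# growing tumor volume through three non-growing transit compartments whose
# exit represents cell death.

#' Tumor growth rate from doubling time
#'
#' @param DT Tumor doubling time, days.
#' @return Growth rate `0.693/DT`, 1/day.
#' @export
growth_rate <- function(DT) {
  if (any(DT <= 0)) stop("doubling time must be positive")
  0.693 / DT
}

#' Occupancy-to-kill Hill function
#'
#' First-order kill rate as a sigmoidal function of percent tubulin
#' occupancy.  With the steep Hill coefficient estimated for MMAE
#' (gamma ~ 15) this behaves as a near-threshold switch around `KC50`.
#'
#' @param Occ Percent tubulin occupancy, in `[0, 100]`.
#' @param Kmax Maximum kill rate, 1/day.
#' @param KC50 Occupancy at half-maximal kill, percent.
#' @param gamma Hill coefficient.
#' @return Kill rate in `[0, Kmax)`, 1/day.
#' @examples
#' kill_rate(96.8, 1.03, 96.8, 15.02)  # half-maximal: 0.515
#' @export
kill_rate <- function(Occ, Kmax, KC50, gamma) {
  if (any(Occ < 0)) stop("occupancy must be non-negative")
  po <- Occ^gamma
  ifelse(Occ == 0, 0, Kmax * po / (KC50^gamma + po))
}

#' Tumor-volume transit right-hand side
#'
#' Growing volume `TV1` expands at `Kg - Kill`; killed volume transits
#' through `TV2 -> TV3 -> TV4` with time constant `tau` and exits from
#' `TV4`.  Total volume obeys `d(TV)/dt = Kg*TV1 - TV4/tau`.
#'
#' @param tv Named vector with `TV1`, `TV2`, `TV3`, `TV4` (mm^3).
#' @param Occ Percent tubulin occupancy driving the kill.
#' @param p An [adc_params()] set (`Kmax`, `KC50`, `gamma`, `tau`, `DT`).
#' @return Named vector of derivatives, mm^3/day.
#' @export
tgi_rhs <- function(tv, Occ, p) {
  if (any(tv < 0)) stop("tumor volume compartments must be non-negative")
  Kg <- growth_rate(p$DT)
  kill <- kill_rate(Occ, p$Kmax, p$KC50, p$gamma)
  c(TV1 = (Kg - kill) * tv[["TV1"]],
    TV2 = kill * tv[["TV1"]] - tv[["TV2"]] / p$tau,
    TV3 = (tv[["TV2"]] - tv[["TV3"]]) / p$tau,
    TV4 = (tv[["TV3"]] - tv[["TV4"]]) / p$tau)
}

#' Time for a tumor-volume curve to exceed a threshold
#'
#' First crossing time of the total tumor volume above `threshold`,
#' linearly interpolated between samples; `Inf` if the curve never crosses.
#'
#' @param times Time grid, days (increasing).
#' @param volumes Total tumor volumes, mm^3.
#' @param threshold Volume threshold, mm^3 (default 1000).
#' @return First crossing time in days, or `Inf`.
#' @export
time_to_volume <- function(times, volumes, threshold = 1000) {
  if (!length(times) || length(times) != length(volumes)) {
    stop("times and volumes must be non-empty and of equal length")
  }
  if (is.unsorted(times)) stop("times must be increasing")
  above <- volumes > threshold
  if (above[1]) return(times[1])
  i <- which(above)[1]
  if (is.na(i)) return(Inf)
  t0 <- times[i - 1]; t1 <- times[i]
  v0 <- volumes[i - 1]; v1 <- volumes[i]
  t0 + (threshold - v0) / (v1 - v0) * (t1 - t0)
}
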