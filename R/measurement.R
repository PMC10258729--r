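#' Read raw probe voltage frames
#'
#' Measurement files are delimited text with one row per
#' (timestamp, channel) pair and columns `time_s`, `wavelength_nm`,
#' `separation_mm`, `Vp` (sample voltage, V), `Vd` (dark voltage, V) and
#' `gain` (transimpedance gain, one of 0.5, 1 or 10 MOhm).
#'
#' @param file Path to a tab- or comma-delimited file.
#' @return A `data.frame` of voltage frames.
#' @export
readVoltageFrames <- function(file) {
  sep <- if (grepl("\\.csv$", file)) "," else "\t"
  f <- read.delim(file, sep = sep, stringsAsFactors = FALSE)
  need <- c("time_s", "wavelength_nm", "separation_mm", "Vp", "Vd", "gain")
  if (!all(need %in% names(f)))
    stop("voltage file must have columns: ", paste(need, collapse = ", "))
  f
}

.validGains <- c(0.5, 1, 10)

#' Gain-correct and dark-subtract voltage frames
#'
#' Converts raw sample/dark voltage pairs to dark-subtracted voltages on a
#' common unit-gain reference: `V = Vp/gain - Vd/gain`. The operation is
#' linear (scaling `Vp` and `Vd` by k scales `V` by k) and
#' gain-invariant: the same light level measured at different gain
#' settings yields identical corrected voltages. Channels whose corrected
#' voltage is not positive are flagged (`ok = FALSE`) with a warning so
#' downstream stages can exclude them.
#'
#' @param frames A `data.frame` of voltage frames (see
#'   [readVoltageFrames()]).
#' @return The frames with columns `V` (corrected voltage) and `ok`
#'   appended.
#' @export
correctFrames <- function(frames) {
  if (!all(frames$gain %in% .validGains))
    stop("gain must be one of ", paste(.validGains, collapse = ", "),
      " MOhm")
  frames$V <- frames$Vp / frames$gain - frames$Vd / frames$gain
  frames$ok <- frames$V > 0
  if (any(!frames$ok))
    warning(sum(!frames$ok),
      " frame(s) with nonpositive corrected voltage flagged")
  frames
}

.channelKey <- function(frames)
  interaction(frames$wavelength_nm, frames$separation_mm, drop = TRUE)

#' Signal-to-noise ratio of a voltage series
#'
#' SNR in dB of the dark-subtracted series per channel:
#' `10 log10(mean(Vp - Vd) / sd(Vp - Vd))`, with the sample standard
#' deviation. A zero-SD series reports `Inf`; a nonpositive mean reports
#' `NaN`.
#'
#' @param frames Voltage frames (corrected on the fly if needed); each
#'   channel needs at least two time points.
#' @return A `data.frame` with one row per channel: `wavelength_nm`,
#'   `separation_mm`, `snr_db`.
#' @examples
#' f <- data.frame(time_s = 1:60, wavelength_nm = 980, separation_mm = 7,
#'   Vp = 1 + rnorm(60, 0, 0.01), Vd = 0, gain = 1)
#' snrDB(f)
#' @export
snrDB <- function(frames) {
  if (is.null(frames$V)) frames <- correctFrames(frames)
  key <- .channelKey(frames)
  out <- do.call(rbind, lapply(split(frames, key), function(d) {
    if (nrow(d) < 2L) stop("SNR needs a series of length >= 2 per channel")
    m <- mean(d$V)
    s <- sd(d$V)
    snr <- if (s == 0) Inf else if (m <= 0) NaN else 10 * log10(m / s)
    data.frame(wavelength_nm = d$wavelength_nm[1L],
      separation_mm = d$separation_mm[1L], snr_db = snr)
  }))
  rownames(out) <- NULL
  out
}

#' Instrument drift of a voltage series
#'
#' Fits the corrected voltage of each channel to a linear function of time
#' and reports the slope normalized to the initial voltage, in percent per
#' hour. The "initial voltage" is the fitted intercept at t = 0 (robust to
#' noise in the first sample).
#'
#' @param frames Voltage frames spanning a positive time range.
#' @return A `data.frame` with one row per channel: `wavelength_nm`,
#'   `separation_mm`, `drift_pct_per_h`.
#' @export
driftRate <- function(frames) {
  if (is.null(frames$V)) frames <- correctFrames(frames)
  key <- .channelKey(frames)
  out <- do.call(rbind, lapply(split(frames, key), function(d) {
    hours <- d$time_s / 3600
    if (diff(range(hours)) <= 0)
      stop("drift needs a series spanning a positive time range")
    fit <- lm(V ~ hours, data = data.frame(V = d$V, hours = hours))
    b <- coef(fit)
    data.frame(wavelength_nm = d$wavelength_nm[1L],
      separation_mm = d$separation_mm[1L],
      drift_pct_per_h = unname(b[2L] / b[1L] * 100))
  }))
  rownames(out) <- NULL
  out
}

#' Per-channel calibration against a reference phantom
#'
#' Maps the known optical properties of a calibration phantom through the
#' Monte Carlo LUT to a theoretical Rd per channel, and divides by the
#' mean corrected calibration voltage to obtain a linear scaling factor
#' `s = Rd_theory / V_cal` specific to each wavelength/separation pair
#' (the photodiode responds linearly to incident power).
#'
#' @slot channels `data.frame` of the channel ordering.
#' @slot scale Per-channel scaling factors (Rd per volt), all > 0.
#' @slot theoreticalRd,meanV The LUT Rd values and mean calibration
#'   voltages they derive from.
#' @aliases CalibrationReference-class
#' @exportClass CalibrationReference
setClass("CalibrationReference",
  representation(channels = "data.frame", scale = "numeric",
    theoreticalRd = "numeric", meanV = "numeric"))

setValidity("CalibrationReference", function(object) {
  if (any(!is.finite(object@scale)) || any(object@scale <= 0))
    return("all scaling factors must be positive and finite")
  if (length(object@scale) != nrow(object@channels))
    return("one scaling factor per channel is required")
  TRUE
})

setMethod("show", "CalibrationReference", function(object) {
  cat("CalibrationReference over", nrow(object@channels), "channels; ",
    "scale range", format(min(object@scale), digits = 3), "-",
    format(max(object@scale), digits = 3), "Rd/V\n")
})

#' @param frames Voltage frames measured on the calibration phantom.
#' @param phantomMua,phantomMusp Known absorption and reduced scattering
#'   of the phantom, one value per wavelength of `geometry` (mm^-1).
#' @param geometry A [ProbeGeometry-class].
#' @param lut A [ReflectanceLUT-class] covering the phantom properties.
#' @return `buildCalibration()` returns a `CalibrationReference`.
#' @rdname CalibrationReference-class
#' @export
buildCalibration <- function(frames, phantomMua, phantomMusp, geometry,
    lut) {
  stopifnot(length(phantomMua) == length(geometry@wavelengths),
    length(phantomMusp) == length(geometry@wavelengths))
  if (is.null(frames$V)) frames <- correctFrames(frames)
  ch <- channels(geometry)
  iwl <- match(ch$wavelength_nm, geometry@wavelengths)
  rdTheory <- lutLookup(lut, phantomMusp[iwl], phantomMua[iwl],
    ch$separation_mm)
  meanV <- vapply(seq_len(nrow(ch)), function(c) {
    d <- frames[frames$wavelength_nm == ch$wavelength_nm[c] &
      frames$separation_mm == ch$separation_mm[c], ]
    if (nrow(d) == 0L)
      stop("no calibration frames for channel ", ch$wavelength_nm[c],
        " nm / ", ch$separation_mm[c], " mm")
    mean(d$V)
  }, numeric(1L))
  if (any(meanV <= 0))
    stop("calibration error: nonpositive mean voltage on ",
      sum(meanV <= 0), " channel(s)")
  new("CalibrationReference", channels = ch, scale = rdTheory / meanV,
    theoreticalRd = rdTheory, meanV = meanV)
}

#' Convert voltage frames to calibrated reflectance
#'
#' Multiplies each corrected sample voltage by the per-channel calibration
#' scaling factor, producing one Rd vector (in the calibration's channel
#' order) per time point. Output of this stage feeds
#' [predictFractions()].
#'
#' @param frames Voltage frames of the measured sample.
#' @param calibration A [CalibrationReference-class].
#' @return A time points x channels matrix of Rd values.
#' @export
toReflectance <- function(frames, calibration) {
  stopifnot(is(calibration, "CalibrationReference"))
  if (is.null(frames$V)) frames <- correctFrames(frames)
  ch <- calibration@channels
  key <- paste(frames$wavelength_nm, frames$separation_mm)
  want <- paste(ch$wavelength_nm, ch$separation_mm)
  if (!all(key %in% want) || !all(want %in% key))
    stop("channel sets of the frames and the calibration differ")
  times <- sort(unique(frames$time_s))
  rd <- matrix(NA_real_, nrow = length(times), ncol = nrow(ch),
    dimnames = list(NULL,
      sprintf("%gnm_%gmm", ch$wavelength_nm, ch$separation_mm)))
  for (c in seq_len(nrow(ch))) {
    d <- frames[key == want[c], ]
    rd[, c] <- d$V[match(times, d$time_s)] * calibration@scale[c]
  }
  rd
}

#' Fabricate synthetic voltage frames from true reflectance
#'
#' Synthetic stand-in for raw probe measurements (no raw instrument data
#' are bundled): converts a true Rd vector into a voltage time series via
#' per-channel responsivities, then applies gain, a dark offset, optional
#' linear drift and relative Gaussian noise. The inverse of this
#' fabrication is exactly the measurement pipeline
#' ([correctFrames()] + [buildCalibration()] + [toReflectance()]), which
#' makes closed-loop end-to-end tests possible.
#'
#' @param rdTrue True Rd vector, one value per channel of `geometry`.
#' @param geometry A [ProbeGeometry-class].
#' @param responsivity Volts of corrected signal per unit Rd, per channel
#'   (recycled).
#' @param gain Gain setting per channel (recycled; one of 0.5, 1, 10).
#' @param dark Dark voltage per channel (recycled).
#' @param nFrames Number of time points (sampled at 1 Hz).
#' @param sigma Relative noise SD applied to the light signal.
#' @param driftPerHour Fractional drift of the light signal per hour.
#' @param seed Integer seed.
#' @return A voltage-frame `data.frame` (see [readVoltageFrames()]).
#' @export
simulateVoltageFrames <- function(rdTrue, geometry, responsivity = 100,
    gain = 1, dark = 0.05, nFrames = 10, sigma = 0.05, driftPerHour = 0,
    seed = 1) {
  ch <- channels(geometry)
  nc <- nrow(ch)
  stopifnot(length(rdTrue) == nc)
  responsivity <- rep_len(responsivity, nc)
  gain <- rep_len(gain, nc)
  dark <- rep_len(dark, nc)
  .withSeed(seed, {
    frames <- do.call(rbind, lapply(seq_len(nFrames), function(t) {
      light <- rdTrue * responsivity *
        (1 + driftPerHour * (t - 1) / 3600) *
        (1 + rnorm(nc, 0, sigma))
      data.frame(time_s = t - 1, wavelength_nm = ch$wavelength_nm,
        separation_mm = ch$separation_mm,
        Vp = (light + dark) * gain, Vd = dark * gain, gain = gain)
    }))
    frames
  })
}
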