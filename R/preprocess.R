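#' Preprocessing configuration
#'
#' Controls the signal-conditioning chain applied before the first network
#' stage: offset removal and energy scaling, airflow inversion, zero-phase
#' low-pass filtering, and inter-channel phase alignment.
#'
#' @param A Dimensionless scaling constant: with `A = 0.5` a unit-amplitude
#'   sine maps to unit amplitude after scaling, keeping signals roughly in
#'   `(-1, 1)`.
#' @param filter_order Butterworth order (even, positive); applied
#'   forward-backward so the effective magnitude response is `|H(f)|^2` and
#'   phase is preserved.
#' @param cutoff_hz Low-pass cutoff in Hz (breathing lives below ~0.5 Hz;
#'   1.25 Hz keeps breath morphology and removes sensor noise).
#' @param max_lag_s Phase-alignment search bound in seconds.
#' @param invert_airflow Multiply the airflow channel by -1 after scaling
#'   (thermal airflow sensors are commonly inverted relative to effort
#'   belts); toggleable per dataset.
#' @param align Run cross-correlation phase alignment (toggleable: some
#'   recorders show no inter-channel lag).
#' @param quality_energy_threshold Per-channel energy-per-second threshold
#'   for [quality_pass()]; the default rejects channels that are
#'   indistinguishable from the simulator's noise floor.
#' @param target_rate_hz Working sample rate; inputs at other rates are
#'   linearly resampled.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(A = 0.5, filter_order = 8, cutoff_hz = 1.25,
                              max_lag_s = 5, invert_airflow = TRUE,
                              align = TRUE,
                              quality_energy_threshold = 0.05,
                              target_rate_hz = 10) {
  stopifnot(filter_order > 0, filter_order %% 2 == 0,
            cutoff_hz > 0, max_lag_s >= 0, target_rate_hz > 0,
            cutoff_hz < target_rate_hz / 2)
  structure(list(A = A, filter_order = filter_order, cutoff_hz = cutoff_hz,
                 max_lag_s = max_lag_s, invert_airflow = invert_airflow,
                 align = align,
                 quality_energy_threshold = quality_energy_threshold,
                 target_rate_hz = target_rate_hz),
            class = "preprocess_config")
}

#' Linear resampling onto a new rate
#'
#' Values on the new grid are linear interpolants of the input; total
#' duration is preserved. Used e.g. to bring 8 Hz recordings to the 10 Hz
#' working rate.
#'
#' @param series Numeric vector.
#' @param from_hz,to_hz Source and target rates in Hz.
#' @return Numeric vector of length `round(length(series) * to_hz/from_hz)`.
#' @export
resample_linear <- function(series, from_hz, to_hz) {
  stopifnot(from_hz > 0, to_hz > 0)
  if (from_hz == to_hz) return(series)
  n <- length(series)
  n_out <- round(n * to_hz / from_hz)
  t_in <- (seq_len(n) - 1) / from_hz
  t_out <- (seq_len(n_out) - 1) / to_hz
  y <- approx(t_in, series, xout = t_out, rule = 2)$y
  # the new grid can extend past the last input sample (duration is
  # preserved); continue the last segment's slope there
  over <- t_out > t_in[n]
  if (any(over) && n >= 2) {
    slope <- (series[n] - series[n - 1]) * from_hz
    y[over] <- series[n] + slope * (t_out[over] - t_in[n])
  }
  y
}

#' Record quality screen by signal energy
#'
#' Per channel, the signal energy is divided by the recording length; a
#' record passes only when all three channels reach the threshold. Records
#' with one or more channels indistinguishable from noise are excluded
#' before training/inference, and the same check flags low-quality inputs
#' at inference time.
#'
#' @param record A [polygraph_record()].
#' @param threshold Energy-per-second threshold.
#' @return List with `energy_rate` (named per channel) and `pass`.
#' @export
quality_pass <- function(record, threshold) {
  stopifnot(record$duration_s > 0)
  er <- vapply(CHANNELS, function(ch) sum(record[[ch]]^2), 0) /
    record$duration_s
  list(energy_rate = er, pass = all(er >= threshold))
}

#' Offset removal and energy scaling of one signal
#'
#' Removes the mean, then multiplies by the scaling factor
#' `SF = A * N / sum(|x(n)|^2)` (sum over the offset-removed signal), which
#' evens out amplitude differences between patients and sensors. For a
#' unit-amplitude sine and `A = 0.5`, `SF -> 1`.
#'
#' @param series Numeric vector.
#' @param A Scaling constant.
#' @return Scaled series with the applied factor in attribute `"SF"`.
#' @export
scale_signal <- function(series, A = 0.5) {
  if (!length(series)) stop("empty series")
  x <- series - mean(series)
  ss <- sum(x^2)
  if (ss == 0) stop("degenerate signal: zero energy after offset removal")
  sf <- A * length(x) / ss
  structure(sf * x, SF = sf)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Designs a digital Butterworth low-pass and applies it forward and
#' backward (`signal::filtfilt`), preserving phase; the effective magnitude
#' response is the squared one-pass response.
#'
#' @param series Numeric vector.
#' @param order Filter order.
#' @param cutoff_hz Cutoff frequency, Hz.
#' @param sample_rate_hz Sampling rate, Hz.
#' @return Filtered series.
#' @export
lowpass_zero_phase <- function(series, order = 8, cutoff_hz = 1.25,
                               sample_rate_hz = 10) {
  stopifnot(cutoff_hz < sample_rate_hz / 2)
  if (length(series) <= 3 * (order + 1))
    stop("series shorter than the filter warm-up length")
  bf <- signal::butter(order, cutoff_hz / (sample_rate_hz / 2), "low")
  as.numeric(signal::filtfilt(bf, series))
}

# Normalized cross-correlation of chan against ref at integer lag l
# (positive l means chan lags ref by l samples, i.e. chan[n + l] ~ ref[n]).
ncc_at_lag <- function(chan, ref, l) {
  n <- length(ref)
  if (l >= 0) { a <- chan[(1 + l):n]; b <- ref[1:(n - l)] }
  else        { a <- chan[1:(n + l)]; b <- ref[(1 - l):n] }
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}

#' Inter-channel phase alignment by cross-correlation
#'
#' Respiration sensors can show mutual time lags of up to a few seconds.
#' The airflow and abdominal channels are shifted by the integer-sample lag
#' (within `max_lag_s`) that maximizes their normalized cross-correlation
#' with the thoracic channel, which stays fixed so that annotations remain
#' valid. Shifted-in samples are zero-filled. Sub-sample alignment is not
#' attempted: downstream temporal resolution is 0.5 s.
#'
#' @param record A preprocessed [polygraph_record()] (scaled, filtered,
#'   airflow already inverted).
#' @param max_lag_s Search bound in seconds.
#' @return List of class `alignment_result`: `aligned`
#'   ([polygraph_record()]), `lags_s` (named applied shifts; thoracic is 0;
#'   a negative value means the channel was found delayed and was shifted
#'   back), and `at_bound` (named flags, `TRUE` when the search hit the
#'   bound and the true lag may be larger).
#' @export
align_phases <- function(record, max_lag_s = 5) {
  fs <- record$sample_rate_hz
  L <- round(max_lag_s * fs)
  ref <- record$thoracic
  out <- record
  lags_s <- c(airflow = 0, thoracic = 0, abdominal = 0)
  at_bound <- c(airflow = FALSE, thoracic = FALSE, abdominal = FALSE)
  for (ch in c("airflow", "abdominal")) {
    x <- record[[ch]]
    cc <- vapply(-L:L, function(l) ncc_at_lag(x, ref, l), 0)
    l_best <- (-L:L)[which.max(cc)]
    at_bound[ch] <- abs(l_best) == L && L > 0
    if (l_best != 0) {
      n <- length(x)
      shifted <- numeric(n)
      if (l_best > 0) shifted[1:(n - l_best)] <- x[(1 + l_best):n]
      else shifted[(1 - l_best):n] <- x[1:(n + l_best)]
      out[[ch]] <- shifted
    }
    lags_s[ch] <- -l_best / fs
  }
  structure(list(aligned = out, lags_s = lags_s, at_bound = at_bound),
            class = "alignment_result")
}

#' Full preprocessing chain for one record
#'
#' Resamples to the working rate if needed, removes offsets and applies the
#' energy scaling per channel, inverts airflow, applies the zero-phase
#' Butterworth low-pass, and aligns channel phases.
#'
#' @param record A [polygraph_record()].
#' @param config A [preprocess_config()].
#' @return The preprocessed [polygraph_record()] with the
#'   `alignment_result` stored in attribute `"alignment"` (or `NULL` when
#'   alignment is disabled).
#' @export
preprocess_record <- function(record, config = preprocess_config()) {
  fs0 <- record$sample_rate_hz
  fs <- config$target_rate_hz
  ch <- lapply(CHANNELS, function(nm) {
    x <- record[[nm]]
    if (fs0 != fs) x <- resample_linear(x, fs0, fs)
    x <- as.numeric(scale_signal(x, config$A))
    if (nm == "airflow" && config$invert_airflow) x <- -x
    lowpass_zero_phase(x, config$filter_order, config$cutoff_hz, fs)
  })
  rec <- polygraph_record(ch[[1]], ch[[2]], ch[[3]], fs)
  al <- NULL
  if (config$align) {
    al <- align_phases(rec, config$max_lag_s)
    rec <- al$aligned
  }
  attr(rec, "alignment") <- al
  rec
}
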