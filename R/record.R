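#' Three-channel polygraphy record
#'
#' Container for one respiratory polygraphy recording: oronasal airflow
#' (thermal sensor), thoracic and abdominal respiratory effort, sampled on a
#' common grid. All pipeline times are in seconds, intervals are half-open
#' `[start, end)`, and sample `n` (1-based) covers `[(n-1)/fs, n/fs)`.
#'
#' @param airflow,thoracic,abdominal Numeric vectors of equal length.
#' @param sample_rate_hz Sampling rate in Hz.
#' @return An object of class `polygraph_record` with fields `airflow`,
#'   `thoracic`, `abdominal`, `sample_rate_hz` and `duration_s`.
#' @export
polygraph_record <- function(airflow, thoracic, abdominal, sample_rate_hz) {
  n <- length(airflow)
  if (length(thoracic) != n || length(abdominal) != n)
    stop("all three channels must have equal length")
  if (sample_rate_hz <= 0) stop("sample_rate_hz must be positive")
  structure(list(airflow = as.numeric(airflow),
                 thoracic = as.numeric(thoracic),
                 abdominal = as.numeric(abdominal),
                 sample_rate_hz = sample_rate_hz,
                 duration_s = n / sample_rate_hz),
            class = "polygraph_record")
}

CHANNELS <- c("airflow", "thoracic", "abdominal")

#' @export
print.polygraph_record <- function(x, ...) {
  cat(sprintf("<polygraph_record> %.1f s at %g Hz (%d samples/channel)\n",
              x$duration_s, x$sample_rate_hz,
              length(x$airflow)))
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  force(code)
}

# Is point t inside any half-open [start, end) interval of `intervals`
# (a data.frame with start_s/end_s)? Vectorized over t.
point_in_intervals <- function(t, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L)
    return(rep(FALSE, length(t)))
  hit <- rep(FALSE, length(t))
  for (k in seq_len(nrow(intervals)))
    hit <- hit | (t >= intervals$start_s[k] & t < intervals$end_s[k])
  hit
}
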