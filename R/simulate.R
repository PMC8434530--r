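#' Configuration for the synthetic polygraphy simulator
#'
#' Describes one simulated overnight (or shorter) polygraphy recording.
#' Breathing is modelled as a quasi-periodic sinusoid whose amplitude
#' envelope wanders slowly (an Ornstein--Uhlenbeck process), reflecting that
#' normal breathing amplitude changes over the night. Apnea episodes
#' multiply the envelope by `apnea_depth` (fraction of amplitude remaining,
#' at most 0.10, i.e. an amplitude drop of at least 90%); hypopnea episodes
#' multiply it by `hypopnea_depth` (0.30--0.70 remaining, i.e. a drop of at
#' least 30%). Episode edges use a raised-cosine ramp so onsets are visible
#' but not discontinuous. Optional wake intervals superimpose broadband
#' movement-artifact bursts.
#'
#' @param duration_s Recording length in seconds (integer seconds).
#' @param sample_rate_hz Sampling rate, Hz.
#' @param breath_freq_hz Breathing frequency, Hz (normal adult breathing is
#'   roughly 0.2--0.3 Hz).
#' @param channel_amplitudes Positive amplitudes for (airflow, thoracic,
#'   abdominal).
#' @param channel_lags_s Carrier time lags in seconds for (airflow,
#'   thoracic, abdominal) relative to the thoracic channel; defaults are
#'   nonzero for airflow and abdominal so phase alignment is exercised.
#' @param noise_sd Additive white Gaussian noise SD (signal units).
#' @param apnea_depth Fraction of breathing amplitude remaining during an
#'   apnea; must be <= 0.10.
#' @param hypopnea_depth Fraction remaining during a hypopnea; in
#'   `[0.30, 0.70]`.
#' @param episode_duration_range_s Length-2 vector of episode duration
#'   bounds in seconds; minimum must be >= 10 (clinically scoreable events).
#' @param n_apnea,n_hypopnea Episode counts to place at random,
#'   non-overlapping positions.
#' @param wake_intervals List of `c(start_s, end_s)` wake intervals.
#' @param envelope_sd,envelope_tau_s SD and correlation time of the
#'   slow amplitude-envelope wander (set `envelope_sd = 0` for a constant
#'   envelope).
#' @param edge_ramp_s Raised-cosine ramp length at episode edges, seconds.
#' @param wake_artifact_sd SD of movement-artifact bursts during wake.
#' @param episodes Optional data.frame (`class`, `start_s`, `end_s`) of
#'   explicitly requested episodes instead of random placement; overlapping
#'   requests are rejected with a message identifying the collision.
#' @param seed Integer seed; a fixed config + seed reproduces the record
#'   exactly.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(duration_s = 1800, sample_rate_hz = 10,
                       breath_freq_hz = 0.25,
                       channel_amplitudes = c(1.0, 0.8, 0.9),
                       channel_lags_s = c(0.8, 0, -0.5),
                       noise_sd = 0.05,
                       apnea_depth = 0.05, hypopnea_depth = 0.5,
                       episode_duration_range_s = c(15, 45),
                       n_apnea = 6, n_hypopnea = 6,
                       wake_intervals = list(),
                       envelope_sd = 0.1, envelope_tau_s = 60,
                       edge_ramp_s = 2, wake_artifact_sd = 0.4,
                       episodes = NULL, seed = 1L) {
  if (duration_s <= 0) stop("duration_s must be positive")
  if (sample_rate_hz <= 0) stop("sample_rate_hz must be positive")
  if (apnea_depth < 0 || apnea_depth > 0.10)
    stop("apnea_depth must be in [0, 0.10] (amplitude drop of at least 90%)")
  if (hypopnea_depth < 0.30 || hypopnea_depth > 0.70)
    stop("hypopnea_depth must be in [0.30, 0.70] (drop of at least 30%)")
  if (length(channel_amplitudes) != 3 || any(channel_amplitudes <= 0))
    stop("channel_amplitudes must be 3 positive values")
  if (length(channel_lags_s) != 3)
    stop("channel_lags_s must have 3 values (airflow, thoracic, abdominal)")
  if (length(episode_duration_range_s) != 2 ||
      episode_duration_range_s[1] < 10 ||
      diff(episode_duration_range_s) < 0)
    stop("episode_duration_range_s must be an increasing pair with min >= 10")
  cfg <- list(duration_s = duration_s, sample_rate_hz = sample_rate_hz,
              breath_freq_hz = breath_freq_hz,
              channel_amplitudes = channel_amplitudes,
              channel_lags_s = channel_lags_s, noise_sd = noise_sd,
              apnea_depth = apnea_depth, hypopnea_depth = hypopnea_depth,
              episode_duration_range_s = episode_duration_range_s,
              n_apnea = n_apnea, n_hypopnea = n_hypopnea,
              wake_intervals = wake_intervals, envelope_sd = envelope_sd,
              envelope_tau_s = envelope_tau_s, edge_ramp_s = edge_ramp_s,
              wake_artifact_sd = wake_artifact_sd, episodes = episodes,
              seed = as.integer(seed))
  if (!is.null(episodes)) validate_episode_request(episodes, duration_s)
  class(cfg) <- "sim_config"
  cfg
}

validate_episode_request <- function(episodes, duration_s) {
  stopifnot(all(c("class", "start_s", "end_s") %in% names(episodes)))
  if (any(episodes$start_s < 0 | episodes$end_s > duration_s))
    stop("requested episodes must lie within [0, duration_s)")
  if (any(episodes$end_s - episodes$start_s < 10))
    stop("requested episodes must last at least 10 s")
  ep <- episodes[order(episodes$start_s), ]
  if (nrow(ep) > 1) {
    for (k in 2:nrow(ep)) {
      if (ep$start_s[k] < ep$end_s[k - 1])
        stop(sprintf(
          "overlapping requested episodes: [%g, %g) collides with [%g, %g)",
          ep$start_s[k - 1], ep$end_s[k - 1], ep$start_s[k], ep$end_s[k]))
    }
  }
  invisible(ep)
}

# Random non-overlapping episode placement with a guard gap around
# episodes, wake intervals and record edges.
place_episodes <- function(cfg, gap_s = 20) {
  n_ep <- cfg$n_apnea + cfg$n_hypopnea
  if (n_ep == 0L)
    return(data.frame(class = character(0), start_s = numeric(0),
                      end_s = numeric(0)))
  classes <- sample(c(rep("apnea", cfg$n_apnea),
                      rep("hypopnea", cfg$n_hypopnea)))
  durations <- runif(n_ep, cfg$episode_duration_range_s[1],
                     cfg$episode_duration_range_s[2])
  blocked <- do.call(rbind, lapply(cfg$wake_intervals, function(w)
    data.frame(start_s = w[1], end_s = w[2])))
  placed <- data.frame(class = character(0), start_s = numeric(0),
                       end_s = numeric(0))
  for (k in order(durations, decreasing = TRUE)) {
    d <- durations[k]
    ok <- FALSE
    for (try in seq_len(4000L)) {
      s <- runif(1, gap_s, cfg$duration_s - gap_s - d)
      cand <- c(s - gap_s, s + d + gap_s)
      clash <- function(iv) !is.null(iv) && nrow(iv) > 0 &&
        any(iv$start_s < cand[2] & iv$end_s > cand[1])
      if (!clash(placed) && !clash(blocked)) { ok <- TRUE; break }
    }
    if (!ok)
      stop("could not place all requested episodes without overlap; ",
           "reduce counts/durations or enlarge duration_s")
    placed <- rbind(placed, data.frame(class = classes[k], start_s = s,
                                       end_s = s + d))
  }
  placed <- placed[order(placed$start_s), c("class", "start_s", "end_s")]
  rownames(placed) <- NULL
  placed
}

#' Generate one synthetic polygraphy record
#'
#' Produces three amplitude-modulated sinusoidal breathing channels with
#' per-channel amplitude and carrier lag, a slowly wandering envelope,
#' additive Gaussian noise, amplitude suppression inside apnea/hypopnea
#' intervals, and optional wake-time movement artifacts. The ground-truth
#' annotations share the thoracic time base (episode modulation is applied
#' at common time, only the breathing carrier is lagged per channel).
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_record`: `record` ([polygraph_record()]),
#'   `annotations` (data.frame `class`, `start_s`, `end_s`, half-open
#'   intervals), `wake` (data.frame of wake intervals) and `config`.
#' @export
generate_record <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    fs <- config$sample_rate_hz
    n <- round(config$duration_s * fs)
    t <- (seq_len(n) - 1) / fs

    ann <- if (!is.null(config$episodes))
      validate_episode_request(config$episodes, config$duration_s)
    else place_episodes(config)

    # slow amplitude-envelope wander (AR(1) ~ discretized OU)
    env <- rep(1, n)
    if (config$envelope_sd > 0) {
      a <- exp(-1 / (fs * config$envelope_tau_s))
      innov <- rnorm(n, 0, config$envelope_sd * sqrt(1 - a^2))
      env <- pmax(1 + as.numeric(stats::filter(innov, a, "recursive")), 0.2)
    }

    # episode depth factor with raised-cosine edges
    depth <- rep(1, n)
    ramp <- config$edge_ramp_s
    for (k in seq_len(nrow(ann))) {
      d0 <- if (ann$class[k] == "apnea") config$apnea_depth
            else config$hypopnea_depth
      s <- ann$start_s[k]; e <- ann$end_s[k]
      idx <- which(t >= s & t < e)
      dk <- rep(d0, length(idx))
      tk <- t[idx]
      dn <- tk < s + ramp
      dk[dn] <- d0 + (1 - d0) * 0.5 * (1 + cos(pi * (tk[dn] - s) / ramp))
      up <- tk >= e - ramp
      dk[up] <- d0 + (1 - d0) * 0.5 * (1 + cos(pi * (e - tk[up]) / ramp))
      depth[idx] <- dk
    }

    wake <- if (length(config$wake_intervals))
      data.frame(start_s = vapply(config$wake_intervals, `[`, 0, 1),
                 end_s = vapply(config$wake_intervals, `[`, 0, 2))
    else data.frame(start_s = numeric(0), end_s = numeric(0))

    artifact <- rep(0, n)
    if (nrow(wake) > 0 && config$wake_artifact_sd > 0) {
      for (k in seq_len(nrow(wake))) {
        len <- wake$end_s[k] - wake$start_s[k]
        n_bursts <- max(1L, stats::rpois(1, len / 10))
        for (b in seq_len(n_bursts)) {
          bs <- runif(1, wake$start_s[k], max(wake$start_s[k],
                                              wake$end_s[k] - 3))
          bd <- runif(1, 0.5, 3)
          idx <- which(t >= bs & t < min(bs + bd, wake$end_s[k]))
          artifact[idx] <- artifact[idx] +
            rnorm(length(idx), 0, config$wake_artifact_sd)
        }
      }
    }

    # base breathing waveform on the thoracic (annotation) time base; each
    # channel observes it with its own sensor delay, so envelope, episode
    # modulation and carrier are all lagged together
    base <- env * depth * sin(2 * pi * config$breath_freq_hz * t)
    chan <- function(i, polarity = 1) {
      lag <- config$channel_lags_s[i]
      delayed <- if (lag == 0) base
                 else approx(t, base, xout = t - lag, rule = 2)$y
      polarity * config$channel_amplitudes[i] * (delayed + artifact) +
        rnorm(n, 0, config$noise_sd)
    }
    # airflow polarity is inverted, emulating thermal airflow sensors that
    # read opposite in sign to the effort belts (undone in preprocessing)
    rec <- polygraph_record(chan(1, polarity = -1), chan(2), chan(3), fs)
    structure(list(record = rec, annotations = ann, wake = wake,
                   config = config),
              class = "sim_record")
  })
}

#' Generate a reproducible corpus of synthetic records
#'
#' Per-record seeds are derived deterministically from the master seed, so
#' the same master seed always yields bitwise-identical channel data.
#'
#' @param n_records Number of records (>= 1).
#' @param config Base [sim_config()] applied to every record.
#' @param seed Master seed.
#' @param config_sampler Optional `function(i)` returning the `sim_config`
#'   for record `i` (its seed is still overridden by the derived seed).
#' @return List of `sim_record` objects.
#' @export
generate_corpus <- function(n_records, config = sim_config(),
                            seed = config$seed, config_sampler = NULL) {
  stopifnot(n_records >= 1)
  lapply(seq_len(n_records), function(i) {
    cfg <- if (is.null(config_sampler)) config else config_sampler(i)
    cfg$seed <- as.integer((as.numeric(seed) * 1009 + i * 7919) %% 2147483647)
    generate_record(cfg)
  })
}
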