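# Minimal EDF (European Data Format) reader/writer for three-channel
# respiratory recordings. EDF stores an ASCII header plus 16-bit
# little-endian samples in fixed-duration data records (1 s here), so a
# write/read round trip is exact up to the per-channel quantization step
# (physical range / 65535). No installed R package provides EDF, hence this
# small self-contained implementation.

pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

num8 <- function(x) pad(formatC(x, format = "g", digits = 6), 8)

#' Write a polygraphy record to an EDF file
#'
#' Signals are quantized to 16-bit over their per-channel physical range.
#' The record duration must be a whole number of seconds and
#' `sample_rate_hz` an integer, since EDF data records are written with a
#' 1-second duration.
#'
#' @param record A [polygraph_record()].
#' @param path Output file path.
#' @param labels Channel labels written into the EDF header, in (airflow,
#'   thoracic, abdominal) order.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path,
                      labels = c("Airflow", "Thor RES", "Abdo RES")) {
  stopifnot(inherits(record, "polygraph_record"))
  fs <- record$sample_rate_hz
  if (fs != round(fs)) stop("EDF writer requires an integer sample rate")
  n <- length(record$airflow)
  if (n %% fs != 0)
    stop("EDF writer requires a whole number of seconds of data")
  n_rec <- n %/% fs
  ns <- 3L

  sig <- lapply(CHANNELS, function(ch) record[[ch]])
  rng <- lapply(sig, function(x) {
    r <- range(x)
    if (diff(r) == 0) r <- r + c(-1, 1)
    # round-trip through the 8-char header representation so that the
    # scaling used for encoding matches exactly what a reader will parse
    c(as.numeric(num8(r[1])), as.numeric(num8(r[2])))
  })
  dig <- mapply(function(x, r) {
    v <- round((x - r[1]) / (r[2] - r[1]) * 65535 - 32768)
    as.integer(pmin(pmax(v, -32768), 32767))
  }, sig, rng, SIMPLIFY = FALSE)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchar(s), eos = NULL)
  wr(pad("0", 8))
  wr(pad("X X X X", 80))
  wr(pad("Startdate 01-JAN-2026 X X X", 80))
  wr(pad("01.01.26", 8)); wr(pad("00.00.00", 8))
  wr(pad(256 * (ns + 1), 8))
  wr(pad("", 44))
  wr(pad(n_rec, 8))
  wr(pad("1", 8))
  wr(pad(ns, 4))
  for (l in labels) wr(pad(l, 16))
  for (i in 1:ns) wr(pad("synthetic", 80))
  for (i in 1:ns) wr(pad("au", 8))
  for (r in rng) wr(num8(r[1]))
  for (r in rng) wr(num8(r[2]))
  for (i in 1:ns) wr(pad("-32768", 8))
  for (i in 1:ns) wr(pad("32767", 8))
  for (i in 1:ns) wr(pad("", 80))
  for (i in 1:ns) wr(pad(fs, 8))
  for (i in 1:ns) wr(pad("", 32))
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in 1:ns) writeBin(dig[[i]][idx], con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a three-channel respiratory EDF file
#'
#' Channels are located by matching header labels against the (regex)
#' patterns in `channel_map`, so files from different recorders can be read
#' by adjusting the map.
#'
#' @param path EDF file path.
#' @param channel_map Named character vector of case-insensitive regular
#'   expressions locating the `airflow`, `thoracic` and `abdominal`
#'   channels among the EDF signal labels.
#' @return A [polygraph_record()].
#' @export
read_edf <- function(path,
                     channel_map = c(airflow = "air|flow",
                                     thoracic = "thor",
                                     abdominal = "abdo|abd")) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(k) trimws(readChar(con, k, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(1:ns, function(i) rd(16), "")
  for (i in 1:ns) rd(80)
  for (i in 1:ns) rd(8)
  pmin_ <- vapply(1:ns, function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(1:ns, function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(1:ns, function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(1:ns, function(i) as.numeric(rd(8)), 0)
  for (i in 1:ns) rd(80)
  spr <- vapply(1:ns, function(i) as.integer(rd(8)), 0L)
  for (i in 1:ns) rd(32)

  raw <- lapply(1:ns, function(i) integer(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in 1:ns) {
      v <- readBin(con, "integer", n = spr[i], size = 2, endian = "little",
                   signed = TRUE)
      raw[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <- v
    }
  }
  phys <- lapply(1:ns, function(i)
    (raw[[i]] - dmin[i]) / (dmax[i] - dmin[i]) * (pmax_[i] - pmin_[i]) +
      pmin_[i])

  find <- function(role) {
    hit <- grep(channel_map[[role]], labels, ignore.case = TRUE)
    if (!length(hit))
      stop(sprintf("missing channel '%s': no EDF label matches '%s' (%s)",
                   role, channel_map[[role]],
                   paste(labels, collapse = ", ")))
    hit[1]
  }
  fs <- spr[find("airflow")] / rec_dur
  polygraph_record(phys[[find("airflow")]], phys[[find("thoracic")]],
                   phys[[find("abdominal")]], fs)
}
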