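# Episode/wake annotation sidecars: plain CSV or JSON with columns
# class (apnea | hypopnea | wake), start_s, end_s. Intervals are half-open
# [start_s, end_s) in seconds from the start of the recording.

ANNOTATION_CLASSES <- c("apnea", "hypopnea", "wake")

#' Read an annotation sidecar file
#'
#' @param path CSV (`class,start_s,end_s`) or JSON (array of objects with
#'   those fields) annotation file.
#' @return A data.frame with columns `class`, `start_s`, `end_s`, validated
#'   and sorted by start time. Rows of class `wake` describe wake intervals
#'   and can be separated with [split_wake()].
#' @export
read_annotations <- function(path) {
  ann <- if (grepl("\\.json$", path, ignore.case = TRUE))
    as.data.frame(jsonlite::fromJSON(path))
  else read.csv(path, stringsAsFactors = FALSE)
  if (nrow(ann) == 0L)
    return(data.frame(class = character(0), start_s = numeric(0),
                      end_s = numeric(0)))
  need <- c("class", "start_s", "end_s")
  if (!all(need %in% names(ann)))
    stop("annotation file must have columns class, start_s, end_s")
  ann <- ann[need]
  for (i in seq_len(nrow(ann))) {
    if (!ann$class[i] %in% ANNOTATION_CLASSES)
      stop(sprintf("annotation row %d: unknown class '%s'", i, ann$class[i]))
    if (!is.finite(ann$start_s[i]) || !is.finite(ann$end_s[i]) ||
        ann$end_s[i] <= ann$start_s[i])
      stop(sprintf("annotation row %d: end_s (%s) must exceed start_s (%s)",
                   i, ann$end_s[i], ann$start_s[i]))
  }
  ann[order(ann$start_s), , drop = FALSE]
}

#' Write an annotation sidecar file
#'
#' @param annotations Data.frame with `class`, `start_s`, `end_s` (extra
#'   columns such as `certainty` are preserved in the output).
#' @param path Destination; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(annotations, path, digits = NA, auto_unbox = FALSE)
  else write.csv(annotations, path, row.names = FALSE)
  invisible(path)
}

#' Split combined annotations into episodes and wake intervals
#'
#' @param annotations Data.frame as returned by [read_annotations()].
#' @return List with `episodes` (apnea/hypopnea rows) and `wake`
#'   (`start_s`/`end_s` of wake intervals).
#' @export
split_wake <- function(annotations) {
  w <- annotations$class == "wake"
  list(episodes = annotations[!w, , drop = FALSE],
       wake = annotations[w, c("start_s", "end_s"), drop = FALSE])
}

#' Read a record together with its annotation sidecar
#'
#' @param edf_path Path to the EDF signal file.
#' @param annotation_path Optional sidecar with episode (and possibly wake)
#'   annotations.
#' @param channel_map Passed to [read_edf()].
#' @return List with `record`, `annotations` (episodes only) and `wake`.
#' @export
read_record <- function(edf_path, annotation_path = NULL,
                        channel_map = c(airflow = "air|flow",
                                        thoracic = "thor",
                                        abdominal = "abdo|abd")) {
  record <- read_edf(edf_path, channel_map)
  ann <- data.frame(class = character(0), start_s = numeric(0),
                    end_s = numeric(0))
  wake <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (!is.null(annotation_path)) {
    parts <- split_wake(read_annotations(annotation_path))
    ann <- parts$episodes
    wake <- parts$wake
  }
  list(record = record, annotations = ann, wake = wake)
}
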