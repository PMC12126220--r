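# Plain-text (CSV) readers and writers for the pipeline's data types.

#' Write / read a trace matrix as CSV
#'
#' Neurons as rows; first column `neuron_id`, remaining columns samples.
#' The sampling rate is not stored in the CSV and must be supplied on read.
#'
#' @param tm A [trace_matrix()].
#' @param path Output path.
#' @return `write_traces_csv` returns `path` invisibly.
#' @export
write_traces_csv <- function(tm, path) {
  df <- data.frame(neuron_id = rownames(tm),
                   unclass(tm), check.names = FALSE)
  colnames(df) <- c("neuron_id", sprintf("s%d", seq_len(ncol(tm))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @param rate_hz Sampling rate of the stored traces.
#' @export
read_traces_csv <- function(path, rate_hz) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  trace_matrix(m, rate_hz, neuron_ids = as.character(df[[1]]))
}

#' Write / read an event schedule as CSV
#'
#' Columns: event_type, onset_s, duration_s.
#'
#' @param schedule Event data frame.
#' @param path File path.
#' @export
write_events_csv <- function(schedule, path) {
  utils::write.csv(schedule[, c("event_type", "onset_s", "duration_s")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  validate_schedule(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a linkage tree as a 4-column merge table
#'
#' Text format with one row per merge: `left`, `right` (negative values are
#' leaf indices, positive values earlier merges, as in [stats::hclust]),
#' `height`, and `size` of the merged cluster.
#'
#' @param linkage An [stats::hclust] object.
#' @param path File path.
#' @export
write_linkage_csv <- function(linkage, path) {
  n <- nrow(linkage$merge)
  size <- integer(n)
  for (i in seq_len(n)) {
    s <- function(j) if (j < 0) 1L else size[j]
    size[i] <- s(linkage$merge[i, 1]) + s(linkage$merge[i, 2])
  }
  utils::write.csv(data.frame(left = linkage$merge[, 1],
                              right = linkage$merge[, 2],
                              height = linkage$height,
                              size = size),
                   path, row.names = FALSE)
  invisible(path)
}
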