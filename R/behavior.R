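# Freezing quantification and cue/context generalization indices.

#' Percentage of time frozen in an interval
#'
#' @param series Data frame (time_s, freezing) with binary freezing per
#'   frame.
#' @param interval Numeric `c(start_s, end_s)`, half-open `[start, end)`.
#' @return Percentage in \[0, 100\].
#' @export
freezing_percentage <- function(series, interval) {
  stopifnot(all(c("time_s", "freezing") %in% names(series)),
            length(interval) == 2)
  sel <- series$time_s >= interval[1] & series$time_s < interval[2]
  if (!any(sel)) stop("empty interval: no frames in [",
                      interval[1], ", ", interval[2], ")")
  f <- series$freezing[sel]
  if (!all(f %in% c(0, 1))) stop("freezing values must be 0/1")
  100 * sum(f) / length(f)
}

#' Per-tone freezing percentages for a session
#'
#' @param series Freezing data frame.
#' @param schedule Event data frame.
#' @param tone_type Tone type to extract.
#' @return Numeric vector, one percentage per presentation.
#' @export
freezing_per_tone <- function(series, schedule, tone_type) {
  rows <- schedule[schedule$event_type == tone_type, , drop = FALSE]
  if (nrow(rows) == 0) stop("no events of type ", tone_type)
  vapply(seq_len(nrow(rows)), function(i)
    freezing_percentage(series, c(rows$onset_s[i],
                                  rows$onset_s[i] + rows$duration_s[i])),
    numeric(1))
}

#' Average per-tone freezing into blocks
#'
#' Means of consecutive pairs (default block 2) in presentation order. A
#' trailing unpaired tone is kept as its own block with a warning, since
#' sessions with odd tone counts occur in partial-reinforcement designs.
#'
#' @param percents Per-tone freezing percentages.
#' @param block Tones per block (default 2).
#' @return Per-block percentages.
#' @export
tone_blocks <- function(percents, block = 2) {
  n <- length(percents)
  if (n < 1) stop("need at least 1 tone")
  full <- n %/% block
  out <- vapply(seq_len(full), function(b)
    mean(percents[((b - 1) * block + 1):(b * block)]), numeric(1))
  if (n %% block != 0) {
    warning("trailing unpaired tone kept as its own block")
    out <- c(out, mean(percents[(full * block + 1):n]))
  }
  out
}

#' Generalization index
#'
#' Freezing to the neutral cue/context relative to freezing to the trained
#' reference (CS+ for cue paradigms; the conditioning context on the last
#' conditioning day for context paradigms). The default convention is the
#' ratio neutral/reference; a difference convention (neutral - reference) is
#' available for sensitivity analyses.
#'
#' @param freeze_neutral,freeze_reference Freezing percentages in \[0, 100\].
#' @param mode `"ratio"` (default) or `"difference"`.
#' @return List of class `generalization_index`: `value` (NA and
#'   `flagged = TRUE` when the ratio reference is 0), `mode`, inputs.
#' @export
generalization_index <- function(freeze_neutral, freeze_reference,
                                 mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  stopifnot(all(freeze_neutral >= 0 & freeze_neutral <= 100),
            all(freeze_reference >= 0 & freeze_reference <= 100))
  if (mode == "ratio") {
    flagged <- freeze_reference == 0
    value <- ifelse(flagged, NA_real_, freeze_neutral / freeze_reference)
  } else {
    flagged <- rep(FALSE, length(freeze_neutral))
    value <- freeze_neutral - freeze_reference
  }
  structure(list(value = value, flagged = flagged, mode = mode,
                 numerator = freeze_neutral, denominator = freeze_reference),
            class = "generalization_index")
}

#' @export
print.generalization_index <- function(x, ...) {
  cat(sprintf("<generalization_index> mode=%s\n", x$mode))
  print(x$value)
  invisible(x)
}
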