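# Peri-tone alignment: 1-s binning, block averaging, pre-tone Z-scoring.

#' Construct a trace matrix
#'
#' Container for neurons-by-timepoints activity sampled at a fixed rate.
#'
#' @param values Numeric matrix, neurons as rows, timepoints as columns.
#' @param rate_hz Sampling rate in Hz (> 0).
#' @param neuron_ids Optional character vector of stable neuron identifiers.
#' @return An object of class `trace_matrix` (a matrix with `rate_hz` and
#'   rownames carrying the ids).
#' @export
trace_matrix <- function(values, rate_hz, neuron_ids = NULL) {
  values <- as.matrix(values)
  stopifnot(rate_hz > 0, !anyNA(values))
  if (is.null(neuron_ids)) {
    neuron_ids <- rownames(values)
    if (is.null(neuron_ids)) neuron_ids <- sprintf("n%04d", seq_len(nrow(values)))
  }
  stopifnot(length(neuron_ids) == nrow(values))
  rownames(values) <- neuron_ids
  structure(values, rate_hz = rate_hz, class = c("trace_matrix", "matrix"))
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<trace_matrix> %d neurons x %d timepoints @ %g Hz (%.1f s)\n",
              nrow(x), ncol(x), attr(x, "rate_hz"),
              ncol(x) / attr(x, "rate_hz")))
  invisible(x)
}

bin_indices <- function(onset_s, b, rate_hz) {
  first <- as.integer(round((onset_s + b) * rate_hz)) + 1L
  last <- as.integer(round((onset_s + b + 1) * rate_hz))
  c(first, last)
}

#' Align traces to tone onsets and bin into 1-second intervals
#'
#' For every presentation of `tone_type`, extracts the window from `pre_s`
#' seconds before onset to `tone_s` seconds after and averages samples into
#' 1-second bins. Bin `b` covers the half-open interval
#' `[onset + b, onset + b + 1)` seconds, with `b = 0` starting at tone onset
#' and negative bins forming the pre-tone baseline.
#'
#' @param traces A [trace_matrix()].
#' @param schedule Event data frame (event_type, onset_s, duration_s).
#' @param tone_type One of `"NT"`, `"CS_PLUS"`, `"CS_MINUS"`.
#' @param pre_s Pre-tone baseline length in seconds (default 15).
#' @param tone_s Tone period length in seconds (default 15).
#' @return 3-d array `[neuron, trial, bin]` of class `aligned_tensor`, with
#'   dimnames on the bin axis giving the bin start offsets, and attributes
#'   `pre_bins`, `tone_bins`, `tone_type`.
#' @export
align_and_bin <- function(traces, schedule, tone_type,
                          pre_s = 15, tone_s = 15) {
  stopifnot(inherits(traces, "trace_matrix"))
  validate_schedule(schedule)
  rate <- attr(traces, "rate_hz")
  onsets <- schedule$onset_s[schedule$event_type == tone_type]
  if (length(onsets) == 0)
    stop("no events of type ", tone_type, " in schedule")
  bins <- seq.int(-pre_s, tone_s - 1)
  out <- array(NA_real_,
               dim = c(nrow(traces), length(onsets), length(bins)),
               dimnames = list(rownames(traces), NULL, bins))
  for (tr in seq_along(onsets)) {
    lim <- c(bin_indices(onsets[tr], -pre_s, rate)[1],
             bin_indices(onsets[tr], tone_s - 1, rate)[2])
    if (lim[1] < 1 || lim[2] > ncol(traces))
      stop(sprintf(
        "peri-tone window out of recording range for %s onset at %g s",
        tone_type, onsets[tr]))
    for (k in seq_along(bins)) {
      ii <- bin_indices(onsets[tr], bins[k], rate)
      out[, tr, k] <- rowMeans(traces[, ii[1]:ii[2], drop = FALSE])
    }
  }
  structure(out, pre_bins = as.integer(pre_s), tone_bins = as.integer(tone_s),
            tone_type = tone_type, class = "aligned_tensor")
}

#' Average aligned trials into blocks
#'
#' Trials are averaged element-wise in presentation order into consecutive
#' blocks of `block_size` (default 2, matching the pipeline's block-of-2
#' presentation averaging). A trailing unpaired trial is dropped with a
#' warning.
#'
#' @param tensor An `aligned_tensor` from [align_and_bin()].
#' @param block_size Trials per block.
#' @return `aligned_tensor` with dims `[neuron, block, bin]`.
#' @export
block_average <- function(tensor, block_size = 2) {
  stopifnot(inherits(tensor, "aligned_tensor"), block_size >= 1)
  n_tr <- dim(tensor)[2]
  n_bl <- n_tr %/% block_size
  if (n_bl == 0) stop("fewer trials than block_size")
  if (n_tr %% block_size != 0)
    warning(sprintf("trial count %d not divisible by %d: dropping %d trailing trial(s)",
                    n_tr, block_size, n_tr %% block_size))
  out <- array(0, dim = c(dim(tensor)[1], n_bl, dim(tensor)[3]),
               dimnames = list(dimnames(tensor)[[1]], NULL,
                               dimnames(tensor)[[3]]))
  for (b in seq_len(n_bl)) {
    sel <- ((b - 1) * block_size + 1):(b * block_size)
    out[, b, ] <- apply(tensor[, sel, , drop = FALSE], c(1, 3), mean)
  }
  attributes(out)[c("pre_bins", "tone_bins", "tone_type", "class")] <-
    attributes(tensor)[c("pre_bins", "tone_bins", "tone_type", "class")]
  out
}

#' Z-score an aligned tensor against its pre-tone baseline
#'
#' Each neuron-by-block slice is Z-transformed using the mean and unbiased
#' (n-1) SD of that slice's own pre-tone baseline bins. Slices with zero
#' baseline SD are set to Z = 0 and flagged rather than erroring, so
#' degenerate (constant) traces do not abort batch runs.
#'
#' @param tensor An `aligned_tensor` (trial- or block-averaged).
#' @return An `aligned_ztensor`: same dims, Z-units, with a logical
#'   `flags` attribute (neuron x block) marking zero-SD baselines.
#' @export
ztransform_pretone <- function(tensor) {
  stopifnot(inherits(tensor, "aligned_tensor"))
  pre <- attr(tensor, "pre_bins")
  bins <- as.numeric(dimnames(tensor)[[3]])
  base_ix <- which(bins < 0)
  if (length(base_ix) < 2) stop("need at least 2 baseline bins")
  out <- tensor
  flags <- matrix(FALSE, dim(tensor)[1], dim(tensor)[2])
  for (i in seq_len(dim(tensor)[1])) {
    for (b in seq_len(dim(tensor)[2])) {
      x <- tensor[i, b, ]
      m <- mean(x[base_ix]); s <- stats::sd(x[base_ix])
      if (s == 0) {
        out[i, b, ] <- 0
        flags[i, b] <- TRUE
      } else {
        out[i, b, ] <- (x - m) / s
      }
    }
  }
  attr(out, "flags") <- flags
  class(out) <- "aligned_ztensor"
  attr(out, "pre_bins") <- pre
  out
}

#' Tone-period bins of a Z-scored tensor
#'
#' @param ztensor An `aligned_ztensor`.
#' @return Array `[neuron, block, tone bin]` restricted to bins >= 0.
#' @export
tone_period <- function(ztensor) {
  bins <- as.numeric(dimnames(ztensor)[[3]])
  ztensor[, , bins >= 0, drop = FALSE]
}

#' Whole-session Z-scored average stimulus response
#'
#' Averages the aligned raw traces of the first `n_avg` presentations of a
#' tone type, Z-scores that average against the neuron's whole-session mean
#' and SD, and averages the Z-score over the tone period, yielding one scalar
#' per neuron (the Z_NT / Z_CS+ inputs of the stimulus-preference index).
#' Neurons with zero whole-session SD get scalar 0 and a flag.
#'
#' @param traces A [trace_matrix()].
#' @param schedule Event data frame.
#' @param tone_type Tone type to average.
#' @param tone_s Tone period in seconds (default 15).
#' @param n_avg Number of presentations averaged (default 2; at least this
#'   many presentations must exist).
#' @return Named numeric vector (one scalar per neuron) with a logical
#'   `flags` attribute.
#' @export
ztransform_whole_session <- function(traces, schedule, tone_type,
                                     tone_s = 15, n_avg = 2) {
  stopifnot(inherits(traces, "trace_matrix"))
  rate <- attr(traces, "rate_hz")
  onsets <- schedule$onset_s[schedule$event_type == tone_type]
  if (length(onsets) < n_avg)
    stop("need at least ", n_avg, " presentations of ", tone_type)
  onsets <- onsets[seq_len(n_avg)]
  n_win <- as.integer(round(tone_s * rate))
  acc <- matrix(0, nrow(traces), n_win)
  for (o in onsets) {
    first <- as.integer(round(o * rate)) + 1L
    if (first + n_win - 1L > ncol(traces))
      stop("tone window out of recording range at onset ", o, " s")
    acc <- acc + traces[, first:(first + n_win - 1L), drop = FALSE]
  }
  acc <- acc / n_avg
  m <- rowMeans(traces)
  s <- apply(traces, 1, stats::sd)
  flags <- s == 0
  z <- numeric(nrow(traces))
  ok <- !flags
  z[ok] <- (rowMeans(acc[ok, , drop = FALSE]) - m[ok]) / s[ok]
  names(z) <- rownames(traces)
  attr(z, "flags") <- flags
  z
}
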