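# Two-channel photometry: downsampling, isosbestic dF/F, peri-tone
# Z-scoring, and freezing-based trial pooling.

#' Downsample a two-channel photometry recording
#'
#' Non-overlapping window means at the target rate; a trailing partial window
#' is truncated.
#'
#' @param phot Data frame (t, signal, isosbestic) with a `rate_hz` attribute.
#' @param target_hz Target rate (default 10); must not exceed the source
#'   rate.
#' @return Downsampled data frame with `rate_hz` set to `target_hz`.
#' @export
downsample_to <- function(phot, target_hz = 10) {
  rate <- attr(phot, "rate_hz")
  if (is.null(rate)) stop("photometry data frame lacks a rate_hz attribute")
  if (rate < target_hz) stop("target rate exceeds source rate")
  if (rate == target_hz) return(phot)
  if (abs(rate / target_hz - round(rate / target_hz)) > 1e-9)
    stop("source rate must be an integer multiple of the target rate")
  win <- (seq_len(nrow(phot)) - 1) %/% round(rate / target_hz)
  keep <- win < max(win) | (nrow(phot) %% round(rate / target_hz) == 0)
  agg <- function(x) as.numeric(tapply(x[keep], win[keep], mean))
  out <- data.frame(t = agg(phot$t), signal = agg(phot$signal),
                    isosbestic = agg(phot$isosbestic))
  out$t <- (seq_len(nrow(out)) - 1) / target_hz + phot$t[1]
  attr(out, "rate_hz") <- target_hz
  out
}

#' Isosbestic-corrected dF/F
#'
#' Fits the isosbestic (activity-independent) channel to the sensor channel
#' by ordinary least squares over the whole session and returns
#' `(signal - fit) / fit`, removing shared motion/bleaching artifacts while
#' preserving sensor-specific transients. A zero-variance isosbestic channel
#' triggers a flagged fallback to the session-median baseline.
#'
#' @param signal,isosbestic Numeric vectors, equal length, positive
#'   fluorescence.
#' @return Numeric dF/F vector with attribute `fallback` (TRUE when the
#'   median-F0 fallback was used).
#' @export
compute_dff <- function(signal, isosbestic) {
  stopifnot(length(signal) == length(isosbestic),
            all(is.finite(signal)), all(is.finite(isosbestic)))
  if (stats::var(isosbestic) == 0) {
    f0 <- stats::median(signal)
    if (f0 == 0) stop("degenerate signal: zero median")
    out <- (signal - f0) / f0
    attr(out, "fallback") <- TRUE
    return(out)
  }
  fit <- stats::lm.fit(cbind(1, isosbestic), signal)
  f0 <- drop(cbind(1, isosbestic) %*% fit$coefficients)
  if (any(f0 <= 0)) {
    f0 <- pmax(f0, .Machine$double.eps * max(abs(signal)))
  }
  out <- (signal - f0) / f0
  attr(out, "fallback") <- FALSE
  out
}

#' Peri-tone Z-scored photometry traces
#'
#' For each tone, Z-scores the window from `pre_s` before onset to `tone_s`
#' after against that trial's own pre-tone baseline mean/SD (sample level).
#'
#' @param dff Numeric dF/F vector.
#' @param rate_hz Sampling rate of `dff`.
#' @param schedule Event data frame.
#' @param tone_type Tone type to align to (default `"NT"`).
#' @param pre_s Baseline length in seconds (default 2).
#' @param tone_s Tone window in seconds (default 15).
#' @return Matrix trials x samples with attributes `time` (seconds relative
#'   to onset) and `tone_cols` (logical, samples within the tone window);
#'   zero-SD baselines give a zero row and a `flags` entry.
#' @export
align_z_pretone <- function(dff, rate_hz, schedule, tone_type = "NT",
                            pre_s = 2, tone_s = 15) {
  onsets <- schedule$onset_s[schedule$event_type == tone_type]
  if (length(onsets) == 0) stop("no events of type ", tone_type)
  n_pre <- as.integer(round(pre_s * rate_hz))
  n_tone <- as.integer(round(tone_s * rate_hz))
  n_win <- n_pre + n_tone
  out <- matrix(NA_real_, length(onsets), n_win)
  flags <- logical(length(onsets))
  for (i in seq_along(onsets)) {
    first <- as.integer(round((onsets[i] - pre_s) * rate_hz)) + 1L
    if (first < 1 || first + n_win - 1L > length(dff))
      stop("peri-tone window out of range at onset ", onsets[i], " s")
    w <- dff[first:(first + n_win - 1L)]
    base <- w[seq_len(n_pre)]
    s <- stats::sd(base)
    if (s == 0) {
      out[i, ] <- 0; flags[i] <- TRUE
    } else {
      out[i, ] <- (w - mean(base)) / s
    }
  }
  structure(out,
            time = (seq_len(n_win) - 1) / rate_hz - pre_s,
            tone_cols = (seq_len(n_win) - 1) / rate_hz - pre_s >= 0,
            flags = flags)
}

#' Peak Z response within the tone window
#'
#' @param z_trace Numeric Z-scored trace (one trial).
#' @param tone_cols Logical vector marking tone-window samples (defaults to
#'   the trace's `tone_cols` attribute).
#' @return Maximum Z within the tone window.
#' @export
peak_response <- function(z_trace, tone_cols = attr(z_trace, "tone_cols")) {
  if (is.null(tone_cols)) tone_cols <- rep(TRUE, length(z_trace))
  if (!any(tone_cols)) stop("empty tone window")
  max(z_trace[tone_cols])
}

#' Pool peri-tone responses by behavioral generalization level
#'
#' High-generalization pool: trials whose freezing exceeds 75%; low pool:
#' trials below 25%. Boundary and intermediate trials are excluded (strict
#' inequalities). Empty pools are flagged, not errors.
#'
#' @param trial_z Matrix trials x samples from [align_z_pretone()].
#' @param trial_freezing Freezing percentage per trial.
#' @param high,low Pool thresholds (default 75, 25).
#' @return List: `high`/`low` each with `trials`, `mean_trace`, `peaks`;
#'   `excluded` trial indices; `flags` naming empty pools.
#' @export
split_by_generalization <- function(trial_z, trial_freezing,
                                    high = 75, low = 25) {
  stopifnot(nrow(trial_z) == length(trial_freezing))
  tone_cols <- attr(trial_z, "tone_cols")
  hi <- which(trial_freezing > high)
  lo <- which(trial_freezing < low)
  pool <- function(idx) {
    if (length(idx) == 0)
      return(list(trials = integer(0), mean_trace = NULL, peaks = numeric(0)))
    zz <- trial_z[idx, , drop = FALSE]
    mt <- colMeans(zz)
    attr(mt, "tone_cols") <- tone_cols
    list(trials = idx,
         mean_trace = mt,
         peaks = apply(zz, 1, peak_response, tone_cols = tone_cols))
  }
  flags <- c(if (length(hi) == 0) "empty_high_pool",
             if (length(lo) == 0) "empty_low_pool")
  list(high = pool(hi), low = pool(lo),
       excluded = setdiff(seq_along(trial_freezing), c(hi, lo)),
       flags = flags)
}
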