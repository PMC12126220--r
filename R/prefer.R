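# Signed stimulus-preference-strength index and distribution comparison.

#' Stimulus preference strength
#'
#' The magnitude is `|z_nt - z_cs| / (|z_nt| + |z_cs|)`, bounded in \[0, 1\].
#' The sign is positive when `|z_nt| > |z_cs|` (NT-preferring), negative when
#' `|z_nt| < |z_cs|` (CS+-preferring). Exact ties in absolute value yield a
#' signed value of 0 with the magnitude recorded separately and a `tie` flag,
#' so histograms are not skewed by an arbitrary sign choice; a zero
#' denominator (both scalars 0) yields 0 with a `zero_denom` flag.
#'
#' @param z_nt,z_cs Numeric vectors (recycled to common length) of
#'   whole-session Z-scored average responses from
#'   [ztransform_whole_session()].
#' @return Data frame (z_nt, z_cs, magnitude, value, flag) of class
#'   `preference_index`; `flag` is "" / "tie" / "zero_denom".
#' @export
preference_strength <- function(z_nt, z_cs) {
  n <- max(length(z_nt), length(z_cs))
  z_nt <- rep_len(z_nt, n); z_cs <- rep_len(z_cs, n)
  if (!all(is.finite(z_nt)) || !all(is.finite(z_cs)))
    stop("preference inputs must be finite")
  denom <- abs(z_nt) + abs(z_cs)
  mag <- ifelse(denom > 0, abs(z_nt - z_cs) / denom, 0)
  sgn <- sign(abs(z_nt) - abs(z_cs))
  value <- sgn * mag
  flag <- ifelse(denom == 0, "zero_denom",
                 ifelse(sgn == 0, "tie", ""))
  value[flag == "tie"] <- 0
  out <- data.frame(z_nt = z_nt, z_cs = z_cs, magnitude = mag,
                    value = value, flag = flag, stringsAsFactors = FALSE)
  class(out) <- c("preference_index", "data.frame")
  out
}

#' Compare two preference distributions (two-sample Kolmogorov-Smirnov)
#'
#' @param valuesA,valuesB Numeric vectors of preference values (n >= 2 each).
#' @return List: `D` (sup-norm ECDF distance), `p_value` (asymptotic
#'   two-sided), `n1`, `n2`.
#' @export
preference_distribution_compare <- function(valuesA, valuesB) {
  if (length(valuesA) < 2 || length(valuesB) < 2)
    stop("each group needs at least 2 values")
  kt <- suppressWarnings(
    stats::ks.test(valuesA, valuesB, alternative = "two.sided",
                   exact = FALSE))
  list(D = unname(kt$statistic), p_value = kt$p.value,
       n1 = length(valuesA), n2 = length(valuesB))
}

#' Histogram counts of preference values on [-1, 1]
#'
#' @param values Preference values.
#' @param n_bins Number of equal-width bins (default 20).
#' @return Data frame (bin_left, bin_right, count).
#' @export
preference_histogram <- function(values, n_bins = 20) {
  br <- seq(-1, 1, length.out = n_bins + 1)
  h <- hist(values, breaks = br, plot = FALSE, include.lowest = TRUE)
  data.frame(bin_left = br[-length(br)], bin_right = br[-1],
             count = h$counts)
}
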