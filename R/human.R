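# Human fear-potentiated startle: ITI standardization, CS generalization,
# endocannabinoid baselines, correlation/regression with bootstrap CI.

#' Standardize startle amplitudes to the ITI mean
#'
#' Within each subject and phase, the cue response is the mean peak-to-peak
#' amplitude over that cue's trials divided by the mean over that phase's ITI
#' trials, removing individual differences in startle gain. At recall, only
#' the first 4 trials per cue enter (the CS generalization test window).
#' Subjects with a zero ITI mean in a phase are excluded from that phase and
#' logged.
#'
#' @param table Data frame (subject_id, trial_index, trial_type, amplitude,
#'   phase) with trial_type in CS_PLUS / CS_MINUS / ITI.
#' @param method `"ratio"` (default, division by ITI mean) or
#'   `"difference"` (subtraction of ITI mean).
#' @param recall_trials Number of leading recall trials per cue used
#'   (default 4).
#' @return Data frame (subject_id, phase, cue, standardized) with an
#'   attribute `excluded` listing dropped subject/phase pairs.
#' @export
standardize_startle <- function(table, method = c("ratio", "difference"),
                                recall_trials = 4) {
  method <- match.arg(method)
  stopifnot(all(c("subject_id", "trial_index", "trial_type",
                  "amplitude", "phase") %in% names(table)),
            all(table$amplitude >= 0))
  out <- list(); excluded <- list()
  for (sid in unique(table$subject_id)) {
    for (ph in unique(table$phase[table$subject_id == sid])) {
      sub <- table[table$subject_id == sid & table$phase == ph, ]
      iti <- sub$amplitude[sub$trial_type == "ITI"]
      if (length(iti) == 0)
        stop("subject ", sid, " has no ITI trials in phase ", ph)
      iti_mean <- mean(iti)
      if (method == "ratio" && iti_mean == 0) {
        excluded[[length(excluded) + 1]] <-
          data.frame(subject_id = sid, phase = ph, reason = "zero ITI mean")
        next
      }
      for (cue in c("CS_PLUS", "CS_MINUS")) {
        tr <- sub[sub$trial_type == cue, ]
        if (nrow(tr) == 0) next
        tr <- tr[order(tr$trial_index), ]
        if (ph == "recall") tr <- utils::head(tr, recall_trials)
        s <- if (method == "ratio") mean(tr$amplitude) / iti_mean
             else mean(tr$amplitude) - iti_mean
        out[[length(out) + 1]] <-
          data.frame(subject_id = sid, phase = ph, cue = cue,
                     standardized = s, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  attr(res, "excluded") <- if (length(excluded))
    do.call(rbind, excluded) else NULL
  res
}

#' Per-subject CS generalization score
#'
#' The difference (CS-) - (CS+) of ITI-standardized startle at recall: higher
#' values mean the never-reinforced cue evokes startle closer to (or beyond)
#' the threat cue, i.e. more generalization.
#'
#' @param standardized Output of [standardize_startle()].
#' @param phase Phase to score (default "recall").
#' @return Data frame (subject_id, generalization).
#' @export
cs_generalization <- function(standardized, phase = "recall") {
  sub <- standardized[standardized$phase == phase, ]
  ids <- unique(sub$subject_id)
  score <- vapply(ids, function(sid) {
    sp <- sub$standardized[sub$subject_id == sid & sub$cue == "CS_PLUS"]
    sm <- sub$standardized[sub$subject_id == sid & sub$cue == "CS_MINUS"]
    if (length(sp) != 1 || length(sm) != 1) return(NA_real_)
    sm - sp
  }, numeric(1))
  data.frame(subject_id = ids, generalization = score,
             stringsAsFactors = FALSE)
}

#' Per-subject log endocannabinoid baseline
#'
#' Baseline is the mean of the two measurement time points, natural-log
#' transformed (the distribution of raw plasma values is right-skewed).
#'
#' @param ecb Data frame (subject_id, analyte, value_t1, value_t2).
#' @param analyte Analyte to extract (default "2AG").
#' @return Data frame (subject_id, log_baseline).
#' @export
ecb_baseline <- function(ecb, analyte = "2AG") {
  sub <- ecb[ecb$analyte == analyte, ]
  if (nrow(sub) == 0) stop("no rows for analyte ", analyte)
  if (any(sub$value_t1 <= 0 | sub$value_t2 <= 0))
    stop("endocannabinoid values must be positive for the log transform")
  data.frame(subject_id = sub$subject_id,
             log_baseline = log((sub$value_t1 + sub$value_t2) / 2),
             stringsAsFactors = FALSE)
}

#' Correlate generalization scores with endocannabinoid baselines
#'
#' Complete-case Pearson correlation with two-sided p, plus a linear
#' regression of generalization on the log baseline with a case-resampling
#' bootstrap percentile CI for the slope.
#'
#' @param scores Data frame (subject_id, generalization).
#' @param log_ecb Data frame (subject_id, log_baseline).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap (required).
#' @return List: `r`, `p_value`, `slope`, `slope_ci` (2.5/97.5 percentile),
#'   `n`, `n_dropped`.
#' @export
associate <- function(scores, log_ecb, n_boot = 1000, seed) {
  if (missing(seed)) stop("bootstrap seed is required")
  m <- merge(scores, log_ecb, by = "subject_id")
  m <- m[stats::complete.cases(m$generalization, m$log_baseline), ]
  n_dropped <- length(union(scores$subject_id, log_ecb$subject_id)) - nrow(m)
  if (nrow(m) < 3) stop("need at least 3 complete cases")
  ct <- stats::cor.test(m$log_baseline, m$generalization,
                        method = "pearson", alternative = "two.sided")
  fit <- stats::lm(generalization ~ log_baseline, data = m)
  slope <- unname(stats::coef(fit)[2])
  set.seed(as.integer(seed))
  bs <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(nrow(m), replace = TRUE)
    x <- m$log_baseline[idx]; y <- m$generalization[idx]
    if (stats::var(x) == 0) return(NA_real_)
    stats::cov(x, y) / stats::var(x)
  }, numeric(1))
  ci <- unname(stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE))
  list(r = unname(ct$estimate), p_value = ct$p.value,
       slope = slope, slope_ci = ci,
       n = nrow(m), n_dropped = n_dropped)
}
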