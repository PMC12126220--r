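# Threshold-based responsive-neuron classification and the 9-type taxonomy.

RESPONSE_LABELS <- c("PLUS", "MINUS", "NONE")

# All qualifying n_consec windows of one sign; returns start bins (0-based)
# and window mean |z|.
qualifying_windows <- function(z, threshold, n_consec, sign) {
  hit <- if (sign > 0) z > threshold else z < -threshold
  n <- length(z) - n_consec + 1
  if (n < 1) return(NULL)
  starts <- which(vapply(seq_len(n), function(i)
    all(hit[i:(i + n_consec - 1)]), logical(1)))
  if (length(starts) == 0) return(NULL)
  list(start = starts - 1L,
       score = vapply(starts, function(i)
         mean(abs(z[i:(i + n_consec - 1)])), numeric(1)))
}

#' Classify a neuron's tone response from tone-period Z-scores
#'
#' A trace is (+)responsive if any `n_consec` consecutive tone-period bins all
#' exceed `+threshold` Z, (-)responsive if any such run falls below
#' `-threshold`, and non-responsive otherwise. If qualifying runs of both
#' signs exist, the label follows the run with the larger mean |Z|.
#'
#' @param z Numeric vector of tone-period Z-scores (bin 0 = tone onset first).
#' @param threshold Z threshold (default 3).
#' @param n_consec Required consecutive bins (default 2).
#' @return List of class `response_label`: `label` in PLUS/MINUS/NONE and
#'   `trigger_bin`, the 0-based first bin of the winning run (NA when NONE).
#' @export
classify_response <- function(z, threshold = 3, n_consec = 2) {
  if (length(z) < n_consec)
    stop("need at least ", n_consec, " tone-period bins")
  stopifnot(all(is.finite(z)))
  plus <- qualifying_windows(z, threshold, n_consec, +1)
  minus <- qualifying_windows(z, threshold, n_consec, -1)
  pick <- function(w) w$start[which.max(w$score)]
  if (!is.null(plus) && !is.null(minus)) {
    if (max(plus$score) >= max(minus$score))
      out <- list(label = "PLUS", trigger_bin = pick(plus))
    else out <- list(label = "MINUS", trigger_bin = pick(minus))
  } else if (!is.null(plus)) {
    out <- list(label = "PLUS", trigger_bin = plus$start[1])
  } else if (!is.null(minus)) {
    out <- list(label = "MINUS", trigger_bin = minus$start[1])
  } else {
    out <- list(label = "NONE", trigger_bin = NA_integer_)
  }
  structure(out, class = "response_label")
}

#' Classify every neuron of a Z-scored tensor
#'
#' Applies [classify_response()] to the tone period of each neuron-by-block
#' slice and combines blocks: a neuron is labelled by the qualifying run with
#' the largest mean |Z| across its blocks, or NONE if no block qualifies.
#'
#' @param ztensor An `aligned_ztensor` (typically block-averaged).
#' @inheritParams classify_response
#' @return Data frame (neuron_id, label, trigger_bin, block).
#' @export
classify_neurons <- function(ztensor, threshold = 3, n_consec = 2) {
  zt <- tone_period(ztensor)
  n <- dim(zt)[1]; nb <- dim(zt)[2]
  label <- character(n); trig <- rep(NA_integer_, n); blk <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    best <- NULL
    for (b in seq_len(nb)) {
      z <- zt[i, b, ]
      p <- qualifying_windows(z, threshold, n_consec, +1)
      m <- qualifying_windows(z, threshold, n_consec, -1)
      for (cand in list(list(w = p, lab = "PLUS"),
                        list(w = m, lab = "MINUS"))) {
        if (is.null(cand$w)) next
        j <- which.max(cand$w$score)
        if (is.null(best) || cand$w$score[j] > best$score) {
          best <- list(score = cand$w$score[j], lab = cand$lab,
                       trig = cand$w$start[j], block = b)
        }
      }
    }
    if (is.null(best)) {
      label[i] <- "NONE"
    } else {
      label[i] <- best$lab; trig[i] <- best$trig; blk[i] <- best$block
    }
  }
  data.frame(neuron_id = dimnames(zt)[[1]], label = label,
             trigger_bin = trig, block = blk, stringsAsFactors = FALSE)
}

#' Per-trial classification labels
#'
#' Classifies each trial of an un-block-averaged Z-scored tensor separately;
#' input for [consecutive_tone_stability()].
#'
#' @inheritParams classify_neurons
#' @return Character matrix `[neuron, trial]` of labels.
#' @export
classify_per_trial <- function(ztensor, threshold = 3, n_consec = 2) {
  zt <- tone_period(ztensor)
  out <- matrix(NA_character_, dim(zt)[1], dim(zt)[2],
                dimnames = list(dimnames(zt)[[1]], NULL))
  for (i in seq_len(dim(zt)[1]))
    for (tr in seq_len(dim(zt)[2]))
      out[i, tr] <- classify_response(zt[i, tr, ], threshold, n_consec)$label
  out
}

#' Build the 9-type NT-by-CS+ response taxonomy
#'
#' Crosses each neuron's NT label with its CS+ label: 3 response patterns per
#' stimulus, 2 stimuli, 9 combined types. The "dual" aggregate collects every
#' type whose two labels are both non-NONE.
#'
#' @param labels_nt,labels_cs Data frames from [classify_neurons()] covering
#'   identical neuron ids.
#' @return Object of class `response_taxonomy`: data frame `per_neuron`
#'   (neuron_id, nt_label, cs_label, type_code), named `counts` and
#'   `proportions` over the 9 types, and `dual_proportion`.
#' @export
response_taxonomy <- function(labels_nt, labels_cs) {
  if (!setequal(labels_nt$neuron_id, labels_cs$neuron_id) ||
      nrow(labels_nt) != nrow(labels_cs))
    stop("NT and CS+ label sets must cover identical neuron ids")
  cs <- labels_cs[match(labels_nt$neuron_id, labels_cs$neuron_id), ]
  types <- as.vector(outer(RESPONSE_LABELS, RESPONSE_LABELS,
                           function(a, b) paste(a, b, sep = "/")))
  code <- paste(labels_nt$label, cs$label, sep = "/")
  counts <- table(factor(code, levels = types))
  per_neuron <- data.frame(neuron_id = labels_nt$neuron_id,
                           nt_label = labels_nt$label,
                           cs_label = cs$label,
                           type_code = code, stringsAsFactors = FALSE)
  props <- as.numeric(counts) / nrow(per_neuron)
  names(props) <- types
  dual <- labels_nt$label != "NONE" & cs$label != "NONE"
  structure(list(per_neuron = per_neuron,
                 counts = setNames(as.integer(counts), types),
                 proportions = props,
                 dual_proportion = mean(dual),
                 n = nrow(per_neuron)),
            class = "response_taxonomy")
}

#' @export
print.response_taxonomy <- function(x, ...) {
  cat(sprintf("<response_taxonomy> %d neurons; dual-responsive %.1f%%\n",
              x$n, 100 * x$dual_proportion))
  nz <- x$counts[x$counts > 0]
  for (i in seq_along(nz))
    cat(sprintf("  %-12s %5d  (%.1f%%)\n", names(nz)[i], nz[i],
                100 * nz[i] / x$n))
  invisible(x)
}

#' Aggregate taxonomy counts
#'
#' Convenience extractors for the aggregates used in group comparisons:
#' `"dual"` (both labels non-NONE), `"any"` (at least one non-NONE),
#' `"nt_plus"`, `"nt_minus"`, `"cs_plus"`, `"cs_minus"` (per-stimulus sign
#' regardless of the other stimulus), or a full `"NT/CS"` type code.
#'
#' @param taxonomy A `response_taxonomy`.
#' @param what Aggregate name or 9-type code.
#' @return Integer count of neurons in the aggregate.
#' @export
taxonomy_count <- function(taxonomy, what) {
  pn <- taxonomy$per_neuron
  n <- switch(what,
    dual = sum(pn$nt_label != "NONE" & pn$cs_label != "NONE"),
    any = sum(pn$nt_label != "NONE" | pn$cs_label != "NONE"),
    nt_plus = sum(pn$nt_label == "PLUS"),
    nt_minus = sum(pn$nt_label == "MINUS"),
    cs_plus = sum(pn$cs_label == "PLUS"),
    cs_minus = sum(pn$cs_label == "MINUS"),
    {
      if (!what %in% names(taxonomy$counts))
        stop("unknown taxonomy aggregate or type code: ", what)
      taxonomy$counts[[what]]
    })
  as.integer(n)
}

#' Compare a response-type proportion between two groups
#'
#' Builds the 2x2 table (in-type vs not) x (group A vs B) and computes the
#' two-sided Fisher exact p-value from the hypergeometric distribution, plus
#' the sample odds ratio.
#'
#' @param taxonomyA,taxonomyB `response_taxonomy` objects (or lists with
#'   elements `count` and `n` for pre-tabulated counts).
#' @param what Aggregate or type code passed to [taxonomy_count()].
#' @return List: `odds_ratio` (sample OR; NaN when degenerate), `p_value`,
#'   `table`.
#' @export
compare_type_proportions <- function(taxonomyA, taxonomyB, what = "dual") {
  get <- function(tx) {
    if (inherits(tx, "response_taxonomy"))
      c(taxonomy_count(tx, what), tx$n)
    else c(tx$count, tx$n)
  }
  a <- get(taxonomyA); b <- get(taxonomyB)
  if (a[2] == 0 || b[2] == 0) stop("empty group")
  tab <- matrix(c(a[1], a[2] - a[1], b[1], b[2] - b[1]), nrow = 2,
                dimnames = list(c("in_type", "not"), c("A", "B")))
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  or <- (tab[1, 1] * tab[2, 2]) / (tab[2, 1] * tab[1, 2])
  list(odds_ratio = or, p_value = p, table = tab)
}

#' Proportion of neurons responsive on consecutive tone presentations
#'
#' A neuron counts iff its per-trial classification is non-NONE on at least
#' two adjacent presentations of the tone type (an ensemble-stability
#' measure).
#'
#' @param labels_by_trial Character matrix `[neuron, trial]` from
#'   [classify_per_trial()] for one tone type, trials in presentation order.
#' @return List: `proportion`, logical `stable` per neuron.
#' @export
consecutive_tone_stability <- function(labels_by_trial) {
  if (ncol(labels_by_trial) < 2)
    stop("need at least 2 presentations")
  resp <- labels_by_trial != "NONE"
  stable <- apply(resp, 1, function(r)
    any(r[-length(r)] & r[-1]))
  list(proportion = mean(stable), stable = stable)
}

#' Spontaneous calcium-event rate in a tone-free window
#'
#' Bins the window into 1-s bins, Z-scores each neuron against the window's
#' own bin mean/SD, and counts excursions where Z exceeds +3 for >= 2
#' consecutive bins (the same rule as tone classification, applied to
#' spontaneous activity), each excursion counted once.
#'
#' @param traces A [trace_matrix()].
#' @param schedule Event data frame; the window must not overlap any event.
#' @param window Numeric `c(start_s, end_s)`.
#' @param threshold,n_consec Excursion rule parameters.
#' @return Numeric vector, events per minute per neuron.
#' @export
spontaneous_event_rate <- function(traces, schedule, window,
                                   threshold = 3, n_consec = 2) {
  stopifnot(inherits(traces, "trace_matrix"), length(window) == 2,
            window[2] > window[1])
  ev_start <- schedule$onset_s
  ev_end <- schedule$onset_s + schedule$duration_s
  if (any(ev_start < window[2] & ev_end > window[1]))
    stop("window overlaps scheduled events")
  rate <- attr(traces, "rate_hz")
  n_bins <- floor(window[2] - window[1])
  if (n_bins < n_consec) stop("window too short")
  binned <- sapply(seq_len(n_bins), function(b) {
    ii <- bin_indices(window[1], b - 1, rate)
    rowMeans(traces[, ii[1]:ii[2], drop = FALSE])
  })
  if (is.null(dim(binned))) binned <- matrix(binned, nrow = nrow(traces))
  counts <- apply(binned, 1, function(x) {
    s <- stats::sd(x)
    if (s == 0) return(0L)
    z <- (x - mean(x)) / s
    r <- rle(z > threshold)
    sum(r$values & r$lengths >= n_consec)
  })
  counts / (n_bins / 60)
}
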