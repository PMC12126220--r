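# Clustergram procedure: bounded rescale, Ward linkage, 5%-of-max cut,
# remap to unscaled Z-traces.

#' Bounded linear rescale of Z-traces
#'
#' Maps `[in_min, in_max]` linearly onto `[out_min, out_max]`, saturating
#' values outside the input range. The defaults (-5..5 onto -3..3) damp the
#' influence of neurons with very large Z excursions on the clustering while
#' preserving the activity pattern.
#'
#' @param x Numeric vector/matrix of Z-scores.
#' @param out_min,out_max Output range (default -3, 3).
#' @param in_min,in_max Input range (default -5, 5); must satisfy
#'   `in_min < in_max`.
#' @return Rescaled object of the same shape.
#' @export
rescale_bounded <- function(x, out_min = -3, out_max = 3,
                            in_min = -5, in_max = 5) {
  if (in_min >= in_max) stop("in_min must be < in_max")
  stopifnot(all(is.finite(x)))
  out_min + (pmin(pmax(x, in_min), in_max) - in_min) *
    (out_max - out_min) / (in_max - in_min)
}

#' Concatenate per-neuron NT and CS+ mean response traces
#'
#' Averages each Z-scored tensor over blocks and concatenates the NT trace
#' followed by the CS+ trace per neuron, the feature layout used for
#' clustering and population geometry.
#'
#' @param zt_nt,zt_cs `aligned_ztensor` objects over the same neurons.
#' @param tone_only If TRUE (default) use tone-period bins only.
#' @return Matrix neurons x (2 * bins) with an `nt_cols` attribute giving the
#'   NT segment width.
#' @export
concat_stimulus_traces <- function(zt_nt, zt_cs, tone_only = TRUE) {
  pick <- function(zt) {
    if (tone_only) zt <- tone_period(zt)
    apply(zt, c(1, 3), mean)
  }
  a <- pick(zt_nt); b <- pick(zt_cs)
  stopifnot(identical(rownames(a), rownames(b)))
  out <- cbind(a, b)
  attr(out, "nt_cols") <- ncol(a)
  out
}

#' Ward hierarchical clustering of response traces
#'
#' Agglomerative clustering with Ward's minimum-variance criterion on
#' Euclidean distances between neurons' (rescaled) concatenated NT+CS+
#' traces. Deterministic for a given input order.
#'
#' @param rescaled Matrix neurons x features, no missing values.
#' @return An [stats::hclust] tree; merge heights are non-decreasing.
#' @export
ward_cluster <- function(rescaled) {
  rescaled <- as.matrix(rescaled)
  if (nrow(rescaled) < 2) stop("need at least 2 neurons to cluster")
  if (anyNA(rescaled) || any(!is.finite(rescaled)))
    stop("non-finite values in clustering input")
  stats::hclust(stats::dist(rescaled, method = "euclidean"),
                method = "ward.D2")
}

#' Cut a Ward tree at a fraction of its maximum linkage and remap profiles
#'
#' Removes merges whose height exceeds `frac` times the largest merge height;
#' the remaining connected components are the clusters. Cluster mean profiles
#' are computed from the unscaled Z-traces so magnitudes are faithful.
#'
#' @param linkage An [stats::hclust] tree from [ward_cluster()].
#' @param unscaled_z Matrix neurons x features of unscaled Z-traces, same
#'   row order as the clustering input.
#' @param frac Height threshold as a fraction of the maximum linkage,
#'   in (0, 1] (default 0.05).
#' @return Object of class `cluster_result`: `linkage`, named `assignments`
#'   (neuron -> cluster id), `cluster_profiles` (clusters x features),
#'   `sizes`, `cut_height`.
#' @export
cut_and_remap <- function(linkage, unscaled_z, frac = 0.05) {
  stopifnot(inherits(linkage, "hclust"))
  if (!(frac > 0 && frac <= 1)) stop("frac must be in (0, 1]")
  unscaled_z <- as.matrix(unscaled_z)
  n <- length(linkage$order)
  if (nrow(unscaled_z) != n)
    stop("unscaled_z must have one row per clustered neuron")
  h <- frac * max(linkage$height)
  assignments <- stats::cutree(linkage, h = h)
  if (!is.null(rownames(unscaled_z))) names(assignments) <- rownames(unscaled_z)
  k <- max(assignments)
  profiles <- rowsum(unscaled_z, assignments) /
    as.vector(table(assignments))
  structure(list(linkage = linkage,
                 assignments = assignments,
                 cluster_profiles = profiles,
                 sizes = as.integer(table(assignments)),
                 cut_height = h,
                 n_clusters = k),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d neurons in %d clusters (cut height %.3g)\n",
              length(x$assignments), x$n_clusters, x$cut_height))
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Per-cluster response-type composition
#'
#' Cross-tabulates cluster membership with the 9-type taxonomy and reports
#' each cluster's mean-profile peak within the NT and CS+ trace segments.
#'
#' @param result A `cluster_result` with named assignments.
#' @param taxonomy A `response_taxonomy` covering the clustered neurons.
#' @param nt_cols Width of the NT segment in the profile features (defaults
#'   to half the features).
#' @return List: `composition` (clusters x 9-type count table),
#'   `segment_peaks` (data frame cluster, nt_peak, cs_peak, size).
#' @export
cluster_report <- function(result, taxonomy, nt_cols = NULL) {
  stopifnot(inherits(result, "cluster_result"),
            inherits(taxonomy, "response_taxonomy"))
  ids <- names(result$assignments)
  m <- match(ids, taxonomy$per_neuron$neuron_id)
  if (all(is.na(m))) stop("taxonomy does not cover any clustered neuron")
  if (anyNA(m)) stop("taxonomy missing some clustered neurons")
  types <- names(taxonomy$counts)
  comp <- table(cluster = result$assignments,
                type = factor(taxonomy$per_neuron$type_code[m],
                              levels = types))
  if (is.null(nt_cols)) nt_cols <- ncol(result$cluster_profiles) %/% 2
  prof <- result$cluster_profiles
  seg <- data.frame(
    cluster = seq_len(nrow(prof)),
    nt_peak = apply(prof[, seq_len(nt_cols), drop = FALSE], 1,
                    function(x) x[which.max(abs(x))]),
    cs_peak = apply(prof[, (nt_cols + 1):ncol(prof), drop = FALSE], 1,
                    function(x) x[which.max(abs(x))]),
    size = result$sizes)
  list(composition = comp, segment_peaks = seg)
}
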