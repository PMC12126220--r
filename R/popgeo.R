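# Population-vector geometry: matched population matrix, PCA trajectories,
# Mahalanobis and instantaneous Euclidean NT-vs-CS+ separation.

#' Build the matched two-group population matrix
#'
#' Per neuron, the NT and CS+ mean block traces are concatenated along time;
#' the larger group is subsampled without replacement (seeded) so both groups
#' contribute the same number of neurons; the group blocks are then stacked
#' along the neuron axis. Rows are time bins (NT bins then CS+ bins), columns
#' are neurons (group A block then matched group B block).
#'
#' @param traces_a,traces_b Matrices neurons x (2 * bins) from
#'   [concat_stimulus_traces()] for the two treatment groups (A = reference,
#'   e.g. vehicle; B = treated).
#' @param match_seed Integer seed for the subsampling; required so that the
#'   selection is reproducible.
#' @return Matrix (2 * bins) x (2 * n_matched) of class `population_matrix`
#'   with attributes `group` (per column), `nt_rows` (NT segment length),
#'   `selected` (row indices kept from the subsampled group), `match_seed`.
#' @export
build_population_matrix <- function(traces_a, traces_b, match_seed) {
  stopifnot(ncol(traces_a) == ncol(traces_b))
  if (missing(match_seed)) stop("match_seed is required")
  nt_cols <- attr(traces_a, "nt_cols")
  if (is.null(nt_cols)) nt_cols <- ncol(traces_a) %/% 2
  na <- nrow(traces_a); nb <- nrow(traces_b)
  sel_a <- seq_len(na); sel_b <- seq_len(nb)
  set.seed(as.integer(match_seed))
  if (nb > na) {
    sel_b <- sort(sample.int(nb, na))
  } else if (nb < na) {
    warning("treated group smaller than reference: subsampling reference")
    sel_a <- sort(sample.int(na, nb))
  }
  a <- traces_a[sel_a, , drop = FALSE]
  b <- traces_b[sel_b, , drop = FALSE]
  m <- t(rbind(a, b))  # rows: time bins; columns: neurons A-block then B-block
  structure(m,
            group = rep(c("A", "B"), c(nrow(a), nrow(b))),
            nt_rows = nt_cols,
            selected = list(A = sel_a, B = sel_b),
            match_seed = as.integer(match_seed),
            class = c("population_matrix", "matrix"))
}

#' PCA reduction and per-group, per-stimulus trajectories
#'
#' Rows (time bins) are observations and columns (neurons) are features,
#' mean-centered per feature. The score of a time bin decomposes as a sum
#' over neurons of centered activity times loading, so each group's
#' trajectory is its columns' partial projection; NT and CS+ trajectories are
#' the corresponding row segments.
#'
#' @param pop_matrix A `population_matrix`.
#' @param k Number of retained components (default 15); must not exceed
#'   `min(bins, neurons)`.
#' @return List of class `pca_trajectories`: `trajectories` (named list
#'   `A_NT`, `A_CS`, `B_NT`, `B_CS`, each bins x k), `variance_explained`
#'   (fraction per component, all components), `rotation`, `k`.
#' @export
pca_reduce <- function(pop_matrix, k = 15) {
  m <- unclass(pop_matrix)
  grp <- attr(pop_matrix, "group")
  nt_rows <- attr(pop_matrix, "nt_rows")
  if (k > min(dim(m))) stop("k exceeds min(bins, neurons)")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  centered <- sweep(m, 2, pc$center)
  seg <- list(NT = seq_len(nt_rows), CS = (nt_rows + 1):nrow(m))
  traj <- list()
  for (g in c("A", "B")) {
    cols <- grp == g
    part <- centered[, cols, drop = FALSE] %*%
      pc$rotation[cols, seq_len(k), drop = FALSE]
    for (s in names(seg))
      traj[[paste(g, s, sep = "_")]] <- part[seg[[s]], , drop = FALSE]
  }
  structure(list(trajectories = traj, variance_explained = ve,
                 rotation = pc$rotation, center = pc$center, k = k),
            class = "pca_trajectories")
}

#' Mahalanobis separation between two trajectories
#'
#' For each point (time bin) of trajectory A, the Mahalanobis distance to the
#' point cloud of trajectory B, using B's bin mean and covariance. Unless an
#' explicit covariance is supplied, the covariance is shrinkage-regularized
#' as `Sigma + lambda I` with `lambda = shrinkage * tr(Sigma) / K`, which
#' keeps the metric invertible when the number of bins is close to the
#' dimensionality.
#'
#' @param trajA,trajB Matrices bins x K in the same component basis.
#' @param cov Optional explicit covariance matrix for the reference cloud;
#'   when given it is used as-is (no shrinkage).
#' @param shrinkage Shrinkage coefficient (default 1e-3).
#' @return List: `distances` (one per bin of A), `mean_distance`, `K`.
#' @export
mahalanobis_separation <- function(trajA, trajB, cov = NULL,
                                   shrinkage = 1e-3) {
  stopifnot(ncol(trajA) == ncol(trajB))
  K <- ncol(trajA)
  mu <- colMeans(trajB)
  if (is.null(cov)) {
    sigma <- stats::cov(trajB)
    lambda <- shrinkage * sum(diag(sigma)) / K
    sigma <- sigma + diag(lambda, K)
  } else {
    sigma <- cov
  }
  d2 <- tryCatch(stats::mahalanobis(trajA, mu, sigma),
                 error = function(e)
                   stop("singular covariance after regularization"))
  d <- sqrt(pmax(d2, 0))
  list(distances = d, mean_distance = mean(d), K = K)
}

#' Instantaneous Euclidean distance between trajectories
#'
#' @param trajA,trajB Matrices bins x K with equal bin counts; the first
#'   `k` components are used.
#' @param k Components to use (default: all columns).
#' @return Numeric vector, one distance per bin.
#' @export
euclidean_trajectory_distance <- function(trajA, trajB, k = ncol(trajA)) {
  if (nrow(trajA) != nrow(trajB)) stop("mismatched bin counts")
  stopifnot(ncol(trajA) == ncol(trajB), k <= ncol(trajA))
  a <- trajA[, seq_len(k), drop = FALSE]
  b <- trajB[, seq_len(k), drop = FALSE]
  sqrt(rowSums((a - b)^2))
}

#' Compare per-bin separation between treatment groups
#'
#' Two-sample t-test (pooled variance) between two groups' per-bin distance
#' vectors; degrees of freedom are `n_binsA + n_binsB - 2`.
#'
#' @param distA,distB Numeric distance vectors.
#' @return List: `t`, `df`, `p_value`, `mean_diff`.
#' @export
compare_separation <- function(distA, distB) {
  tt <- stats::t.test(distA, distB, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = mean(distA) - mean(distB))
}
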