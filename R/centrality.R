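# Eigenvector centrality mapping on the +1-shifted correlation adjacency.

#' Adjacency matrix from ROI time series
#'
#' Builds the nonnegative adjacency used for eigenvector centrality mapping:
#' pairwise Pearson correlation shifted by +1, so entries lie in [0, 2] and
#' the Perron-Frobenius theorem guarantees a nonnegative leading eigenvector.
#' The diagonal is set to 2 (the r = 1 convention); because eigenvectors are
#' invariant to adding a constant to the diagonal, this convention cannot
#' affect the centrality values.
#'
#' @param ts a \code{"roi_timeseries"} or T x N matrix.
#' @param diagonal diagonal value, 2 (default) or 0.
#' @return an object of class \code{"adjacency"}: fields \code{a} (N x N),
#'   \code{roi_ids}.
#' @export
adjacency_from_ts <- function(ts, diagonal = 2) {
  fc <- fc_matrix(ts)               # validates variance, names offenders
  a <- tanh(fc$z) + 1               # recover clipped r, shift
  diag(a) <- diagonal
  structure(list(a = a, roi_ids = fc$roi_ids), class = "adjacency")
}

as_adjacency_matrix <- function(adj) {
  if (inherits(adj, "adjacency")) return(adj$a)
  as_num_matrix(adj, "adj")
}

#' Eigenvector centrality by power iteration
#'
#' Computes the leading eigenvector of a symmetric nonnegative adjacency by
#' power iteration started from the uniform positive vector, normalising to
#' unit Euclidean norm at each step.  Iteration stops when successive
#' normalised iterates differ by less than \code{tol} in max-norm, or at
#' \code{max_iter} (with a warning and \code{converged = FALSE}).  The
#' eigenvalue is the Rayleigh quotient at the returned vector.
#'
#' For strictly positive adjacencies the leading eigenvector is unique and
#' strictly positive, so each ROI receives a well-defined centrality: an ROI
#' is central in proportion to the summed centrality of its neighbours.
#'
#' @param adj an \code{"adjacency"} or symmetric nonnegative N x N matrix.
#' @param tol convergence tolerance on the iterate difference (max-norm).
#' @param max_iter iteration cap.
#' @return an object of class \code{"ec_vector"}: fields \code{ec}
#'   (unit-norm nonnegative length-N vector), \code{eigenvalue},
#'   \code{n_iter}, \code{converged}, \code{roi_ids}.
#' @examples
#' a <- matrix(c(2, 1, 1, 2), 2)
#' eigenvector_centrality(a)$ec          # (1, 1)/sqrt(2)
#' @export
eigenvector_centrality <- function(adj, tol = 1e-12, max_iter = 10000) {
  roi_ids <- if (inherits(adj, "adjacency")) adj$roi_ids else NULL
  a <- as_adjacency_matrix(adj)
  n <- nrow(a)
  if (ncol(a) != n) stop("adjacency must be square")
  scale <- max(abs(a), 1)
  if (max(abs(a - t(a))) > 1e-9 * scale)
    stop("adjacency is not symmetric")
  if (min(a) < -1e-12) stop("adjacency must be nonnegative")
  v <- rep(1 / sqrt(n), n)
  n_iter <- 0L; converged <- FALSE
  repeat {
    n_iter <- n_iter + 1L
    w <- as.vector(a %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) { v_new <- v; converged <- TRUE; break }  # zero matrix
    v_new <- w / nw
    if (max(abs(v_new - v)) < tol) { v <- v_new; converged <- TRUE; break }
    v <- v_new
    if (n_iter >= max_iter) break
  }
  if (!converged)
    warning(sprintf("power iteration did not converge in %d iterations", max_iter))
  v <- abs(v)                                 # Perron vector is nonnegative
  v <- v / sqrt(sum(v^2))
  lambda <- as.numeric(crossprod(v, a %*% v))
  if (is.null(roi_ids)) roi_ids <- colnames(a)
  structure(list(ec = v, eigenvalue = lambda, n_iter = n_iter,
                 converged = converged, roi_ids = roi_ids),
            class = "ec_vector")
}

#' @export
print.ec_vector <- function(x, ...) {
  cat(sprintf("Eigenvector centrality: %d ROIs, eigenvalue %.4f (%d iterations%s)\n",
              length(x$ec), x$eigenvalue, x$n_iter,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Per-participant EC for a whole cohort, as a participants x ROIs table
#'
#' @param ts_list list of \code{"roi_timeseries"} (one per participant).
#' @param ... passed to \code{\link{eigenvector_centrality}}.
#' @return numeric matrix, rows named by participant id, columns by ROI id.
#' @export
cohort_ec_table <- function(ts_list, ...) {
  stopifnot(length(ts_list) >= 1L)
  rows <- lapply(ts_list, function(ts) {
    eigenvector_centrality(adjacency_from_ts(ts), ...)$ec
  })
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(ts_list, function(ts) ts$participant_id, character(1))
  colnames(out) <- as.character(ts_list[[1]]$roi_ids)
  out
}

#' Identify hub ROIs at a centrality percentile
#'
#' Hubs are the ROIs whose group-mean eigenvector centrality reaches the
#' given percentile of the EC distribution across ROIs (default 95th, i.e.
#' the 5\% most central).  The threshold uses the linear-interpolation
#' percentile (quantile type 7); ties at the threshold are all included.
#'
#' @param group_ec named numeric vector of per-ROI group-mean EC.
#' @param percentile percentile in (0, 100), default 95.
#' @return an object of class \code{"hub_set"}: \code{roi_ids},
#'   \code{threshold}, \code{percentile}.
#' @export
identify_hubs <- function(group_ec, percentile = 95) {
  if (!is.numeric(group_ec) || length(group_ec) < 2L || anyNA(group_ec))
    stop("group_ec must be a finite numeric vector of length >= 2")
  if (!is.numeric(percentile) || percentile <= 0 || percentile >= 100)
    stop("percentile must be in (0, 100)")
  thr <- unname(stats::quantile(group_ec, percentile / 100, type = 7))
  ids <- names(group_ec)
  if (is.null(ids)) ids <- as.character(seq_along(group_ec))
  structure(list(roi_ids = ids[group_ec >= thr], threshold = thr,
                 percentile = percentile),
            class = "hub_set")
}

#' @export
print.hub_set <- function(x, ...) {
  cat(sprintf("Hub set: %d ROIs at the %gth percentile (EC >= %.5f)\n",
              length(x$roi_ids), x$percentile, x$threshold))
  cat(" ", paste(x$roi_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Compare hub centrality between groups by permutation
#'
#' For each hub ROI, tests the difference of group means of per-participant
#' EC with a label permutation test; family-wise error across the hub family
#' is controlled by the max-statistic method (the family is the hub set
#' passed in, i.e. the group-level comparisons of one scan — not all ROIs).
#'
#' @param ec_a participants x ROIs EC matrix for group A (columns named by
#'   ROI id).
#' @param ec_b same for group B.
#' @param hubs a \code{"hub_set"} (or character vector of ROI ids).
#' @param n_perm,seed see \code{\link{permutation_group_test}}.
#' @return a \code{"perm_test"} over the hub family.
#' @export
compare_hub_ec <- function(ec_a, ec_b, hubs, n_perm = 10000, seed = 1) {
  ids <- if (inherits(hubs, "hub_set")) hubs$roi_ids else as.character(hubs)
  for (m in list(ec_a, ec_b)) {
    unknown <- setdiff(ids, colnames(m))
    if (length(unknown))
      stop("unknown hub id: ", paste(unknown, collapse = ", "))
  }
  permutation_group_test(ec_a[, ids, drop = FALSE],
                         ec_b[, ids, drop = FALSE],
                         statistic = "diff_of_means",
                         n_perm = n_perm, seed = seed)
}
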