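# Fisher-z functional connectivity and permutation group tests.

#' Fisher-z functional-connectivity matrix
#'
#' Computes pairwise temporal Pearson correlation between ROI columns and
#' applies the Fisher z-transformation \eqn{z = \mathrm{atanh}(r)}, with r
#' clipped to \eqn{|r| \le 1 - 10^{-15}} so z stays finite.  The diagonal is
#' set to NA and excluded from all summaries.
#'
#' @param ts a \code{"roi_timeseries"} (or plain T x N matrix).
#' @return an object of class \code{"fc_matrix"}: fields \code{z} (N x N
#'   symmetric, NA diagonal), \code{roi_ids}, \code{participant_id}.
#' @export
fc_matrix <- function(ts) {
  if (inherits(ts, "roi_timeseries")) {
    x <- ts$data; roi_ids <- ts$roi_ids; pid <- ts$participant_id
  } else {
    x <- as_num_matrix(ts, "ts")
    roi_ids <- colnames(x); if (is.null(roi_ids)) roi_ids <- seq_len(ncol(x))
    pid <- "unknown"
  }
  if (nrow(x) < 3L) stop("need at least 3 time points")
  v <- apply(x, 2, stats::var)
  if (any(v <= .Machine$double.eps))
    stop("zero variance: ", paste(roi_ids[v <= .Machine$double.eps],
                                  collapse = ", "))
  r <- stats::cor(x)
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  z <- atanh(r)
  z <- (z + t(z)) / 2            # enforce exact symmetry
  diag(z) <- NA_real_
  structure(list(z = z, roi_ids = roi_ids, participant_id = pid),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  ut <- x$z[upper.tri(x$z)]
  cat(sprintf("FC matrix: %d ROIs, participant %s; mean z = %.4f (range %.3f..%.3f)\n",
              length(x$roi_ids), x$participant_id, mean(ut), min(ut), max(ut)))
  invisible(x)
}

#' Per-participant whole-brain FC summary
#'
#' The mean of the upper-triangle off-diagonal Fisher-z values: one scalar of
#' whole-brain functional connectivity per participant, the quantity the
#' group-level whole-brain comparison operates on.
#'
#' @param fc an \code{"fc_matrix"}.
#' @return scalar mean z.
#' @export
participant_fc_summary <- function(fc) {
  stopifnot(inherits(fc, "fc_matrix"))
  mean(fc$z[upper.tri(fc$z)])
}

#' Group-label permutation test with max-statistic FWE correction
#'
#' Tests group differences by randomly reassigning participants to groups.
#' The observed statistic is \code{statistic(a) - statistic(b)} (per test for
#' matrix input); the null is built from \code{n_perm} uniformly random label
#' reassignments; p-values use the add-one rule
#' \eqn{p = (1 + \#\{|null| \ge |obs|\})/(n_{perm}+1)}, two-sided.  For a
#' family of tests (matrix input) the family-wise-error-corrected p-value is
#' computed by the max-statistic method: each permutation contributes the
#' maximum absolute statistic across the family.  The family is whatever the
#' caller passes in one call (e.g. the hub set of a scan), not all ROIs.
#'
#' @param values_a numeric vector (one statistic per participant) or matrix
#'   participants x tests, for group A.
#' @param values_b same shape for group B.
#' @param statistic \code{"diff_of_means"} or \code{"diff_of_medians"}.
#' @param n_perm number of random permutations (ignored with
#'   \code{exhaustive}).
#' @param seed RNG seed, recorded in the result.
#' @param exhaustive enumerate all label assignments instead of sampling
#'   (feasible for small groups); p-values are exact tail proportions.
#' @param fwe \code{"max-stat"} (default) or \code{"bonferroni"}.
#' @return an object of class \code{"perm_test"}: \code{observed},
#'   \code{p_raw}, \code{p_fwe}, \code{n_perm}, \code{seed},
#'   \code{statistic}.
#' @export
permutation_group_test <- function(values_a, values_b,
                                   statistic = c("diff_of_means",
                                                 "diff_of_medians"),
                                   n_perm = 10000, seed = 1,
                                   exhaustive = FALSE,
                                   fwe = c("max-stat", "bonferroni")) {
  statistic <- match.arg(statistic)
  fwe <- match.arg(fwe)
  A <- if (is.matrix(values_a)) values_a else matrix(values_a, ncol = 1)
  B <- if (is.matrix(values_b)) values_b else matrix(values_b, ncol = 1)
  if (ncol(A) != ncol(B)) stop("values_a and values_b must have the same tests")
  na <- nrow(A); nb <- nrow(B)
  if (na < 1L || nb < 1L) stop("both groups must be nonempty")
  pooled <- rbind(A, B)
  n <- na + nb
  stat_fun <- if (statistic == "diff_of_means") {
    function(idx_a) colMeans(pooled[idx_a, , drop = FALSE]) -
                    colMeans(pooled[-idx_a, , drop = FALSE])
  } else {
    function(idx_a) apply(pooled[idx_a, , drop = FALSE], 2, stats::median) -
                    apply(pooled[-idx_a, , drop = FALSE], 2, stats::median)
  }
  observed <- stat_fun(seq_len(na))
  if (exhaustive) {
    combos <- utils::combn(n, na)
    nulls <- t(apply(combos, 2, stat_fun))
    if (ncol(A) == 1L) nulls <- matrix(nulls, ncol = 1)
    K <- ncol(combos)
    p_raw <- vapply(seq_len(ncol(A)), function(j)
      sum(abs(nulls[, j]) >= abs(observed[j]) - 1e-12) / K, numeric(1))
    maxnull <- apply(abs(nulls), 1, max)
    p_fwe_ms <- vapply(seq_len(ncol(A)), function(j)
      sum(maxnull >= abs(observed[j]) - 1e-12) / K, numeric(1))
    n_used <- K
  } else {
    if (n_perm < 1L) stop("n_perm must be >= 1")
    nulls <- with_seed(seed, {
      t(vapply(seq_len(n_perm),
               function(i) stat_fun(sample.int(n, na)),
               numeric(ncol(A))))
    })
    if (ncol(A) == 1L) nulls <- matrix(nulls, ncol = 1)
    p_raw <- vapply(seq_len(ncol(A)), function(j)
      (1 + sum(abs(nulls[, j]) >= abs(observed[j]) - 1e-12)) / (n_perm + 1),
      numeric(1))
    maxnull <- apply(abs(nulls), 1, max)
    p_fwe_ms <- vapply(seq_len(ncol(A)), function(j)
      (1 + sum(maxnull >= abs(observed[j]) - 1e-12)) / (n_perm + 1),
      numeric(1))
    n_used <- n_perm
  }
  p_fwe <- if (fwe == "max-stat") p_fwe_ms else pmin(1, p_raw * ncol(A))
  p_fwe <- pmax(p_fwe, p_raw)
  names(observed) <- names(p_raw) <- names(p_fwe) <- colnames(A)
  structure(list(observed = observed, p_raw = p_raw, p_fwe = p_fwe,
                 n_perm = n_used, seed = seed, statistic = statistic,
                 fwe = fwe, exhaustive = exhaustive),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test (%s, %s%d permutations, seed %s)\n",
              x$statistic, if (x$exhaustive) "exhaustive, " else "",
              x$n_perm, format(x$seed)))
  df <- data.frame(observed = x$observed, p_raw = x$p_raw, p_fwe = x$p_fwe)
  print(df, digits = 4)
  invisible(x)
}
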