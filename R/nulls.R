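# Surrogate (iAAFT) and time-point bootstrap null/confidence distributions
# for eigenvector centrality.

#' Iterative amplitude-adjusted Fourier transform surrogate
#'
#' Generates a surrogate series that preserves the original value
#' distribution exactly and the amplitude (power) spectrum approximately,
#' while randomising Fourier phases.  Starting from a random shuffle, each
#' iteration (i) imposes the original Fourier amplitudes on the current
#' iterate, then (ii) rank-remaps the result onto the sorted original
#' values.  Iteration stops when the rank order is unchanged between
#' iterations or at \code{max_iter}; the final step is always the value
#' remapping, so \code{sort(surrogate) == sort(x)} exactly.
#'
#' Because phases are randomised independently per call, surrogates of
#' different ROIs/participants carry no shared structure: applied across a
#' cohort they destroy inter-ROI correlation while keeping each series'
#' autocorrelation (spectrum) and marginal distribution.
#'
#' @param x numeric series, length >= 4.
#' @param max_iter iteration cap (default 100).
#' @param seed RNG seed.
#' @return numeric series of the same length.
#' @export
iaaft_surrogate <- function(x, max_iter = 100, seed = 1) {
  x <- as.numeric(x)
  if (length(x) < 4L) stop("need at least 4 samples")
  if (anyNA(x)) stop("x contains missing values")
  if (stats::sd(x) == 0) {
    warning("constant series: surrogate equals the input")
    return(x)
  }
  amp <- Mod(stats::fft(x))
  s <- sort(x)
  n <- length(x)
  with_seed(seed, {
    y <- x[sample.int(n)]
    prev_rank <- integer(0)
    for (it in seq_len(max_iter)) {
      # (i) impose the original amplitude spectrum
      f <- stats::fft(y)
      phase <- Arg(f)
      y <- Re(stats::fft(amp * exp(1i * phase), inverse = TRUE)) / n
      # (ii) impose the original value distribution by rank remapping
      rk <- rank(y, ties.method = "first")
      y <- s[rk]
      if (identical(rk, prev_rank)) break
      prev_rank <- rk
    }
    y
  })
}

#' Fit a Gaussian by sample moments
#'
#' @param samples numeric vector.
#' @return list \code{mu} (sample mean) and \code{sigma} (sample SD with
#'   denominator n-1); with fewer than 2 samples, \code{sigma = 0} with a
#'   warning.
#' @export
fit_gaussian <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    warning("fewer than 2 samples: sigma set to 0")
    return(list(mu = if (length(samples)) mean(samples) else NA_real_,
                sigma = 0))
  }
  list(mu = mean(samples), sigma = stats::sd(samples))
}

new_null_distribution <- function(samples, kind, seed, config = list()) {
  mu <- apply(samples, 2, mean)
  sigma <- if (nrow(samples) >= 2L) apply(samples, 2, stats::sd)
           else rep(0, ncol(samples))
  structure(list(samples = samples, gauss_mu = mu, gauss_sigma = sigma,
                 kind = kind, seed = seed, config = config),
            class = "null_distribution")
}

#' Surrogate (iAAFT) null distribution of eigenvector centrality
#'
#' For each of \code{n_surrogates} replicates, every ROI series of every
#' participant is replaced by an independent iAAFT surrogate (fresh random
#' phases per ROI and participant, destroying cross-ROI correlation), the
#' adjacency and EC are recomputed per participant, and the group-mean EC per
#' ROI is recorded.  The resulting distribution is the centrality expected
#' when no functional communication is present; because EC values are forced
#' to be nonnegative and unit-norm, it is centered near the uniform value
#' \eqn{1/\sqrt{N}}, not at zero.
#'
#' @param cohort_ts nonempty list of \code{"roi_timeseries"}.
#' @param n_surrogates number of surrogate replicates (default 1000).
#' @param max_iter iAAFT iteration cap.
#' @param seed RNG seed.
#' @return a \code{"null_distribution"} with \code{kind = "surrogate"}:
#'   \code{samples} is an \code{n_surrogates} x N matrix of group-mean EC,
#'   \code{gauss_mu}/\code{gauss_sigma} the per-ROI moment fits.
#' @export
surrogate_ec_distribution <- function(cohort_ts, n_surrogates = 1000,
                                      max_iter = 100, seed = 1) {
  stopifnot(length(cohort_ts) >= 1L)
  N <- ncol(cohort_ts[[1]]$data)
  samples <- matrix(NA_real_, n_surrogates, N,
                    dimnames = list(NULL, as.character(cohort_ts[[1]]$roi_ids)))
  for (r in seq_len(n_surrogates)) {
    acc <- numeric(N)
    for (p in seq_along(cohort_ts)) {
      ts <- cohort_ts[[p]]
      sur <- ts$data
      for (j in seq_len(N))
        sur[, j] <- iaaft_surrogate(ts$data[, j], max_iter = max_iter,
                                    seed = sub_seed(seed, "sur", r, p, j))
      acc <- acc + eigenvector_centrality(adjacency_from_ts(sur))$ec
    }
    samples[r, ] <- acc / length(cohort_ts)
  }
  new_null_distribution(samples, "surrogate", seed,
                        list(n_surrogates = n_surrogates, max_iter = max_iter))
}

#' Resampled time-point index vector for the bootstrap
#'
#' One draw of the bootstrap's time resampling: \code{T} indices with
#' replacement (simple), or a concatenation of moving blocks of length
#' \eqn{\lceil\sqrt{T}\rceil} (block).  Exposed so the joint-resampling
#' construction can be inspected and tested directly.
#'
#' @param T number of time points.
#' @param seed RNG seed.
#' @param block use moving-block resampling.
#' @return integer vector of length T.
#' @export
resample_timepoints <- function(T, seed = 1, block = FALSE) {
  with_seed(seed, {
    if (block) {
      b <- ceiling(sqrt(T))
      starts <- sample.int(T - b + 1L, ceiling(T / b), replace = TRUE)
      utils::head(as.vector(vapply(starts, function(s) s + 0:(b - 1L),
                                   integer(b))), T)
    } else sample.int(T, T, replace = TRUE)
  })
}

#' Time-point bootstrap distribution of eigenvector centrality
#'
#' Per replicate, one time-index vector is resampled with replacement
#' (length T) for each participant and applied to all ROI columns jointly,
#' preserving cross-ROI structure; EC is recomputed per participant and the
#' group-mean EC per ROI recorded.  This gives a confidence distribution for
#' each ROI's centrality.  A moving-block variant (block length
#' \eqn{\lceil\sqrt{T}\rceil}) is available for autocorrelation-respecting
#' resampling.
#'
#' @param cohort_ts nonempty list of \code{"roi_timeseries"}.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param block use moving-block resampling instead of simple resampling.
#' @return a \code{"null_distribution"} with \code{kind = "bootstrap"}.
#' @export
bootstrap_ec_distribution <- function(cohort_ts, n_boot = 1000, seed = 1,
                                      block = FALSE) {
  stopifnot(length(cohort_ts) >= 1L, n_boot >= 1L)
  N <- ncol(cohort_ts[[1]]$data)
  samples <- matrix(NA_real_, n_boot, N,
                    dimnames = list(NULL, as.character(cohort_ts[[1]]$roi_ids)))
  for (r in seq_len(n_boot)) {
    acc <- numeric(N)
    for (p in seq_along(cohort_ts)) {
      ts <- cohort_ts[[p]]
      T <- nrow(ts$data)
      idx <- resample_timepoints(T, seed = sub_seed(seed, "boot", r, p),
                                 block = block)
      acc <- acc + eigenvector_centrality(adjacency_from_ts(
        ts$data[idx, , drop = FALSE]))$ec
    }
    samples[r, ] <- acc / length(cohort_ts)
  }
  new_null_distribution(samples, "bootstrap", seed, list(n_boot = n_boot,
                                                         block = block))
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("%s EC distribution: %d replicates x %d ROIs\n",
              x$kind, nrow(x$samples), ncol(x$samples)))
  cat(sprintf("  pooled mean %.5f, pooled SD %.5f\n",
              mean(x$samples), stats::sd(as.vector(x$samples))))
  invisible(x)
}

#' Density overlay of bootstrap vs surrogate EC distributions per hub
#'
#' @param x a \code{"null_distribution"}.
#' @param roi_ids ROIs (columns) to draw; defaults to the first.
#' @param add add to an existing plot.
#' @param col line colour.
#' @param ... passed to \code{plot}.
#' @export
plot.null_distribution <- function(x, roi_ids = NULL, add = FALSE,
                                   col = if (x$kind == "surrogate") "black"
                                         else "steelblue", ...) {
  if (is.null(roi_ids)) roi_ids <- colnames(x$samples)[1]
  for (id in roi_ids) {
    d <- stats::density(x$samples[, id])
    if (!add) {
      plot(d, col = col, main = sprintf("EC distribution (%s)", x$kind),
           xlab = "eigenvector centrality", ...)
      add <- TRUE
    } else graphics::lines(d, col = col)
  }
  invisible(x)
}
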