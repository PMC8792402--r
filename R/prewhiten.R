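# Two-step GLM prewhitening: motion regression, AR(1) estimation and
# removal, then confound regression on the whitened data.

#' Construct a confound set
#'
#' @param motion T x 6 matrix: 3 translations (mm) and 3 rotations (rad).
#' @param wm length-T white-matter signal.
#' @param csf length-T cerebrospinal-fluid signal.
#' @param participant_id participant label.
#' @return an object of class \code{"confound_set"}.
#' @export
confound_set <- function(motion, wm, csf, participant_id = "unknown") {
  motion <- as_num_matrix(motion, "motion")
  if (ncol(motion) != 6L) stop("motion must have 6 columns")
  wm <- as.numeric(wm); csf <- as.numeric(csf)
  if (length(wm) != nrow(motion) || length(csf) != nrow(motion))
    stop("wm and csf must have the same length as motion has rows")
  if (anyNA(wm) || anyNA(csf)) stop("confounds contain missing values")
  structure(list(motion = motion, wm = wm, csf = csf,
                 participant_id = as.character(participant_id)),
            class = "confound_set")
}

#' Read confounds from a TSV file
#'
#' Expects columns \code{trans_x, trans_y, trans_z, rot_x, rot_y, rot_z,
#' wm, csf}.
#'
#' @param path TSV file path.
#' @param participant_id participant label.
#' @return a \code{"confound_set"}.
#' @export
read_confounds <- function(path, participant_id = "unknown") {
  df <- utils::read.delim(path)
  need <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z",
            "wm", "csf")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("missing column: ", paste(missing, collapse = ", "))
  confound_set(as.matrix(df[, need[1:6]]), df$wm, df$csf, participant_id)
}

#' Ordinary-least-squares confound removal
#'
#' Regresses every column of \code{ts} on the design and returns the
#' residuals.  An intercept column is added automatically if the design does
#' not already span it; rank-deficient designs are handled by the pivoted QR
#' (dependent columns are effectively dropped, with a warning).
#'
#' @param ts T x K numeric matrix of series.
#' @param regressors T x M design matrix (may be NULL/zero-column for
#'   intercept-only).
#' @return T x K residual matrix, orthogonal to the design's column space.
#' @export
regress_out <- function(ts, regressors = NULL) {
  ts <- as_num_matrix(ts, "ts")
  T <- nrow(ts)
  if (is.null(regressors)) {
    X <- matrix(1, T, 1)
  } else {
    X <- as_num_matrix(regressors, "regressors")
    if (nrow(X) != T) stop("ts and regressors must have the same number of rows")
    # add an intercept unless a constant column is already in the span
    X <- cbind(1, X)
  }
  if (T <= ncol(X) - 1L) stop("too few time points for the design (T <= M)")
  qx <- qr(X)
  if (qx$rank < ncol(X))
    warning(sprintf("design is rank deficient (%d of %d columns independent); dependent columns dropped",
                    qx$rank, ncol(X)))
  qr.resid(qx, ts)
}

#' Estimate per-ROI AR(1) coefficients
#'
#' Lag-1 Yule-Walker estimate per column: columns are mean-centered, then
#' \eqn{\phi_j = \sum_t x_t x_{t-1} / \sum_t x_t^2}, clipped to
#' \eqn{[-0.99, 0.99]}.  Zero-variance columns get \eqn{\phi = 0} with a
#' warning.
#'
#' @param residuals T x N matrix (typically motion-filtered residuals).
#' @param pooled if TRUE, return a single pooled coefficient (the mean of the
#'   per-ROI estimates) recycled to length N.
#' @return an object of class \code{"ar1_estimate"} with field \code{phi}
#'   (length-N vector).
#' @export
estimate_ar1 <- function(residuals, pooled = FALSE) {
  x <- as_num_matrix(residuals, "residuals")
  if (nrow(x) < 3L) stop("need at least 3 time points")
  xc <- sweep(x, 2, colMeans(x))
  T <- nrow(xc)
  denom <- colSums(xc^2)
  num <- colSums(xc[-1, , drop = FALSE] * xc[-T, , drop = FALSE])
  zero <- denom <= .Machine$double.eps * T
  if (any(zero)) {
    warning("zero-variance column(s): phi set to 0 for ",
            sum(zero), " column(s)")
    denom[zero] <- 1; num[zero] <- 0
  }
  phi <- pmin(pmax(num / denom, -0.99), 0.99)
  if (pooled) phi <- rep(mean(phi), length(phi))
  structure(list(phi = unname(phi)), class = "ar1_estimate")
}

#' Remove AR(1) autocorrelation from a series matrix
#'
#' Applies the first-difference form of the AR(1) filter per column:
#' output row \eqn{t} is \eqn{x_{t+1} - \phi_j x_t}.  The first time point
#' is dropped; with \code{scale_first = TRUE} a stationarity-scaled first
#' row \eqn{\sqrt{1-\phi^2}\, x_1} is prepended instead, keeping T rows.
#'
#' @param ts T x N matrix.
#' @param ar an \code{"ar1_estimate"} (or numeric vector of length N).
#' @param scale_first keep the first row, scaled by \eqn{\sqrt{1-\phi^2}}.
#' @return (T-1) x N matrix (or T x N with \code{scale_first}).
#' @export
ar1_whiten <- function(ts, ar, scale_first = FALSE) {
  x <- as_num_matrix(ts, "ts")
  phi <- if (inherits(ar, "ar1_estimate")) ar$phi else as.numeric(ar)
  if (length(phi) != ncol(x))
    stop("phi length must equal the number of columns")
  T <- nrow(x)
  out <- x[-1, , drop = FALSE] - sweep(x[-T, , drop = FALSE], 2, phi, "*")
  if (scale_first)
    out <- rbind(sweep(x[1, , drop = FALSE], 2, sqrt(1 - phi^2), "*"), out)
  dimnames(out) <- list(NULL, colnames(x))
  out
}

#' Two-step GLM prewhitening pipeline
#'
#' Step 1: the raw series are filtered against the 6 motion parameters, the
#' AR(1) structure is estimated on those residuals, and the raw series are
#' whitened with the estimates.  Step 2: motion (rows 2..T, matching the
#' whitened length), white-matter and CSF signals are regressed out of the
#' whitened data.  Intercepts are always included.
#'
#' @param ts a \code{"roi_timeseries"}.
#' @param confounds a \code{"confound_set"} for the same participant.
#' @param pooled_phi use one pooled AR(1) coefficient across ROIs.
#' @param scale_first see \code{\link{ar1_whiten}}.
#' @return a cleaned \code{"roi_timeseries"} of length T-1 (T with
#'   \code{scale_first}), same ROI ids and TR; the AR(1) estimate is attached
#'   as attribute \code{"ar1"}.
#' @export
prewhiten_pipeline <- function(ts, confounds, pooled_phi = FALSE,
                               scale_first = FALSE) {
  stopifnot(inherits(ts, "roi_timeseries"), inherits(confounds, "confound_set"))
  if (!identical(ts$participant_id, confounds$participant_id))
    stop("participant_id mismatch between time series and confounds")
  T <- nrow(ts$data)
  if (nrow(confounds$motion) != T)
    stop("confound rows do not match the number of time points")
  resid1 <- regress_out(ts$data, confounds$motion)
  ar <- estimate_ar1(resid1, pooled = pooled_phi)
  white <- ar1_whiten(ts$data, ar, scale_first = scale_first)
  keep <- if (scale_first) seq_len(T) else 2:T
  design2 <- cbind(confounds$motion[keep, , drop = FALSE],
                   wm = confounds$wm[keep], csf = confounds$csf[keep])
  clean <- regress_out(white, design2)
  out <- roi_timeseries(clean, ts$roi_ids, tr = ts$tr,
                        participant_id = ts$participant_id)
  attr(out, "ar1") <- ar
  out
}
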