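# Visual-field scores from Humphrey-style total-deviation grids, and their
# correlation with hub centrality.

#' Standard automated perimetry grid coordinates
#'
#' Returns the test-point locations of the Humphrey 24-2 or 30-2 grid in
#' visual-field coordinates (degrees; x positive to the participant's right,
#' y positive up).  The 24-2 grid has 54 points with a nasal extension (to
#' -27 deg for the right eye, mirrored for the left); the 30-2 grid has 76
#' symmetric points.  The two points over the physiological blind spot
#' (15 deg temporal, +/-3 deg) are excluded by default, leaving 52 and 74
#' points.
#'
#' @param grid "24-2" or "30-2".
#' @param eye "left" or "right" (affects the 24-2 nasal extension and the
#'   blind-spot side).
#' @param blind_spot drop the two blind-spot points (default TRUE).
#' @return data.frame with columns \code{x_deg}, \code{y_deg}.
#' @export
vf_grid <- function(grid = c("24-2", "30-2"), eye = c("right", "left"),
                    blind_spot = TRUE) {
  grid <- match.arg(grid); eye <- match.arg(eye)
  half_width <- if (grid == "24-2") {
    c("21" = 9, "15" = 15, "9" = 21, "3" = 27)
  } else {
    c("27" = 9, "21" = 15, "15" = 21, "9" = 27, "3" = 27)
  }
  pts <- do.call(rbind, lapply(names(half_width), function(ys) {
    w <- half_width[[ys]]; y <- as.numeric(ys)
    x <- seq(-w, w, by = 6)
    if (grid == "24-2" && y == 3) {
      # nasal extension: one extra column on the nasal side only
      x <- if (eye == "right") seq(-27, 21, by = 6) else seq(-21, 27, by = 6)
    }
    rbind(data.frame(x_deg = x, y_deg = y),
          data.frame(x_deg = x, y_deg = -y))
  }))
  if (blind_spot) {
    bs_x <- if (eye == "right") 15 else -15
    pts <- pts[!(pts$x_deg == bs_x & abs(pts$y_deg) == 3), , drop = FALSE]
  }
  pts <- pts[order(-pts$y_deg, pts$x_deg), , drop = FALSE]
  rownames(pts) <- NULL
  pts
}

#' Construct a per-eye visual-field map
#'
#' Holds the total-deviation (TD) values of one eye in visual-field
#' coordinates (left-eye charts are assumed already mapped into the common
#' visual-field frame, as in the instrument printout), plus the mean
#' deviation.  MD should come from the instrument export when available; by
#' default it falls back to \code{mean(td)}, which is flagged in the object.
#'
#' @param eye "left" or "right".
#' @param td numeric vector of total-deviation values (dB, typically <= 0
#'   for loss), one per location.
#' @param grid "24-2", "30-2", or "custom" (arbitrary location sets, e.g.
#'   toy examples).
#' @param locations data.frame with \code{x_deg}, \code{y_deg}; defaults to
#'   \code{vf_grid(grid, eye)} for standard grids.
#' @param md mean deviation (dB) from the instrument; default
#'   \code{mean(td)}.
#' @param participant_id participant label.
#' @return an object of class \code{"vf_map"}.
#' @export
vf_map <- function(eye = c("right", "left"), td, grid = c("24-2", "30-2",
                   "custom"), locations = NULL, md = NULL,
                   participant_id = "unknown") {
  eye <- match.arg(eye); grid <- match.arg(grid)
  td <- as.numeric(td)
  if (anyNA(td) || any(!is.finite(td))) stop("td must be finite")
  if (is.null(locations)) {
    if (grid == "custom") stop("custom grid requires explicit locations")
    locations <- vf_grid(grid, eye)
  }
  if (nrow(locations) != length(td))
    stop("td length must match the number of locations")
  key <- paste(locations$x_deg, locations$y_deg)
  if (anyDuplicated(key)) stop("locations must be unique")
  if (grid != "custom") {
    expect_n <- if (grid == "24-2") 52L else 74L
    if (nrow(locations) != expect_n)
      stop(sprintf("%s grid must have %d locations (blind spot excluded)",
                   grid, expect_n))
  }
  md_from_td <- is.null(md)
  if (md_from_td) md <- mean(td)
  structure(list(eye = eye, grid = grid, td = td,
                 locations = locations[, c("x_deg", "y_deg")],
                 md = md, md_from_td = md_from_td,
                 participant_id = as.character(participant_id)),
            class = "vf_map")
}

#' Read a per-eye visual-field map from CSV
#'
#' Expects columns \code{x_deg}, \code{y_deg}, \code{td_db}; participant,
#' eye, grid and MD are passed as arguments (or embedded via
#' \code{#}-comment header lines \code{key=value}).
#'
#' @param path CSV path.
#' @param eye,grid,md,participant_id see \code{\link{vf_map}}; read from
#'   \code{#key=value} header lines when NULL.
#' @return a \code{"vf_map"}.
#' @export
read_vf_map <- function(path, eye = NULL, grid = NULL, md = NULL,
                        participant_id = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=")[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  df <- utils::read.csv(text = paste(lines[!grepl("^#", lines)],
                                     collapse = "\n"))
  need <- c("x_deg", "y_deg", "td_db")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("missing column: ", paste(missing, collapse = ", "))
  vf_map(eye = eye %||% meta$eye,
         td = df$td_db,
         grid = grid %||% meta$grid %||% "custom",
         locations = df[, c("x_deg", "y_deg")],
         md = md %||% (if (!is.null(meta$md_db)) as.numeric(meta$md_db)),
         participant_id = participant_id %||% meta$participant_id %||% "unknown")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean deviation of the worse eye
#'
#' @param md_left,md_right per-eye mean deviation (dB; more negative =
#'   worse).
#' @return \code{min(md_left, md_right)}, or NA if either is missing.
#' @export
worse_md <- function(md_left, md_right) {
  if (is.null(md_left) || is.null(md_right) ||
      is.na(md_left) || is.na(md_right)) return(NA_real_)
  min(md_left, md_right)
}

#' Absolute between-eye mean-deviation difference
#'
#' @param md_left,md_right per-eye mean deviation (dB).
#' @return \code{abs(md_right - md_left)}, or NA if either is missing.
#' @export
abs_diff_md <- function(md_left, md_right) {
  if (is.null(md_left) || is.null(md_right) ||
      is.na(md_left) || is.na(md_right)) return(NA_real_)
  abs(md_right - md_left)
}

#' Binocular integrated visual field score
#'
#' For each location present in both eyes' maps (in the common visual-field
#' frame), the better (higher) total-deviation value is selected — modelling
#' binocular compensation — and the BIVF is the mean of these pointwise
#' maxima.  The overlap of a 30-2 with a 24-2 map is the 24-2 point set.
#'
#' @param left,right \code{"vf_map"} objects for the two eyes of one
#'   participant.
#' @return scalar BIVF (dB).
#' @export
bivf <- function(left, right) {
  stopifnot(inherits(left, "vf_map"), inherits(right, "vf_map"))
  if (identical(left$eye, right$eye))
    stop("left and right maps report the same eye")
  if (!identical(left$participant_id, right$participant_id))
    stop("maps belong to different participants")
  key_l <- paste(left$locations$x_deg, left$locations$y_deg)
  key_r <- paste(right$locations$x_deg, right$locations$y_deg)
  common <- intersect(key_l, key_r)
  if (!length(common)) stop("no overlapping locations between the two eyes")
  tl <- left$td[match(common, key_l)]
  tr <- right$td[match(common, key_r)]
  mean(pmax(tl, tr))
}

#' All three behavioral scores for one participant
#'
#' @param left,right \code{"vf_map"} objects, or NULL when perimetry is
#'   missing (all scores NA).
#' @param participant_id participant label (defaults to the maps').
#' @return one-row data.frame: \code{participant_id}, \code{worse_md},
#'   \code{bivf}, \code{abs_diff_md}.
#' @export
behavioral_scores <- function(left, right, participant_id = NULL) {
  if (is.null(left) || is.null(right)) {
    return(data.frame(participant_id = participant_id %||% NA_character_,
                      worse_md = NA_real_, bivf = NA_real_,
                      abs_diff_md = NA_real_, stringsAsFactors = FALSE))
  }
  data.frame(
    participant_id = participant_id %||% left$participant_id,
    worse_md = worse_md(left$md, right$md),
    bivf = bivf(left, right),
    abs_diff_md = abs_diff_md(left$md, right$md),
    stringsAsFactors = FALSE)
}

#' Correlate behavioral scores with hub centrality
#'
#' For each hub ROI and each behavioral score, computes Spearman's rank
#' correlation (average ranks for ties) between the participants' scores and
#' their EC values, with a two-sided p-value (exact for n <= 9 without ties,
#' t-approximation otherwise).  Participants with a missing score or EC are
#' dropped pairwise; pairs with fewer than 4 complete observations are
#' marked not computable (NA).
#'
#' @param scores data.frame with \code{participant_id} and score columns
#'   (\code{worse_md}, \code{bivf}, \code{abs_diff_md}); NA = missing.
#' @param ec_table participants x ROIs EC matrix, rows named by participant
#'   id, columns by ROI id.
#' @param hubs a \code{"hub_set"} or character vector of ROI ids.
#' @param score_cols score columns to use.
#' @return data.frame with one row per (hub, score): \code{hub},
#'   \code{score}, \code{rho}, \code{p}, \code{n}.
#' @export
correlate_scores_with_ec <- function(scores, ec_table, hubs,
                                     score_cols = c("worse_md", "bivf",
                                                    "abs_diff_md")) {
  ids <- if (inherits(hubs, "hub_set")) hubs$roi_ids else as.character(hubs)
  unknown <- setdiff(ids, colnames(ec_table))
  if (length(unknown)) stop("unknown hub id: ", paste(unknown, collapse = ", "))
  out <- list(); k <- 0
  for (hub in ids) {
    ec <- ec_table[match(scores$participant_id, rownames(ec_table)), hub]
    for (sc in score_cols) {
      v <- scores[[sc]]
      ok <- !is.na(v) & !is.na(ec)
      n <- sum(ok)
      k <- k + 1
      if (n < 4L) {
        out[[k]] <- data.frame(hub = hub, score = sc, rho = NA_real_,
                               p = NA_real_, n = n, stringsAsFactors = FALSE)
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(v[ok], ec[ok], method = "spearman",
                        exact = n <= 9, alternative = "two.sided"))
      out[[k]] <- data.frame(hub = hub, score = sc,
                             rho = unname(ct$estimate),
                             p = min(1, unname(ct$p.value)), n = n,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
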