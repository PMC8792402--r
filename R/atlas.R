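# Spherical ROI atlases and voxel-averaged time-series extraction.

#' Load a spherical ROI atlas from a table
#'
#' Reads a tab-separated atlas table with one row per region of interest
#' (ROI).  Each ROI is a sphere in MNI space: a center coordinate in mm, a
#' radius, and labels for the functional network, hemisphere and anatomical
#' name.  Row order is preserved and defines the column order of every
#' downstream matrix (time series, connectivity, centrality).
#'
#' @param table path to a TSV file, or a data.frame, with columns
#'   \code{roi_id}, \code{x}, \code{y}, \code{z}, \code{network},
#'   \code{hemisphere}, \code{name}.
#' @param radius sphere radius in mm applied to every ROI (default 5).
#' @return an object of class \code{"ecm_atlas"}: a data.frame of ROIs with a
#'   \code{networks} attribute holding the set of network labels.
#' @examples
#' atlas <- load_atlas(system.file("extdata", "power232_synthetic.tsv",
#'                                 package = "ecmhub"))
#' nrow(atlas)            # 232 ROIs
#' attr(atlas, "networks")
#' @export
load_atlas <- function(table, radius = 5) {
  if (is.character(table)) {
    if (!file.exists(table)) stop("atlas table not found: ", table)
    table <- utils::read.delim(table, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(table)) stop("table must be a file path or data.frame")
  required <- c("roi_id", "x", "y", "z", "network", "hemisphere", "name")
  missing <- setdiff(required, names(table))
  if (length(missing))
    stop("missing column: ", paste(missing, collapse = ", "))
  dup <- table$roi_id[duplicated(table$roi_id)]
  if (length(dup))
    stop("duplicate roi_id: ", paste(unique(dup), collapse = ", "))
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  bad_hemi <- (table$x > 0 & table$hemisphere == "left") |
              (table$x < 0 & table$hemisphere == "right")
  if (any(bad_hemi))
    stop("hemisphere label inconsistent with x sign for roi_id: ",
         paste(table$roi_id[bad_hemi], collapse = ", "))
  atlas <- data.frame(
    roi_id = table$roi_id,
    x = as.numeric(table$x), y = as.numeric(table$y), z = as.numeric(table$z),
    radius = rep_len(radius, nrow(table)),
    network = as.character(table$network),
    hemisphere = as.character(table$hemisphere),
    name = as.character(table$name),
    stringsAsFactors = FALSE
  )
  rownames(atlas) <- NULL
  attr(atlas, "networks") <- unique(atlas$network)
  class(atlas) <- c("ecm_atlas", "data.frame")
  atlas
}

#' @export
print.ecm_atlas <- function(x, ...) {
  cat(sprintf("ROI atlas: %d spherical ROIs (radius %g mm) over %d networks\n",
              nrow(x), x$radius[1], length(attr(x, "networks"))))
  tab <- table(x$network)
  for (nw in attr(x, "networks"))
    cat(sprintf("  %-22s %3d ROIs\n", nw, tab[[nw]]))
  invisible(x)
}

#' Merge and drop atlas networks
#'
#' Applies a network-level restructuring to an atlas: pairs of networks are
#' merged under a new label and whole networks are dropped, preserving the
#' order of surviving ROIs.  This is the step that turns a full parcellation
#' into the analysis set (e.g. combining the somatomotor hand and mouth
#' networks and excluding cerebellar/uncertain regions).
#'
#' @param atlas an \code{"ecm_atlas"}.
#' @param merge_pairs list of character triples \code{c(label_a, label_b,
#'   new_label)}; ROIs in either input network are relabelled to
#'   \code{new_label}.
#' @param drop_labels character vector of network labels whose ROIs are
#'   removed.
#' @param strict if TRUE (default) referencing an absent network label is an
#'   error; if FALSE absent labels are silently ignored.
#' @return a filtered \code{"ecm_atlas"}; \code{attr(, "networks")} is
#'   recomputed from the survivors.
#' @examples
#' atlas <- load_atlas(system.file("extdata", "power232_synthetic.tsv",
#'                                 package = "ecmhub"))
#' cortical <- filter_atlas(atlas,
#'   merge_pairs = list(c("somatomotor_hand", "somatomotor_mouth",
#'                        "somatomotor")),
#'   drop_labels = c("cerebellar", "uncertain", "subcortical"))
#' @export
filter_atlas <- function(atlas, merge_pairs = list(), drop_labels = character(),
                         strict = TRUE) {
  if (!inherits(atlas, "ecm_atlas")) stop("atlas must be an ecm_atlas")
  known <- attr(atlas, "networks")
  refs <- c(unlist(lapply(merge_pairs, function(p) p[1:2])), drop_labels)
  unknown <- setdiff(refs, known)
  if (strict && length(unknown))
    stop("unknown network label: ", paste(unknown, collapse = ", "))
  out <- atlas
  for (p in merge_pairs) {
    if (length(p) != 3L) stop("each merge pair must be (label, label, new_label)")
    out$network[out$network %in% p[1:2]] <- p[3]
  }
  out <- out[!(out$network %in% drop_labels), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "networks") <- unique(out$network)
  class(out) <- c("ecm_atlas", "data.frame")
  out
}

#' Construct an ROI time-series object
#'
#' @param data T x N numeric matrix, rows = time points, columns = ROIs in
#'   atlas order.
#' @param roi_ids length-N identifiers matching an atlas.
#' @param tr repetition time in seconds.
#' @param participant_id participant label.
#' @return an object of class \code{"roi_timeseries"}.
#' @export
roi_timeseries <- function(data, roi_ids, tr, participant_id = "unknown") {
  data <- as_num_matrix(data, "data")
  if (nrow(data) < 2L) stop("need at least 2 time points")
  if (ncol(data) < 1L) stop("need at least 1 ROI")
  if (length(roi_ids) != ncol(data))
    stop("roi_ids length must equal the number of columns")
  if (anyDuplicated(roi_ids)) stop("roi_ids must be unique")
  stopifnot_scalar(tr, "tr")
  if (tr <= 0) stop("tr must be positive")
  colnames(data) <- as.character(roi_ids)
  structure(list(data = data, roi_ids = roi_ids, tr = tr,
                 participant_id = as.character(participant_id)),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("ROI time series: participant %s, %d time points x %d ROIs, TR %g s\n",
              x$participant_id, nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

#' Extract ROI time series from a 4D volume by voxel averaging
#'
#' For each atlas ROI, the set of voxels whose center (in mm, via the image
#' affine) lies within the sphere radius of the ROI center is averaged per
#' time point.  A voxel belongs to a sphere iff its center is within the
#' closed ball; overlapping spheres share voxels without de-duplication.
#'
#' @param volume a 4D \code{RNifti} image (or path to a NIfTI file), or a
#'   plain 4D array if \code{affine} is supplied.
#' @param atlas an \code{"ecm_atlas"}.
#' @param mask optional 3D image/array on the same grid; only voxels with
#'   nonzero mask value contribute.
#' @param affine optional 4x4 voxel-to-mm affine, required for plain arrays;
#'   voxel indices are 0-based in the affine convention.
#' @param tr repetition time override in seconds; by default read from the
#'   image header (\code{pixdim[4]}).
#' @param participant_id participant label for the returned object.
#' @return a \code{"roi_timeseries"} with one column per atlas ROI, in atlas
#'   order.
#' @export
extract_roi_timeseries <- function(volume, atlas, mask = NULL, affine = NULL,
                                   tr = NULL, participant_id = "unknown") {
  if (!inherits(atlas, "ecm_atlas")) stop("atlas must be an ecm_atlas")
  if (is.character(volume)) volume <- RNifti::readNifti(volume)
  if (inherits(volume, "niftiImage")) {
    if (is.null(affine)) affine <- RNifti::xform(volume)
    if (is.null(tr)) {
      pd <- RNifti::pixdim(volume)
      if (length(pd) >= 4 && pd[4] > 0) tr <- pd[4]
    }
  }
  arr <- unclass(as.array(volume))
  if (length(dim(arr)) != 4L) stop("volume must be 4D (x, y, z, t)")
  if (is.null(affine)) stop("no affine available: supply `affine` for plain arrays")
  affine <- unclass(affine)
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)) ||
      abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
    stop("affine missing or singular")
  if (is.null(tr)) stop("TR not available from header: supply `tr`")
  dims <- dim(arr)[1:3]
  T <- dim(arr)[4]
  if (!is.null(mask)) {
    mask <- unclass(as.array(mask))
    if (!all(dim(mask)[1:3] == dims)) stop("mask grid does not match volume")
    mask_keep <- mask != 0
  } else mask_keep <- NULL

  # voxel-center mm coordinates, 0-based indices
  ii <- seq_len(dims[1]) - 1; jj <- seq_len(dims[2]) - 1; kk <- seq_len(dims[3]) - 1
  grid <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  mm <- grid %*% t(affine[1:3, 1:3])
  mm <- sweep(mm, 2, affine[1:3, 4], "+")

  flat <- matrix(arr, nrow = prod(dims), ncol = T)
  out <- matrix(NA_real_, nrow = T, ncol = nrow(atlas))
  empty <- character()
  for (r in seq_len(nrow(atlas))) {
    d2 <- (mm[, 1] - atlas$x[r])^2 + (mm[, 2] - atlas$y[r])^2 +
          (mm[, 3] - atlas$z[r])^2
    sel <- d2 <= atlas$radius[r]^2
    if (!is.null(mask_keep)) sel <- sel & as.vector(mask_keep)
    if (!any(sel)) { empty <- c(empty, as.character(atlas$roi_id[r])); next }
    out[, r] <- colMeans(flat[sel, , drop = FALSE])
  }
  if (length(empty)) stop("empty ROI: ", paste(empty, collapse = ", "))
  roi_timeseries(out, atlas$roi_id, tr = tr, participant_id = participant_id)
}

#' Read/write ROI time series as TSV with a JSON sidecar
#'
#' The TSV holds a first column \code{t} (frame index, 0-based) and one
#' column per ROI named by its id; the sidecar JSON records the TR and
#' participant id.
#'
#' @param ts a \code{"roi_timeseries"}.
#' @param path TSV path; the sidecar is written next to it as
#'   \code{<path>.json}.
#' @return \code{read_roi_timeseries} returns a \code{"roi_timeseries"};
#'   \code{write_roi_timeseries} returns \code{path} invisibly.
#' @export
write_roi_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  df <- data.frame(t = seq_len(nrow(ts$data)) - 1L, ts$data, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(tr = ts$tr, participant_id = ts$participant_id),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_timeseries
#' @param path TSV path written by \code{write_roi_timeseries}.
#' @export
read_roi_timeseries <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  roi_timeseries(as.matrix(df[, -1, drop = FALSE]),
                 roi_ids = names(df)[-1], tr = meta$tr,
                 participant_id = meta$participant_id)
}
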