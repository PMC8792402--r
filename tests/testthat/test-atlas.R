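test_that("load_atlas preserves row order and validates ids/columns", {
  atlas <- load_atlas(tiny_atlas_df())
  expect_s3_class(atlas, "ecm_atlas")
  expect_equal(nrow(atlas), 3)
  expect_equal(atlas$roi_id, 1:3)
  expect_setequal(attr(atlas, "networks"), c("A", "B"))

  dup <- tiny_atlas_df()
  dup$roi_id <- c(7, 7, 3)
  expect_error(load_atlas(dup), "duplicate roi_id: 7")

  nocol <- tiny_atlas_df()
  nocol$network <- NULL
  expect_error(load_atlas(nocol), "missing column: network")

  bad <- tiny_atlas_df()
  bad$hemisphere <- c("right", "right", "left")   # x = -10 labelled right
  expect_error(load_atlas(bad), "hemisphere")
})

test_that("bundled Power-style fixture has 232 ROIs over 11 networks", {
  atlas <- load_atlas(fixture_atlas_path())
  expect_equal(nrow(atlas), 232)
  expect_length(attr(atlas, "networks"), 11)
  expect_true(all(atlas$radius == 5))
})

test_that("filter_atlas merges, drops, and preserves survivor order", {
  df <- data.frame(
    roi_id = 1:6,
    x = c(-5, 5, -5, 5, -5, 5), y = 0, z = 0,
    network = c("A", "A", "A", "B", "B", "C"),
    hemisphere = rep(c("left", "right"), 3),
    name = letters[1:6], stringsAsFactors = FALSE)
  atlas <- load_atlas(df)
  out <- filter_atlas(atlas, merge_pairs = list(c("A", "B", "AB")),
                      drop_labels = "C")
  expect_equal(nrow(out), 5)
  expect_equal(attr(out, "networks"), "AB")
  expect_equal(out$roi_id, 1:5)               # order preserved

  expect_identical(filter_atlas(atlas)$roi_id, atlas$roi_id)  # identity case
  expect_error(filter_atlas(atlas, drop_labels = "Z"),
               "unknown network label: Z")
  expect_silent(filter_atlas(atlas, drop_labels = "Z", strict = FALSE))
})

test_that("filtering the fixture matches an independent tally of its labels", {
  atlas <- load_atlas(fixture_atlas_path())
  out <- filter_atlas(
    atlas,
    merge_pairs = list(c("somatomotor_hand", "somatomotor_mouth",
                         "somatomotor")),
    drop_labels = c("cerebellar", "uncertain", "subcortical"))

  # oracle: count rows of the raw table directly
  raw <- read.delim(fixture_atlas_path(), stringsAsFactors = FALSE)
  keep <- !raw$network %in% c("cerebellar", "uncertain", "subcortical")
  expect_equal(nrow(out), sum(keep))
  merged_labels <- unique(ifelse(
    raw$network[keep] %in% c("somatomotor_hand", "somatomotor_mouth"),
    "somatomotor", raw$network[keep]))
  expect_setequal(attr(out, "networks"), merged_labels)
  expect_length(attr(out, "networks"), 7)

  # idempotence for the same arguments
  again <- filter_atlas(out, merge_pairs = list(
    c("somatomotor_hand", "somatomotor_mouth", "somatomotor")),
    drop_labels = c("cerebellar", "uncertain", "subcortical"),
    strict = FALSE)
  expect_identical(again$roi_id, out$roi_id)
  expect_identical(again$network, out$network)
})

make_volume <- function(dims = c(12, 12, 8), T = 4, value = 0) {
  array(value, dim = c(dims, T))
}
vox_affine <- function(spacing = 2, origin = c(-11, -11, -7)) {
  a <- diag(4)
  a[1:3, 1:3] <- diag(rep(spacing, 3))
  a[1:3, 4] <- origin
  a
}

test_that("extract_roi_timeseries averages voxels within the sphere", {
  dims <- c(12, 12, 8); T <- 4
  vol <- make_volume(dims, T)
  for (t in seq_len(T)) vol[, , , t] <- t - 1   # every voxel equals frame index
  atlas <- load_atlas(data.frame(
    roi_id = c(1, 2), x = c(-5, 5), y = c(0, 0), z = c(0, 0),
    network = "A", hemisphere = c("left", "right"), name = c("l", "r"),
    stringsAsFactors = FALSE))
  ts <- extract_roi_timeseries(vol, atlas, affine = vox_affine(), tr = 2)
  expect_equal(unname(ts$data[, 1]), 0:(T - 1))
  expect_equal(unname(ts$data[, 2]), 0:(T - 1))
  expect_equal(as.character(ts$roi_ids), colnames(ts$data))
})

test_that("in-ball fraction matches a brute-force voxel enumeration", {
  dims <- c(14, 14, 14); T <- 2
  aff <- vox_affine(2, origin = c(-13, -13, -13))
  center <- c(1, -1, 3); radius <- 5; ball_r <- 4
  # volume holds 1 inside a ball of radius 4 around `center`, else 0
  vol <- array(0, c(dims, T))
  # brute-force oracle over every voxel
  n_in_roi <- 0; n_in_both <- 0
  for (i in 0:(dims[1] - 1)) for (j in 0:(dims[2] - 1))
    for (k in 0:(dims[3] - 1)) {
      mm <- aff[1:3, 1:3] %*% c(i, j, k) + aff[1:3, 4]
      d_roi <- sqrt(sum((mm - center)^2))
      in_ball <- sqrt(sum(mm^2)) <= ball_r
      if (in_ball) vol[i + 1, j + 1, k + 1, ] <- 1
      if (d_roi <= radius) {
        n_in_roi <- n_in_roi + 1
        if (in_ball) n_in_both <- n_in_both + 1
      }
    }
  atlas <- load_atlas(data.frame(
    roi_id = 1, x = center[1], y = center[2], z = center[3],
    network = "A", hemisphere = "right", name = "r",
    stringsAsFactors = FALSE))
  ts <- extract_roi_timeseries(vol, atlas, affine = aff, tr = 1)
  expect_equal(unname(ts$data[1, 1]), n_in_both / n_in_roi)
})

test_that("extraction is linear in the volume and errors on empty ROIs", {
  dims <- c(10, 10, 6); T <- 3
  aff <- vox_affine(2, origin = c(-9, -9, -5))
  set.seed(4)
  v1 <- array(rnorm(prod(dims) * T), c(dims, T))
  v2 <- array(rnorm(prod(dims) * T), c(dims, T))
  atlas <- load_atlas(data.frame(
    roi_id = c(10, 20), x = c(-4, 4), y = 0, z = 0,
    network = "A", hemisphere = c("left", "right"), name = c("l", "r"),
    stringsAsFactors = FALSE))
  a <- 2.5; b <- -1.25
  lhs <- extract_roi_timeseries(a * v1 + b * v2, atlas, affine = aff, tr = 1)
  t1 <- extract_roi_timeseries(v1, atlas, affine = aff, tr = 1)
  t2 <- extract_roi_timeseries(v2, atlas, affine = aff, tr = 1)
  expect_equal(lhs$data, a * t1$data + b * t2$data, tolerance = 1e-12)

  # mask excluding ROI 20 entirely -> error naming it
  mask <- array(1, dims); mask[6:10, , ] <- 0
  expect_error(
    extract_roi_timeseries(v1, atlas, mask = mask, affine = aff, tr = 1),
    "empty ROI: 20")
  expect_error(
    extract_roi_timeseries(v1, atlas, affine = diag(c(0, 1, 1, 1)), tr = 1),
    "affine")
})

test_that("NIfTI round trip carries TR and affine through extraction", {
  dims <- c(10, 10, 6); T <- 3
  arr <- array(seq_len(prod(dims) * T), c(dims, T))
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-9, -9, -5)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(2, 2, 2, 0.8)
  RNifti::sform(img) <- structure(aff, code = 2L)
  path <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, path)
  atlas <- load_atlas(data.frame(
    roi_id = 1, x = 5, y = 5, z = 2, network = "A",
    hemisphere = "right", name = "r", stringsAsFactors = FALSE))
  ts <- extract_roi_timeseries(path, atlas, participant_id = "p1")
  expect_equal(ts$tr, 0.8, tolerance = 1e-6)
  expect_equal(nrow(ts$data), T)
  # oracle: voxel centers within 5mm of (5,5,2) under the image affine
  grid <- as.matrix(expand.grid(0:(dims[1] - 1), 0:(dims[2] - 1),
                                0:(dims[3] - 1)))
  mm <- sweep(grid %*% t(aff[1:3, 1:3]), 2, aff[1:3, 4], "+")
  inside <- rowSums(sweep(mm, 2, c(5, 5, 2))^2) <= 25
  flat <- matrix(arr, ncol = T)
  expect_equal(unname(ts$data[, 1]), colMeans(flat[inside, , drop = FALSE]))
})

test_that("ROI time-series TSV round trip preserves data and metadata", {
  x <- matrix(rnorm(40), 10, 4)
  ts <- roi_timeseries(x, roi_ids = c(3, 7, 9, 11), tr = 1.35,
                       participant_id = "P01")
  path <- tempfile(fileext = ".tsv")
  write_roi_timeseries(ts, path)
  back <- read_roi_timeseries(path)
  expect_equal(unname(back$data), unname(ts$data), tolerance = 1e-10)
  expect_equal(as.character(back$roi_ids), as.character(ts$roi_ids))
  expect_equal(back$tr, 1.35)
  expect_equal(back$participant_id, "P01")
})
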