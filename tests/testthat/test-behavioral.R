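test_that("perimetry grids have the standard point counts", {
  g24 <- vf_grid("24-2", "right")
  g30 <- vf_grid("30-2", "right")
  expect_equal(nrow(g24), 52)
  expect_equal(nrow(g30), 74)
  expect_equal(nrow(vf_grid("24-2", "right", blind_spot = FALSE)), 54)
  expect_equal(nrow(vf_grid("30-2", "left", blind_spot = FALSE)), 76)
  expect_false(anyDuplicated(paste(g24$x_deg, g24$y_deg)) > 0)

  # 24-2 points are a subset of 30-2 points (same eye)
  k24 <- paste(g24$x_deg, g24$y_deg)
  k30 <- paste(g30$x_deg, g30$y_deg)
  expect_true(all(k24 %in% k30))

  # blind spot sits temporal: +15 for the right eye, -15 for the left
  expect_false(any(g24$x_deg == 15 & abs(g24$y_deg) == 3))
  g24l <- vf_grid("24-2", "left")
  expect_false(any(g24l$x_deg == -15 & abs(g24l$y_deg) == 3))
  # nasal extension mirrors between eyes
  expect_true(any(g24$x_deg == -27))
  expect_false(any(g24$x_deg == 27))
  expect_true(any(g24l$x_deg == 27))
})

test_that("worse_md and abs_diff_md are elementary and symmetric", {
  expect_equal(worse_md(-7, -9), -9)
  expect_equal(worse_md(0.1, 0.1), 0.1)
  expect_equal(worse_md(-2, 3), -2)
  expect_true(is.na(worse_md(NA, -3)))

  expect_equal(abs_diff_md(-7, -9), 2)
  expect_equal(abs_diff_md(4.2, 4.2), 0)
  expect_equal(abs_diff_md(-12.11, 0), 12.11)
  expect_true(is.na(abs_diff_md(-1, NA)))

  expect_equal(worse_md(-3, 1), worse_md(1, -3))
  expect_equal(abs_diff_md(-3, 1), abs_diff_md(1, -3))
})

toy_map <- function(eye, td, pid = "p") {
  vf_map(eye = eye, td = td, grid = "custom",
         locations = data.frame(x_deg = c(-9, 3, 9), y_deg = c(3, 3, -3)),
         participant_id = pid)
}

test_that("bivf applies the pointwise-max rule", {
  left <- toy_map("left", c(-5, -2, -30))
  right <- toy_map("right", c(-1, -6, -30))
  expect_equal(bivf(left, right), mean(c(-1, -2, -30)))
  expect_equal(bivf(left, right), -11)
  expect_equal(bivf(right, left), bivf(left, right))   # symmetric

  same <- toy_map("right", c(-4, -8, 0))
  lsame <- toy_map("left", c(-4, -8, 0))
  expect_equal(bivf(lsame, same), mean(c(-4, -8, 0)))  # max(x, x) = x

  blindleft <- toy_map("left", c(-30, -30, -30))
  normright <- toy_map("right", c(0, 0, 0))
  expect_equal(bivf(blindleft, normright), 0)          # binocular compensation
})

test_that("bivf validates eyes, participants, and overlap", {
  l <- toy_map("left", c(-1, -2, -3))
  r <- toy_map("right", c(-1, -2, -3))
  expect_error(bivf(l, toy_map("left", c(0, 0, 0))), "same eye")
  expect_error(bivf(l, toy_map("right", c(0, 0, 0), pid = "q")),
               "different participants")
  far <- vf_map(eye = "right", td = c(0, 0), grid = "custom",
                locations = data.frame(x_deg = c(21, 27), y_deg = c(9, 9)),
                participant_id = "p")
  expect_error(bivf(l, far), "no overlapping")
})

test_that("30-2 vs 24-2 overlap is the 24-2 point set", {
  set.seed(1)
  loc30 <- vf_grid("30-2", "left")
  loc24 <- vf_grid("24-2", "right")
  td30 <- -runif(nrow(loc30), 0, 10)
  td24 <- -runif(nrow(loc24), 0, 10)
  l <- vf_map("left", td30, grid = "30-2", participant_id = "p")
  r <- vf_map("right", td24, grid = "24-2", participant_id = "p")
  # oracle: hand-matched pointwise maxima over the 24-2 locations
  k30 <- paste(loc30$x_deg, loc30$y_deg)
  k24 <- paste(loc24$x_deg, loc24$y_deg)
  common <- intersect(k24, k30)
  expect_equal(length(common), sum(k24 %in% k30))
  oracle <- mean(pmax(td24[match(common, k24)], td30[match(common, k30)]))
  expect_equal(bivf(l, r), oracle)
})

test_that("bivf dominates each eye's mean over the overlap (max dominance)", {
  set.seed(2)
  for (i in 1:20) {
    td_l <- -runif(52, 0, 30); td_r <- -runif(52, 0, 30)
    l <- vf_map("left", td_l, grid = "24-2", participant_id = "p")
    r <- vf_map("right", td_r, grid = "24-2", participant_id = "p")
    b <- bivf(l, r)
    k_l <- paste(l$locations$x_deg, l$locations$y_deg)
    k_r <- paste(r$locations$x_deg, r$locations$y_deg)
    common <- intersect(k_l, k_r)
    expect_gte(b, mean(td_l[match(common, k_l)]))
    expect_gte(b, mean(td_r[match(common, k_r)]))
  }
})

test_that("vf_map validates grids, locations and md fallback", {
  expect_error(vf_map("right", rep(0, 10), grid = "24-2"), "match")
  short_loc <- data.frame(x_deg = seq(-27, 27, by = 6), y_deg = 3)
  expect_error(vf_map("right", rep(0, nrow(short_loc)), grid = "24-2",
                      locations = short_loc), "52")
  expect_error(vf_map("right", c(0, 0), grid = "custom",
                      locations = data.frame(x_deg = c(1, 1),
                                             y_deg = c(2, 2))), "unique")
  m <- toy_map("right", c(-2, -4, -6))
  expect_equal(m$md, -4)
  expect_true(m$md_from_td)
  m2 <- vf_map("right", c(-2, -4, -6), grid = "custom",
               locations = data.frame(x_deg = c(-9, 3, 9),
                                      y_deg = c(3, 3, -3)), md = -3.5)
  expect_equal(m2$md, -3.5)
  expect_false(m2$md_from_td)
})

test_that("behavioral_scores bundles the three scores and handles missing eyes", {
  l <- toy_map("left", c(-5, -2, -30)); r <- toy_map("right", c(-1, -6, -30))
  sc <- behavioral_scores(l, r)
  expect_equal(sc$worse_md, min(l$md, r$md))
  expect_equal(sc$bivf, -11)
  expect_equal(sc$abs_diff_md, abs(r$md - l$md))
  miss <- behavioral_scores(NULL, NULL, participant_id = "q")
  expect_true(all(is.na(miss[, c("worse_md", "bivf", "abs_diff_md")])))
})

test_that("vf CSV round trip preserves the map", {
  m <- toy_map("left", c(-5, -2, -30), pid = "P07")
  path <- tempfile(fileext = ".csv")
  writeLines(c("#participant_id=P07", "#eye=left", "#grid=custom",
               sprintf("#md_db=%.15g", m$md)), path)
  suppressWarnings(
    write.table(data.frame(x_deg = m$locations$x_deg,
                           y_deg = m$locations$y_deg, td_db = m$td),
                path, sep = ",", row.names = FALSE, append = TRUE,
                quote = FALSE, col.names = TRUE))
  back <- read_vf_map(path)
  expect_equal(back$td, m$td)
  expect_equal(back$eye, "left")
  expect_equal(back$participant_id, "P07")
  expect_equal(back$md, m$md)
})

test_that("spearman correlation: monotone data, rank-formula oracle, small n", {
  ec_tab <- matrix(seq(0.1, 1, length.out = 10), 10, 1,
                   dimnames = list(paste0("p", 1:10), "h1"))
  sc <- data.frame(participant_id = paste0("p", 1:10),
                   worse_md = (1:10)^2,       # monotone in EC
                   bivf = NA_real_, abs_diff_md = NA_real_)
  out <- correlate_scores_with_ec(sc, ec_tab, "h1",
                                  score_cols = c("worse_md", "bivf"))
  expect_equal(out$rho[out$score == "worse_md"], 1)
  expect_equal(out$n[out$score == "bivf"], 0)
  expect_true(is.na(out$rho[out$score == "bivf"]))   # not computable

  # 5-point hand-ranked example against the rank-difference formula
  x <- c(3, 1, 4, 1.5, 5); y <- c(2.2, 0.4, 1.9, 0.9, 3.3)
  d <- rank(x) - rank(y)
  rho_oracle <- 1 - 6 * sum(d^2) / (5 * (25 - 1))
  ec5 <- matrix(y, 5, 1, dimnames = list(paste0("p", 1:5), "h1"))
  sc5 <- data.frame(participant_id = paste0("p", 1:5), worse_md = x,
                    bivf = NA_real_, abs_diff_md = NA_real_)
  out5 <- correlate_scores_with_ec(sc5, ec5, "h1", score_cols = "worse_md")
  expect_equal(out5$rho, rho_oracle, tolerance = 1e-12)

  expect_error(correlate_scores_with_ec(sc5, ec5, "nope"), "unknown hub id")
})

test_that("spearman test keeps its level on independent data", {
  set.seed(3)
  rej <- replicate(500, {
    sc <- data.frame(participant_id = paste0("p", 1:36),
                     worse_md = rnorm(36), bivf = NA_real_,
                     abs_diff_md = NA_real_)
    ec <- matrix(rnorm(36), 36, 1, dimnames = list(paste0("p", 1:36), "h1"))
    out <- correlate_scores_with_ec(sc, ec, "h1", score_cols = "worse_md")
    out$p <= 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})
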