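# Shared fixture builders: everything is generated in code at test time.

tiny_atlas_df <- function() {
  data.frame(
    roi_id = 1:3,
    x = c(-10, 12, 0), y = c(4, -6, 0), z = c(8, 2, -4),
    network = c("A", "A", "B"),
    hemisphere = c("left", "right", "left"),
    name = c("a1", "a2", "b1"),
    stringsAsFactors = FALSE)
}

# AR(1) series with known coefficient, stationary start
gen_ar1 <- function(T, phi, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  innov <- rnorm(T, sd = sd)
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

# quick multi-ROI series with planted correlation via a shared signal
gen_correlated_ts <- function(T = 120, N = 10, loading = 0.8, seed = 1) {
  set.seed(seed)
  s <- rnorm(T)
  x <- loading * matrix(s, T, N) + matrix(rnorm(T * N), T, N)
  colnames(x) <- as.character(seq_len(N))
  x
}

# random symmetric adjacency with entries in [0, 2]
random_adjacency <- function(n, seed = 1) {
  set.seed(seed)
  a <- matrix(runif(n * n, 0, 2), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 2
  a
}

fixture_atlas_path <- function() {
  system.file("extdata", "power232_synthetic.tsv", package = "ecmhub")
}

# raw periodogram ordinates (positive frequencies, no tapering)
periodogram <- function(x) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2 / n
  p[2:floor(n / 2)]
}
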