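# Synthetic cohorts with planted hubs, AR(1) noise, confounds, and
# paired-eye perimetry coupled to hub connectivity strength.

#' Simulation configuration
#'
#' Defaults emulate the study conditions the analysis targets: 260 BOLD
#' volumes at TR 1.35 s across 131 ROIs in 7 networks, 24 controls and 20
#' patients, two resting-state scans per participant, and perimetry completed
#' by 17 controls and 19 patients.
#'
#' The generative model for ROI \eqn{j} of one participant is
#' \deqn{x_j(t) = \lambda_j s(t) + \gamma c_{net(j)}(t) + confounds + e_j(t)}
#' where \eqn{s} is a shared latent signal, \eqn{c_k} are per-network latent
#' signals, all latents and the noise \eqn{e_j} are unit-variance AR(1)
#' processes with coefficient \code{ar_phi}, and
#' \eqn{\lambda_j = } \code{hub_strength} \eqn{\cdot \max(0,\, 1 -}
#' \code{coupling} \eqn{\cdot severity)} for planted hubs and
#' \code{base_strength} otherwise.  High loading on the shared signal makes
#' an ROI correlate with everything, i.e. a centrality hub; severity couples
#' negatively to hub loading so worse visual fields accompany reduced
#' centrality.
#'
#' @param n_rois number of ROIs.
#' @param n_timepoints number of volumes T.
#' @param tr repetition time (s).
#' @param n_controls,n_patients group sizes.
#' @param n_networks number of ROI networks (round-robin assignment).
#' @param planted_hubs ROI indices of the planted hubs; default 6 evenly
#'   spaced ROIs.
#' @param hub_strength,base_strength loadings of hubs/non-hubs on the shared
#'   latent signal (default ratio 3).
#' @param network_strength loading on the per-network latent signal.
#' @param ar_phi AR(1) coefficient of latents and noise, in [0, 1).
#' @param noise_sd noise SD.
#' @param confound_sd scale of motion/WM/CSF contamination added to the ROI
#'   data.
#' @param coupling slope linking participant severity to hub loading
#'   (loading fraction lost per severity unit).
#' @param severity_mean,severity_sd location/spread of the patients' latent
#'   severity (controls have severity 0).
#' @param asymmetry_sd spread of the between-eye asymmetry of patients'
#'   field loss.
#' @param n_controls_scored,n_patients_scored participants per group with
#'   completed perimetry.
#' @param vf_grid_type perimetry grid for simulated fields.
#' @param seed master RNG seed.
#' @return a \code{"sim_config"} list.
#' @export
sim_config <- function(n_rois = 131, n_timepoints = 260, tr = 1.35,
                       n_controls = 24, n_patients = 20, n_networks = 7,
                       planted_hubs = NULL,
                       hub_strength = 0.9, base_strength = 0.3,
                       network_strength = 0.25, ar_phi = 0.3, noise_sd = 1,
                       confound_sd = 0.1, coupling = 0.1,
                       severity_mean = 3, severity_sd = 1.5,
                       asymmetry_sd = 1.5,
                       n_controls_scored = 17, n_patients_scored = 19,
                       vf_grid_type = "24-2", seed = 1) {
  if (is.null(planted_hubs))
    planted_hubs <- round(seq(1, n_rois, length.out = 8))[2:7]
  cfg <- list(n_rois = n_rois, n_timepoints = n_timepoints, tr = tr,
              n_controls = n_controls, n_patients = n_patients,
              n_networks = n_networks, planted_hubs = planted_hubs,
              hub_strength = hub_strength, base_strength = base_strength,
              network_strength = network_strength, ar_phi = ar_phi,
              noise_sd = noise_sd, confound_sd = confound_sd,
              coupling = coupling, severity_mean = severity_mean,
              severity_sd = severity_sd, asymmetry_sd = asymmetry_sd,
              n_controls_scored = n_controls_scored,
              n_patients_scored = n_patients_scored,
              vf_grid_type = vf_grid_type, seed = seed)
  if (cfg$ar_phi < 0 || cfg$ar_phi >= 1) stop("ar_phi must be in [0, 1)")
  if (cfg$hub_strength < cfg$base_strength || cfg$base_strength < 0)
    stop("need hub_strength >= base_strength >= 0")
  if (any(c(n_rois, n_timepoints, n_controls + n_patients) <= 0))
    stop("counts must be positive")
  if (any(planted_hubs < 1 | planted_hubs > n_rois))
    stop("planted_hubs out of range")
  class(cfg) <- "sim_config"
  cfg
}

# unit-variance AR(1) series
ar1_series <- function(T, phi, sd = 1) {
  innov <- stats::rnorm(T, sd = sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

#' Simulate one participant's ROI time series and confounds
#'
#' @param cfg a \code{"sim_config"}.
#' @param severity latent disease severity (0 for controls); attenuates
#'   planted-hub loadings via \code{cfg$coupling}.
#' @param seed RNG seed for this participant/scan.
#' @param participant_id participant label.
#' @return list with \code{ts} (\code{"roi_timeseries"}), \code{confounds}
#'   (\code{"confound_set"}), and \code{loadings} (the per-ROI shared-signal
#'   loadings actually used).
#' @export
simulate_participant_ts <- function(cfg, severity = 0, seed = 1,
                                    participant_id = "sim") {
  stopifnot(inherits(cfg, "sim_config"))
  T <- cfg$n_timepoints; N <- cfg$n_rois
  lambda <- rep(cfg$base_strength, N)
  lambda[cfg$planted_hubs] <- cfg$hub_strength *
    max(0, 1 - cfg$coupling * severity)
  net <- rep_len(seq_len(cfg$n_networks), N)
  with_seed(seed, {
    s <- ar1_series(T, cfg$ar_phi)
    cnet <- sapply(seq_len(cfg$n_networks),
                   function(k) ar1_series(T, cfg$ar_phi))
    noise <- sapply(seq_len(N),
                    function(j) ar1_series(T, cfg$ar_phi, sd = cfg$noise_sd))
    # motion: smoothed random walks; WM/CSF: low-frequency sinusoid mixtures
    motion <- sapply(1:6, function(k) {
      w <- cumsum(stats::rnorm(T, sd = 0.02))
      as.numeric(stats::filter(w, rep(1 / 5, 5), sides = 2, circular = TRUE))
    })
    tt <- seq_len(T)
    lowfreq <- function() {
      fr <- stats::runif(3, 0.005, 0.02)
      ph <- stats::runif(3, 0, 2 * pi)
      colSums(sin(outer(fr, tt * cfg$tr, "*") * 2 * pi + ph)) / sqrt(3) +
        stats::rnorm(T, sd = 0.1)
    }
    wm <- lowfreq(); csf <- lowfreq()
    w_mot <- matrix(stats::rnorm(6 * N), 6, N)
    w_wm <- stats::rnorm(N); w_csf <- stats::rnorm(N)
    x <- outer(s, lambda) + cnet[, net] * cfg$network_strength + noise +
      cfg$confound_sd * (motion %*% w_mot + outer(wm, w_wm) +
                         outer(csf, w_csf))
    list(ts = roi_timeseries(x, seq_len(N), tr = cfg$tr,
                             participant_id = participant_id),
         confounds = confound_set(motion, wm, csf,
                                  participant_id = participant_id),
         loadings = lambda)
  })
}

softplus <- function(z) ifelse(z > 30, z, log1p(exp(z)))

#' Simulate a paired-eye visual field
#'
#' Total deviation per location is \eqn{-softplus(severity + asymmetry \cdot
#' eye\_sign + field)}, clipped to [-32, 2] dB, where \eqn{field} is a
#' spatially correlated Gaussian field (random linear trend plus local
#' noise); \code{md = mean(td)}.  BIVF therefore decreases monotonically in
#' expectation with severity, and AbsDiffMD grows with |asymmetry|.
#'
#' @param severity latent scalar (0 = healthy-like; larger = worse field).
#' @param asymmetry between-eye asymmetry; the right eye gets
#'   \code{+asymmetry/2}, the left \code{-asymmetry/2}.
#' @param grid "24-2" or "30-2".
#' @param seed RNG seed.
#' @param participant_id participant label.
#' @return list with elements \code{left} and \code{right}
#'   (\code{"vf_map"}).
#' @export
simulate_vf_pair <- function(severity = 0, asymmetry = 0, grid = "24-2",
                             seed = 1, participant_id = "sim") {
  if (!grid %in% c("24-2", "30-2")) stop("invalid grid: ", grid)
  with_seed(seed, {
    maps <- lapply(c(left = -1, right = 1), function(eye_sign) {
      eye <- if (eye_sign > 0) "right" else "left"
      loc <- vf_grid(grid, eye)
      z <- stats::rnorm(3, sd = 0.5)
      field <- z[1] * loc$x_deg / 30 + z[2] * loc$y_deg / 30 + 0.3 * z[3] +
        stats::rnorm(nrow(loc), sd = 0.2)
      td <- -softplus(severity + asymmetry * eye_sign / 2 + field)
      td <- pmin(pmax(td, -32), 2)
      vf_map(eye = eye, td = td, grid = grid, locations = loc,
             participant_id = participant_id)
    })
    maps
  })
}

#' Simulate a full cohort with ground truth
#'
#' Controls get severity 0; patients draw a positive severity
#' (\code{abs(rnorm(severity_mean, severity_sd))}).  Every participant gets
#' two resting-state "scans" with shared loadings but independent latent
#' signals, noise and confounds (so hub test-retest reproducibility is an
#' emergent property), plus a paired-eye visual field generated from the
#' same severity that attenuates their hub loadings.  Perimetry is marked
#' missing for the configured number of participants per group.
#'
#' @param cfg a \code{"sim_config"}.
#' @return an object of class \code{"sim_cohort"}: \code{participants} (list
#'   of bundles with \code{id}, \code{group}, \code{ts} and \code{confounds}
#'   lists indexed by scan, \code{vf}, \code{scores}) and
#'   \code{ground_truth} (planted hubs, per-participant severity, hub
#'   loading, asymmetry and group label), and \code{config}.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_controls + cfg$n_patients
  group <- rep(c("control", "patient"), c(cfg$n_controls, cfg$n_patients))
  ids <- sprintf("%s%02d", ifelse(group == "control", "C", "P"),
                 c(seq_len(cfg$n_controls), seq_len(cfg$n_patients)))
  severity <- with_seed(sub_seed(cfg$seed, "severity"), {
    ifelse(group == "control", 0,
           abs(stats::rnorm(n, cfg$severity_mean, cfg$severity_sd)))
  })
  asymmetry <- with_seed(sub_seed(cfg$seed, "asym"), {
    ifelse(group == "control", stats::rnorm(n, sd = 0.1),
           stats::rnorm(n, sd = cfg$asymmetry_sd))
  })
  scored <- c(seq_len(cfg$n_controls) <= cfg$n_controls_scored,
              seq_len(cfg$n_patients) <= cfg$n_patients_scored)
  participants <- vector("list", n)
  hub_loading <- numeric(n)
  for (i in seq_len(n)) {
    scans <- lapply(1:2, function(scan)
      simulate_participant_ts(cfg, severity[i],
                              seed = sub_seed(cfg$seed, "ts", ids[i], scan),
                              participant_id = ids[i]))
    hub_loading[i] <- scans[[1]]$loadings[cfg$planted_hubs[1]]
    vf <- if (scored[i])
      simulate_vf_pair(severity[i], asymmetry[i], grid = cfg$vf_grid_type,
                       seed = sub_seed(cfg$seed, "vf", ids[i]),
                       participant_id = ids[i])
    else NULL
    participants[[i]] <- list(
      id = ids[i], group = group[i],
      ts = lapply(scans, `[[`, "ts"),
      confounds = lapply(scans, `[[`, "confounds"),
      vf = vf,
      scores = behavioral_scores(vf$left, vf$right, participant_id = ids[i]))
  }
  structure(list(
    participants = participants,
    ground_truth = list(planted_hubs = cfg$planted_hubs,
                        severity = stats::setNames(severity, ids),
                        hub_loading = stats::setNames(hub_loading, ids),
                        asymmetry = stats::setNames(asymmetry, ids),
                        group = stats::setNames(group, ids)),
    config = cfg), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  g <- x$ground_truth$group
  cat(sprintf("Synthetic cohort: %d controls + %d patients, %d ROIs x %d time points, 2 scans\n",
              sum(g == "control"), sum(g == "patient"),
              x$config$n_rois, x$config$n_timepoints))
  cat(sprintf("  planted hubs: %s\n",
              paste(x$ground_truth$planted_hubs, collapse = ", ")))
  invisible(x)
}
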