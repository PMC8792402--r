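# End-to-end cohort analysis: prewhiten -> FC -> whole-brain test -> ECM ->
# hubs -> nulls -> behavioral correlations.

#' Analysis configuration for \code{run_pipeline}
#'
#' All analysis parameters and method flags in one validated list; unknown
#' keys are rejected.  Every stochastic stage derives its own sub-seed from
#' \code{seed}, so identical configurations yield identical results.
#'
#' @param percentile hub percentile (default 95).
#' @param n_perm label permutations per test (default 10000).
#' @param n_surrogates iAAFT surrogate replicates (default 1000).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed master seed.
#' @param whole_brain_statistic group statistic for the whole-brain FC test.
#' @param prewhiten run the two-step AR(1) prewhitening first.
#' @param pooled_phi,scale_first prewhitening flags, see
#'   \code{\link{prewhiten_pipeline}}.
#' @param group_ec \code{"mean_of_participants"} (per-ROI mean of
#'   per-participant EC) or \code{"ec_of_mean_adjacency"}.
#' @param run_nulls compute surrogate/bootstrap EC distributions.
#' @param block_bootstrap moving-block time resampling.
#' @return a \code{"run_config"} list.
#' @export
run_config <- function(percentile = 95, n_perm = 10000, n_surrogates = 1000,
                       n_boot = 1000, seed = 1,
                       whole_brain_statistic = c("diff_of_medians",
                                                 "diff_of_means"),
                       prewhiten = TRUE, pooled_phi = FALSE,
                       scale_first = FALSE,
                       group_ec = c("mean_of_participants",
                                    "ec_of_mean_adjacency"),
                       run_nulls = TRUE, block_bootstrap = FALSE) {
  cfg <- list(percentile = percentile, n_perm = n_perm,
              n_surrogates = n_surrogates, n_boot = n_boot, seed = seed,
              whole_brain_statistic = match.arg(whole_brain_statistic),
              prewhiten = isTRUE(prewhiten), pooled_phi = isTRUE(pooled_phi),
              scale_first = isTRUE(scale_first),
              group_ec = match.arg(group_ec),
              run_nulls = isTRUE(run_nulls),
              block_bootstrap = isTRUE(block_bootstrap))
  class(cfg) <- "run_config"
  cfg
}

group_mean_ec <- function(ts_list, how) {
  if (how == "mean_of_participants") {
    colMeans(cohort_ec_table(ts_list))
  } else {
    A <- Reduce(`+`, lapply(ts_list, function(ts)
      adjacency_from_ts(ts)$a)) / length(ts_list)
    ec <- eigenvector_centrality(A)
    stats::setNames(ec$ec, as.character(ts_list[[1]]$roi_ids))
  }
}

#' Run the full hub analysis on a cohort
#'
#' Executes, per scan: prewhitening, Fisher-z functional connectivity with
#' the whole-brain group permutation test, per-participant eigenvector
#' centrality, group-mean EC and hub identification per group; then the
#' union of hubs found in either group and either scan (hubs enter the
#' correlation analysis only by fulfilling the hub criterion per scan, never
#' by a group difference), the hub-wise group comparison with max-statistic
#' FWE, surrogate/bootstrap EC distributions, behavioral scores and their
#' Spearman correlations with hub EC.
#'
#' @param cohort a \code{"sim_cohort"} from \code{\link{simulate_cohort}},
#'   or any list with the same \code{participants} structure (bundles with
#'   \code{id}, \code{group}, \code{ts} list per scan, \code{confounds} list
#'   per scan, \code{scores} row).
#' @param config a \code{"run_config"}.
#' @return an object of class \code{"ecm_result"}; see Details.
#' @details The result contains, per scan: \code{fc_summary} (per-participant
#'   whole-brain FC by group), \code{whole_brain_test} (a
#'   \code{"perm_test"}), \code{ec} (per-group participants x ROIs tables),
#'   \code{group_ec}, \code{hubs} (per-group \code{"hub_set"}),
#'   \code{hub_test}, \code{nulls} (per-group surrogate and bootstrap
#'   distributions), and \code{correlations}; plus \code{hub_union},
#'   \code{scores}, and a \code{manifest} with the config and seeds.
#' @export
run_pipeline <- function(cohort, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  parts <- cohort$participants
  if (is.null(parts)) stop("cohort has no participants")
  groups <- vapply(parts, `[[`, character(1), "group")
  ids <- vapply(parts, `[[`, character(1), "id")
  glabels <- unique(groups)
  if (length(glabels) > 2) stop("at most two groups supported")
  n_scans <- length(parts[[1]]$ts)
  scans <- vector("list", n_scans)
  for (scan in seq_len(n_scans)) {
    clean <- lapply(seq_along(parts), function(i) {
      ts <- parts[[i]]$ts[[scan]]
      if (config$prewhiten)
        ts <- tryCatch(
          prewhiten_pipeline(ts, parts[[i]]$confounds[[scan]],
                             pooled_phi = config$pooled_phi,
                             scale_first = config$scale_first),
          error = function(e) stop(sprintf(
            "stage prewhiten, participant %s, scan %d: %s",
            parts[[i]]$id, scan, conditionMessage(e)), call. = FALSE))
      ts
    })
    names(clean) <- ids
    fc_sum <- vapply(clean, function(ts)
      participant_fc_summary(fc_matrix(ts)), numeric(1))
    by_group <- split(seq_along(parts), groups)[glabels]
    wb <- if (length(glabels) == 2 && all(lengths(by_group) >= 2)) {
      permutation_group_test(
        fc_sum[by_group[[1]]], fc_sum[by_group[[2]]],
        statistic = config$whole_brain_statistic, n_perm = config$n_perm,
        seed = sub_seed(config$seed, "wb", scan))
    } else NULL
    ec_tables <- lapply(by_group, function(idx) cohort_ec_table(clean[idx]))
    gec <- lapply(by_group, function(idx)
      group_mean_ec(clean[idx], config$group_ec))
    hubs <- lapply(gec, identify_hubs, percentile = config$percentile)
    nulls <- NULL
    if (config$run_nulls) {
      nulls <- lapply(glabels, function(g) list(
        surrogate = surrogate_ec_distribution(
          clean[by_group[[g]]], n_surrogates = config$n_surrogates,
          seed = sub_seed(config$seed, "sur", scan, g)),
        bootstrap = bootstrap_ec_distribution(
          clean[by_group[[g]]], n_boot = config$n_boot,
          seed = sub_seed(config$seed, "boot", scan, g),
          block = config$block_bootstrap)))
      names(nulls) <- glabels
    }
    ec_all <- cohort_ec_table(clean)
    scans[[scan]] <- list(fc_summary = split(fc_sum, groups)[glabels],
                          whole_brain_test = wb, ec = ec_tables,
                          ec_all = ec_all, group_ec = gec, hubs = hubs,
                          nulls = nulls)
  }
  # hubs enter further analysis by fulfilling the criterion in any group/scan
  hub_union <- sort(unique(unlist(lapply(scans, function(s)
    lapply(s$hubs, `[[`, "roi_ids")))))
  scores <- do.call(rbind, lapply(parts, `[[`, "scores"))
  for (scan in seq_len(n_scans)) {
    s <- scans[[scan]]
    scans[[scan]]$hub_test <- if (length(glabels) == 2 &&
                                  all(lengths(s$ec) >= 2)) {
      compare_hub_ec(s$ec[[1]], s$ec[[2]], hub_union,
                     n_perm = config$n_perm,
                     seed = sub_seed(config$seed, "hub", scan))
    } else NULL
    scans[[scan]]$correlations <-
      if (!is.null(scores) && any(!is.na(scores$bivf)))
        correlate_scores_with_ec(scores, s$ec_all, hub_union)
      else NULL
  }
  structure(list(scans = scans, hub_union = hub_union, scores = scores,
                 groups = glabels,
                 manifest = list(config = unclass(config),
                                 n_participants = length(parts),
                                 group_sizes = as.list(table(groups)[glabels]),
                                 n_scans = n_scans,
                                 package_version =
                                   as.character(utils::packageVersion("ecmhub")))),
            class = "ecm_result")
}

#' @export
print.ecm_result <- function(x, ...) {
  cat("Eigenvector-centrality hub analysis\n")
  cat(sprintf("  %d participants (%s), %d scan(s)\n",
              x$manifest$n_participants,
              paste(sprintf("%s: %d", names(x$manifest$group_sizes),
                            unlist(x$manifest$group_sizes)), collapse = ", "),
              x$manifest$n_scans))
  for (scan in seq_along(x$scans)) {
    s <- x$scans[[scan]]
    cat(sprintf("  scan %d:\n", scan))
    if (!is.null(s$whole_brain_test))
      cat(sprintf("    whole-brain FC test: p = %.4g\n",
                  s$whole_brain_test$p_raw))
    for (g in names(s$hubs))
      cat(sprintf("    hubs (%s): %s\n", g,
                  paste(s$hubs[[g]]$roi_ids, collapse = ", ")))
  }
  cat(sprintf("  hub union for correlation: %s\n",
              paste(x$hub_union, collapse = ", ")))
  invisible(x)
}

#' @export
summary.ecm_result <- function(object, ...) {
  x <- object
  print(x)
  for (scan in seq_along(x$scans)) {
    s <- x$scans[[scan]]
    if (!is.null(s$hub_test)) {
      cat(sprintf("\nscan %d hub group comparison (FWE by max statistic):\n",
                  scan))
      print(data.frame(observed = s$hub_test$observed,
                       p_fwe = s$hub_test$p_fwe), digits = 3)
    }
    if (!is.null(s$correlations)) {
      cat(sprintf("\nscan %d hub-score Spearman correlations:\n", scan))
      print(s$correlations, digits = 3)
    }
  }
  invisible(x)
}

#' Group-mean eigenvector centralities of a fitted analysis
#'
#' @param object an \code{"ecm_result"}.
#' @param scan scan index.
#' @param ... unused.
#' @return ROIs x groups matrix of group-mean EC.
#' @export
coef.ecm_result <- function(object, scan = 1, ...) {
  do.call(cbind, object$scans[[scan]]$group_ec)
}

#' Diagnostic plots for a fitted hub analysis
#'
#' Draws (1) histograms of per-participant whole-brain FC by group, (2) the
#' scan-1 vs scan-2 group-mean EC scatter with a least-squares line when two
#' scans are present, (3) bootstrap vs surrogate EC density overlays for the
#' first hubs, and (4) score-vs-EC scatter for the first hub, as available.
#'
#' @param x an \code{"ecm_result"}.
#' @param which subset of panels 1:4.
#' @param ... unused.
#' @export
plot.ecm_result <- function(x, which = 1:4, ...) {
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  s1 <- x$scans[[1]]
  if (1 %in% which) {
    all_fc <- unlist(s1$fc_summary)
    graphics::hist(all_fc, breaks = "FD", main = "whole-brain FC",
                   xlab = "mean Fisher z")
  }
  if (2 %in% which && length(x$scans) >= 2) {
    e1 <- x$scans[[1]]$group_ec[[1]]; e2 <- x$scans[[2]]$group_ec[[1]]
    plot(e1, e2, xlab = "EC scan 1", ylab = "EC scan 2",
         main = "test-retest EC")
    graphics::abline(stats::lm(e2 ~ e1))
  }
  if (3 %in% which && !is.null(s1$nulls)) {
    g <- names(s1$nulls)[1]
    hub1 <- x$hub_union[1]
    plot(s1$nulls[[g]]$surrogate, roi_ids = hub1, col = "black")
    plot(s1$nulls[[g]]$bootstrap, roi_ids = hub1, add = TRUE,
         col = "steelblue")
  }
  if (4 %in% which && !is.null(s1$correlations) && !is.null(x$scores)) {
    hub1 <- x$hub_union[1]
    ec <- s1$ec_all[match(x$scores$participant_id, rownames(s1$ec_all)), hub1]
    plot(x$scores$bivf, ec, xlab = "BIVF (dB)", ylab = sprintf("EC ROI %s", hub1),
         main = "BIVF vs hub EC")
  }
  invisible(x)
}

# strip heavy matrices for serialization, keep every reported statistic
result_for_json <- function(x) {
  list(
    manifest = x$manifest,
    hub_union = x$hub_union,
    scores = x$scores,
    groups = x$groups,
    scans = lapply(x$scans, function(s) list(
      fc_summary = s$fc_summary,
      whole_brain_test = if (!is.null(s$whole_brain_test))
        unclass(s$whole_brain_test),
      group_ec = s$group_ec,
      hubs = lapply(s$hubs, unclass),
      hub_test = if (!is.null(s$hub_test)) unclass(s$hub_test),
      null_gaussians = if (!is.null(s$nulls)) lapply(s$nulls, function(g)
        lapply(g, function(d) list(kind = d$kind, gauss_mu = d$gauss_mu,
                                   gauss_sigma = d$gauss_sigma,
                                   seed = d$seed, config = d$config))),
      correlations = s$correlations)))
}

#' Write a pipeline result as deterministic JSON
#'
#' Serialises every reported statistic (manifest, group summaries, tests,
#' hub sets, null-fit parameters, correlations) with full precision; heavy
#' replicate matrices are omitted.  Identical config + inputs give
#' byte-identical files.
#'
#' @param result an \code{"ecm_result"}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "ecm_result"))
  jsonlite::write_json(result_for_json(result), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Human-readable report with figures
#'
#' Writes a text summary and PNG figures (whole-brain FC histogram,
#' test-retest EC scatter, null/bootstrap density overlays, score-EC
#' scatter) to a directory.  Purely presentational: no new statistics are
#' computed.  A hub-group difference is annotated as replicated when its
#' FWE-corrected p-value is significant in both scans.
#'
#' @param result an \code{"ecm_result"}.
#' @param dir output directory (created if needed).
#' @param alpha significance level used in the annotations.
#' @return \code{dir}, invisibly.
#' @export
report <- function(result, dir, alpha = 0.05) {
  stopifnot(inherits(result, "ecm_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  txt <- file.path(dir, "summary.txt")
  con <- file(txt, "w"); on.exit(close(con))
  sink(con); on.exit(sink(), add = TRUE, after = FALSE)
  summary(result)
  if (length(result$scans) >= 2) {
    t1 <- result$scans[[1]]$hub_test; t2 <- result$scans[[2]]$hub_test
    if (!is.null(t1) && !is.null(t2)) {
      rep_hubs <- result$hub_union[t1$p_fwe <= alpha & t2$p_fwe <= alpha]
      cat("\nreplicated hub group differences (significant in both scans): ",
          if (length(rep_hubs)) paste(rep_hubs, collapse = ", ") else "none",
          "\n", sep = "")
    }
    c1 <- result$scans[[1]]$correlations; c2 <- result$scans[[2]]$correlations
    if (!is.null(c1) && !is.null(c2)) {
      both <- merge(c1, c2, by = c("hub", "score"), suffixes = c("_rs1", "_rs2"))
      rep_cor <- both[!is.na(both$p_rs1) & !is.na(both$p_rs2) &
                      both$p_rs1 <= alpha & both$p_rs2 <= alpha, ]
      cat("replicated hub-score correlations: ",
          if (nrow(rep_cor)) paste(sprintf("%s/%s", rep_cor$hub,
                                           rep_cor$score), collapse = ", ")
          else "none", "\n", sep = "")
    }
  } else cat("\nsingle scan: replication annotations skipped\n")
  sink(); on.exit(close(con))     # reset sink before plotting
  for (w in 1:4) {
    skip <- (w == 2 && length(result$scans) < 2) ||
            (w == 3 && is.null(result$scans[[1]]$nulls)) ||
            (w == 4 && (is.null(result$scans[[1]]$correlations) ||
                        is.null(result$scores)))
    if (skip) { warning("report: panel ", w, " skipped (section missing)")
                next }
    grDevices::png(file.path(dir, sprintf("panel%d.png", w)),
                   width = 600, height = 500)
    plot(result, which = w)
    grDevices::dev.off()
  }
  invisible(dir)
}
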