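#' Run manifests
#'
#' Every pipeline run emits one manifest: the command name, a snapshot of
#' the configuration (including every default the analysis leaves open),
#' the seed(s), input/output paths, package version, a config fingerprint
#' and a timestamp. A manifest suffices to replay a deterministic run.
#'
#' @param command character, e.g. "simulate".
#' @param config list of parameters in effect.
#' @param seed integer seed(s).
#' @param inputs,outputs character vectors of paths.
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(command, config, seed = NULL,
                         inputs = character(0), outputs = character(0)) {
  structure(list(
    command = command,
    config = config,
    config_hash = qp_hash(config),
    seed = seed,
    inputs = inputs, outputs = outputs,
    package_version = as.character(utils::packageVersion("qpalmspt")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
}

write_manifest <- function(manifest, path) {
  m <- unclass(manifest)
  m$config <- unclass(m$config)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Simulate a dataset to disk
#'
#' Delegates to the synthetic-data generator and writes the localization
#' CSV, ground-truth CSV and a run manifest into `out_dir`. Identical
#' configs produce identical data files.
#'
#' @param config a [sim_config()] or path to a YAML config.
#' @param out_dir output directory (created if missing).
#' @param what `"field"` (clustered localization field), `"tracks"`, or
#'   `"blinks"` (blink histogram only).
#' @param n for `"tracks"`/`"blinks"`: number of tracks / clusters.
#' @return list with the simulated objects and the manifest, invisibly.
#' @export
run_simulate <- function(config, out_dir, what = c("field", "tracks", "blinks"),
                         n = NULL) {
  what <- match.arg(what)
  if (is.character(config)) config <- read_sim_config(config)
  .validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outs <- character(0)
  res <- switch(what,
    field = {
      sim <- sim_localization_field(config)
      loc_path <- file.path(out_dir, "localizations.csv")
      gt_path <- file.path(out_dir, "ground_truth.csv")
      write_localizations(sim$table, loc_path)
      utils::write.csv(sim$truth, gt_path, row.names = FALSE)
      outs <- c(loc_path, gt_path)
      sim
    },
    tracks = {
      sim <- sim_tracks(config, n_tracks = n %||% 500)
      loc_path <- file.path(out_dir, "localizations.csv")
      trk_path <- file.path(out_dir, "tracks.csv")
      gt_path <- file.path(out_dir, "ground_truth.csv")
      write_localizations(sim$table, loc_path)
      utils::write.csv(as.data.frame(sim$tracks), trk_path, row.names = FALSE)
      utils::write.csv(sim$truth, gt_path, row.names = FALSE)
      outs <- c(loc_path, trk_path, gt_path)
      sim
    },
    blinks = {
      sim <- sim_blink_counts(n %||% 5000L, config)
      gt_path <- file.path(out_dir, "ground_truth.csv")
      utils::write.csv(sim$truth, gt_path, row.names = FALSE)
      outs <- gt_path
      sim
    })
  manifest <- run_manifest(paste0("simulate/", what), config,
                           seed = config$seed, outputs = outs)
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  invisible(c(res, list(manifest = manifest)))
}

#' qPALM counting pipeline
#'
#' Runs appearance extraction, nanocluster grouping and the blink-count
#' fit on a localization table: in `"mixture"` mode the monomer/dimer
#' mixture fit with fixed photophysics (`p`, `d_abs`), in `"reference"`
#' mode the monomeric p fit (and, when `d_abs` reference fitting is wanted,
#' use [fit_q()] directly on the returned histogram). With a ligand table
#' the analysis is additionally run on the colocalization-gated subset.
#'
#' @param table a [localization_table()] or CSV path.
#' @param mode `"mixture"` or `"reference"`.
#' @param p bleaching probability (required).
#' @param d_abs absolute detection efficiency (required in mixture mode).
#' @param ligand optional ligand-channel [localization_table()] or path.
#' @param coloc_radius nm, colocalization gate (default 150).
#' @param max_dark_frames,merge_radius,eps,min_events,n_max grouping and
#'   histogram settings (see [extract_appearances()], [cluster_events()]).
#' @param B,seed bootstrap settings.
#' @param out optional path for a JSON report.
#' @return list of class `counting_report`: clusters, histogram, fit(s),
#'   settings, manifest.
#' @export
run_count <- function(table, mode = c("mixture", "reference"),
                      p = NULL, d_abs = NULL, ligand = NULL,
                      coloc_radius = 150,
                      max_dark_frames = 3, merge_radius = 30, eps = 50,
                      min_events = 1, n_max = 50, B = 1000, seed = 1,
                      out = NULL) {
  mode <- match.arg(mode)
  if (is.character(table)) table <- read_localizations(table)
  if (is.character(ligand)) ligand <- read_localizations(ligand)
  if (is.null(p)) qp_stop("qp_usage_error", "p must be supplied")
  if (mode == "mixture" && is.null(d_abs))
    qp_stop("qp_usage_error", "d_abs must be supplied in mixture mode")
  events <- extract_appearances(table, max_dark_frames, merge_radius)
  clusters <- cluster_events(events, eps, min_events)
  hist <- blink_histogram(clusters, n_max = n_max)
  fit <- if (mode == "mixture") fit_mixture(hist, p, d_abs, B = B, seed = seed)
  else fit_p(hist, B = B, seed = seed)
  gated <- NULL
  if (!is.null(ligand)) {
    sub <- colocalization_filter(clusters, ligand, coloc_radius)
    gated <- list(clusters = sub,
                  fit = if (nrow(sub)) {
                    h <- blink_histogram(sub, n_max = n_max)
                    if (mode == "mixture")
                      fit_mixture(h, p, d_abs, B = B, seed = seed)
                    else fit_p(h, B = B, seed = seed)
                  })
  }
  settings <- list(mode = mode, p = p, d_abs = d_abs,
                   max_dark_frames = max_dark_frames,
                   merge_radius = merge_radius, eps = eps,
                   min_events = min_events, n_max = n_max,
                   coloc_radius = if (!is.null(ligand)) coloc_radius,
                   B = B, seed = seed)
  report <- structure(list(clusters = clusters, histogram = hist, fit = fit,
                           gated = gated, settings = settings,
                           manifest = run_manifest("count", settings,
                                                   seed = seed)),
                      class = "counting_report")
  if (!is.null(out)) write_counting_report(report, out)
  report
}

# JSON-serializable view of a counting report.
write_counting_report <- function(report, path) {
  fit <- report$fit
  fit_json <- if (inherits(fit, "mixture_fit")) {
    list(type = "mixture",
         fractions_true = as.list(fit$fractions),
         fractions_observed = as.list(fit$fractions_observed),
         ci = lapply(fit$ci, unclass), loglik = fit$loglik,
         converged = fit$converged, n_clusters = fit$n_clusters)
  } else {
    list(type = "reference_p", p = fit$p, ci = unclass(fit$ci),
         n_clusters = fit$n_clusters)
  }
  jsonlite::write_json(list(fit = fit_json, settings = report$settings,
                            manifest = unclass(report$manifest)),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' sptPALM tracking pipeline
#'
#' Links a localization table into trajectories, computes per-track MSD
#' classifications and returns the mobility report; with a second channel
#' a paired receptor-vs-ligand comparison is appended.
#'
#' @param table a [localization_table()] or CSV path (receptor channel).
#' @param sigma_loc localization precision (nm) used for the noise floor.
#' @param ligand optional ligand-channel table or path.
#' @param max_disp,max_gap linking parameters ([link_localizations()]).
#' @param condition label carried into the report.
#' @inheritParams mobility_report
#' @param out optional path for a JSON report.
#' @return list of class `tracking_report`: `tracks`, `report`,
#'   `comparison` (if two channels), `manifest`.
#' @export
run_track <- function(table, sigma_loc = 10, ligand = NULL,
                      max_disp = 500, max_gap = 1, bootstrap_B = 500,
                      seed = 1, condition = "", out = NULL) {
  if (is.character(table)) table <- read_localizations(table)
  if (is.character(ligand)) ligand <- read_localizations(ligand)
  tracks <- link_localizations(table, max_disp, max_gap)
  rep_r <- mobility_report(tracks, sigma_loc, bootstrap_B = bootstrap_B,
                           seed = seed, condition = condition)
  comparison <- NULL
  if (!is.null(ligand)) {
    tr_l <- link_localizations(ligand, max_disp, max_gap)
    rep_l <- mobility_report(tr_l, sigma_loc, bootstrap_B = bootstrap_B,
                             seed = seed, condition = paste0(condition, "/ligand"))
    comparison <- compare_channels(rep_r, rep_l)
  }
  settings <- list(sigma_loc = sigma_loc, max_disp = max_disp,
                   max_gap = max_gap, bootstrap_B = bootstrap_B, seed = seed)
  res <- structure(list(tracks = tracks, report = rep_r,
                        comparison = comparison,
                        manifest = run_manifest("track", settings, seed = seed)),
                   class = "tracking_report")
  if (!is.null(out)) {
    r <- res$report
    jsonlite::write_json(
      list(condition = r$condition, n_tracks = r$n_tracks,
           fractions = as.list(r$fractions),
           fractions_sem = as.list(r$fractions_sem),
           D_mean = as.list(r$D_mean), D_sem = as.list(r$D_sem),
           settings = c(settings, r$settings),
           comparison = comparison,
           manifest = unclass(res$manifest)),
      out, auto_unbox = TRUE, digits = NA, null = "null")
  }
  res
}
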