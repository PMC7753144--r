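#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' are the conditions of the study the pipeline targets: mEos4b-tagged
#' receptor fields with nanocluster density 0.63 per square micrometre,
#' bleaching probability p = 0.27, per-protomer detection efficiency
#' d = 0.79, labeling efficiency L = 0.81 (absolute detection efficiency
#' 0.64), localization precision 10 nm, a resting-state composition of 5%
#' dimers, and three-state diffusion (immobile/confined/free) at membrane-
#' receptor scales with a 20 ms frame time.
#'
#' @param seed master RNG seed; per-component streams (population,
#'   photophysics, positions, noise, diffusion, ligand) are derived from it
#'   so that changing one simulation axis leaves the others untouched.
#' @param fov_nm field of view `c(width, height)` in nm.
#' @param n_frames,frame_time acquisition length (frames) and frame time (s).
#' @param sigma_loc localization precision (nm) added to every position.
#' @param p,d,L photophysics: bleaching probability per appearance,
#'   per-protomer detection efficiency, labeling efficiency.
#' @param lambda_um2 nanocluster density (clusters per um^2).
#' @param composition named fractions over oligomer sizes
#'   `c(monomer, dimer)`, summing to 1.
#' @param max_dark_frames dark-gap tolerance the downstream event
#'   extraction will use; inter-appearance gaps are drawn strictly larger.
#' @param diffusion list: `fractions` (immobile/confined/free, summing to
#'   1), `D_free`, `D_conf` (um^2/s), `r_c` (confinement radius, nm),
#'   `track_mean_length` (frames, geometric; minimum 8).
#' @param ligand list: `bound_fraction`, `channel_sigma` (registration
#'   noise, nm), `locs_per_site`.
#' @return object of class `sim_config` (a named list).
#' @export
sim_config <- function(seed = 1,
                       fov_nm = c(10000, 10000),
                       n_frames = 10000, frame_time = 0.02,
                       sigma_loc = 10,
                       p = 0.27, d = 0.79, L = 0.81,
                       lambda_um2 = 0.63,
                       composition = c(monomer = 0.95, dimer = 0.05),
                       max_dark_frames = 3,
                       diffusion = list(
                         fractions = c(immobile = 0.15, confined = 0.25,
                                       free = 0.60),
                         D_free = 0.1, D_conf = 0.03, r_c = 100,
                         track_mean_length = 20),
                       ligand = list(bound_fraction = 0.5,
                                     channel_sigma = 20,
                                     locs_per_site = 5)) {
  cfg <- list(seed = as.integer(seed), fov_nm = fov_nm, n_frames = n_frames,
              frame_time = frame_time, sigma_loc = sigma_loc,
              p = p, d = d, L = L, lambda_um2 = lambda_um2,
              composition = composition, max_dark_frames = max_dark_frames,
              diffusion = diffusion, ligand = ligand)
  .validate_config(cfg)
  structure(cfg, class = "sim_config")
}

.validate_config <- function(cfg) {
  chk_prob <- function(x, nm, lo = 0, hi = 1) {
    if (!is.numeric(x) || any(x < lo) || any(x > hi) || anyNA(x))
      qp_param_error("config field '%s' out of range", nm)
  }
  if (!is_count(cfg$seed %||% NA)) qp_param_error("config field 'seed' must be an integer")
  chk_prob(cfg$p, "p"); chk_prob(cfg$d, "d"); chk_prob(cfg$L, "L")
  if (cfg$p <= 0 || cfg$d <= 0 || cfg$L <= 0)
    qp_param_error("p, d and L must be > 0")
  if (!is.numeric(cfg$lambda_um2) || cfg$lambda_um2 <= 0)
    qp_param_error("config field 'lambda_um2' must be > 0")
  chk_prob(cfg$composition, "composition")
  if (abs(sum(cfg$composition) - 1) > 1e-9)
    qp_param_error("composition fractions must sum to 1")
  chk_prob(cfg$diffusion$fractions, "diffusion$fractions")
  if (abs(sum(cfg$diffusion$fractions) - 1) > 1e-9)
    qp_param_error("diffusion fractions must sum to 1")
  if (cfg$sigma_loc < 0) qp_param_error("sigma_loc must be >= 0")
  if (!is_count(cfg$n_frames) || cfg$n_frames < 1)
    qp_param_error("n_frames must be a positive integer")
  chk_prob(cfg$ligand$bound_fraction, "ligand$bound_fraction")
  invisible(cfg)
}

# Independent per-component seed streams derived from the master seed.
.streams <- function(seed) {
  s <- with_seed(seed, sample.int(2147483646L, 6))
  names(s) <- c("population", "photophysics", "positions", "noise",
                "diffusion", "ligand")
  s
}

#' Read / write a simulation config as YAML
#' @param config a [sim_config()].
#' @param path YAML file path.
#' @return `read_sim_config`: a `sim_config`; `write_sim_config`: `path`.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) qp_stop("qp_io_error", "file not found: %s", path)
  obj <- tryCatch(yaml::read_yaml(path), error = function(e)
    qp_stop("qp_usage_error", "malformed config YAML: %s", conditionMessage(e)))
  defaults <- sim_config()
  for (nm in names(obj)) {
    if (!nm %in% names(defaults))
      qp_stop("qp_usage_error", "unknown config field '%s'", nm)
    if (is.list(defaults[[nm]])) {
      for (sub in names(obj[[nm]])) {
        v <- unlist(obj[[nm]][[sub]])
        if (!is.null(names(defaults[[nm]][[sub]])) && is.null(names(v)))
          names(v) <- names(defaults[[nm]][[sub]])
        defaults[[nm]][[sub]] <- v
      }
    } else {
      v <- unlist(obj[[nm]])
      if (!is.null(names(defaults[[nm]])) && is.null(names(v)))
        names(v) <- names(defaults[[nm]])
      defaults[[nm]] <- v
    }
  }
  .validate_config(defaults)
  structure(defaults, class = "sim_config")
}

# Draw cluster populations (oligomer size, labeled and detected protomer
# counts), conditioned on >= 1 detected protomer by rejection; the
# rejected count is recorded so detectability corrections can be validated
# exactly.
.draw_population <- function(n_clusters, cfg) {
  sizes_avail <- c(monomer = 1L, dimer = 2L)
  acc <- list(); got <- 0L
  while (got < n_clusters) {
    batch <- max(2L * (n_clusters - got), 100L)
    size <- sizes_avail[sample.int(2L, batch, replace = TRUE,
                                   prob = cfg$composition)]
    labeled <- stats::rbinom(batch, size, cfg$L)
    detected <- stats::rbinom(batch, labeled, cfg$d)
    acc[[length(acc) + 1L]] <- data.frame(size = as.integer(size),
                                          labeled = labeled,
                                          detected = detected)
    got <- got + sum(detected >= 1L)
  }
  all <- do.call(rbind, acc)
  keep <- all$detected >= 1L
  # position of the n-th acceptance: rejections after it never happened
  pos <- which(cumsum(keep) == n_clusters)[1L]
  out <- all[keep & seq_len(nrow(all)) <= pos, , drop = FALSE][seq_len(n_clusters), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- pos - n_clusters
  out
}

#' Simulate per-nanocluster blink counts
#'
#' Generative twin of the counting model: each cluster draws an oligomer
#' size from the configured composition, each protomer is labeled with
#' probability `L` and detected with probability `d`; clusters with zero
#' detected protomers are unobservable and are regenerated (the rejected
#' count is recorded as attribute `n_rejected` of the truth, so the
#' detectability correction can be checked exactly). Every detected
#' protomer contributes `1 + Geometric(p)` appearances.
#'
#' @param n_clusters number of observable clusters to generate.
#' @param config a [sim_config()].
#' @param n_max histogram truncation bound passed to [blink_histogram()].
#' @return list: `hist` (a [blink_histogram()]) and `truth` (data.frame
#'   `cluster_id`, `size`, `labeled`, `detected`, `n_appearances`).
#' @export
sim_blink_counts <- function(n_clusters, config, n_max = 50) {
  if (!is_count(n_clusters) || n_clusters < 1)
    qp_param_error("n_clusters must be an integer >= 1")
  .validate_config(config)
  streams <- .streams(config$seed)
  truth <- with_seed(streams[["population"]],
                     .draw_population(n_clusters, config))
  counts <- with_seed(streams[["photophysics"]], {
    k <- truth$detected
    per_prot <- stats::rgeom(sum(k), config$p) + 1L
    as.integer(rowsum(per_prot, rep(seq_len(n_clusters), k)))
  })
  n_rej <- attr(truth, "n_rejected")
  truth <- cbind(cluster_id = seq_len(n_clusters), truth,
                 n_appearances = counts)
  attr(truth, "n_rejected") <- n_rej
  list(hist = blink_histogram(counts, n_max = n_max), truth = truth)
}

#' Simulate a clustered localization field
#'
#' Nanocluster centers are drawn from a homogeneous Poisson process at the
#' configured density; per-cluster blink counts come from the same
#' generative model as [sim_blink_counts()]. Each appearance occupies one
#' frame; successive appearance events of one cluster are separated by
#' dark gaps strictly longer than `max_dark_frames` (gap =
#' `max_dark_frames + 1 + Geometric(0.2)` frames), so event extraction at
#' the matching defaults recovers the appearance structure exactly. Every
#' localization is jittered by Gaussian noise of width `sigma_loc`.
#'
#' @param config a [sim_config()].
#' @param n_clusters optional fixed cluster count (overrides the Poisson
#'   draw).
#' @return list: `table` (a [localization_table()], channel 0), `truth`
#'   (per-cluster data.frame `cluster_id`, `x`, `y`, `size`, `labeled`,
#'   `detected`, `n_appearances`; localization-level assignment as
#'   attribute `loc_cluster`).
#' @export
sim_localization_field <- function(config, n_clusters = NULL) {
  .validate_config(config)
  streams <- .streams(config$seed)
  area_um2 <- prod(config$fov_nm) / 1e6
  n_cl <- with_seed(streams[["positions"]], {
    n <- n_clusters %||% stats::rpois(1, config$lambda_um2 * area_um2)
    max(n, 1L)
  })
  blink <- sim_blink_counts(n_cl, config)
  truth <- blink$truth
  pos <- with_seed(streams[["positions"]], {
    stats::runif(2L * n_cl)   # burn the count draw reproducibly
    cbind(x = stats::runif(n_cl, 0, config$fov_nm[1]),
          y = stats::runif(n_cl, 0, config$fov_nm[2]))
  })
  truth$x <- pos[, "x"]; truth$y <- pos[, "y"]
  frames <- with_seed(streams[["photophysics"]] + 1L, {
    lapply(seq_len(n_cl), function(i) {
      k <- truth$n_appearances[i]
      # frame difference between successive events must exceed
      # max_dark_frames + 1 so extraction never merges two appearances
      gaps <- config$max_dark_frames + 2L + stats::rgeom(k, 0.2)
      start <- sample.int(max(config$n_frames %/% 2L, 1L), 1L) - 1L
      f <- start + cumsum(c(0L, gaps[-1L]))
      pmin(f, config$n_frames - 1L)
    })
  })
  loc_cluster <- rep(seq_len(n_cl), truth$n_appearances)
  fr <- unlist(frames)
  n_loc <- length(fr)
  noise <- with_seed(streams[["noise"]], {
    matrix(stats::rnorm(2L * n_loc, 0, config$sigma_loc), ncol = 2)
  })
  df <- data.frame(frame = fr,
                   x = truth$x[loc_cluster] + noise[, 1],
                   y = truth$y[loc_cluster] + noise[, 2],
                   precision = if (config$sigma_loc > 0) config$sigma_loc
                   else NA_real_,
                   channel = 0L)
  ord <- order(df$frame)
  df <- df[ord, , drop = FALSE]
  attr(truth, "loc_cluster") <- loc_cluster[ord]
  tab <- localization_table(df, frame_time = config$frame_time,
                            fov = config$fov_nm)
  list(table = tab, truth = truth)
}

#' Simulate three-state diffusing trajectories
#'
#' Each track draws a diffusion state from the configured fractions:
#' immobile tracks are static points, free tracks are 2D Brownian walks
#' with per-axis step variance `2 D_free dt`, and confined tracks are
#' Brownian walks reflected at a circle of radius `r_c` around their
#' origin. Track lengths are `8 + Geometric` with the configured mean;
#' every sample carries Gaussian localization noise of width `sigma_loc`.
#'
#' @param config a [sim_config()].
#' @param n_tracks number of tracks.
#' @return list: `tracks` (a `track_set` with ground-truth ids), `table`
#'   (the flattened [localization_table()]), `truth` (per-track data.frame
#'   `track_id`, `state`, `D`, `r_c`, `length`, `x0`, `y0`, `start_frame`).
#' @export
sim_tracks <- function(config, n_tracks = 500) {
  .validate_config(config)
  if (!is_count(n_tracks) || n_tracks < 1)
    qp_param_error("n_tracks must be an integer >= 1")
  streams <- .streams(config$seed)
  dif <- config$diffusion
  mean_len <- max(dif$track_mean_length, 9)
  truth <- with_seed(streams[["diffusion"]], {
    state <- .states[sample.int(3L, n_tracks, replace = TRUE,
                                prob = dif$fractions)]
    len <- 8L + stats::rgeom(n_tracks, 1 / (mean_len - 7))
    data.frame(track_id = seq_len(n_tracks), state = state,
               D = ifelse(state == "free", dif$D_free,
                          ifelse(state == "confined", dif$D_conf, 0)),
               r_c = ifelse(state == "confined", dif$r_c, NA_real_),
               length = len)
  })
  pos0 <- with_seed(streams[["positions"]], {
    cbind(x0 = stats::runif(n_tracks, 0, config$fov_nm[1]),
          y0 = stats::runif(n_tracks, 0, config$fov_nm[2]),
          start = floor(stats::runif(n_tracks) *
                          pmax(config$n_frames - truth$length, 1)))
  })
  truth$x0 <- pos0[, "x0"]; truth$y0 <- pos0[, "y0"]
  truth$start_frame <- as.integer(pos0[, "start"])
  paths <- with_seed(streams[["diffusion"]] + 1L, {
    lapply(seq_len(n_tracks), function(i) {
      len <- truth$length[i]
      if (truth$state[i] == "immobile") {
        cbind(x = rep(truth$x0[i], len), y = rep(truth$y0[i], len))
      } else {
        step_sd <- sqrt(2 * truth$D[i] * config$frame_time) * 1000  # nm
        dx <- stats::rnorm(len - 1, 0, step_sd)
        dy <- stats::rnorm(len - 1, 0, step_sd)
        if (truth$state[i] == "confined") {
          x <- numeric(len); y <- numeric(len)
          x[1] <- truth$x0[i]; y[1] <- truth$y0[i]
          for (t in 2:len) {
            px <- x[t - 1] + dx[t - 1]; py <- y[t - 1] + dy[t - 1]
            r <- sqrt((px - truth$x0[i])^2 + (py - truth$y0[i])^2)
            if (r > dif$r_c) {          # radial reflection at the boundary
              scale <- (2 * dif$r_c - r) / r
              px <- truth$x0[i] + (px - truth$x0[i]) * scale
              py <- truth$y0[i] + (py - truth$y0[i]) * scale
            }
            x[t] <- px; y[t] <- py
          }
          cbind(x = x, y = y)
        } else {
          cbind(x = truth$x0[i] + cumsum(c(0, dx)),
                y = truth$y0[i] + cumsum(c(0, dy)))
        }
      }
    })
  })
  n_samp <- sum(truth$length)
  noise <- with_seed(streams[["noise"]] + 1L,
                     matrix(stats::rnorm(2L * n_samp, 0, config$sigma_loc),
                            ncol = 2))
  id <- rep(truth$track_id, truth$length)
  fr <- unlist(lapply(seq_len(n_tracks), function(i)
    truth$start_frame[i] + seq_len(truth$length[i]) - 1L))
  xy <- do.call(rbind, paths)
  df <- data.frame(track_id = id, frame = fr,
                   x = xy[, "x"] + noise[, 1],
                   y = xy[, "y"] + noise[, 2])
  tracks <- track_set(df, frame_time = config$frame_time)
  tab <- localization_table(
    data.frame(frame = df$frame, x = df$x, y = df$y,
               precision = if (config$sigma_loc > 0) config$sigma_loc
               else NA_real_, channel = 0L),
    frame_time = config$frame_time, fov = config$fov_nm)
  list(tracks = tracks, table = tab, truth = truth)
}

#' Simulate the ligand channel of a two-color experiment
#'
#' Draws a bound/unbound flag for every site in the ground truth (clusters
#' from [sim_localization_field()] or tracks from [sim_tracks()]) with the
#' configured bound fraction, and places ligand-channel localizations at
#' the bound sites with channel-registration noise.
#'
#' @param truth ground-truth data.frame from a prior simulation (needs
#'   site coordinates `x`,`y` or `x0`,`y0`).
#' @param config a [sim_config()].
#' @return list: `table` (ligand [localization_table()], channel 1) and
#'   `truth` (input truth with a logical `bound` column added).
#' @export
sim_ligand_channel <- function(truth, config) {
  .validate_config(config)
  if (is.null(truth) || !is.data.frame(truth) || !nrow(truth))
    qp_data_error("missing or empty ground truth")
  sx <- truth$x %||% truth$x0
  sy <- truth$y %||% truth$y0
  if (is.null(sx) || is.null(sy))
    qp_data_error("ground truth lacks site coordinates")
  streams <- .streams(config$seed)
  lig <- config$ligand
  n <- nrow(truth)
  out <- with_seed(streams[["ligand"]], {
    bound <- stats::runif(n) < lig$bound_fraction
    idx <- rep(which(bound), each = lig$locs_per_site)
    m <- length(idx)
    df <- data.frame(
      frame = if (m) sample.int(config$n_frames, m, replace = TRUE) - 1L
      else integer(0),
      x = sx[idx] + stats::rnorm(m, 0, lig$channel_sigma),
      y = sy[idx] + stats::rnorm(m, 0, lig$channel_sigma),
      channel = rep(1L, m))
    list(df = df, bound = bound)
  })
  truth$bound <- out$bound
  tab <- localization_table(out$df, frame_time = config$frame_time,
                            fov = config$fov_nm)
  list(table = tab, truth = truth)
}
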