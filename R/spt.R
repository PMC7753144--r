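#' Link localizations into trajectories
#'
#' Greedy nearest-neighbour frame-to-frame linking with gap closing: at
#' each frame, candidate (track, localization) pairs within
#' `max_disp * (gap + 1)` nm are assigned in order of increasing distance
#' (ties broken by lower localization index), each track and localization
#' at most once. Tracks not extended for more than `max_gap` frames are
#' closed; unassigned localizations open new tracks. Deterministic.
#'
#' @param table a [localization_table()] sorted by frame.
#' @param max_disp nm, maximum displacement per frame.
#' @param max_gap frames a track may go dark and still be continued.
#' @return data.frame of class `track_set` (`track_id`, `frame`, `x`, `y`,
#'   plus `channel` if present) with attribute `frame_time`.
#' @export
link_localizations <- function(table, max_disp = 500, max_gap = 1) {
  if (!is.numeric(max_disp) || max_disp < 0) qp_param_error("max_disp must be >= 0")
  if (!is_count(max_gap) || max_gap < 0) qp_param_error("max_gap must be an integer >= 0")
  n <- nrow(table)
  track_of <- integer(n)
  lastx <- numeric(0); lasty <- numeric(0); lastf <- integer(0); tid <- integer(0)
  next_id <- 1L
  frames <- table$frame; xs <- table$x; ys <- table$y
  for (fr in unique(frames)) {
    alive <- lastf >= fr - (max_gap + 1L)
    lastx <- lastx[alive]; lasty <- lasty[alive]
    lastf <- lastf[alive]; tid <- tid[alive]
    idx <- which(frames == fr)
    if (length(tid)) {
      gap <- fr - lastf - 1L
      lim2 <- (max_disp * (gap + 1L))^2
      d2 <- outer(lastx, xs[idx], "-")^2 + outer(lasty, ys[idx], "-")^2
      ok <- which(d2 <= matrix(lim2, nrow = length(tid), ncol = length(idx)),
                  arr.ind = TRUE)
      if (nrow(ok)) {
        ord <- order(d2[ok], ok[, 2])
        used_t <- logical(length(tid)); used_l <- logical(length(idx))
        for (k in ord) {
          ti <- ok[k, 1]; li <- ok[k, 2]
          if (used_t[ti] || used_l[li]) next
          used_t[ti] <- TRUE; used_l[li] <- TRUE
          track_of[idx[li]] <- tid[ti]
          lastx[ti] <- xs[idx[li]]; lasty[ti] <- ys[idx[li]]; lastf[ti] <- fr
        }
        idx <- idx[!used_l]
      }
    }
    if (length(idx)) {
      ids <- next_id + seq_along(idx) - 1L
      next_id <- next_id + length(idx)
      track_of[idx] <- ids
      lastx <- c(lastx, xs[idx]); lasty <- c(lasty, ys[idx])
      lastf <- c(lastf, rep(fr, length(idx))); tid <- c(tid, ids)
    }
  }
  out <- data.frame(track_id = track_of, frame = frames, x = xs, y = ys)
  if (!is.null(table$channel)) out$channel <- table$channel
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, frame_time = loc_frame_time(table),
            class = c("track_set", "data.frame"))
}

track_set <- function(df, frame_time) {
  need <- c("track_id", "frame", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    qp_stop("qp_format_error", "missing track column(s): %s",
            paste(miss, collapse = ", "))
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, frame_time = frame_time,
            class = c("track_set", "data.frame"))
}

#' Time-averaged mean square displacement of one trajectory
#'
#' MSD(tau_k) averaged over all start times, for internal lags
#' k = 1 .. floor(length / 2); gapped tracks contribute pairs whose frame
#' difference equals k. Positions in nm are converted to micrometres, so
#' MSD is in um^2 and lag times in seconds.
#'
#' @param track data.frame with `frame`, `x`, `y` (nm), frames strictly
#'   increasing.
#' @param frame_time seconds per frame.
#' @param min_track_length minimum number of points (default 8).
#' @return list of class `msd_curve`: `tau` (s), `msd` (um^2), `n_pairs`.
#' @export
compute_msd <- function(track, frame_time, min_track_length = 8) {
  len <- nrow(track)
  if (len < min_track_length)
    qp_data_error("track too short (%d < %d points)", len, min_track_length)
  if (any(diff(track$frame) <= 0))
    qp_param_error("track frames must be strictly increasing")
  kmax <- floor(len / 2)
  xu <- track$x / 1000; yu <- track$y / 1000
  fr <- track$frame
  tau <- numeric(kmax); msd <- numeric(kmax); np <- integer(kmax)
  df <- outer(fr, fr, "-")
  d2 <- (outer(xu, xu, "-")^2 + outer(yu, yu, "-")^2)
  for (k in seq_len(kmax)) {
    sel <- df == k
    np[k] <- sum(sel)
    msd[k] <- if (np[k]) mean(d2[sel]) else NA_real_
    tau[k] <- k * frame_time
  }
  structure(list(tau = tau, msd = msd, n_pairs = np),
            class = "msd_curve")
}

#' Classify a trajectory as immobile, confined or free
#'
#' Cascade on the time-averaged MSD curve:
#' 1. Immobile when the early-lag plateau (mean of the first four MSD
#'    values) does not exceed `k_imm * 4 sigma_loc^2` — a multiple of the
#'    pure localization-noise floor `4 sigma_loc^2`.
#' 2. Otherwise two nested models are fitted over all available lags (up
#'    to floor(length/2)): the free model `MSD = 4 D tau + 4 sigma_loc^2`
#'    (slope only, anchored at the noise floor) and the confined model
#'    `MSD = P (1 - exp(-4 D0 tau / P)) + 4 sigma_loc^2` (plateau `P` and
#'    internal coefficient `D0`). "Confined" is assigned only when the
#'    confined residual sum is below `conf_margin` times the free model's
#'    AND the fitted confinement timescale `P / (4 D0)` is shorter than
#'    `conf_tc_frac` of the longest lag — i.e. the saturation the model
#'    claims is actually expressed inside the observation window.
#'    Otherwise "free". The timescale gate protects against the spurious
#'    saturation that time-averaged MSDs of short free tracks show.
#'
#' The apparent diffusion coefficient `D` is taken from the first-four-lag
#' linear fit (free intercept) in all mobile cases.
#'
#' @param msd an `msd_curve` from [compute_msd()].
#' @param sigma_loc localization precision in nm.
#' @param k_imm immobile threshold multiplier (default 3).
#' @param conf_margin model-selection margin (default 0.5).
#' @param conf_tc_frac confinement-timescale gate as a fraction of the
#'   longest fitted lag (default 0.2).
#' @return list of class `diffusion_class`: `state` ("immobile",
#'   "confined", "free"), `D` (um^2/s), `slope`, `intercept`, `plateau`,
#'   `rss_free`, `rss_conf`, `conf_P`, `conf_D0`.
#' @export
classify_track <- function(msd, sigma_loc, k_imm = 3, conf_margin = 0.5,
                           conf_tc_frac = 0.2) {
  if (!is.numeric(sigma_loc) || sigma_loc <= 0)
    qp_param_error("sigma_loc must be > 0")
  ok <- which(!is.na(msd$msd))
  if (length(ok) < 4)
    qp_data_error("fewer than 4 MSD lags: unclassifiable")
  noise <- 4 * (sigma_loc / 1000)^2    # um^2
  tau <- msd$tau[ok]; m <- msd$msd[ok]
  plateau <- mean(m[seq_len(4)])
  base <- list(plateau = plateau, noise_floor = noise)
  if (plateau <= k_imm * noise) {
    return(structure(c(list(state = "immobile", D = 0, slope = 0,
                            intercept = plateau, rss_free = NA_real_,
                            rss_conf = NA_real_, conf_P = NA_real_,
                            conf_D0 = NA_real_), base),
                     class = "diffusion_class"))
  }
  fit <- stats::lm.fit(cbind(1, tau[1:4]), m[1:4])
  intercept <- fit$coefficients[1]; slope <- fit$coefficients[2]
  D <- max(slope / 4, 0)
  # nested model comparison over all lags: slope-only line through the
  # noise floor vs the saturating confined model
  slope_anch <- max(sum((m - noise) * tau) / sum(tau^2), 0)
  rss_free <- sum((m - (slope_anch * tau + noise))^2)
  conf_obj <- function(par) {
    P <- par[1]; D0 <- par[2]
    pred <- P * (1 - exp(-4 * D0 * tau / P)) + noise
    sum((m - pred)^2)
  }
  init <- c(max(max(m) - noise, noise), max(slope_anch / 4, 1e-3))
  cf <- stats::optim(init, conf_obj, method = "L-BFGS-B",
                     lower = c(1e-8, 1e-6), upper = c(Inf, Inf))
  rss_conf <- cf$value
  t_conf <- cf$par[1] / (4 * cf$par[2])
  state <- if (rss_conf < conf_margin * rss_free &&
               t_conf < conf_tc_frac * max(tau)) "confined" else "free"
  structure(c(list(state = state, D = D, slope = slope,
                   intercept = intercept, rss_free = rss_free,
                   rss_conf = rss_conf, conf_P = cf$par[1],
                   conf_D0 = cf$par[2]), base),
            class = "diffusion_class")
}

# Classify every track of sufficient length; returns a data.frame.
classify_tracks <- function(trackset, sigma_loc, frame_time,
                            min_track_length = 8, k_imm = 3,
                            conf_margin = 0.5, conf_tc_frac = 0.2) {
  rows <- split(seq_len(nrow(trackset)), trackset$track_id)
  out <- lapply(names(rows), function(id) {
    tr <- trackset[rows[[id]], , drop = FALSE]
    if (nrow(tr) < min_track_length)
      return(data.frame(track_id = as.integer(id), state = "unclassifiable",
                        D = NA_real_, length = nrow(tr)))
    cl <- tryCatch(
      classify_track(compute_msd(tr, frame_time, min_track_length),
                     sigma_loc, k_imm, conf_margin, conf_tc_frac),
      qp_data_error = function(e) NULL)
    if (is.null(cl))
      return(data.frame(track_id = as.integer(id), state = "unclassifiable",
                        D = NA_real_, length = nrow(tr)))
    data.frame(track_id = as.integer(id), state = cl$state, D = cl$D,
               length = nrow(tr))
  })
  do.call(rbind, out)
}

.states <- c("immobile", "confined", "free")

#' Mobility report: diffusion-state fractions and coefficients
#'
#' Classifies every track (length >= `min_track_length`), pools the
#' classifications and reports the fraction of tracks per diffusion state
#' and the mean apparent diffusion coefficient per state, each with a
#' bootstrap (over tracks) standard error of the mean. Deterministic for a
#' fixed seed.
#'
#' @param trackset a `track_set` ([link_localizations()]).
#' @param sigma_loc localization precision in nm.
#' @param frame_time seconds per frame; defaults to the track set's
#'   attribute.
#' @param bootstrap_B bootstrap replicates (default 500).
#' @param seed RNG seed for the bootstrap.
#' @param condition free-text label carried into the report.
#' @param min_classifiable minimum number of classifiable tracks (30).
#' @inheritParams classify_track
#' @inheritParams compute_msd
#' @return list of class `mobility_report`: `fractions`, `fractions_sem`,
#'   `D_mean`, `D_sem` (all named by state), `n_tracks`,
#'   `n_unclassifiable`, `per_track` (classification data.frame),
#'   `settings`.
#' @export
mobility_report <- function(trackset, sigma_loc, frame_time = NULL,
                            bootstrap_B = 500, seed = 1, condition = "",
                            min_track_length = 8, k_imm = 3,
                            conf_margin = 0.5, conf_tc_frac = 0.2,
                            min_classifiable = 30) {
  frame_time <- frame_time %||% attr(trackset, "frame_time")
  if (is.null(frame_time)) qp_param_error("frame_time must be supplied")
  cls <- classify_tracks(trackset, sigma_loc, frame_time,
                         min_track_length, k_imm, conf_margin, conf_tc_frac)
  ok <- cls[cls$state %in% .states, , drop = FALSE]
  if (nrow(ok) < min_classifiable)
    qp_data_error("too few classifiable tracks (%d < %d)", nrow(ok),
                  min_classifiable)
  frac_of <- function(states) {
    f <- table(factor(states, levels = .states)) / length(states)
    as.numeric(f)
  }
  dmean_of <- function(df) {
    vapply(.states, function(s) {
      v <- df$D[df$state == s]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
  }
  fr <- frac_of(ok$state); names(fr) <- .states
  dm <- dmean_of(ok)
  boots <- with_seed(seed, {
    replicate(bootstrap_B, {
      ix <- sample.int(nrow(ok), replace = TRUE)
      b <- ok[ix, , drop = FALSE]
      c(frac_of(b$state), dmean_of(b))
    })
  })
  fr_sem <- apply(boots[1:3, , drop = FALSE], 1, stats::sd)
  d_sem <- apply(boots[4:6, , drop = FALSE], 1, stats::sd, na.rm = TRUE)
  names(fr_sem) <- names(d_sem) <- .states
  structure(list(condition = condition, n_tracks = nrow(ok),
                 n_unclassifiable = sum(cls$state == "unclassifiable"),
                 fractions = fr, fractions_sem = fr_sem,
                 D_mean = dm, D_sem = d_sem,
                 per_track = cls, frame_time = frame_time,
                 settings = list(sigma_loc = sigma_loc, k_imm = k_imm,
                                 conf_margin = conf_margin,
                                 conf_tc_frac = conf_tc_frac,
                                 min_track_length = min_track_length,
                                 bootstrap_B = bootstrap_B, seed = seed)),
            class = "mobility_report")
}

#' @export
print.mobility_report <- function(x, ...) {
  cat(sprintf("<mobility_report> %s%d tracks\n",
              if (nzchar(x$condition)) paste0(x$condition, ": ") else "",
              x$n_tracks))
  for (s in .states)
    cat(sprintf("  %-9s %5.1f%% +/- %.1f%%   D = %s um^2/s\n", s,
                100 * x$fractions[[s]], 100 * x$fractions_sem[[s]],
                ifelse(is.na(x$D_mean[[s]]), "NA",
                       sprintf("%.4f +/- %.4f", x$D_mean[[s]], x$D_sem[[s]]))))
  invisible(x)
}

#' Compare receptor- and ligand-channel mobility reports
#'
#' Side-by-side per-state fractions and diffusion coefficients from two
#' [mobility_report()]s (e.g. the receptor channel vs the labeled ligand),
#' with differences and combined standard errors. The reports must share
#' the same frame time.
#'
#' @param report_receptor,report_ligand `mobility_report` objects.
#' @return data.frame with one row per state: fractions, Ds, differences
#'   (receptor minus ligand) and combined SEMs.
#' @export
compare_channels <- function(report_receptor, report_ligand) {
  if (!inherits(report_receptor, "mobility_report") ||
      !inherits(report_ligand, "mobility_report"))
    qp_param_error("both arguments must be mobility reports")
  if (!isTRUE(all.equal(report_receptor$frame_time, report_ligand$frame_time)))
    qp_stop("qp_comparison_error",
            "frame time mismatch: %.4g s vs %.4g s",
            report_receptor$frame_time, report_ligand$frame_time)
  data.frame(
    state = .states,
    frac_receptor = as.numeric(report_receptor$fractions),
    frac_ligand = as.numeric(report_ligand$fractions),
    frac_diff = as.numeric(report_receptor$fractions - report_ligand$fractions),
    frac_sem = sqrt(as.numeric(report_receptor$fractions_sem)^2 +
                      as.numeric(report_ligand$fractions_sem)^2),
    D_receptor = as.numeric(report_receptor$D_mean),
    D_ligand = as.numeric(report_ligand$D_mean),
    D_diff = as.numeric(report_receptor$D_mean - report_ligand$D_mean),
    D_sem = sqrt(as.numeric(report_receptor$D_sem)^2 +
                   as.numeric(report_ligand$D_sem)^2)
  )
}
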