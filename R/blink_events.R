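#' Extract appearance events from a localization table
#'
#' Groups localizations into fluorescent bursts ("appearances"): a
#' localization joins an open event when it lies within `merge_radius` of
#' the event centroid and the dark gap since the event's last detection is
#' at most `max_dark_frames` frames. Localizations that match no open event
#' start a new one. Every localization is assigned to exactly one event;
#' appearances of one emitter separated by gaps longer than
#' `max_dark_frames` therefore count as separate events.
#'
#' @param table a [localization_table()] (sorted by frame).
#' @param max_dark_frames integer >= 0, tolerated dark gap inside one event.
#' @param merge_radius nm, spatial gate around the running event centroid.
#' @return data.frame of class `appearance_events`: `event_id`,
#'   `start_frame`, `end_frame`, `x`, `y` (centroid, nm), `n_locs`.
#' @export
extract_appearances <- function(table, max_dark_frames = 3, merge_radius = 30) {
  if (!inherits(table, "loc_table")) qp_param_error("table must be a loc_table")
  if (!is_count(max_dark_frames) || max_dark_frames < 0)
    qp_param_error("max_dark_frames must be an integer >= 0")
  if (!is.numeric(merge_radius) || merge_radius < 0)
    qp_param_error("merge_radius must be >= 0")
  n <- nrow(table)
  ev_of <- integer(n)
  # open events, grown per frame; columns are plain vectors for speed
  ox <- numeric(0); oy <- numeric(0); osx <- numeric(0); osy <- numeric(0)
  olast <- integer(0); ostart <- integer(0); ocnt <- integer(0); oid <- integer(0)
  next_id <- 1L
  res <- list()
  frames <- table$frame
  xs <- table$x; ys <- table$y
  close_stale <- function(fr) {
    stale <- olast < fr - (max_dark_frames + 1L)
    if (any(stale)) {
      res[[length(res) + 1L]] <<- data.frame(
        event_id = oid[stale], start_frame = ostart[stale],
        end_frame = olast[stale], x = osx[stale] / ocnt[stale],
        y = osy[stale] / ocnt[stale], n_locs = ocnt[stale])
      keep <- !stale
      ox <<- ox[keep]; oy <<- oy[keep]; osx <<- osx[keep]; osy <<- osy[keep]
      olast <<- olast[keep]; ostart <<- ostart[keep]
      ocnt <<- ocnt[keep]; oid <<- oid[keep]
    }
  }
  for (fr in unique(frames)) {
    close_stale(fr)
    idx <- which(frames == fr)
    taken <- logical(length(ox))
    for (i in idx) {
      assigned <- FALSE
      if (length(ox)) {
        d2 <- (ox - xs[i])^2 + (oy - ys[i])^2
        cand <- which(!taken & d2 <= merge_radius^2)
        if (length(cand)) {
          j <- cand[which.min(d2[cand])]
          taken[j] <- TRUE
          osx[j] <- osx[j] + xs[i]; osy[j] <- osy[j] + ys[i]
          ocnt[j] <- ocnt[j] + 1L; olast[j] <- fr
          # running centroid keeps the spatial gate stable as the event grows
          ox[j] <- osx[j] / ocnt[j]; oy[j] <- osy[j] / ocnt[j]
          ev_of[i] <- oid[j]
          assigned <- TRUE
        }
      }
      if (!assigned) {
        ox <- c(ox, xs[i]); oy <- c(oy, ys[i])
        osx <- c(osx, xs[i]); osy <- c(osy, ys[i])
        olast <- c(olast, fr); ostart <- c(ostart, fr)
        ocnt <- c(ocnt, 1L); oid <- c(oid, next_id)
        taken <- c(taken, TRUE)
        ev_of[i] <- next_id
        next_id <- next_id + 1L
      }
    }
  }
  if (length(ox))
    res[[length(res) + 1L]] <- data.frame(
      event_id = oid, start_frame = ostart, end_frame = olast,
      x = osx / ocnt, y = osy / ocnt, n_locs = ocnt)
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(event_id = integer(0), start_frame = integer(0),
               end_frame = integer(0), x = numeric(0), y = numeric(0),
               n_locs = integer(0))
  out <- out[order(out$event_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "assignment") <- ev_of
  class(out) <- c("appearance_events", "data.frame")
  out
}

#' Group appearance events into nanoclusters
#'
#' Density-based grouping of event centroids: events whose centroids are
#' connected through chains of neighbours closer than `eps` form one
#' nanocluster (with `min_events = 1` every event belongs to some cluster,
#' isolated events forming singletons). A cluster's appearance count `n` is
#' its number of member events — the quantity the blink-count model fits.
#'
#' @param events an `appearance_events` data.frame from
#'   [extract_appearances()].
#' @param eps nm, neighbourhood radius.
#' @param min_events minimum events per reported cluster; groups smaller
#'   than this are dropped as noise.
#' @return data.frame of class `nanoclusters`: `cluster_id`, `x`, `y`
#'   (centroid, nm), `n` (appearance count), `colocalized` (NA until set by
#'   [colocalization_filter()]); attribute `membership` maps events to
#'   clusters (0 = noise).
#' @export
cluster_events <- function(events, eps = 50, min_events = 1) {
  if (!is.numeric(eps) || eps <= 0) qp_param_error("eps must be > 0")
  if (!is_count(min_events) || min_events < 1)
    qp_param_error("min_events must be an integer >= 1")
  m <- nrow(events)
  if (!m)
    return(structure(data.frame(cluster_id = integer(0), x = numeric(0),
                                y = numeric(0), n = integer(0),
                                colocalized = logical(0)),
                     membership = integer(0),
                     class = c("nanoclusters", "data.frame")))
  comp <- .eps_components(events$x, events$y, eps)
  sizes <- tabulate(comp)
  keep_comp <- which(sizes >= min_events)
  cl_of <- match(comp, keep_comp)          # NA -> noise
  cl_of[is.na(cl_of)] <- 0L
  ids <- sort(unique(cl_of[cl_of > 0L]))
  out <- do.call(rbind, lapply(ids, function(k) {
    sel <- cl_of == k
    data.frame(cluster_id = k, x = mean(events$x[sel]),
               y = mean(events$y[sel]), n = sum(sel), colocalized = NA)
  }))
  rownames(out) <- NULL
  structure(out, membership = cl_of,
            class = c("nanoclusters", "data.frame"))
}

# Connected components of the eps-neighbourhood graph via grid hashing;
# O(N) at the sparse densities of PALM fields.
.eps_components <- function(x, y, eps) {
  n <- length(x)
  cellx <- floor(x / eps); celly <- floor(y / eps)
  key <- paste(cellx, celly)
  cells <- split(seq_len(n), key)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
  for (i in seq_len(n)) {
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(cellx[i] + dx, celly[i] + dy)
      js <- cells[[k]]
      if (is.null(js)) next
      for (j in js) {
        if (j <= i) next
        if ((x[i] - x[j])^2 + (y[i] - y[j])^2 <= eps^2) union(i, j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Blink histogram of per-nanocluster appearance counts
#'
#' @param n_appearances integer vector of appearance counts (one per
#'   nanocluster), or a `nanoclusters` data.frame (its `n` column is used).
#' @param n_max truncation bound; counts above `n_max` are accumulated into
#'   the top bin.
#' @return object of class `blink_histogram`: `counts` (length `n_max`,
#'   indexed by n = 1..n_max), `n_max`, `total_clusters`.
#' @export
blink_histogram <- function(n_appearances, n_max = 50) {
  if (inherits(n_appearances, "nanoclusters")) n_appearances <- n_appearances$n
  if (!is_count(n_max) || n_max < 1) qp_param_error("n_max must be >= 1")
  if (!length(n_appearances)) qp_data_error("no clusters: empty histogram")
  if (any(n_appearances < 1) || any(n_appearances != round(n_appearances)))
    qp_param_error("appearance counts must be integers >= 1")
  counts <- tabulate(pmin(n_appearances, n_max), nbins = n_max)
  structure(list(counts = counts, n_max = n_max,
                 total_clusters = sum(counts)),
            class = "blink_histogram")
}

# Accept a pre-tabulated (possibly non-integer, e.g. expected) count vector.
as_blink_histogram <- function(counts) {
  if (inherits(counts, "blink_histogram")) return(counts)
  if (!is.numeric(counts) || !length(counts) || any(counts < 0))
    qp_param_error("counts must be a nonnegative numeric vector over n = 1..n_max")
  structure(list(counts = as.numeric(counts), n_max = length(counts),
                 total_clusters = sum(counts)),
            class = "blink_histogram")
}

#' @export
print.blink_histogram <- function(x, ...) {
  mean_n <- sum(seq_len(x$n_max) * x$counts) / x$total_clusters
  cat(sprintf("<blink_histogram> %s clusters, mean appearances %.2f, n_max %d\n",
              format(x$total_clusters), mean_n, x$n_max))
  invisible(x)
}
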