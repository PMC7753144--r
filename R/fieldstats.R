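#' NeNA localization precision
#'
#' Estimates the localization precision sigma from the distribution of
#' nearest-neighbor distances between localizations in adjacent frames
#' (frame offset exactly +1). Repeated localizations of the same emitter in
#' consecutive frames are displaced by twice the localization noise, giving
#' the correlated-pair density
#'
#'   p_corr(r) = (r / (2 sigma^2)) exp(-r^2 / (4 sigma^2)),
#'
#' whose mode sits at sqrt(2) sigma. Uncorrelated neighbours contribute a
#' linearly rising background; the fitted model is the two-component
#' mixture `A p_corr(r) + (1 - A) p_bg(r)` with `p_bg(r) = 2 r / r_max^2`,
#' fitted by least squares on the binned distance histogram.
#'
#' @param table a [localization_table()] spanning at least 2 frames.
#' @param max_radius nm; histogram and fit range (0, max_radius].
#' @param bin_nm histogram bin width in nm.
#' @return list of class `precision_estimate`: `sigma` (nm),
#'   `background_weight` (1 - A), `fit_range`, `n_pairs`, `histogram`
#'   (data.frame `r`, `count`).
#' @export
nena_precision <- function(table, max_radius = 150, bin_nm = 1) {
  if (!is.numeric(max_radius) || max_radius <= 0)
    qp_param_error("max_radius must be > 0")
  frames <- sort(unique(table$frame))
  if (length(frames) < 2) qp_data_error("table must span >= 2 frames")
  by_frame <- split(seq_len(nrow(table)), table$frame)
  dists <- lapply(as.character(frames[-length(frames)]), function(f) {
    nxt <- as.character(as.integer(f) + 1L)
    i <- by_frame[[f]]; j <- by_frame[[nxt]]
    if (is.null(j)) return(numeric(0))
    # nearest neighbour in the following frame, for every point in frame f
    d2 <- outer(table$x[i], table$x[j], "-")^2 +
      outer(table$y[i], table$y[j], "-")^2
    sqrt(apply(d2, 1, min))
  })
  d <- unlist(dists)
  d <- d[d <= max_radius]
  if (length(d) < 100)
    qp_data_error("too few adjacent-frame neighbour pairs (%d < 100)", length(d))
  breaks <- seq(0, max_radius, by = bin_nm)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  r <- h$mids
  counts <- h$counts
  norm <- length(d) * bin_nm
  p_corr <- function(r, s) (r / (2 * s^2)) * exp(-r^2 / (4 * s^2))
  p_bg <- function(r) 2 * r / max_radius^2
  obj <- function(par) {
    s <- par[1]; A <- par[2]
    model <- norm * (A * p_corr(r, s) + (1 - A) * p_bg(r))
    sum((counts - model)^2)
  }
  s0 <- max(r[which.max(counts)] / sqrt(2), bin_nm)
  fit <- stats::optim(c(s0, 0.8), obj, method = "L-BFGS-B",
                      lower = c(bin_nm / 2, 0), upper = c(max_radius, 1))
  structure(list(sigma = fit$par[1], background_weight = 1 - fit$par[2],
                 fit_range = c(0, max_radius), n_pairs = length(d),
                 histogram = data.frame(r = r, count = counts),
                 objective = fit$value, converged = fit$convergence == 0),
            class = "precision_estimate")
}

#' @export
print.precision_estimate <- function(x, ...) {
  cat(sprintf("<precision_estimate> sigma = %.2f nm (%d pairs, background %.2f)\n",
              x$sigma, x$n_pairs, x$background_weight))
  invisible(x)
}

#' Nanocluster density per cell
#'
#' Counts nanocluster centroids inside each cell ROI and reports per-cell
#' densities (clusters per square micrometre) with their mean and SD
#' across cells.
#'
#' @param clusters a `nanoclusters` data.frame ([cluster_events()]), or a
#'   list of them (one per cell, matched to `rois` by position).
#' @param rois an [roi_polygon()] or list of ROIs, one per cell.
#' @return list of class `density_report`: `per_cell` (per-ROI densities,
#'   1/um^2), `mean`, `sd`, `n_cells`.
#' @export
cluster_density <- function(clusters, rois) {
  if (inherits(rois, "roi")) rois <- list(rois)
  if (inherits(clusters, "nanoclusters")) clusters <- list(clusters)
  if (length(clusters) == 1L && length(rois) > 1L)
    clusters <- rep(clusters, length(rois))
  if (length(clusters) != length(rois))
    qp_param_error("need one cluster set per ROI (or a single shared set)")
  per_cell <- mapply(function(cl, roi) {
    if (!inherits(roi, "roi")) qp_param_error("rois must be roi objects")
    if (roi$area_um2 <= 0) qp_param_error("zero-area ROI")
    inside <- if (nrow(cl)) sum(points_in_roi(cl$x, cl$y, roi)) else 0
    inside / roi$area_um2
  }, clusters, rois)
  structure(list(per_cell = as.numeric(per_cell),
                 mean = mean(per_cell),
                 sd = if (length(per_cell) > 1) stats::sd(per_cell) else 0,
                 n_cells = length(per_cell)),
            class = "density_report")
}

#' @export
print.density_report <- function(x, ...) {
  cat(sprintf("<density_report> %.2f +/- %.2f clusters/um^2 over %d cell(s)\n",
              x$mean, x$sd, x$n_cells))
  invisible(x)
}

#' Gate nanoclusters on ligand colocalization
#'
#' Marks each nanocluster as colocalized when its centroid lies within
#' `radius` of at least one localization in the ligand channel, and
#' returns the gated subset (clusters assumed to be ligand-bound). The
#' full cluster table with the `colocalized` flag set is attached as
#' attribute `"all"`.
#'
#' @param clusters a `nanoclusters` data.frame.
#' @param ligand a [localization_table()] of the ligand channel (nonempty).
#' @param radius nm, colocalization distance criterion.
#' @return the colocalized subset of `clusters` (same class).
#' @export
colocalization_filter <- function(clusters, ligand, radius = 150) {
  if (!is.numeric(radius) || radius <= 0) qp_param_error("radius must be > 0")
  if (!nrow(ligand)) qp_data_error("empty ligand table")
  if (!nrow(clusters)) return(clusters)
  r2 <- radius^2
  hit <- vapply(seq_len(nrow(clusters)), function(i) {
    any((ligand$x - clusters$x[i])^2 + (ligand$y - clusters$y[i])^2 <= r2)
  }, logical(1))
  clusters$colocalized <- hit
  out <- clusters[hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all") <- clusters
  class(out) <- class(clusters)
  out
}
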