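#' Localization tables
#'
#' A localization table is the universal input of the pipeline: one row per
#' single-molecule detection with columns `frame` (0-based integer), `x`,
#' `y` (nm, origin at the top-left of the field of view, axes right/down)
#' and optional `precision` (nm), `intensity` (photons) and `channel`
#' (0 = receptor, 1 = ligand). Unit metadata (pixel size, frame time, field
#' of view) is carried as attributes so every downstream physical-unit
#' computation has it available.
#'
#' @param records data.frame with at least `frame`, `x`, `y`.
#' @param pixel_size nm per camera pixel (> 0).
#' @param frame_time acquisition frame time in seconds (> 0).
#' @param fov field of view `c(width, height)` in nm; defaults to the
#'   data's bounding box rounded up.
#' @return an object of class `loc_table` (a data.frame).
#' @export
localization_table <- function(records, pixel_size = 100, frame_time = 0.02,
                               fov = NULL) {
  if (!is.data.frame(records))
    qp_param_error("records must be a data.frame")
  need <- c("frame", "x", "y")
  miss <- setdiff(need, names(records))
  if (length(miss))
    qp_stop("qp_format_error", "missing mandatory column(s): %s",
            paste(miss, collapse = ", "))
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    qp_param_error("pixel_size must be > 0")
  if (!is.numeric(frame_time) || frame_time <= 0)
    qp_param_error("frame_time must be > 0")
  records$frame <- as.integer(records$frame)
  if (nrow(records)) {
    if (anyNA(records$frame) || any(records$frame < 0L))
      qp_param_error("frame indices must be integers >= 0")
    if (!all(is.finite(records$x)) || !all(is.finite(records$y)))
      qp_param_error("x and y must be finite")
  }
  if (is.null(fov)) {
    fov <- if (nrow(records)) c(max(records$x), max(records$y)) else c(0, 0)
    fov <- ceiling(fov)
  }
  if ("precision" %in% names(records) && nrow(records) &&
      any(records$precision <= 0, na.rm = TRUE))
    qp_param_error("precision values must be > 0 nm")
  records <- records[order(records$frame), , drop = FALSE]
  rownames(records) <- NULL
  structure(records,
            pixel_size = pixel_size, frame_time = frame_time, fov = fov,
            class = c("loc_table", "data.frame"))
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf("<loc_table> %d localizations, %d frame(s), fov %.0f x %.0f nm, dt %.4g s\n",
              nrow(x), length(unique(x$frame)),
              attr(x, "fov")[1], attr(x, "fov")[2], attr(x, "frame_time")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

loc_frame_time <- function(table) attr(table, "frame_time")
loc_fov        <- function(table) attr(table, "fov")

# Header maps per dialect: on-disk name -> canonical name.
.dialects <- list(
  generic_csv = c(frame = "frame", x = "x", y = "y",
                  precision = "precision", intensity = "intensity",
                  channel = "channel"),
  thunderstorm_like = c(frame = "frame", x = "x [nm]", y = "y [nm]",
                        precision = "uncertainty [nm]",
                        intensity = "intensity [photon]",
                        channel = "channel")
)

#' Read a localization table from CSV
#'
#' Coordinates are converted to nm at this boundary: with `units = "px"`
#' the x/y (and precision) columns are multiplied by `pixel_size`. Records
#' come back sorted by frame.
#'
#' @param path CSV file path.
#' @param dialect header convention: `"generic_csv"` (`frame,x,y,...`) or
#'   `"thunderstorm_like"` (`"frame","x [nm]","y [nm]","uncertainty [nm]"`).
#' @param units `"nm"` or `"px"` for the coordinate columns on disk.
#' @param pixel_size nm per pixel; required for unit conversion.
#' @inheritParams localization_table
#' @return a [localization_table()].
#' @export
read_localizations <- function(path,
                               dialect = c("generic_csv", "thunderstorm_like"),
                               units = c("nm", "px"),
                               pixel_size = 100, frame_time = 0.02,
                               fov = NULL) {
  dialect <- match.arg(dialect)
  units <- match.arg(units)
  if (units == "px" && (is.null(pixel_size) || !is.numeric(pixel_size) ||
                        pixel_size <= 0))
    qp_param_error("pixel_size must be supplied (> 0) for units = 'px'")
  if (!file.exists(path))
    qp_stop("qp_io_error", "file not found: %s", path)
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character", strip.white = TRUE)
  map <- .dialects[[dialect]]
  for (col in c("frame", "x", "y")) {
    if (!map[[col]] %in% names(raw))
      qp_stop("qp_format_error", "missing mandatory column '%s'", map[[col]])
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (col in names(map)) {
    disk <- map[[col]]
    if (!disk %in% names(raw)) next
    v <- raw[[disk]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !(v %in% c("", "NA")))
    if (length(bad))
      qp_stop("qp_parse_error", "non-numeric value '%s' in column '%s', row %d",
              v[bad[1]], disk, bad[1])
    out[[col]] <- num
  }
  if (units == "px") {
    if (is.null(pixel_size) || pixel_size <= 0)
      qp_param_error("pixel_size must be supplied (> 0) for units = 'px'")
    out$x <- out$x * pixel_size
    out$y <- out$y * pixel_size
    if (!is.null(out$precision)) out$precision <- out$precision * pixel_size
  }
  localization_table(out, pixel_size = pixel_size, frame_time = frame_time,
                     fov = fov)
}

#' Write a localization table to CSV
#'
#' Writes the canonical generic dialect (`frame,x,y[,precision,intensity,
#' channel]`), nm units, with enough digits that a read/write round trip
#' reproduces coordinates to below 1e-6 nm.
#'
#' @param table a [localization_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path) {
  if (!inherits(table, "loc_table"))
    qp_param_error("table must be a loc_table")
  df <- as.data.frame(table)
  ok <- tryCatch({
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    qp_stop("qp_io_error", "cannot write '%s': %s", path, conditionMessage(ok))
  invisible(path)
}

#' Render a localization table as an intensity image
#'
#' @param table a [localization_table()].
#' @param bin_nm pixel size of the rendered grid in nm (> 0).
#' @param mode `"histogram"` (2D binning; grid sum equals the number of
#'   records) or `"gaussian"` (each record contributes a unit-integral
#'   Gaussian of width equal to its localization precision).
#' @param default_precision nm; used in gaussian mode for records without a
#'   precision value.
#' @return numeric matrix (rows = y, cols = x) of intensities per bin.
#' @export
render_image <- function(table, bin_nm = 20,
                         mode = c("histogram", "gaussian"),
                         default_precision = 10) {
  mode <- match.arg(mode)
  if (!is.numeric(bin_nm) || bin_nm <= 0)
    qp_param_error("bin_nm must be > 0")
  fov <- loc_fov(table)
  nx <- max(1L, ceiling(fov[1] / bin_nm))
  ny <- max(1L, ceiling(fov[2] / bin_nm))
  img <- matrix(0, nrow = ny, ncol = nx)
  if (!nrow(table)) return(img)
  if (mode == "histogram") {
    ix <- pmin(nx, pmax(1L, floor(table$x / bin_nm) + 1L))
    iy <- pmin(ny, pmax(1L, floor(table$y / bin_nm) + 1L))
    tab <- table(factor(iy, levels = seq_len(ny)),
                 factor(ix, levels = seq_len(nx)))
    img <- img + unclass(tab)
  } else {
    prec <- table$precision %||% rep(default_precision, nrow(table))
    prec[is.na(prec)] <- default_precision
    cx <- (seq_len(nx) - 0.5) * bin_nm
    cy <- (seq_len(ny) - 0.5) * bin_nm
    for (i in seq_len(nrow(table))) {
      s <- prec[i]
      # integrate the 2D Gaussian over each bin via the normal CDF
      px <- stats::pnorm(cx + bin_nm / 2, table$x[i], s) -
        stats::pnorm(cx - bin_nm / 2, table$x[i], s)
      py <- stats::pnorm(cy + bin_nm / 2, table$y[i], s) -
        stats::pnorm(cy - bin_nm / 2, table$y[i], s)
      img <- img + outer(py, px)
    }
  }
  dimnames(img) <- NULL
  img
}

#' Write a rendered image as 16-bit grayscale TIFF
#'
#' Intensities are scaled linearly so the brightest bin maps to the top of
#' the 16-bit range.
#'
#' @param img matrix from [render_image()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  m <- if (max(img) > 0) img / max(img) else img
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  invisible(path)
}
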