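#' Rectangular crop of a point cloud
#'
#' Keeps exactly the points whose x and y fall inside the closed rectangle
#' — the programmatic equivalent of segmenting one object out of a scene
#' cloud with a drawn rectangle.
#'
#' @param cloud a [point_cloud()].
#' @param x_min,x_max,y_min,y_max rectangle bounds (mm), closed on both
#'   sides.
#' @return The cropped [point_cloud()].
#' @export
crop_rectangle <- function(cloud, x_min, x_max, y_min, y_max) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (!(x_min < x_max && y_min < y_max))
    stop("rectangle bounds must satisfy x_min < x_max and y_min < y_max",
         call. = FALSE)
  x <- cloud$xyz[, 1]; y <- cloud$xyz[, 2]
  keep <- x >= x_min & x <= x_max & y >= y_min & y <= y_max
  if (!any(keep))
    stop(sprintf(
      "no points inside rectangle [%.1f, %.1f] x [%.1f, %.1f]",
      x_min, x_max, y_min, y_max), call. = FALSE)
  subset_cloud(cloud, keep)
}

#' Shift a cloud so its bottom sits at z = 0
#'
#' Estimates the object bottom `Z_bottom` as a low percentile of z (robust
#' to the occasional under-floor noise point of SfM reconstructions) and
#' subtracts it from every z.  With `bottom_percentile = 0` this is plain
#' minimum-subtraction.
#'
#' @param cloud a [point_cloud()].
#' @param bottom_percentile percentile (0-100) of z used as the bottom;
#'   default 1.
#' @return The shifted [point_cloud()].
#' @export
zero_bottom <- function(cloud, bottom_percentile = 1.0) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (npoints(cloud) == 0L)
    stop("cannot zero the bottom of an empty cloud", call. = FALSE)
  zb <- stats::quantile(cloud$xyz[, 3], bottom_percentile / 100,
                        names = FALSE, type = 7)
  out <- cloud
  out$xyz[, 3] <- out$xyz[, 3] - zb
  out
}

#' Histogram-trim specification
#'
#' @param n_bins number of equal-width bins spanning `[min, max]` of the
#'   values (default 20).
#' @param trim_low_bins,trim_high_bins number of lowest-edge and
#'   highest-edge bins whose members are discarded (defaults 5 and 5).
#' @param max_trim_frac cap on the fraction of the sample a single side's
#'   trim may discard (default 0.3).  The trim exists to shed extreme
#'   points and noise; when the data bulk itself sits against one end of
#'   the range (e.g. all outliers lie above), trimming that side's full
#'   bin allowance would discard the signal, so bins are dropped from the
#'   outside in and a side stops before exceeding this fraction.
#' @return A `trim_spec` list.
#' @export
trim_spec <- function(n_bins = 20L, trim_low_bins = 5L, trim_high_bins = 5L,
                      max_trim_frac = 0.3) {
  n_bins <- as.integer(n_bins)
  trim_low_bins <- as.integer(trim_low_bins)
  trim_high_bins <- as.integer(trim_high_bins)
  if (n_bins < 1L || trim_low_bins < 0L || trim_high_bins < 0L)
    stop("bin counts must be non-negative and n_bins >= 1", call. = FALSE)
  if (trim_low_bins + trim_high_bins >= n_bins)
    stop("trimmed bins must leave at least one bin", call. = FALSE)
  if (max_trim_frac < 0 || max_trim_frac > 1)
    stop("max_trim_frac must lie in [0, 1]", call. = FALSE)
  structure(list(n_bins = n_bins, trim_low_bins = trim_low_bins,
                 trim_high_bins = trim_high_bins,
                 max_trim_frac = max_trim_frac), class = "trim_spec")
}

# equal-width bin index over [min, max]; value == max goes to the top bin
bin_index <- function(values, n_bins) {
  lo <- min(values); hi <- max(values)
  idx <- floor((values - lo) / (hi - lo) * n_bins) + 1L
  pmin(idx, n_bins)
}

#' Trimmed-histogram mean
#'
#' Bins the values into `n_bins` equal-width bins over their range, drops
#' the values falling in the `trim_low_bins` lowest-edge and
#' `trim_high_bins` highest-edge bins (the bins holding the extreme values
#' and noise), and returns the mean of the remainder.  Bins are dropped
#' from the outside in, and each side stops early if dropping the next bin
#' would discard more than `max_trim_frac` of the sample from that side —
#' so a data bulk resting against one end of the range (as happens under
#' one-sided outliers) is never trimmed away.  Degenerate inputs — an
#' essentially constant sample, or a trim that empties the sample — fall
#' back to the plain mean.
#'
#' @param values numeric vector, at least one value.
#' @param trim a [trim_spec()].
#' @return The trimmed mean (scalar).
#' @export
#' @examples
#' trimmed_histogram_mean(seq(0.5, 19.5, by = 1))  # 10
trimmed_histogram_mean <- function(values, trim = trim_spec()) {
  stopifnot(inherits(trim, "trim_spec"))
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0L)
    stop("cannot take the trimmed mean of an empty sample", call. = FALSE)
  if (max(values) - min(values) < 1e-9)
    return(mean(values))
  idx <- bin_index(values, trim$n_bins)
  counts <- tabulate(idx, nbins = trim$n_bins)
  cap <- trim$max_trim_frac * n
  lo_drop <- 0L
  while (lo_drop < trim$trim_low_bins &&
         sum(counts[seq_len(lo_drop + 1L)]) <= cap)
    lo_drop <- lo_drop + 1L
  hi_drop <- 0L
  while (hi_drop < trim$trim_high_bins &&
         sum(counts[(trim$n_bins - hi_drop):trim$n_bins]) <= cap)
    hi_drop <- hi_drop + 1L
  keep <- idx > lo_drop & idx <= trim$n_bins - hi_drop
  if (!any(keep))
    return(mean(values))
  mean(values[keep])
}

#' Object height from the central region of the object top
#'
#' Automated stand-in for manually picking the central patch of an
#' object's top surface: the top slab of the cloud (points whose z lies in
#' the top `slab_fraction` of the robust z range between the 5th and 95th
#' percentiles) defines the footprint of the object top; all points whose
#' (x, y) fall within the central `center_fraction` of that footprint's
#' bounding box are selected, and the trimmed-histogram mean of their z is
#' returned.  On a bottom-zeroed cloud this `Z_top` is the object height.
#'
#' The default `center_fraction` of 0.3 keeps the patch small enough that
#' even a hemispherical cap's curvature biases the height by less than
#' 1 mm, while a flat top is measured exactly.
#'
#' @param cloud a bottom-zeroed [point_cloud()].
#' @param center_fraction fraction (per axis) of the top footprint
#'   bounding box retained around its center; default 0.3.
#' @param trim a [trim_spec()].
#' @param slab_fraction thickness of the top slab defining the footprint,
#'   as a fraction of the robust z range; default 0.05.
#' @return Height estimate in mm.
#' @export
measure_height <- function(cloud, center_fraction = 0.3, trim = trim_spec(),
                           slab_fraction = 0.05) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (npoints(cloud) == 0L) stop("empty cloud", call. = FALSE)
  if (center_fraction <= 0 || center_fraction > 1)
    stop("center_fraction must lie in (0, 1]", call. = FALSE)
  z <- cloud$xyz[, 3]
  q <- stats::quantile(z, c(0.05, 0.95), names = FALSE)
  slab <- z >= q[2] - slab_fraction * max(q[2] - q[1], 1e-9)
  x <- cloud$xyz[, 1]; y <- cloud$xyz[, 2]
  xs <- x[slab]; ys <- y[slab]
  cx <- (min(xs) + max(xs)) / 2; cy <- (min(ys) + max(ys)) / 2
  hx <- (max(xs) - min(xs)) * center_fraction / 2
  hy <- (max(ys) - min(ys)) * center_fraction / 2
  sel <- abs(x - cx) <= hx & abs(y - cy) <= hy & z >= q[1]
  if (!any(sel))
    stop("no points in the central top region; increase `center_fraction`",
         call. = FALSE)
  trimmed_histogram_mean(z[sel], trim)
}

#' Per-slice x/y extents
#'
#' Quantizes z into consecutive slices of fixed width starting at the
#' cloud bottom (the operational reading of "the group of points with the
#' same Z") and, per slice with enough members, records the x and y
#' extents between the four extreme points.
#'
#' @param cloud a [point_cloud()].
#' @param slice_width_mm slice thickness (mm), default 1.
#' @param min_points_per_slice slices with fewer members are skipped.
#' @return Data frame with columns `z_mid`, `n`, `dim_x`, `dim_y`, one row
#'   per retained slice, ordered by z.
#' @export
slice_extents <- function(cloud, slice_width_mm = 1.0,
                          min_points_per_slice = 5L) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (slice_width_mm <= 0) stop("slice width must be positive", call. = FALSE)
  if (npoints(cloud) == 0L) stop("empty cloud", call. = FALSE)
  z <- cloud$xyz[, 3]
  idx <- floor((z - min(z)) / slice_width_mm)
  counts <- table(idx)
  keep_ids <- as.numeric(names(counts))[counts >= min_points_per_slice]
  if (length(keep_ids) == 0L)
    stop(sprintf("no z-slice holds at least %d points", min_points_per_slice),
         call. = FALSE)
  keep_ids <- sort(keep_ids)
  x <- cloud$xyz[, 1]; y <- cloud$xyz[, 2]
  res <- lapply(keep_ids, function(k) {
    m <- idx == k
    c(z_mid = min(z) + (k + 0.5) * slice_width_mm, n = sum(m),
      dim_x = max(x[m]) - min(x[m]), dim_y = max(y[m]) - min(y[m]))
  })
  as.data.frame(do.call(rbind, res))
}

#' Object x/y dimensions from slice extents
#'
#' Reduces the per-slice extents of [slice_extents()] to a single x and a
#' single y dimension with the trimmed-histogram mean, discarding slices
#' whose extents land in the extreme histogram bins (truncated top slices,
#' noise-inflated ones).  `reduction = "max_retained"` instead returns the
#' maximum over the retained slices.
#'
#' @param cloud a [point_cloud()].
#' @param slice_width_mm slice thickness (mm).
#' @param trim a [trim_spec()].
#' @param min_points_per_slice forwarded to [slice_extents()].
#' @param reduction `"trimmed_mean"` (default) or `"max_retained"`.
#' @return Named numeric vector `c(dim_x, dim_y)` in mm.
#' @export
measure_xy <- function(cloud, slice_width_mm = 1.0, trim = trim_spec(),
                       min_points_per_slice = 5L,
                       reduction = c("trimmed_mean", "max_retained")) {
  reduction <- match.arg(reduction)
  sl <- slice_extents(cloud, slice_width_mm, min_points_per_slice)
  reduce1 <- function(v) {
    if (reduction == "trimmed_mean")
      return(trimmed_histogram_mean(v, trim))
    if (max(v) - min(v) < 1e-9) return(max(v))
    idx <- bin_index(v, trim$n_bins)
    keep <- idx > trim$trim_low_bins & idx <= trim$n_bins - trim$trim_high_bins
    if (!any(keep)) return(max(v))
    max(v[keep])
  }
  c(dim_x = reduce1(sl$dim_x), dim_y = reduce1(sl$dim_y))
}

#' Measure all three dimensions of an object cloud
#'
#' The full per-object pipeline: bottom-zeroing, trimmed-histogram height
#' from the central footprint region, and trimmed per-slice x/y extents.
#'
#' @param cloud a [point_cloud()] holding one segmented object.
#' @param slice_width_mm slice thickness for x/y extraction (mm).
#' @param trim a [trim_spec()] shared by the height and x/y estimators.
#' @param center_fraction central footprint fraction for the height.
#' @param bottom_percentile percentile for [zero_bottom()].
#' @param min_points_per_slice forwarded to [slice_extents()].
#' @param reduction forwarded to [measure_xy()].
#' @return A list of class `object_measurement` with `dim_x_mm`,
#'   `dim_y_mm`, `dim_z_mm` and `n_points`.
#' @export
#' @examples
#' pc <- make_object_cloud(object_spec("cuboid"),
#'                         noise_model(jitter_sd_mm = 0, outlier_rate = 0),
#'                         seed = 1)
#' measure_object(pc)
measure_object <- function(cloud, slice_width_mm = 1.0, trim = trim_spec(),
                           center_fraction = 0.3, bottom_percentile = 1.0,
                           min_points_per_slice = 5L,
                           reduction = "trimmed_mean") {
  stopifnot(inherits(cloud, "point_cloud"))
  if (npoints(cloud) == 0L) stop("empty cloud", call. = FALSE)
  zeroed <- zero_bottom(cloud, bottom_percentile)
  h <- measure_height(zeroed, center_fraction, trim)
  xy <- measure_xy(zeroed, slice_width_mm, trim, min_points_per_slice,
                   reduction)
  structure(list(dim_x_mm = unname(xy["dim_x"]),
                 dim_y_mm = unname(xy["dim_y"]),
                 dim_z_mm = h,
                 n_points = npoints(cloud)),
            class = "object_measurement")
}

#' @export
print.object_measurement <- function(x, ...) {
  cat(sprintf("<object_measurement: x %.1f mm, y %.1f mm, z %.1f mm (%d pts)>\n",
              x$dim_x_mm, x$dim_y_mm, x$dim_z_mm, x$n_points))
  invisible(x)
}

#' Measure every object of a scene cloud
#'
#' Crops each region of a regions table out of a scene cloud and runs
#' [measure_object()] on it.  Per-object failures are recorded in the
#' `status` column rather than aborting the run.
#'
#' @param cloud the scene [point_cloud()].
#' @param regions data frame with columns `object_id`, `x_min`, `x_max`,
#'   `y_min`, `y_max`.
#' @param ... forwarded to [measure_object()].
#' @return Data frame with columns `object_id`, `dim_x`, `dim_y`, `dim_z`,
#'   `n_points`, `status`.
#' @export
measure_objects <- function(cloud, regions, ...) {
  need <- c("object_id", "x_min", "x_max", "y_min", "y_max")
  if (!all(need %in% names(regions)))
    stop("regions table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    out <- data.frame(object_id = r$object_id, dim_x = NA_real_,
                      dim_y = NA_real_, dim_z = NA_real_,
                      n_points = 0L, status = "ok",
                      stringsAsFactors = FALSE)
    tryCatch({
      obj <- crop_rectangle(cloud, r$x_min, r$x_max, r$y_min, r$y_max)
      m <- measure_object(obj, ...)
      out$dim_x <- m$dim_x_mm; out$dim_y <- m$dim_y_mm
      out$dim_z <- m$dim_z_mm; out$n_points <- m$n_points
    }, error = function(e) out$status <<- conditionMessage(e))
    out
  })
  do.call(rbind, rows)
}
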