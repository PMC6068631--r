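#' Triangular greenness index
#'
#' `TGI = -0.5 * (0.19 (R - G) - 0.12 (R - B))`, a chlorophyll-sensitive
#' color index computed on raw 8-bit channel values: positive for green
#' vegetation, zero for any gray, negative for red-dominant material.  The
#' index is invariant to adding a constant to all three channels.
#'
#' @param r,g,b channel values in `[0, 255]`, vectorized.
#' @return Numeric vector of TGI values.
#' @export
#' @examples
#' tgi(50, 150, 50)   #  9.5
#' tgi(100, 100, 100) #  0
tgi <- function(r, g, b) {
  for (ch in list(r, g, b))
    if (any(ch < 0 | ch > 255))
      stop("color channels must lie in [0, 255]", call. = FALSE)
  -0.5 * (0.19 * (r - g) - 0.12 * (r - b))
}

#' Two-cluster k-means in one dimension
#'
#' Deterministic exact 2-means on scalar values.  Runs Lloyd's algorithm
#' initialized at the minimum and maximum of the data (ties at the
#' midpoint go to the upper cluster), then verifies the result against an
#' exact scan: in one dimension the optimal two-cluster partition is a cut
#' in sorted order, so scanning every cut with prefix sums finds the
#' global minimum of the within-cluster sum of squares.  If Lloyd
#' converged to a worse local optimum (possible even from extreme
#' initialization), the scan's partition is returned instead.
#'
#' @param values numeric vector with at least two distinct values.
#' @param max_iter iteration cap for the Lloyd phase.
#' @param tol convergence tolerance on center movement.
#' @return List with `labels` (1 = lower-center cluster, 2 = upper),
#'   `centers` (sorted ascending), `iterations` (Lloyd iterations used),
#'   `withinss` (total within-cluster sum of squares), and `wss_trace`
#'   (WSS after each Lloyd iteration; non-increasing).
#' @export
kmeans_two <- function(values, max_iter = 100L, tol = 1e-6) {
  values <- as.numeric(values)
  if (length(values) < 2L || max(values) - min(values) == 0)
    stop("k-means with k = 2 needs at least two distinct values",
         call. = FALSE)

  wss_for <- function(labels) {
    c1 <- mean(values[labels == 1L]); c2 <- mean(values[labels == 2L])
    sum((values - ifelse(labels == 1L, c1, c2))^2)
  }

  # Lloyd phase from extreme initialization
  centers <- c(min(values), max(values))
  it <- 0L; trace <- numeric()
  repeat {
    it <- it + 1L
    labels <- ifelse(values >= mean(centers), 2L, 1L)
    new_centers <- c(mean(values[labels == 1L]), mean(values[labels == 2L]))
    trace <- c(trace, wss_for(labels))
    if (max(abs(new_centers - centers)) < tol || it >= max_iter) {
      centers <- new_centers
      break
    }
    centers <- new_centers
  }
  labels <- ifelse(values >= mean(centers), 2L, 1L)
  wss <- wss_for(labels)

  # exact phase: best threshold cut by prefix-sum scan
  ord <- order(values)
  v <- values[ord]
  n <- length(v)
  cs <- cumsum(v); cs2 <- cumsum(v^2)
  m <- seq_len(n - 1L)
  ss_lo <- cs2[m] - cs[m]^2 / m
  ss_hi <- (cs2[n] - cs2[m]) - (cs[n] - cs[m])^2 / (n - m)
  best <- which.min(ss_lo + ss_hi)
  if (ss_lo[best] + ss_hi[best] < wss - 1e-12) {
    labels <- integer(n)
    labels[ord[seq_len(best)]] <- 1L
    labels[ord[(best + 1L):n]] <- 2L
    wss <- ss_lo[best] + ss_hi[best]
    centers <- c(cs[best] / best, (cs[n] - cs[best]) / (n - best))
  }
  list(labels = labels, centers = centers, iterations = it,
       withinss = wss, wss_trace = trace)
}

#' Segment plant points from a colored cloud
#'
#' Computes the TGI of every point, splits the TGI distribution with
#' two-cluster k-means, and takes as plant the points that are both in the
#' higher-TGI cluster and strictly green (TGI > 0) — the two published
#' criteria applied conjunctively.  If the TGI values are all identical
#' (k-means degenerate) the sign rule alone is used.
#'
#' @param cloud a colored [point_cloud()].
#' @param rule `"both"` (default), `"kmeans"`, or `"tgi_sign"` — which
#'   criterion defines plant points.
#' @return A `plant_segmentation` list with `plant_idx`, `background_idx`,
#'   `centers` (TGI units, `NA` when k-means is degenerate) and `tgi`.
#' @export
segment_plant <- function(cloud, rule = c("both", "kmeans", "tgi_sign")) {
  stopifnot(inherits(cloud, "point_cloud"))
  rule <- match.arg(rule)
  if (!has_color(cloud))
    stop("plant segmentation needs a cloud with RGB color", call. = FALSE)
  v <- tgi(cloud$rgb[, 1], cloud$rgb[, 2], cloud$rgb[, 3])
  if (!any(v > 0))
    stop("no point has TGI > 0: no plant detected", call. = FALSE)
  positive <- v > 0
  centers <- c(NA_real_, NA_real_)
  if (max(v) - min(v) == 0 || rule == "tgi_sign") {
    plant <- positive
  } else {
    km <- kmeans_two(v)
    centers <- km$centers
    upper <- km$labels == 2L
    plant <- if (rule == "kmeans") upper else upper & positive
    if (!any(plant)) plant <- positive   # degenerate split: fall back
  }
  structure(list(plant_idx = which(plant),
                 background_idx = which(!plant),
                 centers = centers, tgi = v),
            class = "plant_segmentation")
}

#' @export
print.plant_segmentation <- function(x, ...) {
  cat(sprintf("<plant_segmentation: %d plant / %d background points>\n",
              length(x$plant_idx), length(x$background_idx)))
  if (!anyNA(x$centers))
    cat(sprintf("  TGI cluster centers: %.2f (background), %.2f (plant)\n",
                x$centers[1], x$centers[2]))
  invisible(x)
}

#' Plant height from the top histogram bin
#'
#' Divides the plant-point z values (already measured from the bed plane)
#' into `n_bins` equal-width bins and returns the mean z of the points in
#' the highest-edge non-empty bin — the canopy top, insensitive to lower
#' leaf layers.
#'
#' @param z numeric vector of plant-point heights (mm), or a
#'   [point_cloud()] whose z is used.
#' @param n_bins number of bins, default 50.
#' @return Height estimate in mm.
#' @export
plant_height <- function(z, n_bins = 50L) {
  if (inherits(z, "point_cloud")) z <- z$xyz[, 3]
  z <- z[is.finite(z)]
  if (length(z) == 0L)
    stop("no plant points to take a height from", call. = FALSE)
  if (max(z) - min(z) < 1e-9)
    return(mean(z))
  idx <- bin_index(z, as.integer(n_bins))
  mean(z[idx == max(idx)])
}

#' Measure the heights of every plant in a scene
#'
#' For each region of a tray layout: crops the scene cloud, segments plant
#' from background by TGI + k-means, estimates the local bed plane as a
#' low percentile of the background points' z, and extracts the plant
#' height from the top of the 50-bin histogram.  Per-plant failures (e.g.
#' a region with no green points) are reported in the `status` column, not
#' raised.
#'
#' @param cloud a colored scene [point_cloud()].
#' @param regions data frame with columns `plant_id`, `x_min`, `x_max`,
#'   `y_min`, `y_max`.
#' @param n_bins histogram bins for [plant_height()].
#' @param bed_percentile percentile of background z used as the bed plane.
#' @param rule segmentation rule, see [segment_plant()].
#' @return Data frame with columns `plant_id`, `height_mm`,
#'   `n_plant_points`, `status`.
#' @export
measure_plants <- function(cloud, regions, n_bins = 50L,
                           bed_percentile = 1.0, rule = "both") {
  need <- c("plant_id", "x_min", "x_max", "y_min", "y_max")
  if (!all(need %in% names(regions)))
    stop("regions table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    out <- data.frame(plant_id = r$plant_id, height_mm = NA_real_,
                      n_plant_points = 0L, status = "ok",
                      stringsAsFactors = FALSE)
    tryCatch({
      patch <- crop_rectangle(cloud, r$x_min, r$x_max, r$y_min, r$y_max)
      seg <- segment_plant(patch, rule = rule)
      zb <- if (length(seg$background_idx) > 0)
        stats::quantile(patch$xyz[seg$background_idx, 3],
                        bed_percentile / 100, names = FALSE)
      else min(patch$xyz[, 3])
      out$height_mm <- plant_height(
        patch$xyz[seg$plant_idx, 3] - zb, n_bins = n_bins)
      out$n_plant_points <- length(seg$plant_idx)
    }, error = function(e) {
      out$status <<- if (grepl("no plant detected|no points inside",
                              conditionMessage(e)))
        "no_plant" else conditionMessage(e)
    })
    out
  })
  do.call(rbind, rows)
}
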