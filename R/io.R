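#' Read a ground-truth dimensions table
#'
#' Reads a CSV with columns `object_id`, `dim_x`, `dim_y`, `dim_z` (mm).
#' Repeated rows per object are replicate manual measurements (e.g. three
#' caliper readings) and are averaged per object.
#'
#' @param path CSV path (comma-separated, header row, UTF-8).
#' @return Data frame with one row per object.
#' @export
read_truth_csv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("ground-truth file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("object_id", "dim_x", "dim_y", "dim_z")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0)
    stop("ground-truth CSV lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in c("dim_x", "dim_y", "dim_z")) {
    v <- raw[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))
      stop(sprintf("non-numeric value in column '%s' at data row %d",
                   col, bad[1]), call. = FALSE)
    }
  }
  agg <- stats::aggregate(raw[, c("dim_x", "dim_y", "dim_z")],
                          by = list(object_id = raw$object_id), FUN = mean)
  agg[order(agg$object_id), , drop = FALSE]
}

#' Read a regions table
#'
#' CSV with an id column (`object_id` or `plant_id`) and the rectangle
#' bounds `x_min`, `x_max`, `y_min`, `y_max` in mm.
#'
#' @param path CSV path.
#' @return Data frame of regions.
#' @export
read_regions_csv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("regions file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_min", "x_max", "y_min", "y_max")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("regions CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' Read a run configuration file
#'
#' Parses a small indentation-based `block: / key: value` text format (a
#' strict subset of YAML) into a nested list.  Recognised top-level blocks
#' are `camera`, `acquisition`, `measurement`, `plant` and `simulation`;
#' unknown blocks or keys raise an error so that typos do not silently
#' fall back to defaults.  Numeric-looking values are converted.
#'
#' @param path config file path.
#' @return Nested named list of configuration blocks.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  known <- list(
    camera = c("sensor_width_mm", "sensor_height_mm", "focal_length_mm",
               "image_width_px", "image_height_px", "lens_height_mm"),
    acquisition = c("route_spacing_mm", "forward_speed_mm_s",
                    "snapshot_interval_s", "downscale_factor",
                    "target_side_overlap_pct", "target_forward_overlap_pct"),
    measurement = c("slice_width_mm", "n_bins", "trim_low_bins",
                    "trim_high_bins", "center_fraction",
                    "bottom_percentile", "min_points_per_slice",
                    "reduction"),
    plant = c("n_bins", "bed_percentile", "rule"),
    simulation = c("density_pts_per_mm2", "jitter_sd_mm", "outlier_rate",
                   "outlier_offset_mm", "err_a", "err_b", "max_dropout",
                   "pou_ref", "seed", "min_spacing_mm"))
  lines <- readLines(path, warn = FALSE)
  cfg <- list(); block <- NULL
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(line))) next
    indented <- grepl("^\\s", line)
    kv <- strsplit(trimws(line), ":", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    if (!indented) {
      if (!key %in% names(known))
        stop(sprintf("unknown config block '%s' (line %d)", key, i),
             call. = FALSE)
      block <- key
      cfg[[block]] <- cfg[[block]] %||% list()
    } else {
      if (is.null(block))
        stop(sprintf("key '%s' outside any block (line %d)", key, i),
             call. = FALSE)
      if (!key %in% known[[block]])
        stop(sprintf("unknown key '%s' in block '%s' (line %d)",
                     key, block, i), call. = FALSE)
      num <- suppressWarnings(as.numeric(val))
      cfg[[block]][[key]] <- if (!is.na(num)) num else val
    }
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a camera from a config block
#'
#' @param cfg nested list from [read_config()]; only the `camera` block is
#'   used, missing keys take the [camera_config()] defaults.
#' @return A [camera_config()].
#' @export
camera_from_config <- function(cfg) {
  cam <- cfg$camera %||% list()
  do.call(camera_config, cam)
}

#' Simulate a scene of calibration objects and write it to disk
#'
#' Generates one cloud per object spec, places the objects on the bed with
#' a minimum spacing, optionally degrades the merged scene to a target
#' POU, and writes `cloud.ply`, `truth.csv` (per-object ground-truth
#' dimensions) and `regions.csv` (crop rectangles) into `dir`.
#'
#' @param specs named list of [object_spec()]s (names become object ids).
#' @param dir output directory (created if needed).
#' @param pou optional POU to degrade to; `NULL` keeps pristine clouds.
#' @param noise a [noise_model()].
#' @param degradation a [pou_degradation()].
#' @param min_spacing_mm minimum gap between object footprints.
#' @param seed integer seed.
#' @param binary write binary little-endian PLY instead of ASCII.
#' @return Invisibly, a list with the cloud and the two tables.
#' @export
simulate_scene <- function(specs, dir, pou = NULL, noise = noise_model(),
                           degradation = pou_degradation(),
                           min_spacing_mm = 80, seed = 1L, binary = FALSE) {
  if (is.null(names(specs)) || any(!nzchar(names(specs))))
    names(specs) <- paste0("O", seq_along(specs))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  half_x <- vapply(specs, function(s) s$true_dims["x"] / 2, 1.0)
  # lay objects out on a line along x with the requested gap
  offs <- numeric(length(specs)); at <- 0
  for (i in seq_along(specs)) {
    offs[i] <- at + half_x[i]
    at <- at + 2 * half_x[i] + min_spacing_mm
  }
  clouds <- vector("list", length(specs))
  truth <- regions <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    sp$center <- c(offs[i], 0)
    cl <- make_object_cloud(sp, noise, seed = as.integer(seed) + i)
    if (!is.null(pou))
      cl <- degrade_for_pou(cl, pou, degradation,
                            seed = as.integer(seed) + 1000L + i)
    clouds[[i]] <- cl
    td <- sp$true_dims
    truth[[i]] <- data.frame(object_id = names(specs)[i],
                             dim_x = td[["x"]], dim_y = td[["y"]],
                             dim_z = td[["z"]])
    pad <- min_spacing_mm / 2
    regions[[i]] <- data.frame(object_id = names(specs)[i],
                               x_min = offs[i] - half_x[i] - pad,
                               x_max = offs[i] + half_x[i] + pad,
                               y_min = -sp$true_dims[["y"]] / 2 - pad,
                               y_max = sp$true_dims[["y"]] / 2 + pad)
  }
  scene <- point_cloud(do.call(rbind, lapply(clouds, function(c) c$xyz)),
                       label = unlist(lapply(clouds, function(c) c$label)))
  truth <- do.call(rbind, truth); regions <- do.call(rbind, regions)
  write_ply(scene, file.path(dir, "cloud.ply"), binary = binary)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  utils::write.csv(regions, file.path(dir, "regions.csv"), row.names = FALSE)
  invisible(list(cloud = scene, truth = truth, regions = regions))
}
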