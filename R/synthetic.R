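#' Specification of a synthetic calibration object
#'
#' Describes one of the three foam calibration-object shapes used to probe
#' geometric accuracy: a cuboid, a cylinder, or a mushroom (cylindrical stem
#' topped by a hemispherical cap).  Dimensions are in millimetres; defaults
#' are in the 100-150 mm range typical of bench-top calibration targets.
#'
#' @param shape one of `"cuboid"`, `"cylinder"`, `"mushroom"`.
#' @param width_x,depth_y,height_z cuboid dimensions (mm).
#' @param radius,height cylinder dimensions (mm).
#' @param stem_radius,stem_height,cap_radius mushroom dimensions (mm);
#'   the cap is a hemisphere with `cap_radius >= stem_radius`, so total
#'   height is `stem_height + cap_radius`.
#' @param center xy position of the object center on the bed plane (mm).
#' @return An `object_spec` with fields `shape`, `dims` (named list),
#'   `center`, and the ground-truth `true_dims` (x, y, z extents in mm).
#' @export
#' @examples
#' object_spec("cuboid", width_x = 100, depth_y = 80, height_z = 150)
object_spec <- function(shape = c("cuboid", "cylinder", "mushroom"),
                        width_x = 100, depth_y = 100, height_z = 150,
                        radius = 50, height = 150,
                        stem_radius = 30, stem_height = 80, cap_radius = 60,
                        center = c(0, 0)) {
  shape <- match.arg(shape)
  dims <- switch(shape,
    cuboid   = list(width_x = width_x, depth_y = depth_y, height_z = height_z),
    cylinder = list(radius = radius, height = height),
    mushroom = list(stem_radius = stem_radius, stem_height = stem_height,
                    cap_radius = cap_radius))
  if (any(unlist(dims) <= 0))
    stop("all object dimensions must be strictly positive", call. = FALSE)
  if (shape == "mushroom" && cap_radius < stem_radius)
    stop("mushroom cap radius must be >= stem radius", call. = FALSE)
  true_dims <- switch(shape,
    cuboid   = c(x = width_x, y = depth_y, z = height_z),
    cylinder = c(x = 2 * radius, y = 2 * radius, z = height),
    mushroom = c(x = 2 * cap_radius, y = 2 * cap_radius,
                 z = stem_height + cap_radius))
  structure(list(shape = shape, dims = dims, center = center,
                 true_dims = true_dims),
            class = "object_spec")
}

#' Reconstruction noise model
#'
#' Parameters of the imperfections a dense SfM reconstruction superimposes
#' on true surface geometry: isotropic per-point jitter, loss of points on
#' laterally-viewed surfaces, sparse floating outliers displaced along the
#' surface normal, and the surface sampling density.
#'
#' @param jitter_sd_mm standard deviation of isotropic Gaussian jitter (mm).
#' @param lateral_dropout_frac fraction of side-surface points removed.
#' @param outlier_rate fraction of points replaced by floating outliers.
#' @param outlier_offset_mm displacement of outliers along the local
#'   surface normal (mm).
#' @param density_pts_per_mm2 surface sampling density (points per mm^2).
#' @return A `noise_model` list.
#' @export
noise_model <- function(jitter_sd_mm = 0.5, lateral_dropout_frac = 0,
                        outlier_rate = 0.001, outlier_offset_mm = 20,
                        density_pts_per_mm2 = 1.0) {
  if (jitter_sd_mm < 0) stop("jitter sd must be >= 0", call. = FALSE)
  for (f in c(lateral_dropout_frac, outlier_rate))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (density_pts_per_mm2 <= 0)
    stop("sampling density must be positive", call. = FALSE)
  structure(list(jitter_sd_mm = jitter_sd_mm,
                 lateral_dropout_frac = lateral_dropout_frac,
                 outlier_rate = outlier_rate,
                 outlier_offset_mm = outlier_offset_mm,
                 density_pts_per_mm2 = density_pts_per_mm2),
            class = "noise_model")
}

# uniform sampling helpers --------------------------------------------------

# n points uniform on a rectangle patch [0,a]x[0,b] (returned as 2 cols)
runif_rect <- function(n, a, b) cbind(stats::runif(n, 0, a),
                                      stats::runif(n, 0, b))

# n points uniform on a disk of radius r
runif_disk <- function(n, r) {
  rr <- r * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(rr * cos(th), rr * sin(th))
}

# n points uniform on the upper hemisphere of radius r (returns xyz + normal)
runif_hemisphere <- function(n, r) {
  z <- stats::runif(n)            # cos(polar angle), uniform => uniform area
  th <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  u <- cbind(s * cos(th), s * sin(th), z)
  list(xyz = r * u, normal = u)
}

#' Generate a synthetic dense point cloud of a calibration object
#'
#' Samples the camera-visible surface (top and lateral faces; nadir-view
#' systems never reconstruct object undersides) uniformly at the noise
#' model's density, optionally adds an annulus of bed points around the
#' footprint, then applies jitter, lateral dropout and floating outliers.
#' Every point keeps a ground-truth label (`"top"`, `"lateral"`, `"bed"`)
#' so that estimators can be scored against construction.
#'
#' The object sits with its base at `z = 0` and its center at
#' `spec$center`.
#'
#' @param spec an [object_spec()].
#' @param noise a [noise_model()].
#' @param seed integer seed; identical `(spec, noise, seed)` give identical
#'   clouds.
#' @param bed_margin_mm width of the surrounding bed annulus sampled at the
#'   same density (0 to disable).
#' @return A labeled [point_cloud()].
#' @export
#' @examples
#' pc <- make_object_cloud(object_spec("cylinder"), noise_model(), seed = 1)
#' pc
make_object_cloud <- function(spec, noise = noise_model(), seed = 1L,
                              bed_margin_mm = 20) {
  stopifnot(inherits(spec, "object_spec"), inherits(noise, "noise_model"))
  withr::local_seed(as.integer(seed))
  dens <- noise$density_pts_per_mm2
  npois <- function(area) stats::rpois(1, max(area * dens, 1))

  pts <- list(); nrm <- list(); lab <- character(0)
  add <- function(xyz, normal, label) {
    pts[[length(pts) + 1L]] <<- xyz
    nrm[[length(nrm) + 1L]] <<- normal
    lab <<- c(lab, rep(label, nrow(xyz)))
  }

  d <- spec$dims
  if (spec$shape == "cuboid") {
    w <- d$width_x; dp <- d$depth_y; h <- d$height_z
    n <- npois(w * dp)                                   # top face
    uv <- runif_rect(n, w, dp)
    add(cbind(uv[, 1] - w / 2, uv[, 2] - dp / 2, h),
        matrix(rep(c(0, 0, 1), each = n), ncol = 3), "top")
    for (sgn in c(-1, 1)) {                              # x-normal faces
      n <- npois(dp * h)
      uv <- runif_rect(n, dp, h)
      add(cbind(sgn * w / 2, uv[, 1] - dp / 2, uv[, 2]),
          matrix(rep(c(sgn, 0, 0), each = n), ncol = 3), "lateral")
      n <- npois(w * h)                                  # y-normal faces
      uv <- runif_rect(n, w, h)
      add(cbind(uv[, 1] - w / 2, sgn * dp / 2, uv[, 2]),
          matrix(rep(c(0, sgn, 0), each = n), ncol = 3), "lateral")
    }
    foot_r <- sqrt((w / 2)^2 + (dp / 2)^2)
  } else if (spec$shape == "cylinder") {
    r <- d$radius; h <- d$height
    n <- npois(pi * r^2)                                 # top disk
    xy <- runif_disk(n, r)
    add(cbind(xy, h), matrix(rep(c(0, 0, 1), each = n), ncol = 3), "top")
    n <- npois(2 * pi * r * h)                           # wall
    th <- stats::runif(n, 0, 2 * pi)
    add(cbind(r * cos(th), r * sin(th), stats::runif(n, 0, h)),
        cbind(cos(th), sin(th), 0), "lateral")
    foot_r <- r
  } else {                                               # mushroom
    rs <- d$stem_radius; hs <- d$stem_height; rc <- d$cap_radius
    n <- npois(2 * pi * rc^2)                            # hemispherical cap
    hemi <- runif_hemisphere(n, rc)
    add(cbind(hemi$xyz[, 1], hemi$xyz[, 2], hemi$xyz[, 3] + hs),
        hemi$normal, "top")
    n <- npois(2 * pi * rs * hs)                         # stem wall
    th <- stats::runif(n, 0, 2 * pi)
    add(cbind(rs * cos(th), rs * sin(th), stats::runif(n, 0, hs)),
        cbind(cos(th), sin(th), 0), "lateral")
    foot_r <- rc
  }

  if (bed_margin_mm > 0) {                               # bed annulus at z=0
    r0 <- foot_r; r1 <- foot_r + bed_margin_mm
    n <- npois(pi * (r1^2 - r0^2))
    rr <- sqrt(stats::runif(n, r0^2, r1^2))
    th <- stats::runif(n, 0, 2 * pi)
    add(cbind(rr * cos(th), rr * sin(th), 0),
        matrix(rep(c(0, 0, 1), each = n), ncol = 3), "bed")
  }

  xyz <- do.call(rbind, pts)
  normal <- do.call(rbind, nrm)

  # lateral dropout
  if (noise$lateral_dropout_frac > 0) {
    is_lat <- lab == "lateral"
    drop <- is_lat & stats::runif(length(lab)) < noise$lateral_dropout_frac
    xyz <- xyz[!drop, , drop = FALSE]
    normal <- normal[!drop, , drop = FALSE]
    lab <- lab[!drop]
  }
  # floating outliers along the surface normal
  if (noise$outlier_rate > 0) {
    is_out <- stats::runif(length(lab)) < noise$outlier_rate
    xyz[is_out, ] <- xyz[is_out, , drop = FALSE] +
      noise$outlier_offset_mm * normal[is_out, , drop = FALSE]
  }
  # jitter
  if (noise$jitter_sd_mm > 0)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, noise$jitter_sd_mm),
                        ncol = 3)
  xyz[, 1] <- xyz[, 1] + spec$center[1]
  xyz[, 2] <- xyz[, 2] + spec$center[2]
  point_cloud(xyz, label = lab)
}

#' POU-dependent degradation model
#'
#' Maps a power-of-unit (POU) value to the degradation a dense cloud
#' suffers at that acquisition quality: the sampling-density scale
#' increases with POU, the random lateral dropout decreases with POU, the
#' jitter decreases with POU, and the lateral surface is eroded from the
#' +x and +y extremes by a depth following the power law
#' `err_a * POU^err_b` — so the induced x/y dimension errors themselves
#' follow a power law in POU.
#'
#' Defaults calibrate the induced error to roughly 4 mm at POU 556 rising
#' to roughly 37 mm at POU 17, the magnitude range observed for SfM clouds
#' of bench-top objects; they are configuration, not claims.
#'
#' @param pou_ref POU at which density scale reaches 1 and dropout 0.
#' @param density_exponent exponent of the density scale `(pou/pou_ref)^e`.
#' @param max_dropout random lateral dropout as POU tends to 0.
#' @param err_a,err_b power-law coefficients of the erosion depth (mm);
#'   `err_a > 0`, `err_b < 0`.
#' @param jitter_base_mm,jitter_scale jitter sd is
#'   `jitter_base_mm + jitter_scale / sqrt(pou)`.
#' @return A `pou_degradation` list of mapping functions and parameters.
#' @export
pou_degradation <- function(pou_ref = 556, density_exponent = 0.5,
                            max_dropout = 0.6, err_a = 200, err_b = -0.6,
                            jitter_base_mm = 0.2, jitter_scale = 5) {
  if (err_a <= 0 || err_b >= 0)
    stop("power-law erosion needs err_a > 0 and err_b < 0", call. = FALSE)
  if (max_dropout < 0 || max_dropout > 1)
    stop("max_dropout must lie in [0, 1]", call. = FALSE)
  structure(list(
    pou_ref = pou_ref,
    density_scale = function(pou)
      pmin(1, pmax(0.02, (pou / pou_ref)^density_exponent)),
    dropout_frac = function(pou) max_dropout * pmax(0, 1 - pou / pou_ref),
    jitter_sd = function(pou) jitter_base_mm + jitter_scale / sqrt(pou),
    erosion_depth = function(pou) err_a * pou^err_b,
    err_a = err_a, err_b = err_b), class = "pou_degradation")
}

#' Degrade a cloud to a given POU
#'
#' Applies the [pou_degradation()] mapping to a labeled object cloud:
#' subsamples all points to the POU-mapped density, erodes the point set
#' from the +x and +y extremes by the power-law depth (emulating the
#' incomplete side surfaces of low-POU reconstructions), randomly drops the
#' mapped fraction of remaining lateral points, and adds the mapped jitter.
#' Deterministic given `seed`.
#'
#' @param cloud a labeled [point_cloud()] from [make_object_cloud()].
#' @param pou the POU (pixel/mm) to emulate; non-positive values are
#'   clamped to 1 with a warning.
#' @param degradation a [pou_degradation()].
#' @param seed integer seed.
#' @return A degraded [point_cloud()] (labels preserved).
#' @export
degrade_for_pou <- function(cloud, pou, degradation = pou_degradation(),
                            seed = 1L) {
  stopifnot(inherits(cloud, "point_cloud"),
            inherits(degradation, "pou_degradation"))
  if (pou <= 0) {
    warning("non-positive POU clamped to 1")
    pou <- 1
  }
  withr::local_seed(as.integer(seed))
  n <- npoints(cloud)
  keep <- stats::runif(n) < degradation$density_scale(pou)
  out <- subset_cloud(cloud, keep)

  delta <- degradation$erosion_depth(pou)
  # sub-micrometre erosion is below any physical meaning; skip it rather
  # than letting float rounding clip the extreme faces
  if (delta > 1e-6 && npoints(out) > 0) {
    x <- out$xyz[, 1]; y <- out$xyz[, 2]
    # erode relative to the object itself, not the surrounding bed
    obj <- if (!is.null(out$label)) out$label != "bed" else rep(TRUE, length(x))
    if (any(obj)) {
      keep <- !obj | (x <= max(x[obj]) - delta & y <= max(y[obj]) - delta)
      if (any(keep)) out <- subset_cloud(out, keep)
    }
  }

  f <- degradation$dropout_frac(pou)
  if (f > 0 && !is.null(out$label)) {
    drop <- out$label == "lateral" & stats::runif(npoints(out)) < f
    out <- subset_cloud(out, !drop)
  }

  sd <- degradation$jitter_sd(pou)
  if (sd > 0 && npoints(out) > 0)
    out$xyz <- out$xyz + matrix(stats::rnorm(length(out$xyz), 0, sd),
                                ncol = 3)
  out
}

#' Specification of a synthetic potted plant
#'
#' A green-canopy plant on a dark bed: an ellipsoidal canopy shell over a
#' thin stem, with green-dominant canopy RGB (positive TGI by construction)
#' and near-gray dark bed RGB (TGI close to zero).
#'
#' @param canopy_radius_mm horizontal canopy radius (mm).
#' @param plant_height_mm height of the canopy top above the bed (mm).
#' @param stem_radius_mm stem radius (mm).
#' @param center xy position of the plant axis (mm).
#' @param noise a [noise_model()]; jitter and density apply, dropout and
#'   outliers are ignored for plants.
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(canopy_radius_mm = 120, plant_height_mm = 300,
                       stem_radius_mm = 6, center = c(0, 0),
                       noise = noise_model()) {
  if (plant_height_mm <= 0 || canopy_radius_mm <= 0 || stem_radius_mm <= 0)
    stop("plant dimensions must be strictly positive", call. = FALSE)
  structure(list(canopy_radius_mm = canopy_radius_mm,
                 plant_height_mm = plant_height_mm,
                 stem_radius_mm = stem_radius_mm,
                 center = center, noise = noise),
            class = "plant_spec")
}

#' Generate a synthetic colored plant cloud
#'
#' Canopy and stem points are labeled `"plant"` and colored green-dominant
#' (G exceeds R, B does not exceed R), so their triangular greenness index
#' is strictly positive before jitter; bed points are labeled
#' `"background"` and colored dark near-gray, so their TGI is near zero.
#' The highest plant point sits exactly at `plant_height_mm` before
#' jitter.  The bed is sampled at `z = 0` out to twice the canopy radius.
#'
#' @param spec a [plant_spec()].
#' @param seed integer seed.
#' @return A colored, labeled [point_cloud()].
#' @export
make_plant_cloud <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "plant_spec"))
  withr::local_seed(as.integer(seed))
  r <- spec$canopy_radius_mm; h <- spec$plant_height_mm
  dens <- spec$noise$density_pts_per_mm2

  # canopy: upper-biased ellipsoid shell, semi-axes (r, r, 0.45 h),
  # centered at 0.55 h so the canopy spans about [0.1 h, h]
  cz <- 0.45 * h
  area <- 4 * pi * ((2 * r + cz) / 3)^2            # crude shell area
  n_can <- max(500L, stats::rpois(1, 0.5 * area * dens))
  u <- matrix(stats::rnorm(3 * n_can), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  canopy <- cbind(r * u[, 1], r * u[, 2], cz * u[, 3] + 0.55 * h)
  canopy[, 3] <- pmax(canopy[, 3], 0.1 * h)
  canopy[, 3] <- canopy[, 3] * (h / max(canopy[, 3]))  # pin apex at height

  n_stem <- max(50L, stats::rpois(1, 2 * pi * spec$stem_radius_mm * 0.6 * h *
                                    dens))
  th <- stats::runif(n_stem, 0, 2 * pi)
  stem <- cbind(spec$stem_radius_mm * cos(th), spec$stem_radius_mm * sin(th),
                stats::runif(n_stem, 0, 0.6 * h))

  bed_r <- 2 * r
  n_bed <- max(500L, stats::rpois(1, pi * bed_r^2 * dens * 0.25))
  bed <- cbind(runif_disk(n_bed, bed_r), 0)

  n_pl <- n_can + n_stem
  # green-dominant plant colors: G - R in [40, 100], B <= R
  pr <- stats::runif(n_pl, 40, 80)
  pg <- pmin(255, pr + stats::runif(n_pl, 40, 100))
  pb <- stats::runif(n_pl, 20, pr)
  # dark near-gray bed: channel-wise wobble of +-5 around a common base
  base <- stats::runif(n_bed, 20, 60)
  wob <- function() pmax(0, pmin(255, base + stats::runif(n_bed, -5, 5)))
  rgb <- rbind(cbind(pr, pg, pb), cbind(wob(), wob(), wob()))

  xyz <- rbind(canopy, stem, bed)
  xyz[, 1] <- xyz[, 1] + spec$center[1]
  xyz[, 2] <- xyz[, 2] + spec$center[2]
  if (spec$noise$jitter_sd_mm > 0)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, spec$noise$jitter_sd_mm),
                        ncol = 3)
  point_cloud(xyz, rgb = round(rgb),
              label = c(rep("plant", n_pl), rep("background", n_bed)))
}

#' Generate a synthetic power-law error dataset
#'
#' Draws absolute measurement errors following
#' `err_i = a * POU_i^b * exp(eps_i)`, `eps_i ~ N(0, noise_sd_log^2)` —
#' i.e. a power law with multiplicative log-normal noise, the model the
#' error-versus-POU regression assumes.
#'
#' @param a,b power-law coefficient (mm) and exponent; `a > 0`.
#' @param noise_sd_log standard deviation of the log-scale noise.
#' @param pou_values vector of positive POU values.
#' @param seed integer seed.
#' @return A data frame with columns `pou` and `abs_error_mm`.
#' @export
make_error_dataset <- function(a, b, noise_sd_log, pou_values, seed = 1L) {
  if (a <= 0) stop("coefficient a must be positive", call. = FALSE)
  if (any(pou_values <= 0)) stop("POU values must be positive", call. = FALSE)
  withr::local_seed(as.integer(seed))
  err <- a * pou_values^b *
    exp(stats::rnorm(length(pou_values), 0, noise_sd_log))
  data.frame(pou = pou_values, abs_error_mm = err)
}

#' The 17-POU design grid
#'
#' The full-factorial acquisition design evaluated by the package's
#' synthetic experiment: side overlaps 90/80/67 %, forward overlaps
#' 95/85/75 %, at full spatial resolution (SR 2.78 pixel/mm) and at the
#' half-resolution downscale (SR 1.39 pixel/mm), minus the one
#' half-resolution combination (67 %, 85 %) not acquired — 17 settings in
#' total, with integer-rounded POU from 17 to 556 pixel/mm.
#'
#' POU is computed from the spatial resolution at the conventional
#' two-decimal table precision (2.78 / 1.39 pixel/mm), which is what the
#' integer design POUs are quoted from; the exact SR is also returned.
#'
#' @param camera a [camera_config()].
#' @return Data frame with columns `sr_px_per_mm` (exact), `sr_2dp`,
#'   `side_overlap_pct`, `forward_overlap_pct`, `pou_px_per_mm`, `pou_int`.
#' @export
design_pou_grid <- function(camera = camera_config()) {
  fov <- compute_fov(camera)
  sr_full <- compute_sr(camera$image_width_px, fov$fov_w_mm)
  grid <- expand.grid(oy = c(95, 85, 75), ox = c(90, 80, 67),
                      down = c(1, 2))
  grid <- grid[!(grid$down == 2 & grid$ox == 67 & grid$oy == 85), ]
  sr <- sr_full / grid$down
  sr_2dp <- round(sr, 2)
  pou <- compute_pou(sr_2dp, grid$ox, grid$oy)
  data.frame(sr_px_per_mm = sr,
             sr_2dp = sr_2dp,
             side_overlap_pct = grid$ox,
             forward_overlap_pct = grid$oy,
             pou_px_per_mm = pou,
             pou_int = round(pou), row.names = NULL)
}
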