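#' Absolute measurement errors against ground truth
#'
#' Joins a measurements table to a ground-truth table by `object_id` and
#' returns the absolute difference per object and dimension, carrying any
#' grouping columns (e.g. `shape`, `pou`, `replicate`) along.
#'
#' @param measurements data frame with `object_id`, `dim_x`, `dim_y`,
#'   `dim_z` and optional grouping columns.
#' @param ground_truth data frame with `object_id`, `dim_x`, `dim_y`,
#'   `dim_z` (one row per object; see [read_truth_csv()] for replicate
#'   averaging).
#' @return Long data frame with columns `object_id`, grouping columns,
#'   `dimension` (`"x"`, `"y"`, `"z"`) and `abs_error_mm`.
#' @export
abs_errors <- function(measurements, ground_truth) {
  need <- c("object_id", "dim_x", "dim_y", "dim_z")
  for (tab in list(measurements, ground_truth))
    if (!all(need %in% names(tab)))
      stop("tables must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
  missing <- setdiff(measurements$object_id, ground_truth$object_id)
  if (length(missing) > 0)
    stop("no ground truth for object(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  gt <- ground_truth[match(measurements$object_id, ground_truth$object_id), ]
  extra <- setdiff(names(measurements), c(need, "n_points", "status"))
  base <- measurements[, c("object_id", extra), drop = FALSE]
  out <- do.call(rbind, lapply(c("x", "y", "z"), function(d) {
    col <- paste0("dim_", d)
    cbind(base, dimension = d,
          abs_error_mm = abs(measurements[[col]] - gt[[col]]))
  }))
  rownames(out) <- NULL
  out
}

#' Power-law fit of error versus POU
#'
#' Fits `err = a * POU^b` by ordinary least squares on the log-log scale:
#' `log(err) = log(a) + b log(POU)`.  Exact zero errors are floored at
#' `zero_floor` millimetres before the log transform (absolute errors of
#' 0.0 mm do occur) and the number floored is reported.  R-squared is that
#' of the log-log regression; a pseudo R-squared on the original scale is
#' also returned.
#'
#' @param pou_values positive POU values.
#' @param errors absolute errors (mm), same length.
#' @param zero_floor floor applied to zero errors before logging (mm).
#' @return A `power_fit` list with `a`, `b`, `r_squared`,
#'   `r_squared_original`, `n`, `n_floored`.
#' @export
#' @examples
#' pou <- c(17, 56, 111, 278, 556)
#' fit_power(pou, 200 * pou^-0.6)
fit_power <- function(pou_values, errors, zero_floor = 0.01) {
  if (length(pou_values) != length(errors))
    stop("pou_values and errors must have the same length", call. = FALSE)
  if (length(pou_values) < 3L)
    stop("power fit needs at least 3 points", call. = FALSE)
  if (any(pou_values <= 0))
    stop("POU values must be positive", call. = FALSE)
  if (any(errors < 0))
    stop("absolute errors cannot be negative", call. = FALSE)
  n_floored <- sum(errors < zero_floor)
  err <- pmax(errors, zero_floor)
  fit <- stats::lm(log(err) ~ log(pou_values))
  a <- exp(unname(stats::coef(fit)[1]))
  b <- unname(stats::coef(fit)[2])
  ly <- log(err)
  r2_log <- 1 - sum(stats::residuals(fit)^2) / sum((ly - mean(ly))^2)
  pred <- a * pou_values^b
  ss_res <- sum((err - pred)^2)
  ss_tot <- sum((err - mean(err))^2)
  structure(list(a = a, b = b,
                 r_squared = r2_log,
                 r_squared_original =
                   if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 n = length(err), n_floored = n_floored),
            class = "power_fit")
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf("<power_fit: err = %.3g * POU^%.3f, R^2 = %.3f, n = %d>\n",
              x$a, x$b, x$r_squared, x$n))
  invisible(x)
}

#' Agreement between an automated and a reference measurement
#'
#' Ordinary least squares of the estimated values on the reference values
#' (slope, intercept, R-squared) plus the root-mean-square error against
#' the 1:1 line — the RMSE between methods, not the regression residual
#' RMSE.
#'
#' @param estimated,reference equal-length numeric vectors, n >= 3.
#' @return An `agreement_result` list with `slope`, `intercept`,
#'   `r_squared`, `rmse_mm`, `n`.
#' @export
agreement_stats <- function(estimated, reference) {
  if (length(estimated) != length(reference))
    stop("vectors must have the same length", call. = FALSE)
  if (length(estimated) < 3L)
    stop("agreement statistics need at least 3 pairs", call. = FALSE)
  if (stats::var(reference) == 0)
    stop("reference values have zero variance", call. = FALSE)
  fit <- stats::lm(estimated ~ reference)
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((estimated - mean(estimated))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 rmse_mm = sqrt(mean((estimated - reference)^2)),
                 n = length(estimated)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "<agreement: slope %.3f, intercept %.2f, R^2 %.3f, RMSE %.2f mm, n %d>\n",
    x$slope, x$intercept, x$r_squared, x$rmse_mm, x$n))
  invisible(x)
}

#' One-way analysis of variance with pairwise comparisons
#'
#' Standard between/within decomposition over a list of groups, with the
#' F test and optional unadjusted pairwise t tests of group means using
#' the pooled within-group variance (the least-squares-means PDIFF
#' analogue; no multiplicity adjustment by default).
#'
#' @param groups named list of numeric vectors, each with >= 2 values.
#' @param pairwise compute the pairwise table.
#' @param adjust p-value adjustment method for the pairwise table, passed
#'   to [stats::p.adjust()]; `"none"` by default.
#' @return An `anova_result` list with `df_between`, `df_within`,
#'   `ss_between`, `ss_within`, `ms_between`, `ms_within`, `f_value`,
#'   `p_value` and, when requested, `pairwise` (data frame with columns
#'   `group1`, `group2`, `mean_diff`, `t`, `p`).
#' @export
one_way_anova <- function(groups, pairwise = TRUE, adjust = "none") {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least two groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2L))
    stop("every group needs at least two observations", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  all_v <- unlist(groups, use.names = FALSE)
  grand <- mean(all_v)
  ni <- vapply(groups, length, 1L)
  mi <- vapply(groups, mean, 1.0)
  k <- length(groups); n <- sum(ni)
  ss_b <- sum(ni * (mi - grand)^2)
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1.0))
  df_b <- k - 1L; df_w <- n - k
  ms_b <- ss_b / df_b; ms_w <- ss_w / df_w
  f <- if (ms_w > 0) ms_b / ms_w else if (ms_b == 0) 0 else Inf
  p <- if (ms_w > 0) stats::pf(f, df_b, df_w, lower.tail = FALSE)
       else as.numeric(ms_b > 0) * 0 + (ms_b == 0)
  pw <- NULL
  if (pairwise) {
    cmb <- utils::combn(names(groups), 2)
    rows <- apply(cmb, 2, function(pr) {
      i <- pr[1]; j <- pr[2]
      d <- unname(mi[i] - mi[j])
      se <- sqrt(ms_w * (1 / ni[i] + 1 / ni[j]))
      t <- if (se > 0) unname(d / se) else 0
      c(mean_diff = d, t = t,
        p = 2 * stats::pt(abs(t), df_w, lower.tail = FALSE))
    })
    pw <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                     t(rows), row.names = NULL)
    pw$p <- stats::p.adjust(pw$p, method = adjust)
  }
  structure(list(df_between = df_b, df_within = df_w,
                 ss_between = ss_b, ss_within = ss_w,
                 ms_between = ms_b, ms_within = ms_w,
                 f_value = f, p_value = unname(p), pairwise = pw),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("<anova_result>\n")
  cat(sprintf("  between: df %d, SS %.2f, MS %.2f\n",
              x$df_between, x$ss_between, x$ms_between))
  cat(sprintf("  within:  df %d, SS %.2f, MS %.2f\n",
              x$df_within, x$ss_within, x$ms_within))
  cat(sprintf("  F = %.3f, p = %.4g\n", x$f_value, x$p_value))
  invisible(x)
}

#' Mean and standard deviation of errors by group
#'
#' Groups error records by shape and dimension and reports the sample mean
#' and sample standard deviation — the descriptive "mean +- sd" table of an
#' accuracy study.  Groups with a single record report sd = 0 and are
#' flagged.
#'
#' @param records data frame with columns `shape`, `dimension`,
#'   `abs_error_mm` (e.g. from [abs_errors()]).
#' @return Data frame with columns `shape`, `dimension`, `n`, `mean_mm`,
#'   `sd_mm`, `single_obs`.
#' @export
summarize_errors <- function(records) {
  need <- c("shape", "dimension", "abs_error_mm")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  records <- records[is.finite(records$abs_error_mm), ]
  if (nrow(records) == 0)
    stop("no finite error records to summarize", call. = FALSE)
  key <- interaction(records$shape, records$dimension, drop = TRUE)
  rows <- lapply(split(records, key), function(g) {
    data.frame(shape = g$shape[1], dimension = g$dimension[1],
               n = nrow(g), mean_mm = mean(g$abs_error_mm),
               sd_mm = if (nrow(g) > 1) stats::sd(g$abs_error_mm) else 0,
               single_obs = nrow(g) == 1L)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$dimension, out$shape), ]
  rownames(out) <- NULL
  out
}

#' Run the full synthetic accuracy experiment
#'
#' Reproduces the structure of the accuracy evaluation on synthetic data:
#' for each POU of the design grid and each replicate, generates the three
#' calibration-object clouds, degrades them to that POU, measures all
#' three dimensions, computes absolute errors against the generator's
#' ground truth, and then summarises — error table by shape and dimension,
#' power-law fit of mean error versus POU per dimension, and a one-way
#' ANOVA of error across dimensions.
#'
#' The defaults are scaled for a laptop run (3 replicates over the design
#' grid at moderate sampling density); `pou_values`, `n_replicates` and
#' `density` scale the experiment up or down.
#'
#' @param pou_values POU grid; defaults to the 17-setting design grid.
#' @param n_replicates replicates per POU and shape.
#' @param specs list of [object_spec()]s; defaults to one cuboid, one
#'   cylinder, one mushroom.
#' @param degradation a [pou_degradation()].
#' @param density sampling density of the pristine clouds (points/mm^2).
#' @param seed integer master seed; per-cloud seeds are derived from it.
#' @return A list of class `pou_evaluation`: `errors` (long record table),
#'   `summary`, `power_fits` (per dimension), `anova_dimensions`.
#' @export
run_full_evaluation <- function(pou_values = design_pou_grid()$pou_int,
                                n_replicates = 3,
                                specs = list(
                                  O1 = object_spec("cuboid"),
                                  O2 = object_spec("cylinder"),
                                  O3 = object_spec("mushroom")),
                                degradation = pou_degradation(),
                                density = 0.6,
                                seed = 1L) {
  pou_values <- sort(unique(pou_values))
  base_noise <- noise_model(jitter_sd_mm = 0, outlier_rate = 0,
                            density_pts_per_mm2 = density)
  rows <- list()
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    sid <- names(specs)[si]
    truth <- spec$true_dims
    for (pou in pou_values) {
      for (rep in seq_len(n_replicates)) {
        sd_i <- (as.integer(seed) * 97L + si * 1009L +
                   as.integer(round(pou)) * 13L + rep * 101L) %% 2147483647L
        pristine <- make_object_cloud(spec, base_noise, seed = sd_i)
        cl <- degrade_for_pou(pristine, pou, degradation, seed = sd_i + 1L)
        m <- measure_object(cl)
        rows[[length(rows) + 1L]] <- data.frame(
          object_id = sid, shape = sid, replicate = rep, pou = pou,
          dimension = c("x", "y", "z"),
          abs_error_mm = abs(c(m$dim_x_mm, m$dim_y_mm, m$dim_z_mm) -
                               truth[c("x", "y", "z")]))
      }
    }
  }
  errors <- do.call(rbind, rows)
  rownames(errors) <- NULL

  mean_by <- function(dim) {
    sub <- errors[errors$dimension == dim, ]
    agg <- stats::aggregate(abs_error_mm ~ pou, data = sub, FUN = mean)
    fit_power(agg$pou, agg$abs_error_mm)
  }
  power_fits <- list(x = mean_by("x"), y = mean_by("y"), z = mean_by("z"))
  anova_dim <- one_way_anova(split(errors$abs_error_mm, errors$dimension))
  structure(list(errors = errors,
                 summary = summarize_errors(errors),
                 power_fits = power_fits,
                 anova_dimensions = anova_dim,
                 seed = seed),
            class = "pou_evaluation")
}

#' @export
print.pou_evaluation <- function(x, ...) {
  cat(sprintf("<pou_evaluation: %d error records, %d POUs>\n",
              nrow(x$errors), length(unique(x$errors$pou))))
  cat("  power fits (err = a * POU^b):\n")
  for (d in names(x$power_fits)) {
    f <- x$power_fits[[d]]
    cat(sprintf("    %s: a = %.3g, b = %.3f, R^2 = %.3f\n",
                d, f$a, f$b, f$r_squared))
  }
  invisible(x)
}
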