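#' Through-origin least-squares slope
#'
#' Best-fit line restricted to pass through the origin (zero infused, zero
#' measured): the least-squares slope is `sum(x y) / sum(x^2)`. Pairs with a
#' missing measurement are dropped.
#'
#' @param infused,measured paired volumes in uL; alternatively `infused` may
#'   be a [trajectory()] and `measured` omitted.
#' @return Slope in uL measured per uL infused (the Vd/Vi ratio).
#' @export
slope_through_origin <- function(infused, measured) {
  if (inherits(infused, "ced_trajectory")) {
    measured <- infused$measured_uL
    infused <- infused$infused_uL
  }
  ok <- !is.na(infused) & !is.na(measured)
  x <- infused[ok]; y <- measured[ok]
  if (length(x) == 0L || all(x == 0))
    stop("slope undefined: no points with positive infused volume")
  sum(x * y) / sum(x^2)
}

#' Remove measurement noise spikes from a trajectory
#'
#' Single pass: a through-origin line is fitted to all usable points, then
#' points whose measured volume is strictly greater than `factor` times the
#' fitted value are dropped. Points at or below the cutoff are retained.
#' Small-volume optical measurements are prone to upward spikes
#' (reflections, transient mask bridges); this trims them without touching
#' points below the line.
#'
#' @param traj a [trajectory()].
#' @param factor multiplier on the fitted line; the default 1.1 removes
#'   points more than 10% above the fit.
#' @return The trajectory with offending rows removed.
#' @export
filter_noise <- function(traj, factor = 1.1) {
  stopifnot(inherits(traj, "ced_trajectory"))
  b <- slope_through_origin(traj)
  keep <- is.na(traj$measured_uL) |
    traj$measured_uL <= factor * b * traj$infused_uL
  out <- traj[keep, , drop = FALSE]
  class(out) <- class(traj)
  out
}

#' Percent error between a reference and a test mean
#'
#' @param ref_mean reference mean volume (uL, > 0).
#' @param test_mean test mean volume (uL).
#' @return `|ref_mean - test_mean| / ref_mean * 100`.
#' @export
percent_error <- function(ref_mean, test_mean) {
  if (!is.finite(ref_mean) || ref_mean <= 0)
    stop("reference mean must be positive")
  abs(ref_mean - test_mean) / ref_mean * 100
}

#' Pooled two-sample t-test p-value
#'
#' Two-sided two-sample t-test with pooled (equal) variance, used to decide
#' whether volume groups measured at different infusion volumes can be pooled
#' into a single reference set.
#'
#' @param a,b numeric vectors of volumes, each with at least two values.
#' @return The two-sided p-value.
#' @export
pooled_t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least two values")
  stats::t.test(a, b, var.equal = TRUE)$p.value
}

#' Express an 8-bit threshold as a percentage of the intensity range
#'
#' @param threshold integer in `[0, 255]`.
#' @return Integer percent, `round(threshold / 255 * 100)`.
#' @export
threshold_as_percent <- function(threshold) {
  if (any(!is.finite(threshold)) || any(threshold < 0) || any(threshold > 255))
    stop("threshold must lie in [0, 255]")
  round(threshold / 255 * 100)
}

#' Through-origin random-slope mixed model for phantom calibration
#'
#' Fits the comparison model between bench-phantom (agar) and in vivo (NHP)
#' infusion trajectories:
#' \deqn{Vd_{ij} = (\beta + \gamma \cdot g_i + b_i) \, Vi_{ij} + \epsilon_{ij}}
#' where \eqn{\beta} is the mean Vd/Vi slope of the reference group,
#' \eqn{g_i} indicates the non-reference group, \eqn{b_i} is a zero-mean
#' random slope per trial, and there is no intercept, fixed or random: every
#' best-fit line passes through the origin. The interaction effect
#' \eqn{\gamma} approximates the difference in average slope between the two
#' groups — the calibration discrepancy.
#'
#' Estimation is by maximum likelihood via [lme4::lmer()]. When the mixed fit
#' is degenerate (e.g. noiseless data, a single point per trial), the fit
#' falls back to per-trial through-origin slopes and group-mean differences;
#' the `method` field records which route produced the estimates.
#'
#' @param agar list of agar-group [trajectory()] objects (or a single one).
#' @param nhp list of NHP-group trajectories.
#' @param reference which group anchors the base slope; the interaction is
#'   (other group mean slope) - (reference mean slope). Default `"agar"`.
#' @return Object of class `ced_mixed_fit` with fields `base_slope`,
#'   `interaction`, `interaction_se`, `trial_slopes` (named per trial),
#'   `reference_group`, `method` (`"mixed"` or `"slope-means"`), `sigma`
#'   (residual SD), `slope_sd` (random-slope SD), `data`, and `model` (the
#'   underlying `merMod`, or `NULL` for the fallback).
#' @examples
#' set.seed(1)
#' tr <- make_trajectories(seed = 1)
#' fit <- fit_mixed_model(tr$agar, tr$nhp)
#' coef(fit)
#' @export
fit_mixed_model <- function(agar, nhp, reference = c("agar", "nhp")) {
  reference <- match.arg(reference)
  if (inherits(agar, "ced_trajectory")) agar <- list(agar)
  if (inherits(nhp, "ced_trajectory")) nhp <- list(nhp)
  if (length(agar) == 0L || length(nhp) == 0L)
    stop("need at least one trial per group")
  d <- do.call(rbind, c(lapply(agar, as.data.frame),
                        lapply(nhp, as.data.frame)))
  d <- d[!is.na(d$measured_uL), , drop = FALSE]
  if (nrow(d) == 0L) stop("no usable (non-missing) points")
  d$trial <- paste(d$group, d$trial_id, sep = ":")
  d$other <- as.numeric(d$group != reference)
  if (length(unique(d$other)) < 2L)
    stop("both groups must contribute usable points")

  per_trial <- vapply(split(d, d$trial), function(dd)
    slope_through_origin(dd$infused_uL, dd$measured_uL), numeric(1))
  trial_other <- vapply(split(d$other, d$trial), `[`, numeric(1), 1)

  fit <- tryCatch(
    lme4::lmer(measured_uL ~ 0 + infused_uL + infused_uL:other +
                 (0 + infused_uL | trial),
               data = d, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE)),
    error = function(e) e)

  if (inherits(fit, "merMod") &&
      all(is.finite(lme4::fixef(fit))) && stats::sigma(fit) > 1e-8) {
    fe <- lme4::fixef(fit)
    vc <- as.matrix(stats::vcov(fit))
    re <- lme4::ranef(fit)$trial
    blup <- setNames(re[, 1], rownames(re))
    slopes <- fe[["infused_uL"]] + fe[["infused_uL:other"]] * trial_other +
      blup[names(trial_other)]
    out <- list(base_slope = unname(fe[["infused_uL"]]),
                interaction = unname(fe[["infused_uL:other"]]),
                interaction_se = sqrt(vc["infused_uL:other", "infused_uL:other"]),
                trial_slopes = slopes,
                sigma = stats::sigma(fit),
                slope_sd = sqrt(lme4::VarCorr(fit)$trial[1, 1]),
                method = "mixed", model = fit)
  } else {
    # degenerate mixed fit: fall back to per-trial slopes and group means
    ref_s <- per_trial[trial_other == 0]
    oth_s <- per_trial[trial_other == 1]
    se <- if (length(ref_s) > 1L && length(oth_s) > 1L)
      sqrt(stats::var(ref_s) / length(ref_s) + stats::var(oth_s) / length(oth_s))
    else NA_real_
    out <- list(base_slope = mean(ref_s),
                interaction = mean(oth_s) - mean(ref_s),
                interaction_se = se,
                trial_slopes = per_trial,
                sigma = 0,
                slope_sd = stats::sd(per_trial),
                method = "slope-means", model = NULL)
  }
  out$reference_group <- reference
  out$per_trial_ols <- per_trial
  out$data <- d
  class(out) <- "ced_mixed_fit"
  out
}

#' @export
print.ced_mixed_fit <- function(x, ...) {
  other <- setdiff(c("agar", "nhp"), x$reference_group)
  cat("Through-origin random-slope mixed fit (", x$method, ")\n", sep = "")
  cat(sprintf("  reference (%s) mean Vd/Vi slope: %.3f uL/uL\n",
              x$reference_group, x$base_slope))
  cat(sprintf("  interaction (%s - %s): %.3f uL/uL (SE %.3f)\n",
              other, x$reference_group, x$interaction, x$interaction_se))
  cat(sprintf("  %d trials, %d points\n",
              length(x$trial_slopes), nrow(x$data)))
  invisible(x)
}

#' @export
summary.ced_mixed_fit <- function(object, ...) {
  print(object)
  cat("\nPer-trial fitted slopes (uL/uL):\n")
  print(round(object$trial_slopes, 3))
  if (!is.null(object$model)) {
    cat(sprintf("\nrandom-slope SD %.3f, residual SD %.3f uL\n",
                object$slope_sd, object$sigma))
  }
  invisible(object)
}

#' @export
coef.ced_mixed_fit <- function(object, ...) {
  c(base_slope = object$base_slope, interaction = object$interaction)
}

#' @export
predict.ced_mixed_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  other <- as.numeric(newdata$group != object$reference_group)
  slope <- object$base_slope + object$interaction * other
  if (!is.null(newdata$trial_id)) {
    key <- paste(newdata$group, newdata$trial_id, sep = ":")
    known <- key %in% names(object$trial_slopes)
    slope[known] <- object$trial_slopes[key[known]]
  }
  slope * newdata$infused_uL
}

#' @export
residuals.ced_mixed_fit <- function(object, ...) {
  object$data$measured_uL - predict(object, object$data)
}

#' @export
#' @importFrom stats simulate
simulate.ced_mixed_fit <- function(object, nsim = 1, seed = NULL, ...) {
  n_ref <- sum(vapply(split(object$data$other, object$data$trial), `[`,
                      numeric(1), 1) == 0)
  n_oth <- length(object$trial_slopes) - n_ref
  groups <- if (object$reference_group == "agar") c(n_ref, n_oth) else c(n_oth, n_ref)
  slopes_ag <- if (object$reference_group == "agar")
    c(object$base_slope, object$base_slope + object$interaction)
  else c(object$base_slope + object$interaction, object$base_slope)
  lapply(seq_len(nsim), function(i)
    make_trajectories(n_per_group = groups, group_slopes = slopes_ag,
                      slope_sd = object$slope_sd, noise_sd = object$sigma,
                      seed = if (is.null(seed)) NULL else seed + i - 1L))
}

#' @export
plot.ced_mixed_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$infused_uL, d$measured_uL,
                 col = ifelse(d$other == 0, "grey30", "firebrick"),
                 xlab = "infused volume Vi (uL)",
                 ylab = "measured volume Vd (uL)", ...)
  graphics::abline(0, x$base_slope, col = "grey30", lwd = 2)
  graphics::abline(0, x$base_slope + x$interaction, col = "firebrick", lwd = 2)
  graphics::legend("topleft", bty = "n", lwd = 2,
                   col = c("grey30", "firebrick"),
                   legend = c(x$reference_group,
                              setdiff(c("agar", "nhp"), x$reference_group)))
  invisible(x)
}

#' Calibrate segmentation parameters against reference trajectories
#'
#' Deterministic surrogate for the iterative manual alignment of phantom and
#' in vivo data: every combination of colour component and threshold on the
#' grid is used to segment all agar trials, the resulting trajectories are
#' compared with the reference trajectories through [fit_mixed_model()], and
#' the combination minimizing the absolute interaction effect (the absolute
#' mean-slope difference when the mixed fit degenerates) is returned. Ties
#' are broken by the lower threshold, then by channel order red < green <
#' blue.
#'
#' @param frames_by_trial named list: one list of frames per agar trial (see
#'   [segment_series()]).
#' @param protocol the [infusion_protocol()] driving all trials.
#' @param reference list of reference (NHP) trajectories.
#' @param components channels to search.
#' @param thresholds integer thresholds to search.
#' @param base_params a [seg_params()] supplying direction, cut row, scale
#'   and seed; its component/threshold are overridden by the grid.
#' @param region region label for segmented trajectories.
#' @return Object of class `ced_calibration`: `component`, `threshold`,
#'   `objective`, `params` (the winning [seg_params()]), `grid` (all searched
#'   points with objectives), `fit` (the winning mixed fit) and
#'   `slope_table`.
#' @export
calibrate_segmentation <- function(frames_by_trial, protocol, reference,
                                   components = c("red", "green", "blue"),
                                   thresholds, base_params,
                                   region = "cortical") {
  stopifnot(length(frames_by_trial) >= 1L, length(reference) >= 1L,
            length(components) >= 1L, length(thresholds) >= 1L)
  components <- match.arg(components, c("red", "green", "blue"),
                          several.ok = TRUE)
  grid <- expand.grid(threshold = sort(thresholds), component = components,
                      stringsAsFactors = FALSE)
  grid$objective <- NA_real_
  fits <- vector("list", nrow(grid))
  ids <- names(frames_by_trial) %||% paste0("agar-", seq_along(frames_by_trial))

  for (g in seq_len(nrow(grid))) {
    p <- base_params
    p$component <- grid$component[g]
    p$threshold <- grid$threshold[g]
    trajs <- lapply(seq_along(frames_by_trial), function(i)
      segment_series(frames_by_trial[[i]], p, protocol,
                     trial_id = ids[i], region = region))
    usable <- vapply(trajs, function(tr)
      any(!is.na(tr$measured_uL) & tr$infused_uL > 0), logical(1))
    if (!any(usable)) next
    fit <- tryCatch(fit_mixed_model(trajs[usable], reference),
                    error = function(e) NULL)
    if (is.null(fit)) next
    grid$objective[g] <- abs(fit$interaction)
    fits[[g]] <- fit
  }
  if (all(is.na(grid$objective)))
    stop("calibration failed: no grid point produced a usable segmentation")

  ord <- order(grid$objective,
               grid$threshold,
               match(grid$component, c("red", "green", "blue")))
  best <- ord[1]
  wp <- base_params
  wp$component <- grid$component[best]
  wp$threshold <- grid$threshold[best]
  structure(list(component = grid$component[best],
                 threshold = grid$threshold[best],
                 objective = grid$objective[best],
                 params = wp, grid = grid, fit = fits[[best]],
                 slope_table = fits[[best]]$trial_slopes),
            class = "ced_calibration")
}

#' @export
print.ced_calibration <- function(x, ...) {
  cat(sprintf(paste0("segmentation calibration: %s component, threshold %g ",
                     "(%d%% of range), |interaction| = %.4g uL/uL\n"),
              x$component, x$threshold, threshold_as_percent(x$threshold),
              x$objective))
  cat(sprintf("  searched %d grid points (%d usable)\n", nrow(x$grid),
              sum(!is.na(x$grid$objective))))
  invisible(x)
}

#' Match post-infusion diffusion time against a reference volume
#'
#' After a CED infusion ends, diffusion keeps growing the dye bolus in agar.
#' Next-day in vivo scans likewise show a diffusion-grown bolus. This finds
#' the post-infusion diffusion time at which the phantom matches the in vivo
#' reference: per trial, volumes are smoothed with a centred 3-point running
#' median (shifting final picks off noise spikes), the across-trial mean is
#' compared with the reference mean at each common timepoint, and the
#' earliest time with percent error at or below `tolerance` is reported (the
#' global minimizer if the tolerance is never met).
#'
#' @param series list with one data frame per agar trial, columns `time_min`
#'   (minutes after infusion end) and `volume_ul`.
#' @param ref_volumes reference (NHP) bolus volumes in uL.
#' @param tolerance percent-error target, default 5.
#' @return List of class `diffusion_match`: `t_star`, `agar_mean`,
#'   `ref_mean`, `percent_error`, `within_tolerance`, and `profile` (the
#'   per-time means and errors).
#' @export
match_diffusion <- function(series, ref_volumes, tolerance = 5) {
  stopifnot(length(series) >= 1L, length(ref_volumes) >= 1L)
  smoothed <- lapply(series, function(s) {
    stopifnot(all(c("time_min", "volume_ul") %in% names(s)))
    s <- s[order(s$time_min), , drop = FALSE]
    s$volume_ul <- if (nrow(s) >= 3L)
      as.numeric(stats::runmed(s$volume_ul, 3L)) else s$volume_ul
    s
  })
  common <- Reduce(intersect, lapply(smoothed, function(s) s$time_min))
  if (length(common) == 0L)
    stop("no overlapping time support across trials")
  common <- sort(common)
  ref_mean <- mean(ref_volumes)
  agar_means <- vapply(common, function(t)
    mean(vapply(smoothed, function(s) s$volume_ul[s$time_min == t][1],
                numeric(1))), numeric(1))
  pe <- abs(ref_mean - agar_means) / ref_mean * 100
  hit <- which(pe <= tolerance)
  i <- if (length(hit)) hit[1] else which.min(pe)
  structure(list(t_star = common[i], agar_mean = agar_means[i],
                 ref_mean = ref_mean, percent_error = pe[i],
                 within_tolerance = length(hit) > 0,
                 profile = data.frame(time_min = common,
                                      agar_mean = agar_means,
                                      percent_error = pe)),
            class = "diffusion_match")
}

#' @export
print.diffusion_match <- function(x, ...) {
  cat(sprintf(paste0("diffusion match: t* = %g min after infusion end, agar ",
                     "mean %.1f uL vs reference %.1f uL (%.1f%% error%s)\n"),
              x$t_star, x$agar_mean, x$ref_mean, x$percent_error,
              if (x$within_tolerance) "" else "; tolerance not met"))
  invisible(x)
}
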