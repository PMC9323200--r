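#' Infusion trajectory
#'
#' One trial's series of paired volumes: the cumulative volume pushed by the
#' syringe (`infused_uL`, Vi) and the distribution volume measured from
#' imaging (`measured_uL`, Vd). The ratio of the two — the through-origin
#' slope Vd/Vi — is the quantity on which phantom and in vivo data are
#' compared. Missing measurements (`NA`) are allowed; early frames or scans
#' often lack a resolvable bolus.
#'
#' @param trial_id trial label, unique within its group.
#' @param group `"agar"` (bench phantom) or `"nhp"` (in vivo MRI).
#' @param region `"cortical"`, `"thalamic"` or `"mtl"`.
#' @param time_min acquisition times in minutes (may be `NA`, e.g. next-day
#'   scans).
#' @param infused_uL cumulative infused volumes, non-negative and
#'   non-decreasing.
#' @param measured_uL measured bolus volumes, non-negative or `NA`.
#' @return A data frame of class `ced_trajectory` with the six columns above
#'   plus `trial_id`, `group`, `region` repeated per row.
#' @export
trajectory <- function(trial_id, group, region, time_min, infused_uL,
                       measured_uL) {
  group <- match.arg(group, c("agar", "nhp"))
  region <- match.arg(region, c("cortical", "thalamic", "mtl"))
  n <- length(infused_uL)
  stopifnot(length(measured_uL) == n, length(time_min) == n)
  if (n > 0) {
    if (any(is.na(infused_uL)) || any(infused_uL < 0))
      stop("infused_uL must be non-negative")
    if (is.unsorted(infused_uL))
      stop("infused_uL must be non-decreasing")
    if (any(measured_uL < 0, na.rm = TRUE))
      stop("measured_uL must be non-negative")
  }
  out <- data.frame(trial_id = rep(as.character(trial_id), length.out = n),
                    group = rep(group, length.out = n),
                    region = rep(region, length.out = n),
                    time_min = as.numeric(time_min),
                    infused_uL = as.numeric(infused_uL),
                    measured_uL = as.numeric(measured_uL))
  class(out) <- c("ced_trajectory", "data.frame")
  out
}

#' @export
print.ced_trajectory <- function(x, ...) {
  ok <- sum(!is.na(x$measured_uL))
  cat(sprintf("CED trajectory '%s' (%s, %s): %d points (%d measured)\n",
              x$trial_id[1], x$group[1], x$region[1], nrow(x), ok))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
plot.ced_trajectory <- function(x, ...) {
  graphics::plot(x$infused_uL, x$measured_uL,
                 xlab = "infused volume Vi (uL)",
                 ylab = "measured volume Vd (uL)",
                 main = sprintf("%s (%s, %s)", x$trial_id[1], x$group[1],
                                x$region[1]), ...)
  ok <- !is.na(x$measured_uL) & x$infused_uL > 0
  if (any(ok))
    graphics::abline(0, slope_through_origin(x$infused_uL[ok],
                                             x$measured_uL[ok]),
                     lty = 2)
  invisible(x)
}

traj_columns <- c("trial_id", "group", "region", "time_min", "infused_uL",
                  "measured_uL")

#' Read trajectories from CSV
#'
#' Reads the interchange CSV (columns `trial_id, group, region, time_min,
#' infused_uL, measured_uL`), validates vocabularies and volume signs, and
#' splits rows into per-trial trajectories preserving row order.
#'
#' @param path CSV file path.
#' @return List of [trajectory()] objects (possibly empty).
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop(sprintf("trajectory file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(traj_columns, names(df))
  if (length(missing))
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  if (nrow(df) == 0L) return(list())
  bad <- which(!df$group %in% c("agar", "nhp"))
  if (length(bad))
    stop(sprintf("row %d: unknown group '%s'", bad[1], df$group[bad[1]]))
  bad <- which(!df$region %in% c("cortical", "thalamic", "mtl"))
  if (length(bad))
    stop(sprintf("row %d: unknown region '%s'", bad[1], df$region[bad[1]]))
  bad <- which(is.na(df$infused_uL) | df$infused_uL < 0 |
                 (!is.na(df$measured_uL) & df$measured_uL < 0))
  if (length(bad))
    stop(sprintf("row %d: negative or missing volume", bad[1]))
  ids <- unique(df$trial_id)
  lapply(ids, function(id) {
    d <- df[df$trial_id == id, , drop = FALSE]
    trajectory(trial_id = id, group = d$group[1], region = d$region[1],
               time_min = d$time_min, infused_uL = d$infused_uL,
               measured_uL = d$measured_uL)
  })
}

#' Write trajectories to CSV
#'
#' Deterministic output: columns in the interchange order, rows sorted by
#' trial then time, volumes at full precision. Round-trips with
#' [read_trajectories()].
#'
#' @param trials list of [trajectory()] objects (or a single one).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trials, path) {
  if (inherits(trials, "ced_trajectory")) trials <- list(trials)
  if (length(trials) == 0L) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), 6), traj_columns))
  } else {
    df <- do.call(rbind, lapply(trials, as.data.frame))
    df <- df[order(match(df$trial_id, unique(df$trial_id)),
                   xtfrm(df$time_min)), traj_columns]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# split a combined data frame back into per-trial trajectory objects
split_trajectories <- function(df) {
  lapply(unique(df$trial_id), function(id) {
    d <- df[df$trial_id == id, , drop = FALSE]
    trajectory(id, d$group[1], d$region[1], d$time_min, d$infused_uL,
               d$measured_uL)
  })
}
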