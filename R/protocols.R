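#' Stair-step CED infusion protocols
#'
#' Convection-enhanced delivery (CED) pumps are ramped up and back down in
#' discrete rate steps to limit reflux along the cannula track. An
#' `infusion_protocol` is an ordered sequence of (rate, duration) steps; the
#' cumulative infused volume is the piecewise-linear integral of the rate
#' schedule.
#'
#' @param steps a two-column matrix or data frame (rate in uL/min, duration in
#'   min), or a list of length-2 numeric vectors, one per step, in pump order.
#' @param name label for the schedule; one of `"cortical"`, `"thalamic"`,
#'   `"mtl"` or `"custom"`.
#' @return An object of class `infusion_protocol`: a list with elements
#'   `name` and `steps` (a data frame with columns `rate_ul_min`,
#'   `duration_min`).
#' @examples
#' p <- infusion_protocol(list(c(1, 1), c(2, 1), c(1, 1)))
#' protocol_totals(p)
#' @seealso [protocol_preset()] for the benchmark gel schedules,
#'   [cumulative_volume()] for time-resolved infused volume.
#' @export
infusion_protocol <- function(steps, name = "custom") {
  name <- match.arg(name, c("custom", "cortical", "thalamic", "mtl"))
  if (is.list(steps) && !is.data.frame(steps)) {
    steps <- do.call(rbind, lapply(steps, function(s) as.numeric(s[1:2])))
  }
  steps <- as.data.frame(steps)
  if (nrow(steps) == 0L) stop("protocol needs at least one step")
  if (ncol(steps) < 2L) stop("each step needs a rate and a duration")
  names(steps)[1:2] <- c("rate_ul_min", "duration_min")
  steps <- steps[, c("rate_ul_min", "duration_min")]
  for (i in seq_len(nrow(steps))) {
    r <- steps$rate_ul_min[i]; d <- steps$duration_min[i]
    if (!is.finite(r) || r <= 0)
      stop(sprintf("step %d: rate must be positive and finite (got %s)", i, r))
    if (!is.finite(d) || d <= 0)
      stop(sprintf("step %d: duration must be positive and finite (got %s)", i, d))
  }
  structure(list(name = name, steps = steps), class = "infusion_protocol")
}

#' Benchmark gel infusion schedules
#'
#' The three stair-step schedules used for bench-side gel infusions:
#' cortical (50 uL over 14 min, peak 5 uL/min), thalamic (246 uL over 84 min,
#' long 3 uL/min plateau) and medial temporal lobe, MTL (15 uL over 7 min).
#'
#' @param name `"cortical"`, `"thalamic"` or `"mtl"`.
#' @return An [infusion_protocol()].
#' @examples
#' protocol_totals(protocol_preset("thalamic"))
#' @export
protocol_preset <- function(name = c("cortical", "thalamic", "mtl")) {
  name <- match.arg(name)
  steps <- switch(name,
    cortical = list(c(1, 1), c(2, 1), c(3, 1), c(4, 1), c(5, 6),
                    c(4, 1), c(3, 1), c(2, 1), c(1, 1)),
    thalamic = list(c(1, 1), c(2, 1), c(3, 80), c(2, 1), c(1, 1)),
    mtl      = list(c(1, 1), c(2, 1), c(3, 3), c(2, 1), c(1, 1)))
  infusion_protocol(steps, name = name)
}

#' Total infused volume and total time of a protocol
#'
#' @param protocol an [infusion_protocol()].
#' @return Named numeric vector with `volume_ul` (sum of rate x duration) and
#'   `time_min` (sum of durations).
#' @export
protocol_totals <- function(protocol) {
  stopifnot(inherits(protocol, "infusion_protocol"))
  s <- protocol$steps
  c(volume_ul = sum(s$rate_ul_min * s$duration_min),
    time_min = sum(s$duration_min))
}

#' Cumulative infused volume at a given time
#'
#' Piecewise-linear interpolation of the stair-step rate schedule. Time zero
#' is the start of infusion; each step boundary belongs to the later step, so
#' the rate on `[t_i, t_{i+1})` is that of step `i + 1`.
#'
#' @param protocol an [infusion_protocol()].
#' @param t time(s) in minutes, each within `[0, total time]`.
#' @return Cumulative volume(s) in uL, non-decreasing in `t`.
#' @examples
#' cumulative_volume(protocol_preset("cortical"), 2.5)  # 4.5 uL
#' @export
cumulative_volume <- function(protocol, t) {
  stopifnot(inherits(protocol, "infusion_protocol"))
  tot <- protocol_totals(protocol)
  if (any(!is.finite(t)) || any(t < 0) || any(t > tot[["time_min"]]))
    stop(sprintf("t must lie within [0, %g] min", tot[["time_min"]]))
  s <- protocol$steps
  bounds <- c(0, cumsum(s$duration_min))
  cumvol <- c(0, cumsum(s$rate_ul_min * s$duration_min))
  vapply(t, function(ti) {
    i <- findInterval(ti, bounds, rightmost.closed = TRUE)
    cumvol[i] + s$rate_ul_min[i] * (ti - bounds[i])
  }, numeric(1))
}

#' @export
print.infusion_protocol <- function(x, ...) {
  tot <- protocol_totals(x)
  cat(sprintf("CED infusion protocol '%s': %d steps, %g uL over %g min\n",
              x$name, nrow(x$steps), tot[["volume_ul"]], tot[["time_min"]]))
  print(x$steps, row.names = FALSE)
  invisible(x)
}

#' @export
plot.infusion_protocol <- function(x, ...) {
  tot <- protocol_totals(x)
  tt <- seq(0, tot[["time_min"]], length.out = 200)
  graphics::plot(tt, cumulative_volume(x, tt), type = "l",
                 xlab = "time (min)", ylab = "infused volume (uL)",
                 main = sprintf("Protocol '%s'", x$name), ...)
  invisible(x)
}
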