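#' Read a phantom photograph
#'
#' Loads an 8-bit RGB photograph (PNG or TIFF) of the agar phantom as an
#' integer array `H x W x 3` with values in `[0, 255]`, rows running from the
#' top of the image downwards.
#'
#' @param path file path (`.png`, `.tif`/`.tiff`).
#' @param capture_time minutes since the start of infusion, attached as the
#'   `capture_time` attribute (optional).
#' @return Integer array `H x W x 3` (red, green, blue).
#' @export
read_phantom_photo <- function(path, capture_time = NA_real_) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop(sprintf("unsupported image format '.%s'", ext)))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3]  # drop alpha
  out <- array(as.integer(round(img * 255)), dim = dim(img))
  attr(out, "capture_time") <- capture_time
  out
}

check_image <- function(image) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop("image must be an H x W x 3 array of 8-bit RGB values")
  if (min(image) < 0 || max(image) > 255)
    stop("image values must lie in [0, 255]")
  invisible(d)
}

#' Extract a single colour component
#'
#' Reduces a 24-bit RGB image to one 8-bit value per pixel by selecting a
#' single colour channel. No luminance conversion is applied: dye contrast is
#' concentrated in individual channels (a yellow dye absorbs blue), so one raw
#' component separates bolus from background better than a grey-scale mix.
#'
#' @param image `H x W x 3` integer array (see [read_phantom_photo()]).
#' @param component `"red"`, `"green"` or `"blue"`.
#' @return Integer matrix `H x W` with attribute `source_component`.
#' @export
extract_component <- function(image, component = c("red", "green", "blue")) {
  component <- match.arg(component)
  check_image(image)
  plane <- image[, , match(component, c("red", "green", "blue")), drop = FALSE]
  dim(plane) <- dim(image)[1:2]
  attr(plane, "source_component") <- component
  attr(plane, "capture_time") <- attr(image, "capture_time")
  plane
}

#' Threshold an intensity plane into a binary mask
#'
#' Marks pixels strictly below (or strictly above) a threshold. Ties at the
#' threshold are excluded in both directions so that calibration grids over
#' integer thresholds partition pixels reproducibly.
#'
#' @param plane `H x W` intensity matrix (0-255).
#' @param threshold integer in `[0, 255]`.
#' @param direction `"below"` marks `value < threshold` (dye pixels are dark
#'   in the chosen channel); `"above"` marks `value > threshold`.
#' @return Logical matrix with a `provenance` attribute recording the step.
#' @export
threshold_mask <- function(plane, threshold, direction = c("below", "above")) {
  direction <- match.arg(direction)
  if (!is.finite(threshold) || threshold < 0 || threshold > 255)
    stop("threshold must lie in [0, 255]")
  mask <- if (direction == "below") plane < threshold else plane > threshold
  mask <- matrix(as.logical(mask), nrow(plane), ncol(plane))
  attr(mask, "capture_time") <- attr(plane, "capture_time")
  add_provenance(mask, sprintf("threshold %s %g on %s", direction, threshold,
                               attr(plane, "source_component") %||% "plane"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

add_provenance <- function(mask, step) {
  attr(mask, "provenance") <- c(attr(mask, "provenance"), step)
  mask
}

# 8-connected labelling: EBImage's one-pass labelling is 4-connected, so merge
# labels that touch diagonally with a union-find pass over label pairs.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  nr <- nrow(lab); nc <- ncol(lab)
  for (d in list(c(1L, 1L), c(1L, -1L))) {   # the two diagonal directions
    a <- lab[seq_len(nr - 1L), if (d[2] > 0) seq_len(nc - 1L) else 2:nc]
    b <- lab[2:nr,             if (d[2] > 0) 2:nc else seq_len(nc - 1L)]
    keep <- a > 0L & b > 0L & a != b
    if (any(keep)) {
      prs <- unique(cbind(a[keep], b[keep]))
      for (k in seq_len(nrow(prs))) {
        ra <- find(prs[k, 1]); rb <- find(prs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

#' Isolate the bolus cluster
#'
#' Keeps a single 8-connected component of the mask — the one containing
#' `seed` when given, otherwise the largest by pixel count — and clears every
#' other cluster (ruler marks, specks, reflections).
#'
#' @param mask logical matrix from [threshold_mask()].
#' @param seed optional `(row, col)` pixel known to lie inside the bolus.
#' @return Logical matrix with a single connected component.
#' @export
select_bolus_cluster <- function(mask, seed = NULL) {
  if (!any(mask)) stop("mask is empty: no cluster to select")
  lab <- label_components8(mask)
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (length(seed) != 2L || seed[1] < 1L || seed[1] > nrow(mask) ||
        seed[2] < 1L || seed[2] > ncol(mask))
      stop("seed must be a (row, col) coordinate inside the image")
    id <- lab[seed[1], seed[2]]
    if (id == 0L) stop("seed pixel is not marked in the mask")
  } else {
    counts <- tabulate(lab[lab > 0L])
    id <- which.max(counts)
  }
  out <- lab == id
  attributes(out) <- attributes(mask)
  add_provenance(out, if (is.null(seed)) "select largest 8-connected cluster"
                      else sprintf("select cluster at seed (%d,%d)", seed[1], seed[2]))
}

#' Erase the cannula from a mask
#'
#' The cannula enters the phantom from above and, when it survives
#' thresholding, appears as a dark track joined to the top of the bolus. It is
#' removed by clearing every marked pixel above a manually chosen boundary:
#' `cut_row` is the number of pixel rows, counted from the top of the image,
#' that are cleared; rows at or below the boundary are untouched.
#'
#' @param mask logical matrix.
#' @param cut_row integer in `[0, H]`; `0` leaves the mask unchanged, `H`
#'   clears it entirely.
#' @return Logical matrix.
#' @export
erase_cannula <- function(mask, cut_row) {
  nr <- nrow(mask)
  if (!is.finite(cut_row) || cut_row < 0 || cut_row > nr)
    stop(sprintf("cut_row must lie in [0, %d]", nr))
  cut_row <- as.integer(cut_row)
  if (cut_row > 0L) mask[seq_len(cut_row), ] <- FALSE
  add_provenance(mask, sprintf("erase cannula above row %d", cut_row))
}

#' Ellipsoidal volume from bolus height and width
#'
#' The bolus is modelled as an ellipsoid radially symmetric about the cannula
#' axis: `v = (pi/6) h w^2`, with `h` the extent along the cannula and `w` the
#' extent perpendicular to it (both in mm); 1 mm^3 is 1 uL. This equals the
#' standard ellipsoid volume `(4/3) pi a b^2` with semi-axes `a = h/2`,
#' `b = w/2`.
#'
#' @param h,w bolus height and width in mm.
#' @return Volume in uL.
#' @export
ellipsoid_volume <- function(h, w) {
  stopifnot(all(h >= 0), all(w >= 0))
  pi / 6 * h * w^2
}

#' Measure a segmented bolus
#'
#' Converts a binary bolus mask to physical dimensions using the ruler-derived
#' pixel scale: `h` is the row extent of marked pixels and `w` the column
#' extent (axis-aligned bounding extents, in pixels spanned), each divided by
#' `scale`; the volume follows from [ellipsoid_volume()]. An empty mask
#' measures as zero.
#'
#' @param mask logical matrix.
#' @param scale pixels per mm (> 0).
#' @param capture_time minutes since infusion start (optional, carried
#'   through).
#' @return List of class `bolus_measurement` with elements `h_mm`, `w_mm`,
#'   `v_ul`, `capture_time`.
#' @export
measure_bolus <- function(mask, scale, capture_time = NULL) {
  if (!is.finite(scale) || scale <= 0) stop("scale must be positive (px/mm)")
  if (is.null(capture_time))
    capture_time <- attr(mask, "capture_time") %||% NA_real_
  if (!any(mask)) {
    h <- w <- 0
  } else {
    idx <- which(mask, arr.ind = TRUE)
    h <- (max(idx[, 1]) - min(idx[, 1]) + 1L) / scale
    w <- (max(idx[, 2]) - min(idx[, 2]) + 1L) / scale
  }
  structure(list(h_mm = h, w_mm = w, v_ul = ellipsoid_volume(h, w),
                 capture_time = capture_time),
            class = "bolus_measurement")
}

#' @export
print.bolus_measurement <- function(x, ...) {
  cat(sprintf("bolus: h = %.2f mm, w = %.2f mm, v = %.2f uL (t = %s min)\n",
              x$h_mm, x$w_mm, x$v_ul,
              if (is.na(x$capture_time)) "?" else format(x$capture_time)))
  invisible(x)
}

#' Segmentation parameters
#'
#' Bundles the image-processing choices for one infusion type: which colour
#' component carries the dye contrast, the 8-bit threshold and its direction,
#' the cannula erasure boundary, the ruler-derived pixel scale, and an
#' optional in-bolus seed pixel.
#'
#' @param component `"red"`, `"green"` or `"blue"`.
#' @param threshold integer in `[0, 255]`.
#' @param scale pixels per mm (> 0).
#' @param direction `"below"` (default; dye is dark in the chosen channel) or
#'   `"above"`.
#' @param cut_row number of top rows to clear for cannula erasure, or `NULL`
#'   to skip the step.
#' @param seed optional `(row, col)` pixel inside the bolus for cluster
#'   selection; without it the largest cluster is kept.
#' @return List of class `seg_params`.
#' @export
seg_params <- function(component, threshold, scale,
                       direction = c("below", "above"),
                       cut_row = NULL, seed = NULL) {
  component <- match.arg(component, c("red", "green", "blue"))
  direction <- match.arg(direction)
  if (!is.finite(threshold) || threshold < 0 || threshold > 255)
    stop("threshold must lie in [0, 255]")
  if (!is.finite(scale) || scale <= 0) stop("scale must be positive (px/mm)")
  structure(list(component = component, threshold = threshold,
                 direction = direction, cut_row = cut_row,
                 scale = scale, seed = seed),
            class = "seg_params")
}

#' Segment a time-lapse infusion series
#'
#' Runs the full image-processing chain on each frame — component extraction,
#' thresholding, bolus cluster selection, cannula erasure, ellipsoidal
#' volumetry — and pairs each measured volume with the protocol's cumulative
#' infused volume at the capture time (clamped at the protocol total for
#' post-infusion frames). Frames in which no bolus cluster is found are
#' recorded as missing measurements rather than aborting the series: early
#' frames often lack a resolvable bolus.
#'
#' @param frames list of `H x W x 3` images, each with a `capture_time`
#'   attribute (minutes since infusion start), sorted by time; alternatively a
#'   list of `list(image =, time =)` pairs.
#' @param params a [seg_params()].
#' @param protocol an [infusion_protocol()].
#' @param trial_id,region labels for the resulting trajectory.
#' @return A `ced_trajectory` (group `"agar"`) with one row per frame;
#'   `measured_uL` is `NA` where segmentation found no cluster.
#' @export
segment_series <- function(frames, params, protocol,
                           trial_id = "agar-1", region = "cortical") {
  stopifnot(inherits(params, "seg_params"), inherits(protocol, "infusion_protocol"))
  tot <- protocol_totals(protocol)
  rows <- lapply(frames, function(fr) {
    if (is.list(fr) && !is.null(fr$image)) {
      img <- fr$image; t <- fr$time
    } else {
      img <- fr; t <- attr(fr, "capture_time")
    }
    if (is.null(t) || is.na(t)) stop("every frame needs a capture time")
    infused <- cumulative_volume(protocol, min(t, tot[["time_min"]]))
    v <- tryCatch({
      plane <- extract_component(img, params$component)
      mask <- threshold_mask(plane, params$threshold, params$direction)
      mask <- select_bolus_cluster(mask, params$seed)
      if (!is.null(params$cut_row)) mask <- erase_cannula(mask, params$cut_row)
      measure_bolus(mask, params$scale)$v_ul
    }, error = function(e) NA_real_)
    data.frame(time_min = t, infused_uL = infused, measured_uL = v)
  })
  pts <- do.call(rbind, rows)
  pts <- pts[order(pts$time_min), , drop = FALSE]
  trajectory(trial_id = trial_id, group = "agar", region = region,
             time_min = pts$time_min, infused_uL = pts$infused_uL,
             measured_uL = pts$measured_uL)
}
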