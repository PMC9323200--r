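#' 3-D intensity grid with voxel spacing
#'
#' Container for a T1-weighted volumetric scan: a scalar intensity array plus
#' per-axis voxel size in mm. Anisotropic spacing is common (e.g. 0.35 x 0.35
#' x 0.5 mm next-day scans); no resampling is performed, volumes are computed
#' directly from the voxel volume.
#'
#' @param values numeric 3-D array.
#' @param spacing length-3 positive numeric, voxel size per axis in mm.
#' @param acquisition_time minutes since infusion start, or `NA` for next-day
#'   scans.
#' @return List of class `volume_grid`.
#' @export
volume_grid <- function(values, spacing = c(1, 1, 1),
                        acquisition_time = NA_real_) {
  d <- dim(values)
  if (is.null(d) || length(d) != 3L || any(d < 1L))
    stop("values must be a non-empty 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive voxel sizes (mm)")
  structure(list(values = values, spacing = spacing,
                 acquisition_time = acquisition_time),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume grid %s voxels, spacing %s mm, voxel volume %.5g uL\n",
              paste(dim(x$values), collapse = " x "),
              paste(format(x$spacing), collapse = " x "),
              prod(x$spacing)))
  invisible(x)
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers over RNifti. `read_volume_grid` takes voxel spacing from the
#' header `pixdim`; `write_volume_grid` stores the grid (or a bolus mask,
#' see [write_bolus_mask()]) with its spacing.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return A [volume_grid()].
#' @export
read_volume_grid <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  volume_grid(array(as.numeric(img), dim = dim(img)[1:3]), spacing = sp)
}

#' @rdname read_volume_grid
#' @param grid a [volume_grid()].
#' @export
write_volume_grid <- function(grid, path) {
  stopifnot(inherits(grid, "volume_grid"))
  img <- RNifti::asNifti(grid$values)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Save an extracted bolus mask as NIfTI
#'
#' @param extraction a `bolus_extraction` from [extract_bolus_volume()].
#' @param grid the source [volume_grid()] (for spacing).
#' @param path output `.nii`/`.nii.gz` path.
#' @export
write_bolus_mask <- function(extraction, grid, path) {
  stopifnot(inherits(extraction, "bolus_extraction"))
  write_volume_grid(volume_grid(array(as.numeric(extraction$mask),
                                      dim(extraction$mask)),
                                spacing = grid$spacing), path)
}

# shift a 3-D logical array by integer offsets, zero-padding the borders
shift3 <- function(a, d) {
  dm <- dim(a)
  out <- array(FALSE, dm)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    if (d[k] >= 0) {
      src[[k]] <- seq_len(dm[k] - d[k]); dst[[k]] <- seq_len(dm[k] - d[k]) + d[k]
    } else {
      src[[k]] <- seq_len(dm[k] + d[k]) - d[k]; dst[[k]] <- seq_len(dm[k] + d[k])
    }
    if (length(src[[k]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Extract a contrast bolus volume from a scan
#'
#' Operationalizes the shrink-wrap ROI: within a spherical region of interest
#' centred on the infusion site, voxels at or above the threshold that are
#' 26-connected to the centre voxel form the bolus; its volume is the voxel
#' count times the voxel volume (mm^3 = uL). The threshold is chosen below
#' the bolus intensity but above the surrounding tissue; [auto_threshold()]
#' offers a starting point but manual adjustment per scan is the primary
#' interface.
#'
#' @param grid a [volume_grid()].
#' @param center voxel coordinate `(x, y, z)` (1-based indices) inside the
#'   bolus.
#' @param radius_mm ROI sphere radius in mm (> 0).
#' @param threshold intensity cutoff; the centre voxel must be at or above
#'   it.
#' @return List of class `bolus_extraction`: `mask` (logical array, same
#'   dimensions as the grid), `volume_ul`, `n_voxels`, `threshold_used`.
#' @export
extract_bolus_volume <- function(grid, center, radius_mm, threshold) {
  stopifnot(inherits(grid, "volume_grid"))
  dm <- dim(grid$values); sp <- grid$spacing
  center <- as.integer(round(center))
  if (length(center) != 3L || any(center < 1L) || any(center > dm))
    stop("ROI centre must be a voxel coordinate inside the grid")
  if (!is.finite(radius_mm) || radius_mm <= 0)
    stop("ROI radius must be positive (mm)")
  if (grid$values[center[1], center[2], center[3]] < threshold)
    stop("seed outside bolus: centre voxel intensity is below the threshold")

  # crop to the sphere's bounding box; all work happens in the crop
  lo <- pmax(1L, center - ceiling(radius_mm / sp))
  hi <- pmin(dm, center + ceiling(radius_mm / sp))
  vals <- grid$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  cd <- dim(vals)
  ax <- (seq_len(cd[1]) + lo[1] - 1L - center[1]) * sp[1]
  ay <- (seq_len(cd[2]) + lo[2] - 1L - center[2]) * sp[2]
  az <- (seq_len(cd[3]) + lo[3] - 1L - center[3]) * sp[3]
  r2 <- outer(outer(ax^2, ay^2, `+`), az^2, `+`)
  cand <- (r2 <= radius_mm^2) & (vals >= threshold)

  seed <- center - lo + 1L
  visited <- array(FALSE, cd)
  visited[seed[1], seed[2], seed[3]] <- TRUE
  frontier <- visited
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]   # 26 neighbours
  while (any(frontier)) {
    grown <- array(FALSE, cd)
    for (k in seq_len(nrow(offs))) grown <- grown | shift3(frontier, offs[k, ])
    frontier <- grown & cand & !visited
    visited <- visited | frontier
  }

  mask <- array(FALSE, dm)
  mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- visited
  structure(list(mask = mask, n_voxels = sum(visited),
                 volume_ul = sum(visited) * prod(sp),
                 threshold_used = threshold),
            class = "bolus_extraction")
}

#' @export
print.bolus_extraction <- function(x, ...) {
  cat(sprintf("bolus extraction: %d voxels, %.2f uL (threshold %g)\n",
              x$n_voxels, x$volume_ul, x$threshold_used))
  invisible(x)
}

#' Suggest an extraction threshold
#'
#' Midpoint between the mean intensity of a small core region around the ROI
#' centre (radius `radius_mm / 4`) and the mean intensity outside the ROI
#' sphere (the tissue background). A starting point for the per-scan manual
#' adjustment that the shrink-wrap procedure calls for.
#'
#' @inheritParams extract_bolus_volume
#' @return Numeric threshold.
#' @export
auto_threshold <- function(grid, center, radius_mm) {
  stopifnot(inherits(grid, "volume_grid"))
  dm <- dim(grid$values); sp <- grid$spacing
  ax <- (seq_len(dm[1]) - center[1]) * sp[1]
  ay <- (seq_len(dm[2]) - center[2]) * sp[2]
  az <- (seq_len(dm[3]) - center[3]) * sp[3]
  r2 <- outer(outer(ax^2, ay^2, `+`), az^2, `+`)
  core <- mean(grid$values[r2 <= (radius_mm / 4)^2])
  bg <- mean(grid$values[r2 > radius_mm^2])
  (core + bg) / 2
}

#' Assemble successive scan extractions into a trajectory
#'
#' Pairs each scan's extracted bolus volume with the volume infused by that
#' point, preserving scan order, to map the infusion trajectory of one in
#' vivo trial.
#'
#' @param extractions list of `bolus_extraction` objects (or bare volumes in
#'   uL), in scan order.
#' @param infused_uL cumulative infused volume at each scan, non-decreasing.
#' @param trial_id trial label.
#' @param region `"cortical"`, `"thalamic"` or `"mtl"`.
#' @param time_min optional scan times (minutes); `NA` for next-day scans.
#' @return An NHP-group [trajectory()].
#' @export
scans_to_trajectory <- function(extractions, infused_uL, trial_id,
                                region = "cortical", time_min = NULL) {
  vols <- vapply(extractions, function(e)
    if (inherits(e, "bolus_extraction")) e$volume_ul else as.numeric(e),
    numeric(1))
  n <- length(vols)
  stopifnot(length(infused_uL) == n)
  if (n > 0 && is.unsorted(infused_uL))
    stop("infused volumes must be non-decreasing across successive scans")
  if (is.null(time_min)) time_min <- rep(NA_real_, n)
  trajectory(trial_id = trial_id, group = "nhp", region = region,
             time_min = time_min, infused_uL = infused_uL,
             measured_uL = vols)
}
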