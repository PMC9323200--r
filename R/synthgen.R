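# evaluate expr under a temporary RNG state so generators are reproducible
# without disturbing the caller's random stream
with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Ground truth for a synthetic phantom photograph
#'
#' Describes the scene of a bench-side infusion photograph — a dye bolus of
#' known height/width below a vertical cannula, on an agar block against a
#' white backdrop with a ruler — so that rendered frames carry exact ground
#' truth for every downstream measurement. The true volume always satisfies
#' the ellipsoid identity `v = (pi/6) h w^2`.
#'
#' @param h_mm,w_mm true bolus extents along/perpendicular to the cannula
#'   axis (mm).
#' @param scale pixels per mm.
#' @param tip `(row, col)` pixel of the cannula tip; the bolus hangs below
#'   it.
#' @param width_px,height_px frame size.
#' @param dye_color,agar_color,backdrop_color,cannula_color 8-bit RGB
#'   triples. The default dye is yellow: it suppresses the blue channel most
#'   strongly, and green in proportion to concentration, so blue (cortical)
#'   or green (thalamic/MTL) components carry the contrast.
#' @param noise_sd per-channel Gaussian noise SD (intensity units).
#' @param seed RNG seed for the noise.
#' @return List of class `photo_truth`, including the true volume `v_ul`.
#' @export
photo_truth <- function(h_mm, w_mm, scale = 6, tip = c(24, 70),
                        width_px = 140, height_px = 180,
                        dye_color = c(235, 180, 25),
                        agar_color = c(240, 243, 245),
                        backdrop_color = c(250, 250, 250),
                        cannula_color = c(60, 60, 60),
                        noise_sd = 0, seed = NULL) {
  stopifnot(h_mm >= 0, w_mm >= 0, scale > 0, noise_sd >= 0)
  structure(list(h_mm = h_mm, w_mm = w_mm, v_ul = ellipsoid_volume(h_mm, w_mm),
                 scale = scale, tip = as.integer(tip),
                 width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 dye_color = dye_color, agar_color = agar_color,
                 backdrop_color = backdrop_color, cannula_color = cannula_color,
                 noise_sd = noise_sd, seed = seed),
            class = "photo_truth")
}

#' Render a synthetic phantom photograph
#'
#' Deterministic given the truth's seed. The scene: backdrop, agar block,
#' 1 mm-spaced ruler ticks along the left edge, a vertical cannula line
#' ending at `tip`, and the dye ellipse centred below the tip with a mild
#' radial concentration falloff (`alpha = 1 - 0.3 r^4`, so the rim is still
#' strongly dyed and thresholding recovers the full extent).
#'
#' @param truth a [photo_truth()].
#' @return `H x W x 3` integer array.
#' @export
make_photo_frame <- function(truth) {
  stopifnot(inherits(truth, "photo_truth"))
  H <- truth$height_px; W <- truth$width_px; sc <- truth$scale
  tip <- truth$tip
  a <- truth$h_mm * sc / 2; b <- truth$w_mm * sc / 2
  cr <- tip[1] + a; cc <- tip[2]
  if (truth$h_mm > 0 && (cr + a > H || cc - b < 1 || cc + b > W || tip[1] < 1))
    stop("bolus extends outside the frame")

  img <- array(0L, c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- truth$backdrop_color[ch]
  # agar block: top surface 2 mm above the tip, centred horizontally
  agar_top <- max(1L, tip[1] - as.integer(round(2 * sc)))
  acol <- round(c(0.12, 0.88) * W)
  for (ch in 1:3) img[agar_top:H, acol[1]:acol[2], ch] <- truth$agar_color[ch]
  # ruler ticks at 1 mm spacing (visual realism only; scale is an input)
  for (r in seq(4L, H - 3L, by = max(1L, as.integer(round(sc)))))
    img[r, 2:5, ] <- 40L
  # cannula: vertical line from frame top to the tip
  img[seq_len(tip[1]), tip[2], ] <-
    matrix(truth$cannula_color, tip[1], 3, byrow = TRUE)
  # dye ellipse with radial alpha falloff
  if (truth$h_mm > 0 && truth$w_mm > 0 && a >= 0.5 && b >= 0.5) {
    rows <- max(1L, floor(cr - a)):min(H, ceiling(cr + a))
    cols <- max(1L, floor(cc - b)):min(W, ceiling(cc + b))
    rr <- outer(((rows - cr) / a)^2, ((cols - cc) / b)^2, `+`)
    inside <- rr <= 1
    alpha <- (1 - 0.3 * rr^2) * inside
    for (ch in 1:3) {
      patch <- img[rows, cols, ch]
      img[rows, cols, ch] <- as.integer(round((1 - alpha) * patch +
                                                alpha * truth$dye_color[ch]))
    }
  }
  if (truth$noise_sd > 0) {
    img <- with_seed(truth$seed, {
      n <- array(stats::rnorm(length(img), 0, truth$noise_sd), dim(img))
      array(as.integer(pmin(255, pmax(0, round(img + n)))), dim(img))
    })
  }
  attr(img, "truth") <- truth
  img
}

#' Segmentation parameters matched to the synthetic scene
#'
#' Convenience constructor for segmenting frames from [make_photo_frame()]:
#' blue component (the yellow dye's strongest contrast), a threshold midway
#' between the dyed rim and the agar background, and cannula erasure just
#' above the tip.
#'
#' @param truth a [photo_truth()].
#' @param threshold 8-bit threshold; the default 150 separates the dye rim
#'   (blue around 90 at the default colours) from agar (blue around 245).
#' @param component colour channel.
#' @return A [seg_params()].
#' @export
synthetic_seg_params <- function(truth, threshold = 150, component = "blue") {
  seg_params(component = component, threshold = threshold,
             scale = truth$scale, direction = "below",
             cut_row = truth$tip[1] - 1L)
}

#' Render a time-lapse synthetic infusion series
#'
#' During infusion the true bolus volume tracks the protocol:
#' `v(t) = slope_true * Vi(t)`. After infusion end, if `diffusion_tau` is
#' set, the bolus keeps growing as `v_end * (2 - exp(-t'/tau))`, a saturating
#' curve (asymptote `2 v_end`) standing in for continued diffusion of dye in
#' agar; it is not a physical diffusion solver. Bolus shape keeps a fixed
#' aspect ratio `h = 2 w`.
#'
#' @param protocol an [infusion_protocol()].
#' @param slope_true true Vd/Vi slope (uL/uL).
#' @param frame_interval minutes between frames.
#' @param diffusion_tau post-infusion growth time constant (min), or `NULL`
#'   for no post-infusion frames.
#' @param post_minutes how long to keep shooting after infusion end (min);
#'   only used when `diffusion_tau` is set.
#' @param truth a [photo_truth()] template supplying scene geometry, colours
#'   and noise (its `h_mm`/`w_mm` are ignored).
#' @return List of frames, each an image with attributes `capture_time` and
#'   `truth` (including the per-frame `v_ul` ground truth).
#' @export
make_photo_series <- function(protocol, slope_true = 3, frame_interval = 1,
                              diffusion_tau = NULL, post_minutes = 0,
                              truth = photo_truth(0, 0)) {
  stopifnot(inherits(protocol, "infusion_protocol"),
            slope_true > 0, frame_interval > 0)
  tot <- protocol_totals(protocol)
  t_end <- tot[["time_min"]]
  t_max <- t_end + if (is.null(diffusion_tau)) 0 else post_minutes
  times <- seq(frame_interval, t_max, by = frame_interval)
  if (!t_end %in% times && t_end <= t_max) times <- sort(c(times, t_end))
  v_end <- slope_true * tot[["volume_ul"]]
  lapply(seq_along(times), function(i) {
    t <- times[i]
    v <- if (t <= t_end) slope_true * cumulative_volume(protocol, t)
         else min(2 * v_end, v_end * (2 - exp(-(t - t_end) / diffusion_tau)))
    w <- (3 * v / pi)^(1 / 3)      # from v = (pi/6) h w^2 with h = 2 w
    ft <- truth
    ft$h_mm <- 2 * w; ft$w_mm <- w; ft$v_ul <- ellipsoid_volume(2 * w, w)
    if (!is.null(ft$seed)) ft$seed <- ft$seed + i
    frame <- make_photo_frame(ft)
    attr(frame, "capture_time") <- t
    frame
  })
}

#' Ground truth for a synthetic contrast-enhanced scan
#'
#' An ellipsoidal bolus of elevated intensity over a uniform tissue
#' background; the analytic volume is `(4/3) pi a b c`.
#'
#' @param semi_axes_mm ellipsoid semi-axes (mm).
#' @param center_mm bolus centre in physical coordinates (mm).
#' @param spacing voxel size per axis (mm).
#' @param dim grid dimensions (voxels).
#' @param bolus_intensity,background_intensity scan intensities.
#' @param noise_sd Gaussian intensity noise SD.
#' @param seed RNG seed for the noise.
#' @return List of class `mri_truth`, including `v_ul` (analytic volume) and
#'   `center_voxel` (the voxel containing the centre).
#' @export
mri_truth <- function(semi_axes_mm = c(4, 4, 6), center_mm = NULL,
                      spacing = c(0.5, 0.5, 0.5), dim = c(64, 64, 64),
                      bolus_intensity = 200, background_intensity = 100,
                      noise_sd = 0, seed = NULL) {
  stopifnot(all(semi_axes_mm >= 0), all(spacing > 0), all(dim >= 1),
            noise_sd >= 0)
  extent <- dim * spacing
  if (is.null(center_mm)) center_mm <- extent / 2
  structure(list(semi_axes_mm = semi_axes_mm, center_mm = center_mm,
                 spacing = spacing, dim = as.integer(dim),
                 bolus_intensity = bolus_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, seed = seed,
                 v_ul = 4 / 3 * pi * prod(semi_axes_mm),
                 center_voxel = pmax(1L, as.integer(ceiling(center_mm / spacing)))),
            class = "mri_truth")
}

#' Render a synthetic contrast-enhanced scan
#'
#' Voxels whose centres fall inside the truth ellipsoid take the bolus
#' intensity, all others the background intensity, plus optional Gaussian
#' noise. Deterministic given the truth's seed.
#'
#' @param truth an [mri_truth()].
#' @return A [volume_grid()].
#' @export
make_mri_volume <- function(truth) {
  stopifnot(inherits(truth, "mri_truth"))
  sp <- truth$spacing; dm <- truth$dim
  ctr <- truth$center_mm; ax <- truth$semi_axes_mm
  if (any(ax > 0) &&
      (any(ctr - ax < 0) || any(ctr + ax > dm * sp)))
    stop("ellipsoid extends outside the grid")
  vals <- array(truth$background_intensity, dm)
  if (all(ax > 0)) {
    gx <- ((seq_len(dm[1]) - 0.5) * sp[1] - ctr[1]) / ax[1]
    gy <- ((seq_len(dm[2]) - 0.5) * sp[2] - ctr[2]) / ax[2]
    gz <- ((seq_len(dm[3]) - 0.5) * sp[3] - ctr[3]) / ax[3]
    inside <- outer(outer(gx^2, gy^2, `+`), gz^2, `+`) <= 1
    vals[inside] <- truth$bolus_intensity
  }
  if (truth$noise_sd > 0)
    vals <- with_seed(truth$seed,
                      vals + array(stats::rnorm(length(vals), 0, truth$noise_sd),
                                   dm))
  g <- volume_grid(vals, spacing = sp)
  attr(g, "truth") <- truth
  g
}

#' Simulate infusion trajectory sets with known group slopes
#'
#' Statistical ground truth for the mixed-model machinery: each trial draws
#' its Vd/Vi slope from a normal distribution around its group mean, then
#' measured volumes follow `slope * infused + noise` over an evenly spaced
#' infused-volume grid (negative draws are clamped at zero). Defaults mirror
#' the bench-study design scale: 10 trials per group over a 50 uL infusion
#' with ~0.3 uL/uL between-trial slope spread and ~2 uL measurement noise.
#'
#' @param n_per_group trials in the (agar, nhp) groups.
#' @param group_slopes true mean Vd/Vi slopes (agar, nhp).
#' @param slope_sd between-trial slope SD (uL/uL).
#' @param noise_sd measurement noise SD (uL).
#' @param n_points points per trial.
#' @param max_infused final infused volume (uL).
#' @param region region label.
#' @param seed RNG seed; fixed seed gives bit-identical output.
#' @return List with elements `agar` and `nhp` (lists of [trajectory()]
#'   objects) and `true_slopes` (per-trial drawn slopes).
#' @export
make_trajectories <- function(n_per_group = c(10, 10), group_slopes = c(3, 4),
                              slope_sd = 0.3, noise_sd = 2, n_points = 20,
                              max_infused = 50, region = "cortical",
                              seed = NULL) {
  stopifnot(length(n_per_group) == 2L, all(n_per_group >= 1L),
            slope_sd >= 0, noise_sd >= 0, n_points >= 1L, max_infused > 0)
  with_seed(seed, {
    infused <- seq(max_infused / n_points, max_infused, length.out = n_points)
    gen_group <- function(n, mu, group) {
      slopes <- stats::rnorm(n, mu, slope_sd)
      trials <- lapply(seq_len(n), function(i) {
        measured <- pmax(0, slopes[i] * infused +
                           stats::rnorm(n_points, 0, noise_sd))
        trajectory(sprintf("%s-%02d", group, i), group, region,
                   time_min = seq_len(n_points), infused_uL = infused,
                   measured_uL = measured)
      })
      list(trials = trials, slopes = slopes)
    }
    ag <- gen_group(n_per_group[1], group_slopes[1], "agar")
    nh <- gen_group(n_per_group[2], group_slopes[2], "nhp")
    list(agar = ag$trials, nhp = nh$trials,
         true_slopes = c(setNames(ag$slopes, paste0("agar-", seq_len(n_per_group[1]))),
                         setNames(nh$slopes, paste0("nhp-", seq_len(n_per_group[2])))))
  })
}
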