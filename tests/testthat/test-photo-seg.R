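rgb_image <- function(r, g, b) {
  img <- array(0L, c(dim(r), 3))
  img[, , 1] <- r; img[, , 2] <- g; img[, , 3] <- b
  img
}

test_that("component extraction returns the raw channel untouched", {
  img <- rgb_image(matrix(255L, 2, 2), matrix(255L, 2, 2), matrix(0L, 2, 2))
  expect_equal(unname(extract_component(img, "blue")[1, 1]), 0L)  # pure yellow
  img2 <- rgb_image(matrix(10L, 1, 1), matrix(110L, 1, 1), matrix(210L, 1, 1))
  expect_equal(unname(extract_component(img2, "green")[1, 1]), 110L)
  expect_equal(unname(extract_component(img2, "red")[1, 1]), 10L)
  expect_error(extract_component(img2, "luma"))
  # identity with the generator's stored channel
  fr <- make_photo_frame(default_scene(6, 3))
  expect_identical(matrix(extract_component(fr, "green"),
                          nrow(fr), ncol(fr)),
                   fr[, , 2])
})

test_that("thresholding marks strict inequalities and excludes ties", {
  plane <- matrix(255L, 4, 4)
  expect_false(any(threshold_mask(plane, 67, "below")))
  plane[2, 3] <- 50L
  m <- threshold_mask(plane, 67, "below")
  expect_equal(which(m), which(plane == 50L))
  tie <- matrix(c(66L, 67L, 68L), 1, 3)
  expect_equal(as.vector(threshold_mask(tie, 67, "below")),
               c(TRUE, FALSE, FALSE))
  expect_equal(as.vector(threshold_mask(tie, 67, "above")),
               c(FALSE, FALSE, TRUE))
  expect_error(threshold_mask(plane, 300, "below"), "\\[0, 255\\]")
})

test_that("threshold mask matches an exhaustive per-pixel oracle and is monotone", {
  fr <- make_photo_frame(default_scene(8, 4))
  plane <- extract_component(fr, "blue")
  for (thr in c(40, 100, 150, 200)) {
    m <- threshold_mask(plane, thr, "below")
    brute <- 0L
    for (i in seq_len(nrow(plane)))
      for (j in seq_len(ncol(plane)))
        if (plane[i, j] < thr) brute <- brute + 1L
    expect_equal(sum(m), brute)
  }
  sizes <- vapply(c(40, 100, 150, 200, 255),
                  function(thr) sum(threshold_mask(plane, thr, "below")),
                  numeric(1))
  expect_true(all(diff(sizes) >= 0))  # raising threshold never shrinks mask
})

test_that("cluster selection keeps one 8-connected component", {
  m <- matrix(FALSE, 10, 10); m[3:5, 3:5] <- TRUE
  expect_equal(which(select_bolus_cluster(m)), which(m))  # idempotent
  # largest-cluster rule
  m2 <- matrix(FALSE, 20, 20)
  m2[1:10, 1:10] <- TRUE              # 100 px
  m2[15:19, 15] <- TRUE               # 5 px
  sel <- select_bolus_cluster(m2)
  expect_equal(sum(sel), 100L)
  expect_true(all(which(sel) %in% which(m2)))
  # seed precedence between equal components
  m3 <- matrix(FALSE, 10, 10)
  m3[1:2, 1:2] <- TRUE; m3[8:9, 8:9] <- TRUE
  sel3 <- select_bolus_cluster(m3, seed = c(8, 8))
  expect_true(sel3[8, 8] && !sel3[1, 1])
  # diagonal touching counts as connected (8-connectivity)
  m4 <- matrix(FALSE, 5, 5)
  m4[1, 1] <- m4[2, 2] <- m4[3, 3] <- TRUE
  expect_equal(sum(select_bolus_cluster(m4)), 3L)
  expect_error(select_bolus_cluster(matrix(FALSE, 3, 3)), "empty")
  expect_error(select_bolus_cluster(m3, seed = c(5, 5)), "not marked")
})

test_that("cannula erasure clears only rows above the boundary", {
  m <- matrix(FALSE, 100, 10); m[, 4] <- TRUE  # vertical line rows 1..100
  expect_equal(sum(erase_cannula(m, 0)), 100L)
  cut <- erase_cannula(m, 50)
  expect_equal(sum(cut), 50L)
  expect_true(all(which(cut, arr.ind = TRUE)[, 1] > 50))
  expect_equal(sum(erase_cannula(m, 100)), 0L)
  expect_error(erase_cannula(m, 101), "\\[0, 100\\]")
})

test_that("ellipsoidal volumetry follows v = (pi/6) h w^2", {
  expect_equal(ellipsoid_volume(6, 2), 4 * pi)
  # algebraic identity with (4/3) pi a b^2 over a grid
  for (h in c(0.5, 2, 7.3)) for (w in c(0.1, 1, 4.8))
    expect_equal(ellipsoid_volume(h, w), 4 / 3 * pi * (h / 2) * (w / 2)^2)
  # filled ellipse 100 px tall x 50 px wide at 10 px/mm
  r <- matrix(1:100, 100, 50); c <- matrix(1:50, 100, 50, byrow = TRUE)
  m <- ((r - 50.5) / 50)^2 + ((c - 25.5) / 25)^2 <= 1
  mb <- measure_bolus(m, scale = 10)
  expect_equal(mb$h_mm, 10)
  expect_equal(mb$w_mm, 5)
  expect_equal(mb$v_ul, pi / 6 * 10 * 25, tolerance = 1e-10)
  # empty mask measures zero
  z <- measure_bolus(matrix(FALSE, 5, 5), scale = 10)
  expect_equal(c(z$h_mm, z$w_mm, z$v_ul), c(0, 0, 0))
  expect_error(measure_bolus(m, scale = 0), "positive")
})

test_that("ellipsoid volume agrees with a lattice-count oracle within 1%", {
  for (hw in list(c(6, 2), c(10, 5), c(4, 4))) {
    v <- ellipsoid_volume(hw[1], hw[2])
    expect_equal(v, lattice_ellipsoid_volume(hw[1], hw[2], res = 40),
                 tolerance = 0.01)
  }
})

test_that("the segmentation pipeline is deterministic", {
  tr <- default_scene(8, 4)
  fr <- make_photo_frame(tr)
  p <- synthetic_seg_params(tr)
  run <- function() {
    m <- threshold_mask(extract_component(fr, p$component), p$threshold,
                        p$direction)
    m <- erase_cannula(select_bolus_cluster(m), p$cut_row)
    measure_bolus(m, p$scale)
  }
  expect_identical(run()[1:3], run()[1:3])
})

test_that("segment_series pairs measurements with protocol volumes", {
  proto <- protocol_preset("mtl")
  tmpl <- photo_truth(0, 0, scale = 8, tip = c(24, 80), width_px = 160,
                      height_px = 200, noise_sd = 0)
  frames <- make_photo_series(proto, slope_true = 3, frame_interval = 1,
                              truth = tmpl)
  params <- synthetic_seg_params(tmpl)
  traj <- segment_series(frames, params, proto, trial_id = "t1",
                         region = "mtl")
  expect_s3_class(traj, "ced_trajectory")
  expect_equal(traj$infused_uL, cumulative_volume(proto, traj$time_min))
  # noiseless series: measured volume non-decreasing
  v <- traj$measured_uL[!is.na(traj$measured_uL)]
  expect_true(all(diff(v) >= -1e-9))
  # slope recovery
  expect_equal(slope_through_origin(traj), 3, tolerance = 0.05)
})

test_that("blank frames are recorded as missing, lone final frame works", {
  proto <- protocol_preset("mtl")
  blank <- array(255L, c(40, 40, 3))
  attr(blank, "capture_time") <- 1
  blank2 <- blank; attr(blank2, "capture_time") <- 2
  params <- seg_params("blue", 67, scale = 5)
  traj <- segment_series(list(blank, blank2), params, proto)
  expect_true(all(is.na(traj$measured_uL)))
  # single frame at t = total time pairs with the protocol total
  tmpl <- default_scene(8, 4)
  fr <- make_photo_frame(tmpl); attr(fr, "capture_time") <- 7
  tr1 <- segment_series(list(fr), synthetic_seg_params(tmpl), proto)
  expect_equal(tr1$infused_uL, 15)
  expect_equal(nrow(tr1), 1L)
})
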