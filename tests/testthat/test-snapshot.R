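band_seg <- function(shape = c(32, 32, 32), lo = 10, hi = 40) {
  arr <- array(0L, shape)
  arr[, , lo:min(hi, shape[3])] <- 1L
  arr
}

test_that("slice selection stays inside the segmentation support", {
  seg <- array(0L, c(8, 8, 50))
  seg[4:5, 4:5, 10:40] <- 1L
  idx <- select_slices(seg, "axial", 4)
  expect_length(idx, 4)
  expect_true(all(idx >= 10 & idx <= 40))
  expect_equal(select_slices(seg, "axial", 1), 25)  # support midpoint
  expect_equal(select_slices(seg, "axial", 2), c(10, 40))
  # min_voxels filters thin slices
  seg[4, 4, 41] <- 1L
  idx2 <- select_slices(seg, "axial", 10, min_voxels = 2)
  expect_false(41 %in% idx2)
  expect_error(select_slices(array(0L, c(4, 4, 4)), "axial", 3),
               "empty segmentation")
})

test_that("zero opacity reproduces the background exactly", {
  seg <- make_labelmap(c(24, 24, 24), c("1" = 300, "2" = 200), seed = 3)
  bg <- make_phantom(c(24, 24, 24), seed = 4)
  at0 <- render_grid(bg, seg, snapshot_spec(opacity = 0))
  # same spec but no label rendered at all: pure background grid
  bg_only <- render_grid(bg, seg, snapshot_spec(opacity = 0.8, labels = -1))
  expect_identical(at0, bg_only)
})

test_that("label masking hides deselected labels and only them", {
  seg <- make_labelmap(c(24, 24, 24), c("1" = 300, "2" = 200), seed = 3)
  bg <- make_phantom(c(24, 24, 24), seed = 4)
  spec1 <- snapshot_spec(planes = "axial", n_slices = 1, margin = 0,
                         opacity = 0.7, labels = 1)
  only1 <- render_grid(bg, seg, spec1)
  bg_only <- render_grid(bg, seg, snapshot_spec(planes = "axial",
                                                n_slices = 1, margin = 0,
                                                opacity = 0.7, labels = -1))
  idx <- select_slices(seg, "axial", 1)
  slice <- neuroqc:::extract_slice(seg, 3L, idx)
  touched <- apply(only1 != bg_only, c(1, 2), any)
  expect_true(all(slice[touched] == 1))   # only label-1 voxels recolored
  expect_true(any(slice == 1))            # and some actually were
  expect_false(any(touched[slice == 2]))  # label 2 invisible
})

test_that("contour rendering matches the neighbor-difference oracle", {
  boundary_oracle <- function(sl) {
    out <- matrix(FALSE, nrow(sl), ncol(sl))
    for (i in seq_len(nrow(sl))) {
      for (j in seq_len(ncol(sl))) {
        if (sl[i, j] == 0) next
        nb <- c(
          if (i > 1) sl[i - 1, j] else -1,
          if (i < nrow(sl)) sl[i + 1, j] else -1,
          if (j > 1) sl[i, j - 1] else -1,
          if (j < ncol(sl)) sl[i, j + 1] else -1)
        out[i, j] <- any(nb != sl[i, j])
      }
    }
    out
  }
  set.seed(55)
  for (rep in 1:20) {
    sl <- matrix(sample(0:3, 32 * 32, replace = TRUE,
                        prob = c(0.7, 0.1, 0.1, 0.1)), 32, 32)
    expect_identical(neuroqc:::label_boundary(sl), boundary_oracle(sl))
  }
  # a filled disk renders as a ring with the interior untouched
  disk <- matrix(0L, 32, 32)
  for (i in 1:32) for (j in 1:32) {
    if ((i - 16)^2 + (j - 16)^2 <= 64) disk[i, j] <- 1L
  }
  b <- neuroqc:::label_boundary(disk)
  expect_false(b[16, 16])
  expect_true(sum(b) > 0 && sum(b) < sum(disk == 1))
})

test_that("renders are byte-deterministic and grid mismatches error out", {
  seg <- make_labelmap(c(20, 20, 20), c("1" = 150), seed = 9)
  bg <- make_phantom(c(20, 20, 20), seed = 10)
  dir <- withr::local_tempdir()
  segf <- file.path(dir, "seg.nii.gz")
  bgf <- file.path(dir, "bg.nii.gz")
  RNifti::writeNifti(seg, segf)
  RNifti::writeNifti(bg, bgf)
  p1 <- file.path(dir, "a.png")
  p2 <- file.path(dir, "b.png")
  plot_segment(segf, bg = bgf, out_path = p1)
  plot_segment(segf, bg = bgf, out_path = p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))

  small <- file.path(dir, "small.nii.gz")
  RNifti::writeNifti(make_phantom(c(10, 10, 10), seed = 1), small)
  expect_error(plot_segment(segf, bg = small, out_path = p1),
               "voxel grids differ")
})

test_that("animation ramps opacity symmetrically and writes a multi-frame GIF", {
  seg <- make_labelmap(c(20, 20, 20), c("1" = 150), seed = 9)
  bg <- make_phantom(c(20, 20, 20), seed = 10)
  spec <- snapshot_spec(animated = TRUE, n_frames = 7, opacity = 0.6,
                        planes = "axial", n_slices = 2)
  frames <- animate(bg, seg, spec)
  expect_length(frames, 7)
  base <- snapshot_spec(planes = "axial", n_slices = 2)
  expect_identical(frames[[1]],
                   render_grid(bg, seg, modifyList(base, list(opacity = 0))))
  expect_identical(frames[[4]],
                   render_grid(bg, seg, modifyList(base, list(opacity = 0.6))))
  expect_identical(frames[[1]], frames[[7]])

  dir <- withr::local_tempdir()
  segf <- file.path(dir, "seg.nii.gz")
  RNifti::writeNifti(seg, segf)
  gif <- file.path(dir, "anim.gif")
  plot_segment(segf, out_path = gif, spec = spec)
  expect_gt(file.size(gif), 0)
  expect_equal(neuroqc:::gif_frame_count(gif), 7)
})
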