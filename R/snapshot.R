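PLANE_AXES <- c(sagittal = 1L, coronal = 2L, axial = 3L)

# Fixed categorical palette keyed by sorted label value: stable colors
# across sessions. Recycled beyond 12 labels.
DEFAULT_PALETTE <- rbind(
  c(0.894, 0.102, 0.110), c(0.216, 0.494, 0.722), c(0.302, 0.686, 0.290),
  c(0.596, 0.306, 0.639), c(1.000, 0.498, 0.000), c(1.000, 1.000, 0.200),
  c(0.651, 0.337, 0.157), c(0.969, 0.506, 0.749), c(0.600, 0.600, 0.600),
  c(0.090, 0.745, 0.812), c(0.737, 0.741, 0.133), c(0.122, 0.467, 0.706))

#' Rendering options for segmentation snapshots
#'
#' @param planes Subset of `c("sagittal", "coronal", "axial")` (voxel axes
#'   1, 2, 3 of RAS-oriented data).
#' @param n_slices Slices rendered per plane (>= 1).
#' @param opacity Overlay opacity in `[0, 1]`; at 0 the output equals the
#'   background-only rendering.
#' @param contours Render one-pixel label boundary traces instead of solid
#'   fill.
#' @param animated Produce a looping GIF with a fading overlay instead of
#'   a static PNG.
#' @param labels Optional subset of labels to render; others are omitted.
#' @param colormap Optional named list mapping label value to an RGB
#'   triplet in `[0, 1]`; unknown labels get auto-assigned palette colors
#'   (with a warning when an explicit colormap was given).
#' @param rowsize Slices per row in the grid.
#' @param margin Margin between tiles, in pixels.
#' @param n_frames Frame count of the animated rendering.
#' @param min_voxels Minimum nonzero voxels for a slice to be selected.
#' @return A list of class `snapshot_spec`.
#' @export
snapshot_spec <- function(planes = c("sagittal", "coronal", "axial"),
                          n_slices = 9, opacity = 0.5, contours = FALSE,
                          animated = FALSE, labels = NULL, colormap = NULL,
                          rowsize = 3, margin = 2, n_frames = 15,
                          min_voxels = 1) {
  planes <- match.arg(planes, several.ok = TRUE)
  stopifnot(n_slices >= 1, opacity >= 0, opacity <= 1, rowsize >= 1,
            margin >= 0, n_frames >= 2)
  structure(list(planes = planes, n_slices = as.integer(n_slices),
                 opacity = opacity, contours = isTRUE(contours),
                 animated = isTRUE(animated), labels = labels,
                 colormap = colormap, rowsize = as.integer(rowsize),
                 margin = as.integer(margin), n_frames = as.integer(n_frames),
                 min_voxels = min_voxels),
            class = "snapshot_spec")
}

#' Select representative slices through a segmentation
#'
#' Returns up to `n` evenly spaced slice indices within the bounding range
#' of the nonzero segmentation along the plane's axis; a candidate falling
#' on a slice with fewer than `min_voxels` nonzero voxels is snapped to
#' the nearest adequately filled slice (fewer than `n` indices are
#' returned when the support is narrow). `n = 1` returns the support
#' midpoint. Deterministic.
#'
#' @param seg Label map (array or `niftiImage`).
#' @param plane `"sagittal"`, `"coronal"` or `"axial"`.
#' @param n Requested number of slices.
#' @param min_voxels Minimum nonzero voxel count per selected slice.
#' @return Integer vector of slice indices (1-based), increasing.
#' @export
select_slices <- function(seg, plane, n, min_voxels = 1) {
  axis <- PLANE_AXES[[match.arg(plane, names(PLANE_AXES))]]
  counts <- apply(unclass(seg) != 0, axis, sum)
  support <- which(counts > 0)
  if (!length(support)) abort("empty segmentation")
  lo <- min(support)
  hi <- max(support)
  idx <- if (n == 1L) round((lo + hi) / 2) else
    unique(round(seq(lo, hi, length.out = n)))
  eligible <- which(counts >= min_voxels)
  if (!length(eligible)) abort("empty segmentation")
  # snap candidates falling on thin/empty slices to the nearest eligible
  # slice (ties toward the lower index)
  sort(unique(vapply(idx, function(i) {
    eligible[which.min(abs(eligible - i))]
  }, integer(1))))
}

extract_slice <- function(vol, axis, index) {
  m <- switch(axis, unclass(vol)[index, , ], unclass(vol)[, index, ],
              unclass(vol)[, , index])
  # display orientation: second voxel axis up
  t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
}

# In-slice 4-neighborhood boundary: voxels with at least one differing
# neighbor (image border counts as differing for nonzero labels).
label_boundary <- function(sl) {
  pad <- function(m, dr, dc) {
    out <- matrix(-1, nrow(m), ncol(m))
    rs <- seq_len(nrow(m)) + dr
    cs <- seq_len(ncol(m)) + dc
    ok_r <- rs >= 1 & rs <= nrow(m)
    ok_c <- cs >= 1 & cs <= ncol(m)
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  diff_any <- (sl != pad(sl, 1, 0)) | (sl != pad(sl, -1, 0)) |
    (sl != pad(sl, 0, 1)) | (sl != pad(sl, 0, -1))
  diff_any & sl != 0
}

label_colors <- function(labels, colormap = NULL) {
  labels <- sort(labels)
  cols <- matrix(0, length(labels), 3,
                 dimnames = list(as.character(labels), NULL))
  auto <- DEFAULT_PALETTE[(seq_along(labels) - 1L) %% nrow(DEFAULT_PALETTE) + 1L, ,
                          drop = FALSE]
  for (i in seq_along(labels)) {
    key <- as.character(labels[i])
    if (!is.null(colormap) && !is.null(colormap[[key]])) {
      cols[i, ] <- unlist(colormap[[key]])
    } else {
      if (!is.null(colormap)) {
        warn(sprintf("label %s has no colormap entry; auto-assigned a color", key))
      }
      cols[i, ] <- auto[i, ]
    }
  }
  cols
}

window_background <- function(bg) {
  v <- as.vector(unclass(bg))
  qs <- stats::quantile(v, c(0.01, 0.99), names = FALSE)
  if (qs[2] <= qs[1]) qs[2] <- qs[1] + 1
  pmin(pmax((unclass(bg) - qs[1]) / (qs[2] - qs[1]), 0), 1)
}

render_slice_rgb <- function(bg_sl, seg_sl, spec, cols, opacity) {
  h <- nrow(seg_sl)
  w <- ncol(seg_sl)
  rgb <- array(0, c(h, w, 3))
  if (!is.null(bg_sl)) for (ch in 1:3) rgb[, , ch] <- bg_sl
  keep <- if (is.null(spec$labels)) rownames(cols) else
    intersect(rownames(cols), as.character(spec$labels))
  mask_src <- if (spec$contours) label_boundary(seg_sl) else seg_sl != 0
  for (key in keep) {
    sel <- mask_src & (seg_sl == as.numeric(key))
    if (!any(sel)) next
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[sel] <- (1 - opacity) * plane[sel] + opacity * cols[key, ch]
      rgb[, , ch] <- plane
    }
  }
  rgb
}

compose_grid <- function(tiles, rowsize, margin) {
  th <- max(vapply(tiles, nrow, 1L))
  tw <- max(vapply(tiles, ncol, 1L))
  nrows <- ceiling(length(tiles) / rowsize)
  H <- nrows * th + (nrows + 1) * margin
  W <- rowsize * tw + (rowsize + 1) * margin
  out <- array(0, c(H, W, 3))
  for (i in seq_along(tiles)) {
    r <- (i - 1) %/% rowsize
    c <- (i - 1) %% rowsize
    r0 <- margin + r * (th + margin)
    c0 <- margin + c * (tw + margin)
    tile <- tiles[[i]]
    out[r0 + seq_len(nrow(tile)), c0 + seq_len(ncol(tile)), ] <- tile
  }
  out
}

render_grid_at_opacity <- function(bg, seg, spec, opacity) {
  seg_labels <- sort(setdiff(unique(as.vector(unclass(seg))), 0))
  if (!length(seg_labels)) abort("empty segmentation")
  cols <- label_colors(seg_labels, spec$colormap)
  bgw <- if (!is.null(bg)) window_background(bg) else NULL
  tiles <- list()
  for (plane in spec$planes) {
    axis <- PLANE_AXES[[plane]]
    for (idx in select_slices(seg, plane, spec$n_slices, spec$min_voxels)) {
      seg_sl <- extract_slice(seg, axis, idx)
      bg_sl <- if (!is.null(bgw)) extract_slice(bgw, axis, idx) else NULL
      tiles[[length(tiles) + 1L]] <-
        render_slice_rgb(bg_sl, seg_sl, spec, cols, opacity)
    }
  }
  compose_grid(tiles, spec$rowsize, spec$margin)
}

check_grids_match <- function(bg, seg) {
  if (!is.null(bg) && !identical(dim(unclass(bg))[1:3], dim(unclass(seg))[1:3])) {
    abort(sprintf(
      "background and segmentation voxel grids differ (%s vs %s); no resampling is performed",
      paste(dim(unclass(bg)), collapse = "x"),
      paste(dim(unclass(seg)), collapse = "x")))
  }
}

#' Render a static snapshot grid of a segmentation overlay
#'
#' Compiles a grid of selected slices per plane, with the label map
#' rendered over the (optional) anatomical background in solid color or
#' one-pixel contours at the configured opacity. The background is
#' windowed to its 1st-99th intensity percentiles in grayscale. Pixels are
#' deterministic for fixed inputs.
#'
#' @param bg Optional background volume (same voxel grid as `seg`; a
#'   mismatch is an error, never an interpolation).
#' @param seg Label map volume.
#' @param spec A [snapshot_spec()].
#' @return A numeric array `height x width x 3` in `[0, 1]`.
#' @export
render_grid <- function(bg, seg, spec = snapshot_spec()) {
  check_grids_match(bg, seg)
  render_grid_at_opacity(bg, seg, spec, spec$opacity)
}

#' Render an animated overlay (opacity-fading frame sequence)
#'
#' Produces a looping frame sequence whose overlay opacity ramps linearly
#' from 0 up to `spec$opacity` and back to 0: the first frame equals the
#' pure background rendering and the middle frame the static render at
#' peak opacity.
#'
#' @inheritParams render_grid
#' @return A list of frames (arrays as in [render_grid()]) of class
#'   `qc_animation`.
#' @export
animate <- function(bg, seg, spec = snapshot_spec(animated = TRUE)) {
  check_grids_match(bg, seg)
  nf <- spec$n_frames
  half <- ceiling((nf + 1) / 2)
  up <- seq(0, spec$opacity, length.out = half)
  ramp <- c(up, rev(up)[-1])[seq_len(nf)]
  frames <- lapply(ramp, function(op) render_grid_at_opacity(bg, seg, spec, op))
  structure(frames, class = "qc_animation", opacities = ramp)
}

load_volume_ras <- function(path) {
  img <- RNifti::readNifti(path)
  # reorient to RAS so that voxel axes 1/2/3 are sagittal/coronal/axial
  tryCatch({ RNifti::orientation(img) <- "RAS"; img },
           error = function(e) img)
}

#' Render a segmentation snapshot to an image file
#'
#' The main entry point: reads NIfTI inputs, reorients them to RAS,
#' renders a static grid or an animated fade, and writes a PNG or GIF at
#' `out_path`. Rendering is fully offscreen, usable from scripts and the
#' command line.
#'
#' @param seg Path to the segmentation label map (NIfTI).
#' @param bg Optional path to the anatomical background (NIfTI, same voxel
#'   grid).
#' @param out_path Output file (`.png`, or `.gif` when
#'   `spec$animated`).
#' @param spec A [snapshot_spec()].
#' @return The output path, invisibly.
#' @export
plot_segment <- function(seg, bg = NULL, out_path, spec = snapshot_spec()) {
  seg_img <- load_volume_ras(seg)
  bg_img <- if (!is.null(bg)) load_volume_ras(bg) else NULL
  if (spec$animated || grepl("\\.gif$", out_path, ignore.case = TRUE)) {
    frames <- animate(bg_img, seg_img, spec)
    write_gif(frames, out_path)
  } else {
    png::writePNG(render_grid(bg_img, seg_img, spec), out_path)
  }
  invisible(out_path)
}
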