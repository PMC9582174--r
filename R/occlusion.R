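#' Occlusion configuration
#'
#' Parameters of the systematic patch-masking procedure used to build an
#' occlusion saliency map: the scorer is re-evaluated after blanking each
#' patch of the volume in turn, and the change in its output is recorded.
#'
#' @param patch per-axis patch size in voxels (length 1 or 3). Default
#'   `c(4, 4, 4)`, the block size used for the 128-cubed screening volumes.
#' @param stride per-axis step between patch origins in voxels (length 1
#'   or 3). Default 4 voxels per block, i.e. non-overlapping patches.
#' @param fill_mode how occluded voxels are filled: `"volume_mean"` (mean
#'   intensity of the whole input volume; a neutral perturbation and the
#'   default), `"constant"` (use `fill_value`) or `"local_mean"` (mean of the
#'   voxels inside the patch itself).
#' @param fill_value fill intensity when `fill_mode = "constant"`.
#' @param sign `"drop"` records `score(original) - score(occluded)`, so
#'   positive saliency marks regions that supported the malignancy score
#'   (red on the overlay); `"signed"` records the raw change
#'   `score(occluded) - score(original)`.
#' @return an object of class `occlusion_config`.
#' @seealso [compute_occlusion_map()]
#' @export
occlusion_config <- function(patch = c(4L, 4L, 4L), stride = c(4L, 4L, 4L),
                             fill_mode = c("volume_mean", "constant", "local_mean"),
                             fill_value = 0,
                             sign = c("drop", "signed")) {
  patch <- as.integer(rep_len(patch, 3L))
  stride <- as.integer(rep_len(stride, 3L))
  if (any(patch < 1L)) stop("patch size must be >= 1 on every axis", call. = FALSE)
  if (any(stride < 1L)) stop("stride must be >= 1 on every axis", call. = FALSE)
  fill_mode <- match.arg(fill_mode)
  sign <- match.arg(sign)
  stopifnot(is.numeric(fill_value), length(fill_value) == 1L, is.finite(fill_value))
  structure(list(patch = patch, stride = stride, fill_mode = fill_mode,
                 fill_value = fill_value, sign = sign),
            class = "occlusion_config")
}

#' @export
print.occlusion_config <- function(x, ...) {
  cat(sprintf("occlusion config: patch %s, stride %s, fill %s%s, sign %s\n",
              paste(x$patch, collapse = "x"), paste(x$stride, collapse = "x"),
              x$fill_mode,
              if (x$fill_mode == "constant") sprintf(" (%g)", x$fill_value) else "",
              x$sign))
  invisible(x)
}

#' Size of the occlusion grid
#'
#' Number of patch positions per axis when a patch of size `patch` is slid
#' with step `stride` over a volume of size `shape`:
#' `floor((shape - patch) / stride) + 1`. Trailing voxels that do not admit a
#' full patch are dropped (no partial windows).
#'
#' @param shape,patch,stride integer vectors (recycled to length 3).
#' @return integer vector of grid cells per axis.
#' @export
occlusion_grid_shape <- function(shape, patch, stride) {
  shape <- as.integer(rep_len(shape, 3L))
  patch <- as.integer(rep_len(patch, 3L))
  stride <- as.integer(rep_len(stride, 3L))
  if (any(patch > shape))
    stop("patch size exceeds the volume shape on axis ",
         which(patch > shape)[1L], call. = FALSE)
  (shape - patch) %/% stride + 1L
}

# linear-index offsets of a patch anchored at the origin
patch_offsets <- function(patch, nx, ny) {
  as.integer(outer(outer(seq_len(patch[1L]) - 1L,
                         (seq_len(patch[2L]) - 1L) * nx, "+"),
                   (seq_len(patch[3L]) - 1L) * nx * ny, "+"))
}

patch_fill <- function(values, cfg, volume_mean) {
  switch(cfg$fill_mode,
         constant = cfg$fill_value,
         volume_mean = volume_mean,
         local_mean = mean(values))
}

#' Occlude one patch of a volume
#'
#' Returns a copy of `volume` with the half-open patch
#' `[origin, origin + patch)` replaced according to the fill mode; the input
#' volume is left untouched.
#'
#' @param volume 3D numeric array.
#' @param origin 0-based per-axis voxel index of the patch corner.
#' @param config an [occlusion_config()].
#' @return the occluded volume.
#' @export
occlude <- function(volume, origin, config = occlusion_config()) {
  validate_volume(volume)
  stopifnot(inherits(config, "occlusion_config"))
  origin <- as.integer(rep_len(origin, 3L))
  shape <- dim(volume)
  if (any(origin < 0L))
    stop("patch origin must be >= 0 on axis ", which(origin < 0L)[1L], call. = FALSE)
  over <- origin + config$patch > shape
  if (any(over))
    stop("patch extends out of bounds on axis ", which(over)[1L], call. = FALSE)
  idx <- (origin[1L] + origin[2L] * shape[1L] + origin[3L] * shape[1L] * shape[2L]) +
    1L + patch_offsets(config$patch, shape[1L], shape[2L])
  out <- volume
  out[idx] <- patch_fill(volume[idx], config, mean(volume))
  out
}

#' Compute an occlusion-based saliency map
#'
#' Slides an occluding patch over `volume` on a regular grid (origin of grid
#' cell `g` is `g * stride`, 0-based) and records, for every position, the
#' change in the scorer's output relative to the intact volume. With the
#' default `sign = "drop"` the stored value is
#' `score(original) - score(occluded)`: positive values mark regions whose
#' removal lowers the malignancy score, i.e. regions that supported it.
#' A 128x128x128 input with a 4x4x4 patch and stride 4 yields a 32x32x32 map.
#'
#' The scorer is called exactly once per grid cell plus once on the intact
#' volume. It must be a deterministic function mapping a 3D array to a single
#' finite score in `[0, 1]`.
#'
#' @param volume 3D numeric array.
#' @param scorer `function(volume) -> numeric(1)`.
#' @param config an [occlusion_config()].
#' @return an object of class `saliency_map`: a list with `values` (3D array
#'   over the occlusion grid), `grid_shape`, `source_shape` and `config`.
#' @export
compute_occlusion_map <- function(volume, scorer, config = occlusion_config()) {
  validate_volume(volume)
  stopifnot(is.function(scorer), inherits(config, "occlusion_config"))
  shape <- dim(volume)
  grid <- occlusion_grid_shape(shape, config$patch, config$stride)
  if (any((shape - config$patch) %% config$stride != 0L))
    message("volume shape minus patch is not a multiple of the stride; ",
            "trailing voxels are not covered by any window")

  base <- scorer(volume)
  if (!is.numeric(base) || length(base) != 1L || !is.finite(base))
    stop("scorer returned a non-finite value for the intact volume", call. = FALSE)

  vol_mean <- mean(volume)
  nx <- shape[1L]; ny <- shape[2L]
  offs <- patch_offsets(config$patch, nx, ny)
  sx <- config$stride[1L]; sy <- config$stride[2L]; sz <- config$stride[3L]

  # mutate/restore a single working copy: the patch is tiny compared with the
  # volume, so this avoids reallocating the full array for every grid cell
  work <- volume + 0
  values <- array(NA_real_, dim = grid)
  flip <- if (config$sign == "drop") 1 else -1
  cell <- 0L
  for (gz in seq_len(grid[3L]) - 1L) {
    oz <- gz * sz * nx * ny
    for (gy in seq_len(grid[2L]) - 1L) {
      oy <- oz + gy * sy * nx
      for (gx in seq_len(grid[1L]) - 1L) {
        idx <- oy + gx * sx + 1L + offs
        old <- work[idx]
        work[idx] <- patch_fill(old, config, vol_mean)
        s <- scorer(work)
        work[idx] <- old
        if (!is.numeric(s) || length(s) != 1L || !is.finite(s))
          stop(sprintf("scorer returned a non-finite value at grid cell (%d, %d, %d)",
                       gx, gy, gz), call. = FALSE)
        cell <- cell + 1L
        values[cell] <- flip * (base - s)
      }
    }
  }
  structure(list(values = values, grid_shape = grid, source_shape = shape,
                 base_score = base, config = config),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("occlusion saliency map: grid %s from source %s (base score %.4f)\n",
              paste(x$grid_shape, collapse = "x"),
              paste(x$source_shape, collapse = "x"), x$base_score))
  print(x$config)
  invisible(x)
}

# 0-based centre (in source voxel coordinates) of grid cell g on one axis
grid_centers <- function(m, patch, stride) (seq_len(m) - 1) * stride + (patch - 1) / 2

#' Upsample a saliency map to the source resolution
#'
#' Zooms the coarse occlusion grid back to the shape of the original volume.
#' `"nearest"` assigns each voxel the value of the grid cell whose occlusion
#' window centre is nearest (ties broken towards the lower index) and so
#' preserves the multiset of distinct values; `"trilinear"` (the display
#' default) interpolates linearly between grid-cell centres, with constant
#' extrapolation beyond the outermost centres.
#'
#' @param map a `saliency_map`.
#' @param method `"trilinear"` or `"nearest"`.
#' @return 3D numeric array with `dim = source_shape`.
#' @export
upsample_map <- function(map, method = c("trilinear", "nearest")) {
  stopifnot(inherits(map, "saliency_map"))
  method <- match.arg(method)
  grid <- map$grid_shape
  if (!identical(dim(map$values), as.integer(grid)))
    stop("saliency values are inconsistent with the stated grid shape", call. = FALSE)
  shape <- map$source_shape
  cfg <- map$config

  if (method == "nearest") {
    near <- function(n, m, patch, stride) {
      t <- ((seq_len(n) - 1) - (patch - 1) / 2) / stride
      pmin(pmax(ceiling(t - 0.5), 0), m - 1) + 1L
    }
    ix <- near(shape[1L], grid[1L], cfg$patch[1L], cfg$stride[1L])
    iy <- near(shape[2L], grid[2L], cfg$patch[2L], cfg$stride[2L])
    iz <- near(shape[3L], grid[3L], cfg$patch[3L], cfg$stride[3L])
    return(map$values[ix, iy, iz, drop = FALSE])
  }

  # trilinear: per-axis lower cell index and fractional weight
  axis_interp <- function(n, m, patch, stride) {
    t <- ((seq_len(n) - 1) - (patch - 1) / 2) / stride
    t <- pmin(pmax(t, 0), m - 1)
    lo <- pmin(floor(t), max(m - 2, 0))
    list(lo = as.integer(lo) + 1L, w = t - lo)
  }
  ax <- axis_interp(shape[1L], grid[1L], cfg$patch[1L], cfg$stride[1L])
  ay <- axis_interp(shape[2L], grid[2L], cfg$patch[2L], cfg$stride[2L])
  az <- axis_interp(shape[3L], grid[3L], cfg$patch[3L], cfg$stride[3L])
  hi <- function(a, m) pmin(a$lo + 1L, m)
  out <- array(0, dim = shape)
  v <- map$values
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    jx <- if (cx == 0) ax$lo else hi(ax, grid[1L])
    jy <- if (cy == 0) ay$lo else hi(ay, grid[2L])
    jz <- if (cz == 0) az$lo else hi(az, grid[3L])
    wx <- if (cx == 0) 1 - ax$w else ax$w
    wy <- if (cy == 0) 1 - ay$w else ay$w
    wz <- if (cz == 0) 1 - az$w else az$w
    w <- outer(outer(wx, wy), wz)
    out <- out + v[jx, jy, jz, drop = FALSE] * w
  }
  out
}

#' Select the axial slice with the highest saliency
#'
#' Returns the 0-based z index of the slice containing the global maximum of
#' the (upsampled) saliency volume — the slice that was presented to readers.
#' Ties are broken towards the lowest z; a constant (degenerate) map returns
#' slice 0 with a warning.
#'
#' @param upsampled 3D numeric array.
#' @return integer 0-based axial slice index.
#' @export
select_peak_slice <- function(upsampled) {
  validate_volume(upsampled)
  rng <- range(upsampled)
  if (rng[1L] == rng[2L]) {
    warning("saliency volume is constant; returning slice 0", call. = FALSE)
    return(0L)
  }
  per_slice <- apply(upsampled, 3L, max)
  which.max(per_slice) - 1L
}

#' Render a blue-to-red saliency overlay on a grayscale slice
#'
#' The saliency slice is min-max normalised and mapped through a blue-to-red
#' colour ramp (blue = low, red = high probability of abnormality), then
#' alpha-blended over the grayscale base image. A constant saliency slice
#' renders fully blue rather than dividing by zero.
#'
#' @param base_slice 2D numeric matrix (grayscale intensities, any range).
#' @param saliency_slice 2D numeric matrix of the same shape.
#' @param alpha blend weight of the colour layer in `[0, 1]`; 0 returns the
#'   base image (as RGB).
#' @param colors colour ramp endpoints (low to high).
#' @return numeric array `nrow x ncol x 3` with RGB values in `[0, 1]`.
#' @export
render_overlay <- function(base_slice, saliency_slice, alpha = 0.5,
                           colors = c("blue", "red")) {
  stopifnot(is.matrix(base_slice), is.matrix(saliency_slice),
            identical(dim(base_slice), dim(saliency_slice)),
            is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1)
  norm01 <- function(x) {
    r <- range(x)
    if (r[1L] == r[2L]) array(0, dim = dim(x)) else (x - r[1L]) / (r[2L] - r[1L])
  }
  gray <- norm01(base_slice)
  sal <- norm01(saliency_slice)
  ramp <- grDevices::colorRamp(colors)(as.vector(sal)) / 255
  d <- dim(base_slice)
  out <- array(0, dim = c(d, 3L))
  for (ch in 1:3)
    out[, , ch] <- (1 - alpha) * gray + alpha * array(ramp[, ch], dim = d)
  out
}

#' Write an RGB overlay to a PNG file
#'
#' @param rgb array `h x w x 3` in `[0, 1]`, e.g. from [render_overlay()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
save_overlay_png <- function(rgb, path) {
  stopifnot(is.array(rgb), length(dim(rgb)) == 3L, dim(rgb)[3L] == 3L)
  # image rows run top-to-bottom in PNG; our first axis is x
  png::writePNG(aperm(rgb, c(2L, 1L, 3L)), path)
  invisible(path)
}

#' Tight crop around the activated area of a saliency slice
#'
#' Bounding box (0-based, half-open) of the pixels on the selected axial
#' slice whose saliency exceeds the given quantile of that slice, padded by
#' `margin` pixels and clipped to the image bounds. This reproduces the
#' deliberate zoom onto the region of interest containing the activated area.
#'
#' @param upsampled 3D numeric saliency array at source resolution.
#' @param slice_index 0-based axial slice index (e.g. from
#'   [select_peak_slice()]).
#' @param threshold_quantile quantile in `[0, 1)`; pixels strictly above this
#'   quantile of the slice are kept. Quantile 0 disables thresholding and
#'   returns the full slice.
#' @param margin padding in pixels added on every side before clipping.
#' @return named numeric vector `c(x, y, w, h)`.
#' @export
extract_roi_crop <- function(upsampled, slice_index, threshold_quantile = 0.95,
                             margin = 0L) {
  validate_volume(upsampled)
  stopifnot(threshold_quantile >= 0, threshold_quantile < 1,
            slice_index >= 0, slice_index < dim(upsampled)[3L])
  sl <- upsampled[, , slice_index + 1L]
  d <- dim(sl)
  keep <- if (threshold_quantile == 0) {
    array(TRUE, dim = d)
  } else {
    sl > stats::quantile(sl, threshold_quantile, names = FALSE)
  }
  if (!any(keep)) {
    warning("no pixel above the saliency threshold; returning the full slice",
            call. = FALSE)
    return(c(x = 0, y = 0, w = d[1L], h = d[2L]))
  }
  w <- which(keep, arr.ind = TRUE)
  x0 <- max(min(w[, 1L]) - 1L - margin, 0)
  y0 <- max(min(w[, 2L]) - 1L - margin, 0)
  x1 <- min(max(w[, 1L]) + margin, d[1L])   # half-open upper edge
  y1 <- min(max(w[, 2L]) + margin, d[2L])
  c(x = x0, y = y0, w = x1 - x0, h = y1 - y0)
}

#' Persist / load a saliency map as NIfTI plus a JSON sidecar
#'
#' The coarse grid values are written as a NIfTI volume and the occlusion
#' configuration and source shape as `<path>.json`, so a map can be re-read
#' and upsampled without access to the scorer.
#'
#' @param map a `saliency_map`.
#' @param path output NIfTI path.
#' @return `path`, invisibly (`write_saliency`); a `saliency_map`
#'   (`read_saliency`).
#' @export
write_saliency <- function(map, path) {
  stopifnot(inherits(map, "saliency_map"))
  RNifti::writeNifti(RNifti::asNifti(map$values), path)
  sidecar <- list(grid_shape = map$grid_shape, source_shape = map$source_shape,
                  base_score = map$base_score,
                  config = unclass(map$config))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_saliency
#' @export
read_saliency <- function(path) {
  img <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- occlusion_config(patch = meta$config$patch, stride = meta$config$stride,
                          fill_mode = meta$config$fill_mode,
                          fill_value = meta$config$fill_value,
                          sign = meta$config$sign)
  structure(list(values = array(as.numeric(img), dim = dim(img)),
                 grid_shape = as.integer(meta$grid_shape),
                 source_shape = as.integer(meta$source_shape),
                 base_score = meta$base_score, config = cfg),
            class = "saliency_map")
}
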