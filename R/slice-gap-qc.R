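#' Atlas-space mask of interslice gap coverage for one scan
#'
#' Maps every atlas voxel centre back into the scan's acquisition slab
#' through the inverse of the normalization transform, and marks it `TRUE`
#' when it falls strictly inside an interslice gap: within the slab but
#' farther than half a slice thickness from the nearest slice centre.
#' Zero-gap geometries (slice spacing equal to thickness) give an all-false
#' mask.
#'
#' @param scan The [volume_image()] as acquired (its grid defines slice
#'   positions along the slice axis).
#' @param geom The scan's [scan_geometry()].
#' @param chain `transform_chain` or 4x4 matrix mapping scan world to atlas
#'   world.
#' @param atlas_geom Atlas grid (as in [normalize_to_atlas()]).
#' @return Logical array on the atlas grid.
#' @export
gap_mask_for_scan <- function(scan, geom, chain, atlas_geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  M <- if (inherits(chain, "transform_chain")) chain$composite else chain
  g <- atlas_grid(atlas_geom)
  gap <- slice_gap(geom)
  if (gap <= 0)
    return(array(FALSE, dim = g$dim))
  d <- g$dim
  idx <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  w_atlas <- voxel_to_world(g$affine, idx)
  w_scan <- apply_chain(solve(M), w_atlas)
  vox <- world_to_voxel(scan$affine, w_scan)
  ax <- slice_axis(geom)
  # continuous slice coordinate: slices sit at integer values
  s <- vox[, ax]
  n_slices <- dim(scan$data)[ax]
  half_th <- geom$slice_thickness / 2 / geom$slice_spacing
  in_slab <- s >= -half_th & s <= (n_slices - 1) + half_th
  off <- abs(s - round(s))
  array(in_slab & off > half_th, dim = d)
}

#' Voxelwise count of scans with gap coverage
#'
#' @param gap_masks List of logical atlas-grid arrays from
#'   [gap_mask_for_scan()].
#' @param affine Optional atlas affine carried for plotting/export.
#' @return An object of class `gap_overlap_map` with integer `counts` and
#'   `n_scans`.
#' @export
overlap_map <- function(gap_masks, affine = NULL) {
  stopifnot(length(gap_masks) >= 1)
  d <- dim(gap_masks[[1]])
  counts <- array(0L, dim = d)
  for (m in gap_masks) {
    if (!identical(dim(m), d))
      stop("gap masks must share a common atlas grid", call. = FALSE)
    counts <- counts + as.integer(m)
  }
  structure(list(counts = counts, n_scans = length(gap_masks),
                 affine = affine),
            class = "gap_overlap_map")
}

#' @export
print.gap_overlap_map <- function(x, ...) {
  cat(sprintf("<gap_overlap_map> %d scans, max overlap %d, mean %.2f\n",
              x$n_scans, max(x$counts), mean(x$counts)))
  invisible(x)
}

#' Compare striping of a t map against slice-gap overlap
#'
#' Descriptive QC comparing the spatial periodicity of a statistical map
#' with that of the gap-overlap map along the slice axis. Computes the mean
#' profile of `|t|` and of the overlap counts along the axis, their Pearson
#' correlation, and the fraction of (mean-removed) profile variance
#' concentrated at the slice-spacing frequency. No decision threshold is
#' applied; a stripe-free t map shows low profile correlation and low
#' spectral power at the gap period while the overlap map shows a strong
#' peak.
#'
#' @param t_map 3D array of t values (`NA` outside the analysis mask).
#' @param overlap A `gap_overlap_map` on the same grid.
#' @param axis World axis along which slices are stacked (1 = RL,
#'   2 = RC; use [scan_geometry()]'s plane: axial is 2, sagittal 1).
#' @param period_mm Slice centre-to-centre spacing in mm.
#' @param spacing_mm Atlas grid spacing along `axis` in mm.
#' @return An object of class `striping_report`: list with `profiles`
#'   (tibble), `profile_correlation`, `power_t`, `power_overlap` (fractions
#'   of profile variance at the gap frequency).
#' @export
striping_check <- function(t_map, overlap, axis, period_mm, spacing_mm) {
  stopifnot(inherits(overlap, "gap_overlap_map"),
            identical(dim(t_map), dim(overlap$counts)))
  prof_t <- axis_profile(abs(t_map), axis)
  prof_o <- axis_profile(overlap$counts + 0, axis)
  ok <- is.finite(prof_t) & is.finite(prof_o)
  corr <- if (sum(ok) > 2 && sd(prof_t[ok]) > 0 && sd(prof_o[ok]) > 0)
    stats::cor(prof_t[ok], prof_o[ok]) else NA_real_
  freq <- spacing_mm / period_mm  # cycles per sample
  structure(
    list(
      profiles = tibble(position_mm = (seq_along(prof_t) - 1) * spacing_mm,
                        t_profile = prof_t, overlap_profile = prof_o),
      profile_correlation = corr,
      power_t = spectral_fraction(prof_t, freq),
      power_overlap = spectral_fraction(prof_o, freq),
      period_mm = period_mm
    ),
    class = "striping_report"
  )
}

axis_profile <- function(a, axis) {
  apply(a, axis, function(x) mean(x, na.rm = TRUE))
}

# fraction of mean-removed variance at frequency f (cycles/sample),
# evaluated by direct DFT at f
spectral_fraction <- function(x, f) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) return(NA_real_)
  x <- x - mean(x)
  tot <- sum(x^2)
  if (tot == 0) return(0)
  t <- seq_len(n) - 1
  amp2 <- (sum(x * cos(2 * pi * f * t)))^2 + (sum(x * sin(2 * pi * f * t)))^2
  (2 * amp2 / n) / tot
}

#' @export
print.striping_report <- function(x, ...) {
  cat(sprintf(
    "<striping_report> profile correlation %.3f; variance at %.3g mm period: t %.3f, overlap %.3f\n",
    x$profile_correlation, x$period_mm, x$power_t, x$power_overlap))
  invisible(x)
}
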