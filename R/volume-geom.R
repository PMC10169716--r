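#' Scalar 3D image with world geometry
#'
#' The universal currency of the pipeline: a 3D scalar array together with a
#' 4x4 affine that maps 0-based voxel indices to world coordinates in mm.
#' The world frame is RAS: +x right, +y rostral, +z dorsal. A voxel's world
#' position is its centre; extents are half-open.
#'
#' @param data 3D numeric array with all values finite.
#' @param affine 4x4 numeric matrix, invertible, mapping 0-based voxel index
#'   (homogeneous) to world mm. Column norms of the 3x3 block are the voxel
#'   spacings and must be strictly positive.
#' @param modality One of `"T2W"`, `"T1W"`, `"GRE_PRE"`, `"GRE_POST"`,
#'   `"GRE_DIFF"`, `"OTHER"`.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, affine, modality = "OTHER") {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (!all(is.finite(data)))
    stop("all voxel values must be finite", call. = FALSE)
  affine <- unname(as.matrix(affine))
  if (!identical(dim(affine), c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix", call. = FALSE)
  det3 <- det(affine[1:3, 1:3])
  if (!is.finite(det3) || abs(det3) < .Machine$double.eps)
    stop("`affine` must be invertible", call. = FALSE)
  sp <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(sp <= 0))
    stop("voxel spacings must be strictly positive", call. = FALSE)
  modality <- match.arg(modality, modality_levels())
  structure(
    list(data = data, affine = affine, modality = modality),
    class = "volume_image"
  )
}

modality_levels <- function() {
  c("T2W", "T1W", "GRE_PRE", "GRE_POST", "GRE_DIFF", "OTHER")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  sp <- voxel_spacing(x)
  cat(sprintf("<volume_image> %s  %d x %d x %d voxels, spacing %s mm\n",
              x$modality, d[1], d[2], d[3],
              paste(signif(sp, 4), collapse = " x ")))
  invisible(x)
}

#' Voxel spacing of an image or label volume
#'
#' Column norms of the 3x3 block of the affine, in mm.
#' @param v A `volume_image` or `label_volume`.
#' @return Numeric vector of length 3.
#' @export
voxel_spacing <- function(v) {
  sqrt(colSums(v$affine[1:3, 1:3]^2))
}

#' Acquisition geometry of an anisotropic multi-slice scan
#'
#' Describes a 2D multi-slice acquisition: in-plane pixel spacing, slice
#' thickness (the excited slab), and centre-to-centre slice spacing. The
#' interslice gap is `slice_spacing - slice_thickness` and must be
#' non-negative. Defaults follow a fast spin echo protocol with 0.137 mm
#' pixels, 1.0 mm slices at 1.5 mm spacing (0.5 mm gaps) and a 35 mm FOV.
#'
#' @param in_plane_spacing Pixel spacing in mm.
#' @param slice_thickness Excited slice thickness in mm.
#' @param slice_spacing Centre-to-centre slice spacing in mm
#'   (>= `slice_thickness`).
#' @param n_slices Number of slices, or `NULL` to derive from the target
#'   extent when reslicing.
#' @param fov In-plane field of view in mm.
#' @param plane `"axial"` (slices stacked along the rostro-caudal axis) or
#'   `"sagittal"` (stacked along the right-left axis).
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(in_plane_spacing = 0.137, slice_thickness = 1.0,
                          slice_spacing = 1.5, n_slices = NULL, fov = 35,
                          plane = c("axial", "sagittal")) {
  plane <- match.arg(plane)
  stopifnot(in_plane_spacing > 0, slice_thickness > 0,
            is.null(fov) || fov > 0)
  if (slice_spacing < slice_thickness)
    stop("`slice_spacing` must be >= `slice_thickness`", call. = FALSE)
  if (!is.null(n_slices)) stopifnot(n_slices >= 1)
  structure(
    list(in_plane_spacing = in_plane_spacing,
         slice_thickness = slice_thickness,
         slice_spacing = slice_spacing,
         n_slices = n_slices, fov = fov, plane = plane),
    class = "scan_geometry"
  )
}

#' Interslice gap of a scan geometry
#' @param geom A `scan_geometry`.
#' @return Gap in mm (`slice_spacing - slice_thickness`).
#' @export
slice_gap <- function(geom) {
  geom$slice_spacing - geom$slice_thickness
}

# world axis index along which slices are stacked (RAS frame)
slice_axis <- function(geom) {
  switch(geom$plane, axial = 2L, sagittal = 1L)
}

#' Integer atlas labels with a brain mask
#'
#' @param labels 3D integer array; 0 is background, 1..K are regions.
#' @param brain_mask 3D logical array covering at least all labelled voxels.
#' @param affine 4x4 voxel-to-world map shared by labels and mask.
#' @param region_names Data frame with columns `label` and `name`, or `NULL`
#'   for automatic `region_<k>` names.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, brain_mask, affine, region_names = NULL) {
  if (!identical(dim(labels), dim(brain_mask)))
    stop("`labels` and `brain_mask` must share dimensions", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (any(labels > 0 & !brain_mask))
    stop("`brain_mask` must cover all labelled voxels", call. = FALSE)
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) < 1)
    stop("at least one nonzero label is required", call. = FALSE)
  if (is.null(region_names)) {
    region_names <- tibble(label = ids, name = paste0("region_", ids))
  } else {
    region_names <- as_tibble(region_names)
    stopifnot(all(c("label", "name") %in% names(region_names)))
  }
  structure(
    list(labels = labels, brain_mask = brain_mask,
         affine = unname(as.matrix(affine)), region_names = region_names),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d regions, %d x %d x %d voxels, %d brain voxels\n",
              nrow(x$region_names), d[1], d[2], d[3], sum(x$brain_mask)))
  invisible(x)
}

#' Stereotaxic bregma reference frame
#'
#' Locations are reported as (RL, VD, RC) offsets from bregma in mm:
#' RL positive to the right, VD positive dorsal / negative ventral, RC
#' positive rostral / negative caudal. In the package's RAS world frame the
#' offsets are simply coordinate differences: RL = dx, RC = dy, VD = dz.
#'
#' @param bregma_world World position of bregma (3-vector, mm).
#' @return An object of class `bregma_frame`.
#' @export
bregma_frame <- function(bregma_world) {
  bregma_world <- as.numeric(bregma_world)
  stopifnot(length(bregma_world) == 3, all(is.finite(bregma_world)))
  structure(list(bregma_world = bregma_world), class = "bregma_frame")
}

#' Convert a world position to a bregma offset
#'
#' @param p_world World coordinates (3-vector or n x 3 matrix, mm).
#' @param frame A [bregma_frame()].
#' @return Named vector (or matrix) with components `RL`, `VD`, `RC` in mm.
#' @seealso [bregma_offset_to_world()]
#' @export
world_to_bregma_offset <- function(p_world, frame) {
  stopifnot(inherits(frame, "bregma_frame"))
  if (is.matrix(p_world)) {
    d <- sweep(p_world, 2, frame$bregma_world)
    out <- cbind(RL = d[, 1], VD = d[, 3], RC = d[, 2])
    return(out)
  }
  d <- as.numeric(p_world) - frame$bregma_world
  c(RL = d[1], VD = d[3], RC = d[2])
}

#' Convert a bregma offset to world coordinates
#'
#' @param offset Offset as `c(RL, VD, RC)` in mm.
#' @param frame A [bregma_frame()].
#' @return World coordinates (3-vector, mm).
#' @export
bregma_offset_to_world <- function(offset, frame) {
  stopifnot(inherits(frame, "bregma_frame"))
  offset <- as.numeric(offset)
  frame$bregma_world + c(offset[1], offset[3], offset[2])
}

# ---- voxel/world plumbing ---------------------------------------------------

#' Map 0-based voxel indices to world coordinates
#' @param affine 4x4 voxel-to-world matrix.
#' @param idx n x 3 matrix (or 3-vector) of 0-based voxel indices.
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_to_world <- function(affine, idx) {
  idx <- rbind_point(idx)
  t(affine[1:3, 1:3] %*% t(idx) + affine[1:3, 4])
}

#' Map world coordinates to continuous 0-based voxel indices
#' @param affine 4x4 voxel-to-world matrix.
#' @param pts n x 3 matrix (or 3-vector) of world mm coordinates.
#' @return n x 3 matrix of continuous voxel indices.
#' @export
world_to_voxel <- function(affine, pts) {
  pts <- rbind_point(pts)
  inv <- solve(affine)
  t(inv[1:3, 1:3] %*% t(pts) + inv[1:3, 4])
}

rbind_point <- function(p) {
  if (is.matrix(p)) p else matrix(as.numeric(p), nrow = 1)
}

# ---- NIfTI I/O --------------------------------------------------------------

#' Read a 3D NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` file into a [volume_image()]. The sform is taken
#' as the authoritative voxel-to-world map (the qform is ignored). If a JSON
#' sidecar (same path with extension `.json`) exists, its `scan_type` entry
#' sets the modality and the full sidecar is attached as the `sidecar`
#' attribute.
#'
#' @param path Path to a NIfTI-1 file.
#' @param modality Optional modality override.
#' @return A [volume_image()].
#' @export
read_volume <- function(path, modality = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D single-channel volume: ", path, call. = FALSE)
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(aff) <- list(dim = dim(aff))
  sidecar <- NULL
  scpath <- sidecar_path(path)
  if (file.exists(scpath))
    sidecar <- jsonlite::read_json(scpath, simplifyVector = TRUE)
  if (is.null(modality)) {
    modality <- if (!is.null(sidecar$scan_type) &&
                    sidecar$scan_type %in% modality_levels())
      sidecar$scan_type else "OTHER"
  }
  v <- volume_image(array(as.numeric(img), dim = dim(img)), aff, modality)
  attr(v, "sidecar") <- sidecar
  v
}

#' Write a 3D NIfTI volume
#'
#' Writes a [volume_image()] as NIfTI-1 with the affine encoded in the sform.
#' If `sidecar` is given it is written as JSON next to the volume with the
#' modality added as `scan_type`.
#'
#' @param v A [volume_image()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param sidecar Optional named list of metadata (subject, day, plane, ...).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, sidecar = NULL) {
  stopifnot(inherits(v, "volume_image"))
  img <- RNifti::asNifti(v$data)
  sf <- v$affine
  attr(sf, "code") <- 2L
  RNifti::`sform<-`(img, sf) -> img
  RNifti::writeNifti(img, path)
  if (!is.null(sidecar)) {
    sidecar$scan_type <- v$modality
    jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

# ---- resampling -------------------------------------------------------------

# Resample a 3D array from one grid to another given both affines.
# Returns list(data, inside).
resample_array <- function(data, src_affine, target_affine, target_dim,
                           interp = c("linear", "nearest"), outside = 0) {
  interp <- match.arg(interp)
  M <- solve(src_affine) %*% target_affine   # target voxel -> source voxel
  cpp_resample_affine(data, as.integer(target_dim), M[1:3, 1:3], M[1:3, 4],
                      if (interp == "linear") 0L else 1L, outside)
}

#' Resample a volume onto an arbitrary target grid
#'
#' @param v A [volume_image()].
#' @param target_affine 4x4 voxel-to-world map of the target grid.
#' @param target_dim Target grid dimensions (length 3).
#' @param interp `"linear"` or `"nearest"`.
#' @return A [volume_image()] on the target grid, with a logical `validity`
#'   attribute marking voxels whose centre fell inside the source grid.
#' @export
resample_volume <- function(v, target_affine, target_dim,
                            interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  res <- resample_array(v$data, v$affine, target_affine, target_dim, interp)
  out <- volume_image(res$data, target_affine, v$modality)
  attr(out, "validity") <- res$inside
  out
}

#' Resample a volume to an isotropic grid
#'
#' Builds an axis-aligned isotropic grid covering the volume's field of view
#' (to within one voxel) and resamples onto it. The default spacing of
#' 0.1367 mm matches the in-plane resolution of the spin-echo protocols the
#' pipeline was designed around.
#'
#' @param v A [volume_image()].
#' @param spacing Isotropic spacing in mm.
#' @param interp `"linear"` for intensities, `"nearest"` for label data.
#' @return A [volume_image()] with equal spacings.
#' @export
resample_to_isotropic <- function(v, spacing = 0.1367,
                                  interp = c("linear", "nearest")) {
  stopifnot(spacing > 0)
  interp <- match.arg(interp)
  bb <- volume_bbox(v)
  dims <- pmax(1L, as.integer(ceiling((bb[2, ] - bb[1, ]) / spacing)))
  aff <- diag(c(rep(spacing, 3), 1))
  aff[1:3, 4] <- bb[1, ] + spacing / 2
  resample_volume(v, aff, dims, interp)
}

# world-space bounding box of the half-open voxel extent; rows = min, max
volume_bbox <- function(v) {
  d <- dim(if (inherits(v, "label_volume")) v$labels else v$data)
  corners <- as.matrix(expand.grid(c(-0.5, d[1] - 0.5),
                                   c(-0.5, d[2] - 0.5),
                                   c(-0.5, d[3] - 0.5)))
  w <- voxel_to_world(v$affine, corners)
  rbind(apply(w, 2, min), apply(w, 2, max))
}

#' Reslice an isotropic atlas into an anisotropic scan geometry
#'
#' Downsamples a labelled atlas to the in-plane resolution of an anisotropic
#' multi-slice acquisition and reslices it into the acquisition plane, using
#' nearest-neighbour transport so labels remain categorical. Slices are
#' placed at `slice_spacing` intervals centred on the atlas extent; when
#' `geom$n_slices` is `NULL` the count is derived from the atlas extent.
#'
#' @param atlas A [label_volume()] on an isotropic grid.
#' @param geom A [scan_geometry()].
#' @return A [label_volume()] on the scan grid.
#' @export
reslice_atlas_to_scan <- function(atlas, geom) {
  stopifnot(inherits(atlas, "label_volume"), inherits(geom, "scan_geometry"))
  ax <- slice_axis(geom)
  bb <- volume_bbox(atlas)
  centre <- colMeans(bb)
  extent <- bb[2, ] - bb[1, ]
  sp <- rep(geom$in_plane_spacing, 3)
  sp[ax] <- geom$slice_spacing
  dims <- integer(3)
  for (a in 1:3) {
    dims[a] <- if (a == ax && !is.null(geom$n_slices)) geom$n_slices
    else if (a != ax && !is.null(geom$fov))
      max(1L, as.integer(round(geom$fov / sp[a])))
    else max(1L, as.integer(round(extent[a] / sp[a])))
  }
  aff <- diag(c(sp, 1))
  aff[1:3, 4] <- centre - sp * (dims - 1) / 2
  lab <- resample_array(atlas$labels + 0, atlas$affine, aff, dims, "nearest")
  msk <- resample_array(atlas$brain_mask + 0, atlas$affine, aff, dims,
                        "nearest")
  labs <- array(as.integer(lab$data), dim = dims)
  mask <- array(msk$data > 0.5, dim = dims) | labs > 0
  label_volume(labs, mask, aff, atlas$region_names)
}
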