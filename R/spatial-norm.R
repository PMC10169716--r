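#' Ordered chain of rigid/affine world-to-world transforms
#'
#' Represents the composite mapping used for spatial normalization: e.g.
#' scan -> subject baseline (rigid), baseline -> reference subject (affine),
#' reference -> atlas (affine). Applying the chain to a point applies the
#' steps in order; the composite matrix is the ordered product.
#'
#' @param ... Steps in application order: 4x4 matrices, optionally named, or
#'   lists with elements `name`, `kind` (`"rigid"`/`"affine"`) and `matrix`.
#' @return An object of class `transform_chain` with the composite matrix in
#'   `$composite`.
#' @export
transform_chain <- function(...) {
  raw <- list(...)
  if (length(raw) == 1 && is.list(raw[[1]]) && !is.matrix(raw[[1]]) &&
      is.null(raw[[1]]$matrix))
    raw <- raw[[1]]
  nms <- names(raw)
  steps <- lapply(seq_along(raw), function(i) {
    s <- raw[[i]]
    if (is.matrix(s)) {
      s <- list(name = if (!is.null(nms) && nzchar(nms[i])) nms[i]
                       else paste0("step_", i),
                kind = guess_kind(s), matrix = s)
    }
    stopifnot(is.matrix(s$matrix), identical(dim(s$matrix), c(4L, 4L)))
    if (abs(det(s$matrix)) < 1e-12)
      stop("singular transform step: ", s$name, call. = FALSE)
    if (identical(s$kind, "rigid") && !is_rigid(s$matrix))
      stop("step ", s$name, " declared rigid but rotation block is not ",
           "orthonormal with det +1", call. = FALSE)
    s$matrix <- unclass_matrix(s$matrix)
    s
  })
  composite <- diag(4)
  for (s in steps) composite <- s$matrix %*% composite
  structure(list(steps = steps, composite = composite),
            class = "transform_chain")
}

guess_kind <- function(M) {
  if (is_rigid(M)) "rigid" else "affine"
}

is_rigid <- function(M, tol = 1e-6) {
  R <- M[1:3, 1:3]
  max(abs(t(R) %*% R - diag(3))) < tol && abs(det(R) - 1) < tol
}

#' Compose transforms into a chain and composite matrix
#'
#' `compose_chain(T1, T2)` applied to a point `p` equals `T2(T1(p))`.
#'
#' @inheritParams transform_chain
#' @return A `transform_chain`.
#' @export
compose_chain <- function(...) {
  transform_chain(...)
}

#' @export
print.transform_chain <- function(x, ...) {
  cat(sprintf("<transform_chain> %d step(s): %s\n", length(x$steps),
              paste(vapply(x$steps, function(s) sprintf("%s[%s]", s$name,
                                                        s$kind), ""),
                    collapse = " -> ")))
  invisible(x)
}

#' Exact inverse of a transform chain
#' @param chain A `transform_chain`.
#' @return A `transform_chain` with reversed, inverted steps.
#' @export
chain_inverse <- function(chain) {
  steps <- rev(lapply(chain$steps, function(s) {
    list(name = paste0(s$name, "_inv"), kind = s$kind,
         matrix = solve(s$matrix))
  }))
  transform_chain(steps)
}

#' Apply a transform chain to world points
#' @param chain A `transform_chain` (or 4x4 matrix).
#' @param pts 3-vector or n x 3 matrix of world mm points.
#' @return Transformed points, same shape convention as [voxel_to_world()].
#' @export
apply_chain <- function(chain, pts) {
  M <- if (inherits(chain, "transform_chain")) chain$composite else chain
  pts <- rbind_point(pts)
  t(M[1:3, 1:3] %*% t(pts) + M[1:3, 4])
}

#' Serialise a transform chain to JSON
#'
#' Writes named steps and the composite as 4x4 row-major world matrices
#' (mm).
#' @param chain A `transform_chain`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chain, path) {
  obj <- list(
    steps = lapply(chain$steps, function(s)
      list(name = s$name, kind = s$kind,
           matrix = as.numeric(t(s$matrix)))),
    composite = as.numeric(t(chain$composite))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a transform chain from JSON
#' @param path JSON path written by [write_chain()].
#' @return A `transform_chain`.
#' @export
read_chain <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  steps <- lapply(seq_len(nrow(obj$steps)), function(i) {
    list(name = obj$steps$name[i], kind = obj$steps$kind[i],
         matrix = matrix(unlist(obj$steps$matrix[i]), 4, 4, byrow = TRUE))
  })
  transform_chain(steps)
}

#' Resample a scan into atlas space through a transform chain
#'
#' Applies the composite transform (scan world to atlas world) and
#' resamples the scan with linear interpolation onto the atlas grid. Atlas
#' voxels whose source position falls outside the scan grid are recorded as
#' invalid; if `geom` is supplied, voxels whose source position falls inside
#' an interslice gap of the acquisition slab are additionally invalidated,
#' so that group statistics can be restricted to genuinely observed tissue.
#'
#' @param scan A [volume_image()].
#' @param chain A `transform_chain` or 4x4 matrix mapping scan world to
#'   atlas world.
#' @param atlas_geom A [label_volume()], [volume_image()], or
#'   `list(affine, dim)` defining the atlas grid.
#' @param geom Optional [scan_geometry()] describing the acquisition slab of
#'   `scan`, used to flag gap voxels.
#' @return A [volume_image()] on the atlas grid with logical attribute
#'   `validity`.
#' @export
normalize_to_atlas <- function(scan, chain, atlas_geom, geom = NULL) {
  M <- if (inherits(chain, "transform_chain")) chain$composite else chain
  g <- atlas_grid(atlas_geom)
  res <- resample_array(scan$data, M %*% scan$affine, g$affine, g$dim,
                        "linear")
  validity <- res$inside
  if (!is.null(geom)) {
    gap <- gap_mask_for_scan(scan, geom, M, atlas_geom)
    validity <- validity & !gap
  }
  out <- volume_image(res$data, g$affine, scan$modality)
  attr(out, "validity") <- validity
  out
}

atlas_grid <- function(atlas_geom) {
  if (inherits(atlas_geom, "label_volume"))
    return(list(affine = atlas_geom$affine, dim = dim(atlas_geom$labels)))
  if (inherits(atlas_geom, "volume_image"))
    return(list(affine = atlas_geom$affine, dim = dim(atlas_geom$data)))
  stopifnot(is.list(atlas_geom), !is.null(atlas_geom$affine),
            !is.null(atlas_geom$dim))
  atlas_geom
}
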