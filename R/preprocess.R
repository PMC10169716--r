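#' Atlas-guided skull stripping
#'
#' Estimates an affine transform from the subject scan to the atlas by
#' gradient-descent maximisation of a correlation objective evaluated over
#' the atlas brain-mask region, then carries the atlas brain mask through
#' the inverse transform into subject space with nearest-neighbour
#' resampling.
#'
#' When an atlas `template` image is supplied the correlation is computed
#' between the scan and the template within the (slightly dilated) brain
#' mask, which anchors the brain boundary accurately. Without a template
#' the scan is registered against a lightly smoothed rendering of the mask
#' itself; this fallback recovers pose well but is less accurate in scale,
#' since a flat silhouette carries no interior contrast.
#'
#' @param scan A [volume_image()] in native subject space.
#' @param atlas A [label_volume()] providing the brain mask.
#' @param template Optional atlas template [volume_image()] on the atlas
#'   grid.
#' @param max_iter Optimiser iteration cap per resolution level.
#' @return An object of class `brain_mask_result`: a list with `mask`
#'   (logical array on the scan grid), `transform_to_atlas` (4x4 world map,
#'   scan to atlas) and `objective_value` (correlation at convergence).
#' @export
skull_strip_atlas_guided <- function(scan, atlas, template = NULL,
                                     max_iter = 120L) {
  stopifnot(inherits(scan, "volume_image"), inherits(atlas, "label_volume"))
  if (!is.null(template)) {
    stopifnot(inherits(template, "volume_image"),
              identical(dim(template$data), dim(atlas$labels)))
    region <- dilate_mask(atlas$brain_mask, 2L)
    M <- register_ncc(scan, template, "affine", max_iter = max_iter,
                      fixed_region = region)
  } else {
    # light smoothing gives the binary mask an edge ramp comparable to the
    # scan's partial-volume boundary
    fixed <- smooth_gaussian(volume_image(atlas$brain_mask + 0,
                                          atlas$affine),
                             sigma = rep(2 * min(voxel_spacing(atlas)), 3),
                             through_axis = 2L)
    M <- register_affine(scan, fixed, max_iter = max_iter)
  }
  obj <- attr(M, "objective")
  if (!is.finite(obj) || obj <= 0)
    stop("skull stripping failed: correlation objective did not improve ",
         "(objective = ", signif(obj, 3), ")", call. = FALSE)
  # transport the atlas mask through the inverse transform into scan space
  res <- resample_array(atlas$brain_mask + 0, solve(M) %*% atlas$affine,
                        scan$affine, dim(scan$data), "nearest")
  mask <- array(res$data > 0.5, dim = dim(scan$data))
  if (!any(mask))
    stop("skull stripping produced an empty brain mask", call. = FALSE)
  structure(
    list(mask = mask, transform_to_atlas = unclass_matrix(M),
         objective_value = obj),
    class = "brain_mask_result"
  )
}

unclass_matrix <- function(M) {
  attributes(M) <- list(dim = dim(M))
  M
}

#' @export
print.brain_mask_result <- function(x, ...) {
  cat(sprintf("<brain_mask_result> %d brain voxels, NCC = %.4f\n",
              sum(x$mask), x$objective_value))
  invisible(x)
}

#' Multiplicative bias-field correction
#'
#' Estimates a smooth multiplicative intensity inhomogeneity inside the
#' brain mask and divides it out. The field is modelled in the log domain as
#' a low-order polynomial fitted to class-conditional intensity residuals:
#' voxels are partitioned into `n_classes` tissue classes by k-means on the
#' (current) corrected log intensities, the per-class mean is subtracted,
#' and the polynomial is refitted to the residual; a few such iterations
#' separate anatomy (piecewise-constant) from the smooth field. The returned
#' field is strictly positive and scaled so the masked mean intensity of the
#' corrected image equals that of the input.
#'
#' @param scan A [volume_image()] with non-negative intensities in the mask.
#' @param mask Logical array of brain voxels.
#' @param order Polynomial order of the log-domain field (default 3).
#' @param n_classes Number of tissue classes for the residual model.
#' @param n_iter Field/classification alternations.
#' @param max_fit_voxels Random-free cap on voxels used in the fit (uniform
#'   decimation).
#' @return A list with `corrected` and `field` (both [volume_image()]);
#'   `corrected$data * field$data == scan$data` up to rounding.
#' @export
correct_bias_field <- function(scan, mask, order = 3L, n_classes = 4L,
                               n_iter = 6L, max_fit_voxels = 30000L) {
  stopifnot(inherits(scan, "volume_image"))
  mask <- as.logical(mask)
  if (!any(mask)) stop("`mask` is empty", call. = FALSE)
  d <- dim(scan$data)
  mask <- array(mask, dim = d)
  vals <- scan$data[mask]
  if (all(vals == 0))
    stop("degenerate input: scan is zero everywhere inside the mask",
         call. = FALSE)
  if (any(vals < 0))
    stop("intensities inside the mask must be non-negative", call. = FALSE)
  eps <- max(vals) * 1e-6
  # fit on the eroded mask: boundary voxels are partial-volume mixtures
  # that would masquerade as field variation
  fit_mask <- erode_mask(mask)
  if (sum(fit_mask) < 500) fit_mask <- mask
  idx <- which(fit_mask)
  coord <- arrayInd(idx, d)
  X <- sweep(coord, 2, (d + 1) / 2)
  X <- sweep(X, 2, pmax(d / 2, 1), "/")
  keep <- seq(1, nrow(X), by = max(1L, floor(nrow(X) / max_fit_voxels)))
  B <- poly_basis(X[keep, , drop = FALSE], order)
  logI <- log(scan$data[fit_mask] + eps)[keep]
  coef <- numeric(ncol(B))
  for (it in seq_len(n_iter)) {
    fieldfit <- as.numeric(B %*% coef)
    corrected <- logI - fieldfit
    class_means <- classify_means_1d(corrected, n_classes)
    resid <- logI - class_means
    # robust (Huber) reweighting: partial-volume voxels far from any class
    # mean should not drive the field
    r0 <- resid - fieldfit
    s <- stats::mad(r0, constant = 1.4826)
    w <- if (s > 0) pmin(1, 1.345 * s / pmax(abs(r0), 1e-12)) else
      rep(1, length(r0))
    coef <- stats::lm.wfit(B, resid, w)$coefficients
    coef[is.na(coef)] <- 0
  }
  # evaluate the field on the full grid
  full <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  Xf <- sweep(full, 2, (d + 1) / 2)
  Xf <- sweep(Xf, 2, pmax(d / 2, 1), "/")
  logfield <- array(as.numeric(poly_basis(Xf, order) %*% coef), dim = d)
  field <- exp(logfield - mean(logfield[mask]))
  corrected <- scan$data / field
  # fold the mean-preservation constant into the field
  cfac <- mean(corrected[mask]) / mean(scan$data[mask])
  field <- field * cfac
  corrected <- scan$data / field
  list(
    corrected = volume_image(corrected, scan$affine, scan$modality),
    field = volume_image(field, scan$affine, "OTHER")
  )
}

# binary dilation with the 6-neighbourhood, `times` passes
dilate_mask <- function(m, times = 1L) {
  for (i in seq_len(times)) m <- !erode_mask(!m)
  m
}

# binary erosion with the 6-neighbourhood
erode_mask <- function(m) {
  d <- dim(m)
  out <- m
  shift <- function(a, axis, by) {
    idx <- lapply(d, seq_len)
    src <- pmin(pmax(idx[[axis]] + by, 1), d[axis])
    pad <- idx; pad[[axis]] <- src
    res <- a[pad[[1]], pad[[2]], pad[[3]], drop = FALSE]
    # out-of-range shifts are treated as FALSE (eroded at the border)
    edge <- if (by > 0) idx[[axis]] > d[axis] - by else idx[[axis]] <= -by
    slc <- idx; slc[[axis]] <- which(edge)
    if (length(slc[[axis]]))
      res[slc[[1]], slc[[2]], slc[[3]]] <- FALSE
    res
  }
  for (axis in 1:3) {
    out <- out & shift(m, axis, 1L) & shift(m, axis, -1L)
  }
  out
}

# Lloyd iterations on 1D values with quantile initialisation; returns each
# value's class mean. Degenerate inputs (fewer distinct values than
# classes) collapse gracefully to the available centres.
classify_means_1d <- function(x, k, iters = 10L) {
  centers <- unique(stats::quantile(x, probs = seq(0.5, k - 0.5) / k,
                                    names = FALSE))
  if (length(centers) == 1) return(rep(centers, length(x)))
  for (i in seq_len(iters)) {
    cl <- max.col(-abs(outer(x, centers, "-")), ties.method = "first")
    newc <- vapply(seq_along(centers), function(j) {
      v <- x[cl == j]
      if (length(v)) mean(v) else centers[j]
    }, 0)
    if (max(abs(newc - centers)) < 1e-12) break
    centers <- newc
  }
  cl <- max.col(-abs(outer(x, centers, "-")), ties.method = "first")
  centers[cl]
}

# monomial basis x^a y^b z^c with a+b+c <= order, on an n x 3 matrix
poly_basis <- function(X, order) {
  terms <- expand.grid(a = 0:order, b = 0:order, c = 0:order)
  terms <- terms[rowSums(terms) <= order, , drop = FALSE]
  out <- matrix(1, nrow(X), nrow(terms))
  for (t in seq_len(nrow(terms)))
    out[, t] <- X[, 1]^terms$a[t] * X[, 2]^terms$b[t] * X[, 3]^terms$c[t]
  out
}

#' Rescale a scan to a fixed mean intensity within the brain
#'
#' Pure scalar multiplication so that the masked mean equals `target_mean`,
#' making scans from different sessions exchangeable in group statistics.
#'
#' @param scan A [volume_image()].
#' @param mask Logical array of brain voxels.
#' @param target_mean Target masked mean (default 1000, an arbitrary fixed
#'   constant applied to every scan).
#' @return A rescaled [volume_image()].
#' @export
rescale_mean_intensity <- function(scan, mask, target_mean = 1000) {
  mask <- as.logical(mask)
  m <- mean(scan$data[mask])
  if (!is.finite(m) || m <= 0)
    stop("masked mean must be positive to rescale", call. = FALSE)
  volume_image(scan$data * (target_mean / m), scan$affine, scan$modality)
}

#' Gadolinium difference image
#'
#' Rigidly registers the post-contrast image onto the pre-contrast image and
#' subtracts the pre-contrast image voxelwise, yielding a map of contrast
#' uptake.
#'
#' @param pre,post Pre- and post-contrast [volume_image()] from the same
#'   session.
#' @param max_iter Registration iteration cap.
#' @return A [volume_image()] with modality `GRE_DIFF` on the pre-contrast
#'   grid, with the estimated rigid transform attached as attribute
#'   `transform` (post world to pre world).
#' @export
gd_difference <- function(pre, post, max_iter = 120L) {
  stopifnot(inherits(pre, "volume_image"), inherits(post, "volume_image"))
  M <- register_rigid(post, pre, max_iter = max_iter)
  res <- resample_array(post$data, M %*% post$affine, pre$affine,
                        dim(pre$data), "linear")
  diffd <- res$data - pre$data
  diffd[!res$inside] <- 0
  out <- volume_image(diffd, pre$affine, "GRE_DIFF")
  attr(out, "transform") <- unclass_matrix(M)
  attr(out, "validity") <- res$inside
  out
}
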