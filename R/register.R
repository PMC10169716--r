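#' @title Intensity-based rigid and affine registration
#' @description Registration maximises normalised cross-correlation (NCC)
#'   between a moving and a fixed image with a multi-resolution (3-level)
#'   regular-step gradient descent. Transforms are parameterised about the
#'   fixed image's world centre and returned as 4x4 world-to-world matrices
#'   mapping moving-image world coordinates to fixed-image world
#'   coordinates.
#' @name registration
NULL

# build world-to-world matrix from parameters
# rigid:  p = (rx, ry, rz, tx, ty, tz)           rotations in radians
# affine: p = rigid + (log sx, log sy, log sz, kxy, kxz, kyz)
transform_matrix_from_params <- function(p, center, kind = c("rigid", "affine")) {
  kind <- match.arg(kind)
  cx <- cos(p[1]); sx <- sin(p[1])
  cy <- cos(p[2]); sy <- sin(p[2])
  cz <- cos(p[3]); sz <- sin(p[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  A <- Rz %*% Ry %*% Rx
  if (kind == "affine") {
    S <- diag(exp(p[7:9]))
    K <- rbind(c(1, p[10], p[11]), c(0, 1, p[12]), c(0, 0, 1))
    A <- A %*% S %*% K
  }
  M <- diag(4)
  M[1:3, 1:3] <- A
  M[1:3, 4] <- p[4:6] + center - A %*% center
  M
}

world_center <- function(v) {
  colMeans(volume_bbox(v))
}

# NCC between fixed values and moving values resampled through M
# (moving world -> fixed world), evaluated on a subsampled fixed grid,
# optionally restricted to a region of the fixed grid.
ncc_objective <- function(moving, fixed_data, fixed_affine, fixed_dim, M,
                          region = NULL) {
  res <- resample_array(moving$data, M %*% moving$affine, fixed_affine,
                        fixed_dim, "linear")
  f <- as.numeric(fixed_data)
  m <- as.numeric(res$data)
  ok <- as.logical(res$inside)
  if (!is.null(region)) ok <- ok & as.logical(region)
  if (sum(ok) < 32) return(NA_real_)
  f <- f[ok]; m <- m[ok]
  sf <- sd(f); sm <- sd(m)
  if (sf == 0 || sm == 0) return(0)
  sum((f - mean(f)) * (m - mean(m))) / ((length(f) - 1) * sf * sm)
}

# subsample a fixed image grid by an integer factor (voxel decimation)
decimate_grid <- function(v, factor) {
  d <- dim(v$data)
  idx <- lapply(d, function(n) seq(1, n, by = factor))
  data <- v$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  aff <- v$affine
  aff[1:3, 1:3] <- aff[1:3, 1:3] * factor
  list(data = data, affine = aff, dim = dim(data))
}

# decimation factors for a 3-level pyramid, chosen so objective evaluations
# stay cheap: coarse/mid/fine capped at ~8k/30k/100k fixed-grid voxels
pyramid_levels <- function(fixed, caps = c(8e3, 3e4, 1e5)) {
  n <- prod(dim(fixed$data))
  f <- vapply(caps, function(cap) max(1L, as.integer(ceiling((n / cap)^(1 / 3)))),
              0L)
  unique(rev(sort(f)))
}

register_ncc <- function(moving, fixed, kind, levels = NULL,
                         max_iter = 60L, init = NULL,
                         init_step = NULL, min_step = 1e-4,
                         patience = 25L, fixed_region = NULL) {
  if (is.null(levels)) levels <- pyramid_levels(fixed)
  npar <- if (kind == "rigid") 6L else 12L
  center <- world_center(fixed)
  # parameter scales chosen so one unit of any parameter moves a point at
  # the object radius by ~1 mm: radians/log-scale/shear scale as 1/r_obj,
  # translations as 1 mm
  bb <- volume_bbox(fixed)
  r_obj <- max(1, mean(bb[2, ] - bb[1, ]) / 4)
  scales <- c(rep(1 / r_obj, 3), rep(1, 3),
              if (kind == "affine") rep(1 / r_obj, 6) else NULL)
  p <- if (is.null(init)) numeric(npar) else init
  if (is.null(init_step)) init_step <- 1
  # centre-of-mass initial translation
  if (is.null(init)) {
    cm_f <- center_of_mass(fixed)
    cm_m <- center_of_mass(moving)
    p[4:6] <- cm_f - cm_m
  }
  total_evals <- 0L
  best_obj <- -Inf
  for (lev in levels) {
    fg <- decimate_grid(fixed, lev)
    rg <- if (is.null(fixed_region)) NULL else
      decimate_grid(list(data = fixed_region + 0, affine = fixed$affine),
                    lev)$data > 0.5
    loss <- function(q) {
      M <- transform_matrix_from_params(q * scales, center, kind)
      v <- ncc_objective(moving, fg$data, fg$affine, fg$dim, M, rg)
      if (!is.finite(v)) return(Inf)
      -v
    }
    q <- p / scales
    f0 <- loss(q)
    step <- init_step
    stall <- 0L
    f_prev <- f0
    for (iter in seq_len(max_iter)) {
      # central-difference gradient in scaled parameter space
      g <- numeric(npar)
      h <- 0.25
      for (j in seq_len(npar)) {
        qp <- q; qp[j] <- qp[j] + h
        qm <- q; qm[j] <- qm[j] - h
        g[j] <- (loss(qp) - loss(qm)) / (2 * h)
        total_evals <- total_evals + 2L
      }
      gn <- sqrt(sum(g^2))
      if (gn < 1e-12) break
      moved <- FALSE
      while (step >= min_step) {
        q_new <- q - step * g / gn
        f_new <- loss(q_new)
        total_evals <- total_evals + 1L
        if (f_new < f0 - 1e-10) {
          q <- q_new
          f0 <- f_new
          step <- min(step * 1.2, 4)
          moved <- TRUE
          break
        }
        step <- step / 2
      }
      if (!moved) break
      if (f_prev - f0 < 1e-7) {
        stall <- stall + 1L
        if (stall >= 3L) break
      } else stall <- 0L
      f_prev <- f0
    }
    p <- q * scales
    best_obj <- -f0
  }
  if (!is.finite(best_obj))
    stop("registration failed: objective not finite (no overlap?)",
         call. = FALSE)
  M <- transform_matrix_from_params(p, center, kind)
  structure(M, params = p, objective = best_obj, evals = total_evals,
            kind = kind)
}

center_of_mass <- function(v) {
  d <- dim(v$data)
  w <- abs(v$data)
  tot <- sum(w)
  if (tot == 0) return(world_center(v))
  ix <- sum(slice.index(w, 1) * w) / tot - 1
  iy <- sum(slice.index(w, 2) * w) / tot - 1
  iz <- sum(slice.index(w, 3) * w) / tot - 1
  as.numeric(voxel_to_world(v$affine, c(ix, iy, iz)))
}

#' Rigid (6-DOF) registration of one volume to another
#'
#' Estimates the rigid world-to-world transform mapping `moving` onto
#' `fixed` by maximising normalised cross-correlation with a three-level
#' multi-resolution gradient descent.
#'
#' @param moving,fixed [volume_image()] objects that overlap in world space.
#' @param init Optional initial parameter vector
#'   (rx, ry, rz radians, tx, ty, tz mm).
#' @param max_iter Maximum gradient-descent iterations per level.
#' @return A 4x4 matrix mapping moving world mm to fixed world mm, with
#'   attributes `objective` (NCC at convergence), `params` and `kind`.
#' @export
register_rigid <- function(moving, fixed, init = NULL, max_iter = 120L) {
  register_ncc(moving, fixed, "rigid", init = init, max_iter = max_iter)
}

#' Affine (12-DOF) registration of one volume to another
#'
#' As [register_rigid()] with additional per-axis log-scale and shear
#' parameters.
#'
#' @inheritParams register_rigid
#' @return A 4x4 matrix mapping moving world mm to fixed world mm.
#' @export
register_affine <- function(moving, fixed, init = NULL, max_iter = 120L) {
  register_ncc(moving, fixed, "affine", init = init, max_iter = max_iter)
}

# decompose: translation magnitude (mm) and rotation angle (degrees) of a
# transform relative to another; the rotation is taken from the polar
# decomposition so scale/shear components do not masquerade as rotation
rigid_discrepancy <- function(M, N = diag(4)) {
  D <- solve(N) %*% M
  sv <- svd(D[1:3, 1:3])
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) {
    u <- sv$u; u[, 3] <- -u[, 3]
    R <- u %*% t(sv$v)
  }
  tr <- sum(diag(R))
  ang <- acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
  list(translation = sqrt(sum(D[1:3, 4]^2)), rotation_deg = ang,
       max_scale_dev = max(abs(sv$d - 1)))
}
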