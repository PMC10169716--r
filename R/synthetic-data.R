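#' Specification of a synthetic study phantom
#'
#' Defines the geometry, tissue contrast, corruption model and injected
#' post-injury effects of the phantom generator. The defaults emulate the
#' study design the pipeline targets: an ellipsoidal multi-tissue brain with
#' a superficial mid-sagittal venous tube whose baseline caliber is 0.96 mm,
#' dilating by a factor of about 1.3 on post-injury day 1 and decaying back
#' to baseline by day 14; contrast-enhanced scans additionally show
#' subarachnoid surface enhancement on P1-P2 and a focal deep perivascular
#' enhancement on P1-P7.
#'
#' @param grid_shape Atlas grid dimensions, or `NULL` to derive from the
#'   brain semi-axes and spacing.
#' @param iso_spacing Isotropic atlas spacing in mm.
#' @param brain_semiaxes Ellipsoid semi-axes (RL, RC, VD) in mm.
#' @param n_regions Number of atlas regions (>= 2; the venous tube is one of
#'   them).
#' @param tissue_means Named intensities for `gm`, `wm`, `csf`, `vessel`,
#'   `skull` (a thin dark shell around the brain) and `scalp` (a thin
#'   bright outer rind); the extracerebral shells exist to exercise skull
#'   stripping.
#' @param noise_sigma Additive Gaussian noise SD (intensity units).
#' @param bias_amplitude Peak fractional amplitude of the multiplicative
#'   bias field, in `[0, 1)`.
#' @param tube_diameter_by_day Named day -> tube diameter (mm) for days
#'   B1, B2, P1, P2, P7, P14.
#' @param tube_center_depth Depth of the tube centreline below the dorsal
#'   brain surface, mm.
#' @param dilation_rc_range Optional rostro-caudal extent (bregma RC
#'   offsets, mm) over which the day-dependent dilation applies, with a
#'   0.5 mm taper at both ends; `NULL` dilates the whole tube. The default
#'   restricts dilation to the rostral segment (RC > -3 mm, covering the
#'   rostral measurement site but not the caudal one), matching an injury
#'   focused near the impact site.
#' @param vessel_enhancement_by_day Named day -> additive intensity applied
#'   to the tube lumen in post-contrast scans (contrast agent filling the
#'   vessel).
#' @param sa_enhancement_by_day Named day -> additive intensity applied to
#'   the dorsal subarachnoid surface shell in post-contrast scans.
#' @param focal_effects List of focal enhancements, each a list with
#'   `center` (bregma offset `c(RL, VD, RC)` mm), `radius` (mm), `amplitude`
#'   (intensity) and `days` (character vector).
#' @param rng_seed Integer seed from which all randomness derives.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = NULL,
                         iso_spacing = 0.25,
                         brain_semiaxes = c(7, 13, 5.5),
                         n_regions = 80L,
                         tissue_means = c(gm = 400, wm = 550, csf = 150,
                                          vessel = 800, skull = 80,
                                          scalp = 250),
                         noise_sigma = 20,
                         bias_amplitude = 0.2,
                         tube_diameter_by_day = 0.96 * c(B1 = 1, B2 = 1,
                                                         P1 = 1.3, P2 = 1.14,
                                                         P7 = 1.10, P14 = 1),
                         tube_center_depth = 1.0,
                         dilation_rc_range = c(-3, Inf),
                         vessel_enhancement_by_day = c(B1 = 250, B2 = 250,
                                                       P1 = 250, P2 = 250,
                                                       P7 = 250, P14 = 250),
                         sa_enhancement_by_day = c(P1 = 120, P2 = 60),
                         focal_effects = list(
                           list(center = c(RL = 0, VD = -4.5, RC = -4.0),
                                radius = 0.8, amplitude = 150,
                                days = c("P1", "P2", "P7"))
                         ),
                         rng_seed = 1L) {
  stopifnot(iso_spacing > 0, length(brain_semiaxes) == 3,
            all(brain_semiaxes > 0), n_regions >= 1,
            noise_sigma >= 0, bias_amplitude >= 0, bias_amplitude < 1,
            all(tube_diameter_by_day > 0), tube_center_depth > 0)
  if (max(tube_diameter_by_day) / 2 > tube_center_depth)
    stop("tube diameter exceeds available brain depth: max radius ",
         max(tube_diameter_by_day) / 2, " mm > tube_center_depth ",
         tube_center_depth, " mm", call. = FALSE)
  if (is.null(grid_shape)) {
    margin <- 1.5
    grid_shape <- as.integer(ceiling(2 * (brain_semiaxes + margin) /
                                       iso_spacing))
  }
  structure(
    list(grid_shape = as.integer(grid_shape), iso_spacing = iso_spacing,
         brain_semiaxes = brain_semiaxes, n_regions = as.integer(n_regions),
         tissue_means = tissue_means, noise_sigma = noise_sigma,
         bias_amplitude = bias_amplitude,
         tube_diameter_by_day = tube_diameter_by_day,
         tube_center_depth = tube_center_depth,
         dilation_rc_range = dilation_rc_range,
         vessel_enhancement_by_day = vessel_enhancement_by_day,
         sa_enhancement_by_day = sa_enhancement_by_day,
         focal_effects = focal_effects,
         rng_seed = as.integer(rng_seed)),
    class = "phantom_spec"
  )
}

study_days <- function() c("B1", "B2", "P1", "P2", "P7", "P14")

# dorsal surface height of the mid-sagittal ellipse at rostro-caudal
# position y (NA outside the ellipse)
dorsal_surface <- function(y, semiaxes) {
  u <- 1 - (y / semiaxes[2])^2
  ifelse(u > 0, semiaxes[3] * sqrt(pmax(u, 0)), NA_real_)
}

# Place bregma so that the two published stereotaxic seed offsets
# (0, -1.07, -0.22) and (0, -0.53, -5.55) both land on the phantom tube
# centreline, which follows the dorsal surface at constant depth.
solve_bregma_y <- function(semiaxes) {
  g <- function(yb) {
    zr <- dorsal_surface(yb - 0.22, semiaxes)
    zc <- dorsal_surface(yb - 5.55, semiaxes)
    if (is.na(zr) || is.na(zc)) return(NA_real_)
    (zc - zr) - (1.07 - 0.53)
  }
  lo <- 3.0
  hi <- min(semiaxes[2] - 0.8, 9)
  glo <- g(lo); ghi <- g(hi)
  if (is.na(glo) || is.na(ghi) || glo * ghi > 0) {
    warning("could not place bregma so both default seeds lie on the tube ",
            "centreline; using mid-dorsal fallback")
    return(semiaxes[2] / 2)
  }
  stats::uniroot(g, c(lo, hi), tol = 1e-8)$root
}

#' Generate a phantom atlas: template, labels and bregma frame
#'
#' Builds an ellipsoidal multi-tissue brain (grey matter with a white-matter
#' core and a small CSF compartment), a thin bright extracerebral rind, and
#' a superficial mid-sagittal tube following the dorsal surface at constant
#' depth (the venous sinus analogue). The brain mask is partitioned into
#' exactly `n_regions` labels: `n_regions - 1` contiguous parcels plus the
#' tube as its own region. Bregma is placed on the dorsal midline such that
#' the pipeline's two default sinus seed points fall on the tube centreline.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `atlas_phantom`: list with `template`
#'   ([volume_image()]), `atlas` ([label_volume()]), `frame`
#'   ([bregma_frame()]), the `spec`, and generator internals in `meta`.
#' @export
make_atlas_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  h <- spec$iso_spacing
  ax <- spec$brain_semiaxes
  aff <- diag(c(h, h, h, 1))
  aff[1:3, 4] <- -h * (d - 1) / 2
  xv <- aff[1, 4] + h * (0:(d[1] - 1))
  yv <- aff[2, 4] + h * (0:(d[2] - 1))
  zv <- aff[3, 4] + h * (0:(d[3] - 1))
  rx2 <- (xv / ax[1])^2
  ry2 <- (yv / ax[2])^2
  rz2 <- (zv / ax[3])^2
  re2 <- outer(outer(rx2, ry2, "+"), rz2, "+")
  # a caudal-ventral lobe (cerebellum analogue) breaks the rotational
  # near-symmetry of the main ellipsoid, so shape-based registration is
  # well conditioned about every axis
  lobe_c <- c(0, -0.72 * ax[2], -0.45 * ax[3])
  lobe_ax <- c(0.6 * ax[1], 0.35 * ax[2], 0.55 * ax[3])
  rl2 <- outer(outer(((xv - lobe_c[1]) / lobe_ax[1])^2,
                     ((yv - lobe_c[2]) / lobe_ax[2])^2, "+"),
               ((zv - lobe_c[3]) / lobe_ax[3])^2, "+")
  mask <- re2 <= 1 | rl2 <= 1
  # extracerebral shells (approximate mm distance from the brain surface):
  # a dark skull layer then a dimmer scalp rind
  shell_mm <- pmin((sqrt(re2) - 1) * mean(ax),
                   (sqrt(rl2) - 1) * mean(lobe_ax))
  skull <- shell_mm > 0 & shell_mm <= 0.45
  scalp <- shell_mm > 0.45 & shell_mm <= 0.9
  wm <- outer(outer((xv / (0.55 * ax[1]))^2, (yv / (0.55 * ax[2]))^2, "+"),
              (zv / (0.55 * ax[3]))^2, "+") <= 1
  csf <- outer(outer(((xv - 0) / 1.2)^2, ((yv + 1) / 2.2)^2, "+"),
               ((zv - 0.5) / 0.8)^2, "+") <= 1
  tm <- spec$tissue_means
  base <- array(0, dim = d)
  base[skull] <- tm[["skull"]]
  base[scalp] <- tm[["scalp"]]
  base[mask] <- tm[["gm"]]
  base[mask & wm] <- tm[["wm"]]
  base[mask & csf] <- tm[["csf"]]
  # tube centreline along the dorsal surface at constant depth
  yb <- solve_bregma_y(ax)
  zc <- dorsal_surface(yv, ax) - spec$tube_center_depth
  tube_range <- c(yb - 7.0, yb + 0.8)
  in_range <- !is.na(zc) & yv >= tube_range[1] & yv <= tube_range[2]
  t1 <- outer(ifelse(in_range, zc, Inf), zv,
              function(a, b) ifelse(is.finite(a), (b - a)^2, Inf))
  rho <- sqrt(outer(xv^2, t1, "+"))
  d_base <- spec$tube_diameter_by_day[[1]]
  frac <- tube_fraction(rho, d_base / 2, h)
  template <- base * (1 - frac) + tm[["vessel"]] * frac
  # bregma above the rostral seed's centreline point
  zr <- dorsal_surface(yb - 0.22, ax) - spec$tube_center_depth
  frame <- bregma_frame(c(0, yb, zr + 1.07))
  # labels: tube region plus contiguous parcels of the remaining mask
  tube_lab <- frac > 0.5 & mask
  labels <- array(0L, dim = d)
  parcel_vox <- which(mask & !tube_lab)
  labels[parcel_vox] <- partition_parcels(arrayInd(parcel_vox, d),
                                          spec$n_regions - 1L)
  labels[tube_lab] <- spec$n_regions
  region_names <- tibble(
    label = seq_len(spec$n_regions),
    name = c(paste0("parcel_", seq_len(spec$n_regions - 1L)),
             "superior_sagittal_sinus")
  )
  atlas <- label_volume(labels, mask | tube_lab, aff, region_names)
  meta <- list(base = base, rho = rho, mask = mask, affine = aff,
               xv = xv, yv = yv, zv = zv, h = h, semiaxes = ax,
               # dorsal subarachnoid shell, restricted to the cortex near
               # the impact site (it must not overlap the caudal
               # measurement site)
               sa_shell = re2 <= 1 & sqrt(re2) > 1 - 0.35 / mean(ax) &
                 array(rep(zv > 0, each = d[1] * d[2]), dim = d) &
                 array(rep(rep(yv > yb - 3 & yv < yb + 1.5, each = d[1]),
                           times = d[3]), dim = d),
               tube_range = tube_range, y_bregma = yb)
  structure(
    list(template = volume_image(template, aff, "OTHER"), atlas = atlas,
         frame = frame, spec = spec, meta = meta),
    class = "atlas_phantom"
  )
}

# sub-voxel partial-volume fraction of the tube at centreline distance rho
tube_fraction <- function(rho, radius, h) {
  pmin(1, pmax(0, (radius - rho) / h + 0.5))
}

# split voxel coordinates into exactly n contiguous, nonempty parcels by
# nested equal-count slab splits (rostro-caudal, then dorso-ventral)
partition_parcels <- function(coords, n) {
  m <- nrow(coords)
  stopifnot(m >= n)
  k <- max(1L, as.integer(floor(sqrt(n))))
  per_slab <- diff(round(seq(0, n, length.out = k + 1)))
  ord_y <- order(coords[, 2], coords[, 3], coords[, 1])
  slab_sizes <- diff(round(seq(0, m, length.out = k + 1)))
  out <- integer(m)
  nxt <- 1L
  pos <- 0L
  for (s in seq_len(k)) {
    vox <- ord_y[(pos + 1):(pos + slab_sizes[s])]
    pos <- pos + slab_sizes[s]
    nsub <- per_slab[s]
    ord_z <- vox[order(coords[vox, 3], coords[vox, 1], coords[vox, 2])]
    sub_sizes <- diff(round(seq(0, length(vox), length.out = nsub + 1)))
    p2 <- 0L
    for (t in seq_len(nsub)) {
      out[ord_z[(p2 + 1):(p2 + sub_sizes[t])]] <- nxt
      nxt <- nxt + 1L
      p2 <- p2 + sub_sizes[t]
    }
  }
  out
}

#' Per-subject, per-session acquisition truth
#'
#' @param subject_id Subject identifier.
#' @param day Day label (`B1`, `B2`, `P1`, `P2`, `P7`, `P14`).
#' @param true_affine 4x4 subject pose/size map (atlas world to subject
#'   world).
#' @param true_rigid_jitter 4x4 per-session rigid map (orthonormal rotation,
#'   det +1).
#' @param fov_shift Field-of-view shift along the slice axis, mm.
#' @return An object of class `subject_session`.
#' @export
subject_session <- function(subject_id, day, true_affine = diag(4),
                            true_rigid_jitter = diag(4), fov_shift = 0) {
  if (!is_rigid(true_rigid_jitter))
    stop("`true_rigid_jitter` must be rigid (orthonormal rotation, det +1)",
         call. = FALSE)
  structure(
    list(subject_id = subject_id, day = day,
         true_affine = unname(true_affine),
         true_rigid_jitter = unname(true_rigid_jitter),
         fov_shift = fov_shift),
    class = "subject_session"
  )
}

# deterministic 31-bit seed from a base seed and a string key
stable_seed <- function(base, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer((base %% 2147483647) * 69069 %% 2147483647 + h) %% 2147483647L
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# draw a random subject pose / session jitter, seeded deterministically
random_session <- function(spec, subject_id, day) {
  pose <- with_local_seed(
    stable_seed(spec$rng_seed, paste0("pose/", subject_id)), {
      p <- c(runif(3, -2, 2) * pi / 180, runif(3, -0.5, 0.5))
      M <- transform_matrix_from_params(c(p, log(rnorm(3, 1, 0.03)),
                                          runif(3, -0.02, 0.02)),
                                        c(0, 0, 0), "affine")
      M
    })
  jit <- with_local_seed(
    stable_seed(spec$rng_seed, paste0("jitter/", subject_id, "/", day)), {
      transform_matrix_from_params(c(runif(3, -0.5, 0.5) * pi / 180,
                                     runif(3, -0.3, 0.3)),
                                   c(0, 0, 0), "rigid")
    })
  fov <- with_local_seed(
    stable_seed(spec$rng_seed, paste0("fov/", subject_id, "/", day)),
    runif(1, -1, 1))
  subject_session(subject_id, day, pose, jit, fov)
}

#' Synthesize one anisotropic scan from the phantom
#'
#' Applies, in order: the day-dependent effects (tube dilation to the
#' configured diameter; for post-contrast scans, vessel lumen, subarachnoid
#' shell and focal enhancements), the subject pose and per-session rigid
#' jitter with FOV shift, boxcar slice-profile averaging over the slice
#' thickness sampled at the slice spacing (gap tissue is never observed), a
#' smooth multiplicative bias field (exponential of a random order-2
#' polynomial scaled to `bias_amplitude`), and additive Gaussian noise. All
#' randomness is derived deterministically from the spec's `rng_seed` and
#' the (subject, day, modality) key.
#'
#' @param phantom An [make_atlas_phantom()] result.
#' @param session A [subject_session()].
#' @param geom A [scan_geometry()].
#' @param modality Scan modality.
#' @param day Day label; must be present in the spec's
#'   `tube_diameter_by_day`.
#' @return A [volume_image()] on the scan grid; the truth parameters are
#'   attached as attribute `truth` (list with `pose` = composite
#'   atlas-to-scan world map, `tube_diameter`, `fov_shift`).
#' @export
synthesize_scan <- function(phantom, session, geom, modality, day) {
  stopifnot(inherits(phantom, "atlas_phantom"),
            inherits(session, "subject_session"),
            inherits(geom, "scan_geometry"))
  spec <- phantom$spec
  modality <- match.arg(modality, modality_levels())
  if (!day %in% names(spec$tube_diameter_by_day))
    stop("undefined modality/day combination: no tube diameter configured ",
         "for day ", day, call. = FALSE)
  meta <- phantom$meta
  ideal <- day_effect_volume(phantom, day, modality)
  W <- session$true_rigid_jitter %*% session$true_affine  # atlas -> scanner
  ax <- slice_axis(geom)
  sp <- rep(geom$in_plane_spacing, 3)
  sp[ax] <- geom$slice_spacing
  centre <- as.numeric(apply_chain(W, c(0, 0, 0)))
  centre[ax] <- centre[ax] + session$fov_shift
  dims <- integer(3)
  for (a in 1:3) {
    if (a == ax) {
      dims[a] <- if (!is.null(geom$n_slices)) geom$n_slices else {
        ext <- 2 * spec$brain_semiaxes[c(1, 2, 3)][a] + 3
        max(1L, as.integer(ceiling(ext / sp[a])))
      }
    } else {
      dims[a] <- max(1L, as.integer(round(geom$fov / sp[a])))
    }
  }
  G <- diag(c(sp, 1))
  G[1:3, 4] <- centre - sp * (dims - 1) / 2
  # boxcar slice profile: average several sub-slab offsets along slice axis
  n_prof <- 5L
  offs <- (seq_len(n_prof) - (n_prof + 1) / 2) / n_prof *
    geom$slice_thickness
  acc <- array(0, dim = dims)
  src_aff <- W %*% meta$affine
  for (o in offs) {
    Go <- G
    Go[ax, 4] <- Go[ax, 4] + o
    res <- resample_array(ideal, src_aff, Go, dims, "linear")
    acc <- acc + res$data
  }
  data <- acc / n_prof
  key <- paste0("scan/", session$subject_id, "/", day, "/", modality, "/",
                geom$plane)
  data <- with_local_seed(stable_seed(spec$rng_seed, key), {
    if (spec$bias_amplitude > 0) {
      coords <- lapply(seq_len(3), function(a)
        (seq_len(dims[a]) - (dims[a] + 1) / 2) / pmax(dims[a] / 2, 1))
      Xf <- as.matrix(expand.grid(coords[[1]], coords[[2]], coords[[3]]))
      B <- poly_basis(Xf, 2L)
      cf <- rnorm(ncol(B))
      p <- as.numeric(B %*% cf)
      p <- p / max(abs(p)) * log1p(spec$bias_amplitude)
      data <- data * array(exp(p), dim = dims)
    }
    if (spec$noise_sigma > 0)
      data <- data + rnorm(length(data), 0, spec$noise_sigma)
    data
  })
  out <- volume_image(data, G, modality)
  attr(out, "truth") <- list(pose = W, tube_diameter =
                               spec$tube_diameter_by_day[[day]],
                             fov_shift = session$fov_shift, day = day)
  out
}

# noise-free, bias-free ideal volume on the atlas grid for a given day and
# modality (day effects applied; no pose, no slicing)
day_effect_volume <- function(phantom, day, modality) {
  spec <- phantom$spec
  meta <- phantom$meta
  tm <- spec$tissue_means
  r_base <- spec$tube_diameter_by_day[[1]] / 2
  r_day <- spec$tube_diameter_by_day[[day]] / 2
  if (is.null(spec$dilation_rc_range) || r_day == r_base) {
    radius <- r_day
  } else {
    # restrict dilation to the configured rostro-caudal extent with a
    # 0.5 mm taper
    rc <- meta$yv - phantom$frame$bregma_world[2]
    w <- pmin(1, pmax(0, (rc - spec$dilation_rc_range[1]) / 0.5)) *
      pmin(1, pmax(0, (spec$dilation_rc_range[2] - rc) / 0.5))
    r_eff <- r_base + (r_day - r_base) * w
    d <- dim(meta$rho)
    radius <- array(rep(rep(r_eff, each = d[1]), times = d[3]), dim = d)
  }
  frac <- tube_fraction(meta$rho, radius, meta$h)
  ideal <- meta$base * (1 - frac) + tm[["vessel"]] * frac
  if (modality == "GRE_POST") {
    venh <- lookup_day(spec$vessel_enhancement_by_day, day)
    if (venh != 0) ideal <- ideal + venh * frac
    samp <- lookup_day(spec$sa_enhancement_by_day, day)
    if (samp != 0) ideal <- ideal + samp * meta$sa_shell
    for (fe in spec$focal_effects) {
      if (!day %in% fe$days) next
      cw <- bregma_offset_to_world(fe$center, phantom$frame)
      d2 <- outer(outer((meta$xv - cw[1])^2, (meta$yv - cw[2])^2, "+"),
                  (meta$zv - cw[3])^2, "+")
      bfrac <- pmin(1, pmax(0, (fe$radius - sqrt(d2)) / meta$h + 0.5))
      ideal <- ideal + fe$amplitude * bfrac
    }
  }
  ideal
}

lookup_day <- function(tbl, day) {
  if (!is.null(tbl) && day %in% names(tbl)) tbl[[day]] else 0
}

#' Generate and write a full synthetic study
#'
#' Writes NIfTI volumes plus JSON sidecars for every (subject, day, scan
#' type) combination, the phantom atlas files, and a TSV manifest carrying
#' the truth parameters needed for recovery tests. Baseline days B1 and B2
#' are both generated, so a study of `n_subjects` has a baseline group of
#' `2 * n_subjects` scans per scan type.
#'
#' @param spec A [phantom_spec()].
#' @param n_subjects Number of subjects (>= 2).
#' @param out_dir Output directory (created if needed).
#' @param scan_types Named list of scan types; each element is a list with
#'   `modality` and `geom`. The default provides an anisotropic T2-weighted
#'   scan (1.0 mm slices at 1.5 mm spacing) and a gap-free gradient-echo
#'   pre/post contrast pair (1.0 mm slices at 1.0 mm spacing).
#' @param days Day labels to generate.
#' @return The study manifest as a tibble (also written to
#'   `study_manifest.tsv`), with the `atlas_phantom` attached as attribute
#'   `phantom`.
#' @export
make_study <- function(spec, n_subjects, out_dir,
                       scan_types = default_scan_types(),
                       days = study_days()) {
  stopifnot(inherits(spec, "phantom_spec"), n_subjects >= 2)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  phantom <- make_atlas_phantom(spec)
  write_phantom_atlas(phantom, out_dir)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("sub%02d", s)
    for (day in days) {
      session <- random_session(spec, sid, day)
      for (tn in names(scan_types)) {
        st <- scan_types[[tn]]
        scan <- synthesize_scan(phantom, session, st$geom, st$modality, day)
        fn <- sprintf("%s_%s_%s.nii.gz", sid, day, tn)
        write_volume(scan, file.path(out_dir, fn),
                     sidecar = list(subject = sid, day = day,
                                    plane = st$geom$plane))
        truth <- attr(scan, "truth")
        rows[[length(rows) + 1]] <- tibble(
          file = fn, subject = sid, day = day, scan_type = st$modality,
          type_name = tn, plane = st$geom$plane,
          fov_shift = session$fov_shift,
          tube_diameter = truth$tube_diameter,
          pose = paste(signif(as.numeric(t(truth$pose)), 12),
                       collapse = " ")
        )
      }
    }
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.table(manifest, file.path(out_dir, "study_manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  attr(manifest, "phantom") <- phantom
  manifest
}

#' Default scan-type set for synthetic studies
#' @return Named list of scan types for [make_study()].
#' @export
default_scan_types <- function() {
  list(
    T2W_axial = list(modality = "T2W",
                     geom = scan_geometry(plane = "axial")),
    GRE_pre = list(modality = "GRE_PRE",
                   geom = scan_geometry(slice_thickness = 1, slice_spacing = 1,
                                        plane = "axial")),
    GRE_post = list(modality = "GRE_POST",
                    geom = scan_geometry(slice_thickness = 1, slice_spacing = 1,
                                         plane = "axial"))
  )
}

write_phantom_atlas <- function(phantom, out_dir) {
  spec <- phantom$spec
  yaml::write_yaml(
    lapply(unclass(spec), function(x) if (is.matrix(x)) as.numeric(x) else x),
    file.path(out_dir, "phantom_spec.yaml"))
  write_volume(phantom$template, file.path(out_dir, "template.nii.gz"))
  lab <- volume_image(phantom$atlas$labels + 0, phantom$atlas$affine)
  write_volume(lab, file.path(out_dir, "atlas_labels.nii.gz"))
  msk <- volume_image(phantom$atlas$brain_mask + 0, phantom$atlas$affine)
  write_volume(msk, file.path(out_dir, "atlas_mask.nii.gz"))
  utils::write.table(phantom$atlas$region_names,
                     file.path(out_dir, "atlas_regions.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(bregma_world = phantom$frame$bregma_world),
                       file.path(out_dir, "frame.json"), digits = NA)
  invisible(out_dir)
}

#' Read the truth pose matrix from a manifest row
#' @param manifest_row One row of a [make_study()] manifest.
#' @return 4x4 matrix (atlas world to scanner world).
#' @export
manifest_pose <- function(manifest_row) {
  matrix(as.numeric(strsplit(manifest_row$pose, " ")[[1]]), 4, 4,
         byrow = TRUE)
}

#' Straight-tube phantom at isotropic resolution
#'
#' A zero-noise volume containing a straight high-contrast tube along the
#' rostro-caudal axis, with sub-voxel partial-volume rendering of the tube
#' boundary (in-plane supersampling). Used to validate the sphere-growing
#' caliber estimator against analytic truth.
#'
#' @param diameter Tube diameter in mm.
#' @param spacing Isotropic voxel spacing in mm.
#' @param extent Volume extent `c(x, y, z)` in mm.
#' @param intensities `c(bg, tube)` intensities.
#' @param supersample In-plane supersampling factor per axis.
#' @return List with `image` ([volume_image()]), `frame` (bregma at the tube
#'   centre so the seed offset `c(0, 0, 0)` lies on the axis) and
#'   `diameter`.
#' @export
make_tube_phantom <- function(diameter, spacing = 0.1367,
                              extent = c(6, 10, 6),
                              intensities = c(bg = 100, tube = 1000),
                              supersample = 4L) {
  stopifnot(diameter > 0, spacing > 0)
  d <- as.integer(ceiling(extent / spacing))
  aff <- diag(c(spacing, spacing, spacing, 1))
  aff[1:3, 4] <- -spacing * (d - 1) / 2
  xv <- aff[1, 4] + spacing * (0:(d[1] - 1))
  zv <- aff[3, 4] + spacing * (0:(d[3] - 1))
  ss <- (seq_len(supersample) - (supersample + 1) / 2) / supersample * spacing
  frac2d <- matrix(0, d[1], d[3])
  r2 <- (diameter / 2)^2
  for (ox in ss) for (oz in ss) {
    frac2d <- frac2d + (outer((xv + ox)^2, (zv + oz)^2, "+") <= r2)
  }
  frac2d <- frac2d / supersample^2
  plane <- intensities[["bg"]] + (intensities[["tube"]] -
                                    intensities[["bg"]]) * frac2d
  data <- aperm(array(rep(plane, d[2]), dim = c(d[1], d[3], d[2])),
                c(1, 3, 2))
  list(image = volume_image(data, aff, "GRE_DIFF"),
       frame = bregma_frame(c(0, 0, 0)), diameter = diameter)
}
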