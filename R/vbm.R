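#' Gaussian smoothing of a normalized scan
#'
#' Separable Gaussian filtering with per-world-axis standard deviations in
#' mm. The default kernel corresponds to the coarsest original acquisition
#' resolution: 0.2734 mm in-plane (two voxels on the 0.1367 mm atlas grid,
#' since in-plane k-space was zero-filled) and 1.5 mm through-plane,
#' oriented by the scan's acquisition plane (`through_axis`).
#'
#' @param scan_in_atlas A [volume_image()] on an axis-aligned grid.
#' @param sigma Length-3 per-axis standard deviation in mm, or a length-2
#'   `c(in_plane, through_plane)` pair used with `through_axis`.
#' @param through_axis World axis (1-3) holding the through-plane sigma
#'   when `sigma` has length 2 (2 = rostro-caudal for axial stacks).
#' @return Smoothed [volume_image()].
#' @export
smooth_gaussian <- function(scan_in_atlas, sigma = c(0.2734, 1.5),
                            through_axis = 2L) {
  stopifnot(inherits(scan_in_atlas, "volume_image"))
  if (length(sigma) == 2) {
    s <- rep(sigma[1], 3)
    s[through_axis] <- sigma[2]
    sigma <- s
  }
  stopifnot(length(sigma) == 3, all(sigma > 0))
  sp <- voxel_spacing(scan_in_atlas)
  out <- cpp_gaussian_smooth(scan_in_atlas$data, sigma / sp)
  volume_image(out, scan_in_atlas$affine, scan_in_atlas$modality)
}

# stack a list of volume_image/arrays into a voxels x n matrix over mask
stack_to_matrix <- function(group, mask) {
  idx <- which(mask)
  cols <- lapply(group, function(g) {
    a <- if (inherits(g, "volume_image")) g$data else g
    a[idx]
  })
  do.call(cbind, cols)
}

#' Voxelwise pooled two-sample t map
#'
#' Pooled-variance, two-tailed Student's t at every masked voxel comparing
#' a post-injury group against the baseline group; `t > 0` where the
#' post-injury mean exceeds baseline. Voxels with zero pooled variance get
#' `t = 0`.
#'
#' @param group_post,group_base Lists of [volume_image()] (or 3D arrays) on
#'   a common atlas grid, one element per sample.
#' @param mask Logical analysis mask (e.g. the atlas brain mask).
#' @return List with `t_map` (array, `NA` outside the mask), `df`,
#'   `n_post`, `n_base`.
#' @export
voxelwise_ttest <- function(group_post, group_base, mask) {
  mask <- as.logical(mask)
  dims <- dim(if (inherits(group_post[[1]], "volume_image"))
    group_post[[1]]$data else group_post[[1]])
  A <- stack_to_matrix(group_post, array(mask, dims))
  B <- stack_to_matrix(group_base, array(mask, dims))
  nA <- ncol(A); nB <- ncol(B)
  stopifnot(nA >= 2, nB >= 2)
  df <- nA + nB - 2
  mA <- rowMeans(A); mB <- rowMeans(B)
  ssA <- rowSums((A - mA)^2); ssB <- rowSums((B - mB)^2)
  sp2 <- (ssA + ssB) / df
  t <- ifelse(sp2 > 0, (mA - mB) / sqrt(sp2 * (1 / nA + 1 / nB)), 0)
  t_map <- array(NA_real_, dim = dims)
  t_map[which(mask)] <- t
  list(t_map = t_map, df = df, n_post = nA, n_base = nB)
}

#' Form suprathreshold clusters from a t map
#'
#' Thresholds at the two-tailed critical value for `p_voxel` and labels
#' connected components separately among positive and negative
#' suprathreshold voxels.
#'
#' @param t_map 3D array of t values (`NA` treated as subthreshold).
#' @param df Degrees of freedom.
#' @param p_voxel Two-tailed uncorrected voxelwise p threshold.
#' @param connectivity 6, 18 or 26.
#' @return Tibble with one row per cluster (`cluster_id`, `sign`, `size`,
#'   `max_t`, `peak_voxel` 0-based index columns `pi`, `pj`, `pk`), sorted
#'   by decreasing size, with the signed label array as attribute `labels`
#'   and the threshold as attribute `t_crit`.
#' @export
form_clusters <- function(t_map, df, p_voxel = 0.001, connectivity = 26L) {
  stopifnot(p_voxel > 0, p_voxel < 1)
  t_crit <- qt(1 - p_voxel / 2, df)
  tm <- t_map
  tm[!is.finite(tm)] <- 0
  out <- list()
  labarr <- array(0L, dim = dim(tm))
  next_id <- 0L
  for (sgn in c(1, -1)) {
    m <- if (sgn > 0) tm >= t_crit else tm <= -t_crit
    if (!any(m)) next
    lab <- cpp_label_components(m, as.integer(connectivity))
    k <- max(lab)
    for (cl in seq_len(k)) {
      vox <- which(lab == cl)
      tv <- tm[vox]
      peak <- vox[which.max(abs(tv))]
      pidx <- arrayInd(peak, dim(tm)) - 1L
      next_id <- next_id + 1L
      labarr[vox] <- next_id * as.integer(sgn)
      out[[next_id]] <- tibble(
        cluster_id = next_id, sign = sgn, size = length(vox),
        max_t = tv[which.max(abs(tv))],
        pi = pidx[1], pj = pidx[2], pk = pidx[3])
    }
  }
  res <- if (length(out)) dplyr::arrange(dplyr::bind_rows(out),
                                         dplyr::desc(.data$size))
         else tibble(cluster_id = integer(), sign = numeric(),
                     size = integer(), max_t = numeric(), pi = integer(),
                     pj = integer(), pk = integer())
  attr(res, "labels") <- labarr
  attr(res, "t_crit") <- t_crit
  res
}

#' Permutation-calibrated cluster-size cutoff
#'
#' Estimates the null distribution of the maximum suprathreshold cluster
#' size by randomly reassigning group labels (preserving group sizes),
#' recomputing the pooled t map, and forming clusters at the voxelwise
#' threshold; positive and negative clusters share a single two-sided null
#' (the maximum over both signs). The cutoff is the
#' `ceiling((1 - alpha_cluster) * N)`-th order statistic of the null
#' maximum sizes; clusters smaller than the cutoff are excluded downstream
#' (`size >= cutoff` survives).
#'
#' @param group_post,group_base Sample lists as in [voxelwise_ttest()].
#' @param mask Logical analysis mask.
#' @param cfg A [stat_config()].
#' @param rng_seed Optional integer seed for reproducible permutations.
#' @return List with `cutoff` (voxels), `null_max_sizes`, `t_crit`, `df`,
#'   `n_permutations`, `rng_seed`.
#' @export
permutation_cluster_threshold <- function(group_post, group_base, mask,
                                          cfg = stat_config(),
                                          rng_seed = NULL) {
  mask <- as.logical(mask)
  if (cfg$n_permutations < 1 / cfg$alpha_cluster)
    stop("too few permutations (", cfg$n_permutations,
         ") to calibrate alpha_cluster = ", cfg$alpha_cluster, call. = FALSE)
  dims <- dim(if (inherits(group_post[[1]], "volume_image"))
    group_post[[1]]$data else group_post[[1]])
  maskarr <- array(mask, dims)
  A <- stack_to_matrix(group_post, maskarr)
  B <- stack_to_matrix(group_base, maskarr)
  data <- cbind(A, B)
  df <- ncol(data) - 2
  t_crit <- qt(1 - cfg$p_voxel / 2, df)
  voxidx0 <- which(maskarr) - 1L
  if (!is.null(rng_seed)) set.seed(rng_seed)
  null_sizes <- cpp_perm_max_cluster(data, ncol(A), voxidx0,
                                     as.integer(dims), t_crit,
                                     cfg$connectivity, cfg$n_permutations)
  sorted <- sort(null_sizes)
  k <- max(1L, as.integer(ceiling((1 - cfg$alpha_cluster) *
                                    cfg$n_permutations)))
  list(cutoff = sorted[k], null_max_sizes = null_sizes, t_crit = t_crit,
       df = df, n_permutations = cfg$n_permutations, rng_seed = rng_seed)
}

#' Report surviving clusters in stereotaxic coordinates
#'
#' Filters clusters by the calibrated size cutoff and reports each with its
#' size, signed peak t, peak location as a bregma offset (RL, VD, RC) and
#' the atlas region name at the peak. Direction is `hyper` for positive
#' peaks (day > baseline) and `hypo` for negative.
#'
#' @param clusters [form_clusters()] output.
#' @param cutoff Cluster-size cutoff (voxels) from
#'   [permutation_cluster_threshold()].
#' @param atlas A [label_volume()] on the t-map grid.
#' @param frame A [bregma_frame()].
#' @param contrast Contrast label, e.g. `"P1_vs_B"`.
#' @return Tibble with columns `contrast`, `size`, `max_t`, `RL`, `VD`,
#'   `RC`, `region_name`, `direction`.
#' @export
report_clusters <- function(clusters, cutoff, atlas, frame,
                            contrast = "day_vs_B") {
  surv <- dplyr::filter(clusters, .data$size >= cutoff)
  if (nrow(surv) == 0)
    return(tibble(contrast = character(), size = integer(),
                  max_t = numeric(), RL = numeric(), VD = numeric(),
                  RC = numeric(), region_name = character(),
                  direction = character()))
  peaks <- as.matrix(surv[, c("pi", "pj", "pk")])
  w <- voxel_to_world(atlas$affine, peaks)
  off <- world_to_bregma_offset(w, frame)
  labs <- atlas$labels[peaks + 1L]
  nm <- atlas$region_names$name[match(labs, atlas$region_names$label)]
  nm[is.na(nm)] <- "outside_atlas"
  tibble(contrast = contrast, size = surv$size, max_t = surv$max_t,
         RL = off[, "RL"], VD = off[, "VD"], RC = off[, "RC"],
         region_name = nm,
         direction = ifelse(surv$max_t > 0, "hyper", "hypo"))
}

#' Full voxel-based morphometry contrast
#'
#' Runs the VBM stage for one day-versus-baseline contrast on smoothed,
#' normalized scans: voxelwise pooled t map, cluster formation at the
#' uncorrected voxelwise threshold, permutation calibration of the
#' cluster-size cutoff at the corrected alpha, and reporting of surviving
#' clusters.
#'
#' @inheritParams permutation_cluster_threshold
#' @param atlas A [label_volume()] on the scan grid.
#' @param frame A [bregma_frame()].
#' @param contrast Contrast label.
#' @return An object of class `vbm_result` with elements `table`
#'   (surviving-cluster tibble), `clusters` (all formed clusters), `t_map`,
#'   `df`, `cutoff`, `null_max_sizes`, `config`.
#' @export
vbm_contrast <- function(group_post, group_base, mask, atlas, frame,
                         cfg = stat_config(), contrast = "day_vs_B",
                         rng_seed = NULL) {
  tt <- voxelwise_ttest(group_post, group_base, mask)
  cl <- form_clusters(tt$t_map, tt$df, cfg$p_voxel, cfg$connectivity)
  perm <- permutation_cluster_threshold(group_post, group_base, mask, cfg,
                                        rng_seed)
  tab <- report_clusters(cl, perm$cutoff, atlas, frame, contrast)
  structure(
    list(table = tab, clusters = cl, t_map = tt$t_map, df = tt$df,
         cutoff = perm$cutoff, null_max_sizes = perm$null_max_sizes,
         config = cfg, contrast = contrast, rng_seed = rng_seed),
    class = "vbm_result"
  )
}

#' @export
print.vbm_result <- function(x, ...) {
  cat(sprintf("<vbm_result> %s: %d surviving cluster(s), cutoff %d voxels (df = %d)\n",
              x$contrast, nrow(x$table), x$cutoff, x$df))
  if (nrow(x$table)) print(x$table)
  invisible(x)
}

#' @describeIn vbm_contrast Tidy the surviving-cluster table.
#' @param x A `vbm_result`.
#' @param ... Unused.
#' @export
tidy.vbm_result <- function(x, ...) {
  x$table
}

#' @describeIn vbm_contrast One-row summary (cutoff, cluster counts).
#' @export
glance.vbm_result <- function(x, ...) {
  tibble(contrast = x$contrast, df = x$df, cutoff = x$cutoff,
         n_clusters_formed = nrow(x$clusters),
         n_clusters_surviving = nrow(x$table),
         n_permutations = x$config$n_permutations)
}
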