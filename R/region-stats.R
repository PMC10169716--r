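#' Statistical configuration for group comparisons
#'
#' Houses the thresholds used throughout the group analyses: FDR level for
#' the region-based tests, cluster-forming voxelwise p, corrected
#' cluster-level alpha, and the permutation count for cluster-size
#' calibration.
#'
#' @param alpha_fdr FDR level across regions.
#' @param alpha_cluster Corrected cluster-level alpha.
#' @param p_voxel Two-tailed uncorrected voxelwise cluster-forming p.
#' @param n_permutations Label permutations for the cluster-size null
#'   (>= 100).
#' @param connectivity Cluster connectivity: 6, 18 or 26.
#' @return An object of class `stat_config`.
#' @export
stat_config <- function(alpha_fdr = 0.05, alpha_cluster = 0.05,
                        p_voxel = 0.001, n_permutations = 10000L,
                        connectivity = 26L) {
  stopifnot(alpha_fdr > 0, alpha_fdr < 1, alpha_cluster > 0,
            alpha_cluster < 1, p_voxel > 0, p_voxel < 1,
            n_permutations >= 100, connectivity %in% c(6L, 18L, 26L))
  structure(list(alpha_fdr = alpha_fdr, alpha_cluster = alpha_cluster,
                 p_voxel = p_voxel,
                 n_permutations = as.integer(n_permutations),
                 connectivity = as.integer(connectivity)),
            class = "stat_config")
}

#' Mean intensity per atlas region
#'
#' @param scan_in_atlas A [volume_image()] on the atlas grid.
#' @param atlas A [label_volume()] on the same grid.
#' @param validity Optional logical array restricting to validly observed
#'   voxels (defaults to the scan's `validity` attribute, else all voxels).
#' @return Tibble with columns `label`, `name`, `mean` (`NA` when a region
#'   has no valid voxels) and `n_valid`.
#' @export
region_means <- function(scan_in_atlas, atlas, validity = NULL) {
  stopifnot(inherits(scan_in_atlas, "volume_image"),
            inherits(atlas, "label_volume"),
            identical(dim(scan_in_atlas$data), dim(atlas$labels)))
  if (is.null(validity)) validity <- attr(scan_in_atlas, "validity")
  if (is.null(validity)) validity <- array(TRUE, dim = dim(atlas$labels))
  keep <- atlas$labels > 0 & validity
  labs <- atlas$labels[keep]
  vals <- scan_in_atlas$data[keep]
  ids <- atlas$region_names$label
  sums <- vapply(split(vals, factor(labs, levels = ids)), sum, 0)
  ns <- tabulate(factor(labs, levels = ids), nbins = length(ids))
  tibble(label = ids, name = atlas$region_names$name,
         mean = ifelse(ns > 0, sums / ns, NA_real_), n_valid = ns)
}

# pooled-variance two-sample t (classical Student form); returns t, df, p.
# Degenerate zero-variance cases: equal means -> t = 0, p = 1; unequal
# means -> p = 0, flagged degenerate.
pooled_t_stat <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2)
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                degenerate = FALSE, n_x = nx, n_y = ny))
  df <- nx + ny - 2
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / df
  dm <- mean(x) - mean(y)
  if (sp2 <= 0) {
    if (dm == 0)
      return(list(t = 0, df = df, p = 1, degenerate = FALSE,
                  n_x = nx, n_y = ny))
    return(list(t = sign(dm) * Inf, df = df, p = 0, degenerate = TRUE,
                n_x = nx, n_y = ny))
  }
  t <- dm / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, df = df, p = 2 * pt(-abs(t), df), degenerate = FALSE,
       n_x = nx, n_y = ny)
}

#' Region-wise two-sample group test with FDR correction
#'
#' Pooled-variance, two-tailed Student's t-test per region comparing a
#' post-injury day group against the baseline group, followed by
#' Benjamini-Hochberg FDR correction across regions. The t statistic is
#' positive when the day mean exceeds the baseline mean. Regions with fewer
#' than two valid samples in either group (possible when interslice gaps
#' leave a region unobserved) are dropped listwise, with the per-region `n`
#' reported.
#'
#' @param means_B Samples x regions matrix of baseline per-region means
#'   (`NA` for unobserved regions).
#' @param means_day Samples x regions matrix for the post-injury day group.
#' @param cfg A [stat_config()].
#' @param region_names Optional tibble with `label`, `name` matching the
#'   columns.
#' @param contrast Label for the comparison, e.g. `"P1_vs_B"`.
#' @return Tibble with one row per region: `region_id`, `region_name`,
#'   `contrast`, `n_B`, `n_day`, `mean_B`, `mean_day`, `t`, `p`, `q`,
#'   `significant`, `degenerate`.
#' @export
region_group_test <- function(means_B, means_day, cfg = stat_config(),
                              region_names = NULL, contrast = "day_vs_B") {
  means_B <- as.matrix(means_B)
  means_day <- as.matrix(means_day)
  stopifnot(ncol(means_B) == ncol(means_day))
  m <- ncol(means_B)
  res <- lapply(seq_len(m), function(j)
    pooled_t_stat(means_day[, j], means_B[, j]))
  out <- tibble(
    region_id = if (!is.null(region_names)) region_names$label
                else seq_len(m),
    region_name = if (!is.null(region_names)) region_names$name
                  else colnames(means_B) %||% paste0("region_", seq_len(m)),
    contrast = contrast,
    n_B = vapply(res, function(r) r$n_y, 0L),
    n_day = vapply(res, function(r) r$n_x, 0L),
    mean_B = colMeans(means_B, na.rm = TRUE),
    mean_day = colMeans(means_day, na.rm = TRUE),
    t = vapply(res, function(r) r$t, 0),
    p = vapply(res, function(r) r$p, 0),
    degenerate = vapply(res, function(r) r$degenerate, FALSE)
  )
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$q) & out$q <= cfg$alpha_fdr
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
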