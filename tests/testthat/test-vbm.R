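atlas_vol <- function(data) {
  volume_image(data, diag(c(0.1367, 0.1367, 0.1367, 1)))
}

test_that("Gaussian smoothing preserves constants and matches the analytic kernel", {
  cst <- atlas_vol(array(4, c(16, 16, 16)))
  sm <- smooth_gaussian(cst, sigma = c(0.2734, 1.5) / 2)
  inner <- sm$data[6:11, 6:11, 6:11]
  expect_equal(inner, array(4, dim(inner)), tolerance = 1e-9)

  # unit impulse reproduces the dense separable Gaussian
  d <- c(33, 33, 33)
  imp <- array(0, d); imp[17, 17, 17] <- 1
  sig_vox <- c(2, 2, 3)
  got <- ratvbm:::cpp_gaussian_smooth(imp, sig_vox)
  k <- function(s) {
    r <- ceiling(4 * s)
    kk <- exp(-0.5 * ((-r:r) / s)^2)
    kk / sum(kk)
  }
  expected <- outer(outer(k(2), k(2)), k(3))
  idx <- 17 + (-4:4)
  expect_equal(got[idx, idx, idx],
               expected[9 + (-4:4), 9 + (-4:4), 13 + (-4:4)],
               tolerance = 1e-6)
  # intensity integral preserved within boundary renormalisation effects
  expect_equal(sum(got), 1, tolerance = 1e-3)

  # the default in-plane sigma equals two voxels on the 0.1367 mm grid
  expect_equal(0.2734 / 0.1367, 2)
})

test_that("voxelwise t agrees with the region-test oracle per voxel", {
  set.seed(5)
  dims <- c(6, 5, 4)
  mask <- array(TRUE, dims)
  gp <- replicate(6, array(rnorm(prod(dims)), dims), simplify = FALSE)
  gb <- replicate(8, array(rnorm(prod(dims)), dims), simplify = FALSE)
  tt <- voxelwise_ttest(gp, gb, mask)
  expect_equal(tt$df, 12)
  v <- c(2, 3, 2)
  x <- sapply(gp, function(a) a[v[1], v[2], v[3]])
  y <- sapply(gb, function(a) a[v[1], v[2], v[3]])
  expect_equal(tt$t_map[v[1], v[2], v[3]],
               ratvbm:::pooled_t_stat(x, y)$t, tolerance = 1e-12)
  # identical groups give a zero map
  t0 <- voxelwise_ttest(gp, gp, mask)
  expect_true(all(t0$t_map[mask] == 0))
  # outside the mask the map is undefined
  m2 <- mask; m2[1, , ] <- FALSE
  t2 <- voxelwise_ttest(gp, gb, m2)
  expect_true(all(is.na(t2$t_map[1, , ])))
})

test_that("cluster formation counts components by sign and connectivity", {
  dims <- c(20, 20, 20)
  tm <- array(0, dims)
  cl0 <- form_clusters(tm, df = 28)
  expect_equal(nrow(cl0), 0)

  # one suprathreshold 3x3x3 cube
  tm[5:7, 5:7, 5:7] <- 10
  cl1 <- form_clusters(tm, df = 28)
  expect_equal(nrow(cl1), 1)
  expect_equal(cl1$size, 27L)
  expect_equal(cl1$max_t, 10)

  # negative blob is tracked separately with its sign
  tm[12:13, 12:13, 12:13] <- -8
  cl2 <- form_clusters(tm, df = 28)
  expect_equal(nrow(cl2), 2)
  expect_equal(sort(cl2$sign), c(-1, 1))
  expect_equal(cl2$max_t[cl2$sign == -1], -8)

  # two cubes touching only at a corner: one cluster at 26-connectivity,
  # two at 6-connectivity
  tm2 <- array(0, dims)
  tm2[4:5, 4:5, 4:5] <- 9
  tm2[6:7, 6:7, 6:7] <- 9
  expect_equal(nrow(form_clusters(tm2, 28, connectivity = 26L)), 1)
  expect_equal(nrow(form_clusters(tm2, 28, connectivity = 6L)), 2)

  # threshold equals the two-tailed critical value
  expect_equal(attr(form_clusters(tm, 28, 0.001), "t_crit"),
               qt(1 - 0.001 / 2, 28))

  # raising p_voxel (less strict) never shrinks a cluster
  set.seed(33)
  noisy <- array(rnorm(prod(dims), sd = 2), dims)
  strict <- form_clusters(noisy, 28, 0.001)
  loose <- form_clusters(noisy, 28, 0.01)
  if (nrow(strict) > 0) expect_gte(max(loose$size), max(strict$size))
})

test_that("permutation cutoff is deterministic, calibrated and monotone in alpha", {
  set.seed(17)
  dims <- c(16, 16, 16)
  mask <- array(TRUE, dims)
  gp <- replicate(6, array(rnorm(prod(dims)), dims), simplify = FALSE)
  gb <- replicate(8, array(rnorm(prod(dims)), dims), simplify = FALSE)
  cfg <- stat_config(n_permutations = 300)
  p1 <- permutation_cluster_threshold(gp, gb, mask, cfg, rng_seed = 7)
  p2 <- permutation_cluster_threshold(gp, gb, mask, cfg, rng_seed = 7)
  expect_identical(p1$null_max_sizes, p2$null_max_sizes)
  expect_identical(p1$cutoff, p2$cutoff)

  # alpha close to 1 selects the minimum of the null distribution
  loose <- stat_config(alpha_cluster = 0.995, n_permutations = 300)
  pl <- permutation_cluster_threshold(gp, gb, mask, loose, rng_seed = 7)
  expect_equal(pl$cutoff, min(pl$null_max_sizes))
  # raising alpha never increases the cutoff
  expect_lte(pl$cutoff, p1$cutoff)

  # too few permutations for the requested alpha errors out
  tiny <- stat_config(alpha_cluster = 0.001, n_permutations = 300)
  expect_error(permutation_cluster_threshold(gp, gb, mask, tiny), "too few")
})

test_that("an injected effect is detected and reported at the right place", {
  ph <- fixture_phantom()
  atlas <- ph$atlas
  dims <- dim(atlas$labels)
  mask <- atlas$brain_mask
  set.seed(40)
  # blob centred at a known bregma offset, 1.5 pooled-SD amplitude
  off <- c(RL = 1, VD = -2, RC = -1.5)
  cw <- bregma_offset_to_world(off, ph$frame)
  cv <- world_to_voxel(atlas$affine, cw)
  blob <- array(0, dims)
  ii <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                              seq_len(dims[3])))
  dist2 <- (ii[, 1] - 1 - cv[1])^2 + (ii[, 2] - 1 - cv[2])^2 +
    (ii[, 3] - 1 - cv[3])^2
  # graded effect peaking at the centre, ~1.5 SD over its core
  blob[] <- 2 * exp(-dist2 / (2 * (0.8 / 0.35)^2))
  blob[blob < 0.2] <- 0
  gb <- replicate(12, array(rnorm(prod(dims)), dims), simplify = FALSE)
  gp <- replicate(8, array(rnorm(prod(dims)), dims) + blob,
                  simplify = FALSE)
  tt <- voxelwise_ttest(gp, gb, mask)
  # voxels in the effect core dominate the surround
  core <- blob > 1 & mask
  outb <- blob == 0 & mask
  expect_gt(median(tt$t_map[core]),
            quantile(tt$t_map[outb], 0.99, na.rm = TRUE))
  cl <- form_clusters(tt$t_map, tt$df)
  cfg <- stat_config(n_permutations = 300)
  perm <- permutation_cluster_threshold(gp, gb, mask, cfg, rng_seed = 2)
  tab <- report_clusters(cl, perm$cutoff, atlas, ph$frame, "P1_vs_B")
  expect_gte(nrow(tab), 1)
  expect_equal(tab$direction[1], "hyper")
  # reported peak within 1 mm of the injected centre
  expect_lt(sqrt((tab$RL[1] - off[1])^2 + (tab$VD[1] - off[2])^2 +
                   (tab$RC[1] - off[3])^2), 1.0)
  expect_true(tab$region_name[1] %in% atlas$region_names$name)

  # a hypointense effect reports direction "hypo" with negative peak t
  gp2 <- replicate(8, array(rnorm(prod(dims)), dims) - blob,
                   simplify = FALSE)
  tt2 <- voxelwise_ttest(gp2, gb, mask)
  cl2 <- form_clusters(tt2$t_map, tt2$df)
  tab2 <- report_clusters(cl2, perm$cutoff, atlas, ph$frame, "P1_vs_B")
  expect_gte(nrow(tab2), 1)
  expect_equal(tab2$direction[1], "hypo")
  expect_lt(tab2$max_t[1], 0)

  # empty input reports an empty table
  expect_equal(nrow(report_clusters(form_clusters(array(0, dims), 18),
                                    1, atlas, ph$frame)), 0)
})

test_that("vbm_contrast bundles the stage with tidy and glance methods", {
  set.seed(77)
  dims <- c(14, 14, 14)
  mask <- array(TRUE, dims)
  mk <- function() atlas_vol(array(rnorm(prod(dims)), dims))
  gp <- replicate(5, mk(), simplify = FALSE)
  gb <- replicate(6, mk(), simplify = FALSE)
  atlas <- label_volume(array(1L, dims), array(TRUE, dims),
                        diag(c(0.1367, 0.1367, 0.1367, 1)),
                        tibble::tibble(label = 1L, name = "all"))
  res <- vbm_contrast(gp, gb, mask, atlas, bregma_frame(c(0, 0, 0)),
                      stat_config(n_permutations = 200), "P1_vs_B",
                      rng_seed = 11)
  expect_s3_class(res, "vbm_result")
  expect_identical(tidy(res), res$table)
  g <- glance(res)
  expect_equal(g$contrast, "P1_vs_B")
  expect_equal(g$df, 9)
  expect_s3_class(autoplot(res), "ggplot")
})
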