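test_that("atlas-guided skull stripping recovers the brain mask", {
  ph <- fixture_phantom()
  sc <- fixture_scan()
  truth <- fixture_scan_mask()
  res <- skull_strip_atlas_guided(sc, ph$atlas, template = ph$template)
  # identity pose: transform close to identity, mask matches the truth
  expect_rigid_close(res$transform_to_atlas, diag(4), 0.05, 0.5)
  expect_gt(dice(res$mask, truth), 0.98)
  expect_gt(res$objective_value, 0.5)

  # offset pose: 10 deg rotation, 2 mm shift, 5% scale
  S <- affine_param_matrix(rot_deg = c(10, 0, 0), trans = c(2, 0, 0),
                           scales = c(1.05, 1.05, 1.05))
  moved <- volume_image(sc$data, S %*% sc$affine)
  res2 <- skull_strip_atlas_guided(moved, ph$atlas, template = ph$template)
  # truth mask in the moved scan's own voxel grid is unchanged
  expect_gt(dice(res2$mask, truth), 0.95)
})

test_that("identity-pose mask voxel count matches nearest-neighbour transport", {
  ph <- fixture_phantom()
  sc <- fixture_scan()
  res <- skull_strip_atlas_guided(sc, ph$atlas, template = ph$template)
  direct <- ratvbm:::resample_array(
    ph$atlas$brain_mask + 0,
    solve(res$transform_to_atlas) %*% ph$atlas$affine,
    sc$affine, dim(sc$data), "nearest")
  expect_identical(res$mask, array(direct$data > 0.5, dim(sc$data)))
})

test_that("bias correction satisfies its field contract", {
  sc <- fixture_scan()
  mask <- fixture_scan_mask()
  bc <- correct_bias_field(sc, mask)
  # nothing to correct on a bias-free scan
  expect_lt(max(abs(bc$field$data[mask] - 1)), 0.02)
  # field is strictly positive and corrected * field reproduces the input
  expect_true(all(bc$field$data > 0))
  expect_equal(bc$corrected$data * bc$field$data, sc$data,
               tolerance = 1e-12)
  # masked mean preserved to well under 0.1%
  expect_equal(mean(bc$corrected$data[mask]), mean(sc$data[mask]),
               tolerance = 1e-9)
})

test_that("a known 20% polynomial bias is removed", {
  sc <- fixture_scan()
  mask <- fixture_scan_mask()
  d <- dim(sc$data)
  co <- lapply(1:3, function(a) (seq_len(d[a]) - (d[a] + 1) / 2) / (d[a] / 2))
  Xf <- as.matrix(expand.grid(co[[1]], co[[2]], co[[3]]))
  set.seed(7)
  p <- as.numeric(ratvbm:::poly_basis(Xf, 2) %*% rnorm(10))
  p <- p / max(abs(p)) * log1p(0.2)
  ftrue <- array(exp(p), d)
  biased <- volume_image(sc$data * ftrue, sc$affine, "T2W")
  bc <- correct_bias_field(biased, mask)
  cv <- function(x) stats::sd(x) / mean(x)
  excess_before <- cv(biased$data[mask]) - cv(sc$data[mask])
  excess_after <- cv(bc$corrected$data[mask]) - cv(sc$data[mask])
  expect_lt(excess_after, 0.5 * excess_before)
  # idempotence: correcting a corrected image changes it by < 1% RMS
  bc2 <- correct_bias_field(bc$corrected, mask)
  rel_rms <- sqrt(mean((bc2$corrected$data[mask] -
                          bc$corrected$data[mask])^2)) /
    mean(bc$corrected$data[mask])
  expect_lt(rel_rms, 0.01)
})

test_that("degenerate bias inputs raise errors", {
  sc <- fixture_scan()
  expect_error(correct_bias_field(sc, array(FALSE, dim(sc$data))), "empty")
  zero <- volume_image(array(0, dim(sc$data)), sc$affine)
  expect_error(correct_bias_field(zero, fixture_scan_mask()), "degenerate")
})

test_that("mean rescaling is exact, linear and idempotent", {
  sc <- fixture_scan()
  mask <- fixture_scan_mask()
  r <- rescale_mean_intensity(sc, mask, 1000)
  expect_equal(mean(r$data[mask]), 1000, tolerance = 1e-12)
  # doubling the input halves the applied factor
  r2 <- rescale_mean_intensity(
    volume_image(sc$data * 2, sc$affine, sc$modality), mask, 1000)
  expect_equal(r2$data, r$data, tolerance = 1e-12)
  # already at target: unchanged
  r3 <- rescale_mean_intensity(r, mask, 1000)
  expect_equal(r3$data, r$data, tolerance = 1e-12)
  expect_error(rescale_mean_intensity(
    volume_image(array(0, dim(sc$data)), sc$affine), mask, 1000),
    "positive")
})

test_that("gd_difference recovers enhancement and registration shifts", {
  ph <- make_atlas_phantom(phantom_spec(iso_spacing = 0.35, noise_sigma = 2,
                                        bias_amplitude = 0))
  geom <- scan_geometry(slice_thickness = 1, slice_spacing = 1,
                        plane = "axial", n_slices = 26,
                        in_plane_spacing = 0.274)
  ses <- subject_session("s1", "P1")
  pre <- synthesize_scan(ph, ses, geom, "GRE_PRE", "P1")
  post <- synthesize_scan(ph, ses, geom, "GRE_POST", "P1")

  # self-difference is zero up to the noise floor
  dd0 <- gd_difference(pre, pre)
  expect_lt(max(abs(dd0$data)), 3 * 2)
  expect_equal(dd0$modality, "GRE_DIFF")

  # post = pre + known enhancement, no motion: the difference recovers the
  # enhancement map within interpolation tolerance
  truth_enh <- ratvbm:::day_effect_volume(ph, "P1", "GRE_POST") -
    ratvbm:::day_effect_volume(ph, "P1", "GRE_PRE")
  # apply the same boxcar slice profile to the truth map as the scans get
  offs <- (1:5 - 3) / 5 * geom$slice_thickness
  enh_acc <- array(0, dim(pre$data))
  for (o in offs) {
    Go <- pre$affine
    Go[2, 4] <- Go[2, 4] + o
    enh_acc <- enh_acc + ratvbm:::resample_array(
      truth_enh, ph$meta$affine, Go, dim(pre$data), "linear")$data
  }
  enh_scan <- list(data = enh_acc / 5)
  post_c <- volume_image(pre$data + enh_scan$data, pre$affine, "GRE_POST")
  dd <- gd_difference(pre, post_c)
  strong <- enh_scan$data > 100
  expect_gt(cor(dd$data[strong], enh_scan$data[strong]), 0.95)
  # the subtraction itself is exact; the residual mean deficit is trilinear
  # interpolation loss on structures about one voxel thick
  expect_equal(mean((post_c$data - pre$data)[strong]),
               mean(enh_scan$data[strong]), tolerance = 1e-9)
  expect_equal(mean(dd$data[strong]), mean(enh_scan$data[strong]),
               tolerance = 0.15)
  # the fully synthesised pre/post pair still shows the injected contrast
  dd_s <- gd_difference(pre, post)
  expect_gt(cor(dd_s$data[strong], enh_scan$data[strong]), 0.8)

  # a 0.5 mm translation of the post scan is recovered by registration
  postT <- volume_image(post$data, post$affine, "GRE_POST")
  postT$affine[1, 4] <- postT$affine[1, 4] + 0.5
  dd2 <- gd_difference(pre, postT)
  M <- attr(dd2, "transform")
  expect_lt(abs(M[1, 4] + 0.5), 0.1)
  head <- ratvbm:::resample_array(
    ph$template$data, ph$meta$affine, pre$affine, dim(pre$data),
    "linear")$data > 10
  background <- !head & abs(enh_scan$data) < 1
  inside <- attr(dd2, "validity") & background
  # residual air signal stays near the (doubled, resampled) noise floor
  expect_lt(stats::quantile(abs(dd2$data[inside]), 0.9), 3 * 2)
})
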