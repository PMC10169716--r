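test_that("phantom atlas partitions the brain into the requested regions", {
  ph <- fixture_phantom()
  labs <- ph$atlas$labels
  expect_equal(length(unique(labs[labs > 0])), 80L)
  # union of labels equals the brain mask
  expect_identical(labs > 0, ph$atlas$brain_mask)
  expect_equal(ph$atlas$region_names$name[80], "superior_sagittal_sinus")
})

test_that("region count is configurable and validated", {
  sp <- phantom_spec(iso_spacing = 0.6, n_regions = 12)
  ph <- make_atlas_phantom(sp)
  expect_equal(length(unique(ph$atlas$labels[ph$atlas$labels > 0])), 12L)
  expect_error(phantom_spec(tube_diameter_by_day = c(B1 = 3, B2 = 3, P1 = 3,
                                                     P2 = 3, P7 = 3, P14 = 3),
                            tube_center_depth = 1),
               "exceeds")
})

test_that("tube voxel volume approximates the analytic cylinder volume", {
  # generous caliber relative to spacing so discretisation error is small
  sp <- phantom_spec(iso_spacing = 0.15,
                     brain_semiaxes = c(7, 13, 5.5),
                     tube_diameter_by_day = c(B1 = 1.6, B2 = 1.6, P1 = 1.6,
                                              P2 = 1.6, P7 = 1.6, P14 = 1.6),
                     tube_center_depth = 1.0)
  ph <- make_atlas_phantom(sp)
  n_tube <- sum(ph$atlas$labels == sp$n_regions)
  L <- diff(ph$meta$tube_range)
  analytic <- pi * 0.8^2 * L / 0.15^3
  expect_lt(abs(n_tube - analytic) / analytic, 0.10)
})

test_that("scan synthesis is deterministic and honours the corruption model", {
  ph <- fixture_phantom()
  geom <- fixture_geom()
  s <- subject_session("d", "B1")
  noisy_spec <- phantom_spec(iso_spacing = 0.35, noise_sigma = 15,
                             bias_amplitude = 0.15, rng_seed = 3)
  ph_noisy <- make_atlas_phantom(noisy_spec)
  a <- synthesize_scan(ph_noisy, s, geom, "T2W", "B1")
  b <- synthesize_scan(ph_noisy, s, geom, "T2W", "B1")
  expect_identical(a$data, b$data)
  # different session keys decorrelate the noise
  c2 <- synthesize_scan(ph_noisy, subject_session("e", "B1"), geom, "T2W",
                        "B1")
  expect_false(identical(a$data, c2$data))
  # unknown day is rejected
  expect_error(synthesize_scan(ph, s, geom, "T2W", "P99"), "undefined")
})

test_that("clean identity-pose synthesis reproduces the resliced template", {
  ph <- fixture_phantom()
  # thin slices so the boxcar slice profile is negligible
  geom <- scan_geometry(in_plane_spacing = 0.274, slice_thickness = 0.2,
                        slice_spacing = 0.2, n_slices = 80, plane = "axial")
  sc <- synthesize_scan(ph, subject_session("f", "B1"), geom, "T2W", "B1")
  ref <- resample_volume(volume_image(ph$template$data, ph$template$affine),
                         sc$affine, dim(sc$data))
  ok <- attr(ref, "validity")
  # residual discrepancy is the 0.2 mm boxcar average at sharp tissue edges
  expect_lt(max(abs(sc$data - ref$data)[ok]) /
              diff(range(ph$template$data)), 0.15)
  expect_lt(mean(abs(sc$data - ref$data)[ok]) /
              diff(range(ph$template$data)), 0.005)
  expect_gt(cor(sc$data[ok], ref$data[ok]), 0.995)
})

test_that("post-contrast enhancement raises the dilated lumen intensity by the configured amount", {
  spec <- phantom_spec(iso_spacing = 0.35, noise_sigma = 0,
                       bias_amplitude = 0)
  ph <- make_atlas_phantom(spec)
  pre_b <- ratvbm:::day_effect_volume(ph, "B1", "GRE_PRE")
  post_b <- ratvbm:::day_effect_volume(ph, "B1", "GRE_POST")
  lumen <- ph$atlas$labels == spec$n_regions
  # enhancement is additive in the partial-volume lumen fraction
  frac <- ratvbm:::tube_fraction(ph$meta$rho,
                                 spec$tube_diameter_by_day[["B1"]] / 2,
                                 spec$iso_spacing)
  expected <- spec$vessel_enhancement_by_day[["B1"]] * mean(frac[lumen])
  got <- mean((post_b - pre_b)[lumen])
  expect_equal(got, expected, tolerance = 1e-9)
  # P1 dilation changes the structural lumen neighbourhood relative to B
  pre_p1 <- ratvbm:::day_effect_volume(ph, "P1", "GRE_PRE")
  expect_gt(mean(pre_p1[lumen]) , mean(pre_b[lumen]) - 1e-9)
  expect_gt(sum(pre_p1 > 700), sum(pre_b > 700))
})

test_that("slice stack never samples gap material", {
  geom <- scan_geometry(plane = "axial", n_slices = 17)
  ph <- fixture_phantom()
  sc <- synthesize_scan(ph, subject_session("g", "B1"), geom, "T2W", "B1")
  # slice world positions are spaced at slice_spacing centre-to-centre
  idx <- cbind(0, 0:(dim(sc$data)[2] - 1), 0)
  w <- voxel_to_world(sc$affine, idx)
  expect_equal(diff(w[, 2]), rep(1.5, 16), tolerance = 1e-12)
})

test_that("a small study writes coherent files, sidecars and truth manifest", {
  td <- withr::local_tempdir()
  spec <- phantom_spec(iso_spacing = 0.6, noise_sigma = 5,
                       bias_amplitude = 0.05, rng_seed = 9)
  types <- list(T2W_axial = list(modality = "T2W",
                                 geom = scan_geometry(plane = "axial",
                                                      n_slices = 12,
                                                      in_plane_spacing = 0.4)))
  man <- make_study(spec, 2, td, scan_types = types,
                    days = c("B1", "B2", "P1"))
  expect_equal(nrow(man), 2 * 3 * 1)
  expect_true(all(file.exists(file.path(td, man$file))))
  # baseline group size is twice the subject count
  expect_equal(sum(man$day %in% c("B1", "B2")), 2 * 2)
  # truth diameters match the spec
  expect_equal(unique(man$tube_diameter[man$day == "P1"]),
               spec$tube_diameter_by_day[["P1"]])
  # sidecars carry subject/day and the modality
  sc <- jsonlite::read_json(file.path(td, sub("\\.nii\\.gz$", ".json",
                                              man$file[1])))
  expect_equal(sc$scan_type, "T2W")
  # regenerating the study reproduces the files bit-identically
  td2 <- withr::local_tempdir()
  man2 <- make_study(spec, 2, td2, scan_types = types,
                     days = c("B1", "B2", "P1"))
  f1 <- read_volume(file.path(td, man$file[4]))
  f2 <- read_volume(file.path(td2, man2$file[4]))
  expect_identical(f1$data, f2$data)
  # truth pose round-trips through the manifest text encoding
  pose <- manifest_pose(man[1, ])
  expect_equal(dim(pose), c(4L, 4L))
})
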