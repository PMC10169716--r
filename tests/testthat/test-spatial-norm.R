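test_that("transform chains compose, invert and validate", {
  # chain of identities is the identity
  ch0 <- compose_chain(diag(4), diag(4), diag(4))
  expect_equal(ch0$composite, diag(4))

  T1 <- rigid_param_matrix(rot_deg = c(3, 0, 0), trans = c(1, 0, 0))
  T2 <- affine_param_matrix(scales = c(1.1, 0.9, 1), trans = c(0, 2, -1))
  ch <- compose_chain(rigid_step = T1, affine_step = T2)
  # applying the chain equals T2(T1(p)) for random points
  set.seed(3)
  p <- matrix(rnorm(30), ncol = 3)
  expect_equal(apply_chain(ch, p), apply_chain(T2, apply_chain(T1, p)),
               tolerance = 1e-12)
  # composite times its inverse is the identity
  inv <- chain_inverse(ch)
  expect_lt(max(abs(ch$composite %*% inv$composite - diag(4))), 1e-10)
  # step kinds are tracked and rigid steps validated
  expect_equal(vapply(ch$steps, function(s) s$kind, ""),
               c("rigid", "affine"))
  expect_error(transform_chain(list(list(name = "bad", kind = "rigid",
                                         matrix = T2))),
               "orthonormal")
  sing <- diag(4); sing[1, 1] <- 0
  expect_error(compose_chain(sing), "singular")
})

test_that("chains serialise to JSON and back", {
  T1 <- rigid_param_matrix(rot_deg = c(0, 2, 0), trans = c(0.5, -1, 2))
  T2 <- affine_param_matrix(scales = c(1.05, 1, 0.95))
  ch <- compose_chain(scan_to_B = T1, B_to_atlas = T2)
  path <- tempfile(fileext = ".json")
  write_chain(ch, path)
  ch2 <- read_chain(path)
  expect_equal(ch2$composite, ch$composite, tolerance = 1e-12)
  expect_equal(ch2$steps[[1]]$name, "scan_to_B")
})

test_that("normalization through the truth chain hits atlas landmarks", {
  ph <- fixture_phantom()
  geom <- fixture_geom()
  ses <- ratvbm:::random_session(ph$spec, "sub01", "P1")
  sc <- synthesize_scan(ph, ses, geom, "T2W", "P1")
  W <- attr(sc, "truth")$pose
  nv <- normalize_to_atlas(sc, solve(W), ph$atlas, geom = geom)
  expect_equal(dim(nv$data), dim(ph$atlas$labels))
  val <- attr(nv, "validity") & ph$atlas$brain_mask
  # normalized scan matches the template over validly observed brain tissue
  expect_gt(cor(nv$data[val], ratvbm:::day_effect_volume(ph, "P1", "T2W")[val]),
            0.85)
  # identity chain on a scan already in atlas space is a no-op
  tmpl <- ph$template
  nv0 <- normalize_to_atlas(tmpl, diag(4), ph$atlas)
  expect_equal(nv0$data, tmpl$data, tolerance = 1e-9)
})

test_that("validity marks interslice gaps where the slab is unobserved", {
  ph <- fixture_phantom()
  geom <- fixture_geom()  # 1.0 mm slices at 1.5 mm spacing
  sc <- synthesize_scan(ph, subject_session("s", "B1"), geom, "T2W", "B1")
  nv <- normalize_to_atlas(sc, diag(4), ph$atlas, geom = geom)
  gap <- gap_mask_for_scan(sc, geom, diag(4), ph$atlas)
  val <- attr(nv, "validity")
  # gap voxels are never valid
  expect_true(!any(val & gap))
  # the gap fraction within the slab is the analytic 0.5 / 1.5
  inslab <- val | gap
  expect_equal(sum(gap) / sum(inslab), 1 / 3, tolerance = 0.05)
})

test_that("two sessions of one subject agree after normalization", {
  ph <- fixture_phantom()
  # near-isotropic slicing: the anisotropic protocol's thick-slice boxcar
  # genuinely changes observed content between sessions, so the agreement
  # bound is checked where acquisition loss is negligible
  geom <- scan_geometry(in_plane_spacing = 0.274, slice_thickness = 0.25,
                        slice_spacing = 0.375, n_slices = 70,
                        plane = "axial")
  s1 <- ratvbm:::random_session(ph$spec, "sub01", "B1")
  s2 <- ratvbm:::random_session(ph$spec, "sub01", "B2")
  a <- synthesize_scan(ph, s1, geom, "T2W", "B1")
  b <- synthesize_scan(ph, s2, geom, "T2W", "B2")
  na <- normalize_to_atlas(a, solve(attr(a, "truth")$pose), ph$atlas,
                           geom = geom)
  nb <- normalize_to_atlas(b, solve(attr(b, "truth")$pose), ph$atlas,
                           geom = geom)
  jv <- attr(na, "validity") & attr(nb, "validity") & ph$atlas$brain_mask
  expect_gt(cor(na$data[jv], nb$data[jv]), 0.98)

  # at the study's anisotropic geometry the agreement is weaker but real
  geo2 <- fixture_geom()
  a2 <- synthesize_scan(ph, s1, geo2, "T2W", "B1")
  b2 <- synthesize_scan(ph, s2, geo2, "T2W", "B2")
  na2 <- normalize_to_atlas(a2, solve(attr(a2, "truth")$pose), ph$atlas,
                            geom = geo2)
  nb2 <- normalize_to_atlas(b2, solve(attr(b2, "truth")$pose), ph$atlas,
                            geom = geo2)
  jv2 <- attr(na2, "validity") & attr(nb2, "validity") & ph$atlas$brain_mask
  expect_gt(cor(na2$data[jv2], nb2$data[jv2]), 0.85)
})

test_that("estimated full chain lands a landmark within one atlas voxel", {
  ph <- fixture_phantom()
  geom <- fixture_geom()
  # subject scan at a known affine pose; baseline anchor at identity
  S <- affine_param_matrix(rot_deg = c(3, 0, 2), trans = c(1, -0.8, 0.5),
                           scales = c(1.04, 0.98, 1.02))
  ses <- subject_session("sub01", "B1", true_affine = S)
  moving <- synthesize_scan(ph, ses, geom, "T2W", "B1")
  M <- ratvbm:::register_ncc(moving, ph$template, "affine",
                             fixed_region = ratvbm:::dilate_mask(
                               ph$atlas$brain_mask, 2L))
  ch <- compose_chain(scan_to_atlas = ratvbm:::unclass_matrix(M))
  # the bregma landmark maps back to itself through the estimated chain
  lm_atlas <- ph$frame$bregma_world
  lm_scan <- as.numeric(apply_chain(S, lm_atlas))
  lm_est <- as.numeric(apply_chain(ch, lm_scan))
  expect_lt(sqrt(sum((lm_est - lm_atlas)^2)), 0.35)
})
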