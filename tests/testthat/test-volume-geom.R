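test_that("NIfTI write/read round-trips data and affine", {
  set.seed(10)
  aff <- diag(c(0.137, 0.137, 1.5, 1))
  aff[1:3, 4] <- c(-5, -6, -7)
  v <- volume_image(array(rnorm(4 * 5 * 6), c(4, 5, 6)), aff, "T2W")
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v, path, sidecar = list(subject = "s1", day = "B1"))
  r <- read_volume(path)
  expect_equal(r$data, v$data, tolerance = 1e-7)
  # sform is stored as float32 in the header
  expect_equal(r$affine, v$affine, tolerance = 1e-7)
  expect_equal(r$modality, "T2W")  # via sidecar scan_type
  expect_equal(attr(r, "sidecar")$day, "B1")

  # constant image round-trips with all-equal voxels
  cpath <- tempfile(fileext = ".nii.gz")
  write_volume(volume_image(array(7, c(3, 3, 3)), diag(4)), cpath)
  cr <- read_volume(cpath)
  expect_true(all(cr$data == 7))

  # 1.5 mm slice spacing preserved bit-exact in the sform
  expect_identical(r$affine[3, 3], 1.5)
})

test_that("phantom written at protocol geometry reports 0.137 mm pixels", {
  ph <- fixture_phantom()
  sc <- synthesize_scan(ph, subject_session("s", "B1"),
                        scan_geometry(n_slices = 4), "T2W", "B1")
  expect_equal(unname(voxel_spacing(sc)[c(1, 3)]), c(0.137, 0.137))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(sc, path)
  r <- read_volume(path)
  expect_equal(unname(sqrt(colSums(r$affine[1:3, 1:3]^2))[c(1, 3)]),
               c(0.137, 0.137), tolerance = 1e-7)
})

test_that("non-3D input is rejected", {
  img <- RNifti::asNifti(matrix(0, 4, 4))
  path <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, path)
  expect_error(read_volume(path), "3D")
  expect_error(volume_image(matrix(0, 3, 3), diag(4)), "3D")
  expect_error(read_volume(tempfile(fileext = ".nii")), "not found")
})

test_that("volume_image enforces its invariants", {
  a <- array(0, c(2, 2, 2))
  bad <- a; bad[1] <- NA
  expect_error(volume_image(bad, diag(4)), "finite")
  sing <- diag(4); sing[1, 1] <- 0
  expect_error(volume_image(a, sing), "invertible")
})

test_that("scan_geometry derives the interslice gap and validates it", {
  g <- scan_geometry()
  expect_equal(g$slice_spacing, 1.5)
  expect_equal(g$slice_thickness, 1.0)
  expect_equal(slice_gap(g), 0.5)
  expect_error(scan_geometry(slice_thickness = 2, slice_spacing = 1.5),
               ">=")
})

test_that("bregma offsets follow the stereotaxic sign convention", {
  frame <- bregma_frame(c(1, 2, 3))
  expect_equal(world_to_bregma_offset(c(1, 2, 3), frame),
               c(RL = 0, VD = 0, RC = 0))
  # 1 mm dorsal of bregma
  expect_equal(world_to_bregma_offset(c(1, 2, 4), frame),
               c(RL = 0, VD = 1, RC = 0))
  # round trip is exact
  off <- c(0.3, -1.07, -0.22)
  expect_equal(
    world_to_bregma_offset(bregma_offset_to_world(off, frame), frame),
    c(RL = off[1], VD = off[2], RC = off[3]), tolerance = 1e-12)
  # matrix form agrees
  m <- world_to_bregma_offset(rbind(c(1, 2, 3), c(2, 2, 3)), frame)
  expect_equal(unname(m[2, ]), c(1, 0, 0))
})

test_that("rostral sinus seed matches the published stereotaxic offset", {
  ph <- fixture_phantom()
  seeds <- default_sss_seeds()
  expect_equal(seeds$VD, c(-1.07, -0.53))
  expect_equal(seeds$RC, c(-0.22, -5.55))
  # both seeds land inside the phantom's vessel lumen
  for (i in 1:2) {
    w <- bregma_offset_to_world(c(seeds$RL[i], seeds$VD[i], seeds$RC[i]),
                                ph$frame)
    vox <- world_to_voxel(ph$template$affine, w)
    val <- ratvbm:::cpp_sample_trilinear(ph$template$data, vox)
    expect_equal(val, ph$spec$tissue_means[["vessel"]], tolerance = 0.05)
  }
})

test_that("isotropic resampling preserves constants, ramps and FOV", {
  aff <- diag(c(0.2, 0.3, 1.0, 1))
  cst <- volume_image(array(5, c(10, 12, 8)), aff)
  iso <- resample_to_isotropic(cst, spacing = 0.25)
  expect_equal(unname(voxel_spacing(iso)), rep(0.25, 3))
  expect_true(all(abs(iso$data[attr(iso, "validity")] - 5) < 1e-12))
  # FOV preserved within one voxel
  bb_in <- ratvbm:::volume_bbox(cst)
  bb_out <- ratvbm:::volume_bbox(iso)
  expect_lt(max(abs(bb_in - bb_out)), 0.25)

  # axis-aligned linear ramp is reproduced exactly at interior voxels
  d <- c(12, 10, 8)
  ramp <- volume_image(
    array(rep(seq_len(d[1]), times = prod(d[2:3])), d),
    diag(c(0.5, 0.5, 0.5, 1)))
  iso2 <- resample_to_isotropic(ramp, spacing = 0.25)
  # analytic: value is linear in world x
  ctr <- floor(dim(iso2$data) / 2)
  idx <- cbind(seq_len(dim(iso2$data)[1]) - 1, ctr[2], ctr[3])
  w <- voxel_to_world(iso2$affine, idx)
  expected <- w[, 1] / 0.5 + 1
  got <- iso2$data[cbind(idx[, 1] + 1, ctr[2] + 1, ctr[3] + 1)]
  interior <- w[, 1] > 0.3 & w[, 1] < (d[1] - 1) * 0.5 - 0.3
  expect_equal(got[interior], expected[interior], tolerance = 1e-9)

  # default spacing matches the spin-echo in-plane resolution
  expect_equal(formals(resample_to_isotropic)$spacing, 0.1367)
})

test_that("resampling back to the original grid is near-lossless on smooth images", {
  set.seed(42)
  d <- c(16, 16, 12)
  base <- array(rnorm(prod(d)), d)
  smooth <- ratvbm:::cpp_gaussian_smooth(base, c(2.5, 2.5, 2.5))
  v <- volume_image(smooth, diag(c(0.4, 0.4, 0.4, 1)))
  iso <- resample_to_isotropic(v, spacing = 0.2)
  back <- resample_volume(iso, v$affine, dim(v$data))
  inner <- array(FALSE, d)
  inner[4:13, 4:13, 4:9] <- TRUE
  err <- abs(back$data - v$data)[inner]
  expect_lt(max(err), 0.03 * diff(range(smooth)))
})

test_that("atlas reslicing keeps labels categorical and counts slices", {
  ph <- fixture_phantom()
  atlas <- ph$atlas
  # reslice to the atlas's own geometry reproduces the labels
  own <- scan_geometry(in_plane_spacing = 0.35, slice_thickness = 0.35,
                       slice_spacing = 0.35, fov = NULL,
                       n_slices = dim(atlas$labels)[2], plane = "axial")
  r <- reslice_atlas_to_scan(atlas, own)
  expect_identical(r$labels, atlas$labels)
  # anisotropic reslice: label closure and derived slice count
  geo <- scan_geometry(in_plane_spacing = 0.35, fov = NULL, plane = "axial")
  r2 <- reslice_atlas_to_scan(atlas, geo)
  expect_true(all(r2$labels %in% c(0L, atlas$region_names$label)))
  extent <- ratvbm:::volume_bbox(atlas)[2, 2] - ratvbm:::volume_bbox(atlas)[1, 2]
  expect_equal(dim(r2$labels)[2], round(extent / 1.5), tolerance = 1)
})
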