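# Shared fixtures, built once per test run. Phantoms are generated in code;
# nothing binary ships with the package.

.fixtures <- new.env(parent = emptyenv())

# coarse noise-free phantom (0.35 mm iso) used by most geometry tests
fixture_phantom <- function() {
  if (is.null(.fixtures$phantom)) {
    .fixtures$phantom <- make_atlas_phantom(
      phantom_spec(iso_spacing = 0.35, noise_sigma = 0, bias_amplitude = 0))
  }
  .fixtures$phantom
}

# matching clean anisotropic T2W scan at the identity pose
fixture_scan <- function() {
  if (is.null(.fixtures$scan)) {
    .fixtures$scan <- synthesize_scan(
      fixture_phantom(), subject_session("fix", "B1"),
      fixture_geom(), "T2W", "B1")
  }
  .fixtures$scan
}

fixture_geom <- function() {
  scan_geometry(plane = "axial", n_slices = 20, in_plane_spacing = 0.274)
}

# brain mask transported onto the fixture scan grid at the identity pose
fixture_scan_mask <- function() {
  if (is.null(.fixtures$scan_mask)) {
    ph <- fixture_phantom()
    sc <- fixture_scan()
    res <- ratvbm:::resample_array(ph$atlas$brain_mask + 0, ph$atlas$affine,
                                   sc$affine, dim(sc$data), "nearest")
    .fixtures$scan_mask <- res$data > 0.5
  }
  .fixtures$scan_mask
}

rigid_param_matrix <- function(rot_deg = c(0, 0, 0), trans = c(0, 0, 0)) {
  ratvbm:::transform_matrix_from_params(
    c(rot_deg * pi / 180, trans), c(0, 0, 0), "rigid")
}

affine_param_matrix <- function(rot_deg = c(0, 0, 0), trans = c(0, 0, 0),
                                scales = c(1, 1, 1),
                                shears = c(0, 0, 0)) {
  ratvbm:::transform_matrix_from_params(
    c(rot_deg * pi / 180, trans, log(scales), shears), c(0, 0, 0), "affine")
}

expect_rigid_close <- function(M, truth, tol_mm, tol_deg) {
  d <- ratvbm:::rigid_discrepancy(M, truth)
  expect_lt(d$translation, tol_mm)
  expect_lt(d$rotation_deg, tol_deg)
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
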