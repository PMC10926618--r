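make_ellipsoid_sweep <- function(n = 48, a = 20, b = 15, cz = 23.5, c_ax = 22,
                                 size = 64, spacing = 1) {
  st <- data.frame(class_index = 1L, cx = size / 2, cy = size / 2, cz = cz,
                   a = a, b = b, c = c_ax)
  sw <- sweep_spec(n, spacing, structures = st, image_size = size)
  generate_sweep(sw, phantom_spec(image_size = size, speckle_shape = Inf,
                                  psf_sigma = 0), seed = 1)
}

test_that("stacking conserves per-class voxel counts when smoothing is off", {
  out <- make_ellipsoid_sweep()
  vol <- stack_predictions(out$label_frames, spacing = 1, closing_radius = 0)
  expect_equal(dim(vol$values), c(48L, 64L, 64L))
  counts <- sum(vapply(out$label_frames, function(f) sum(f == 1), 0))
  expect_equal(sum(vol$values == 1), counts)
  # identical frames stack to a z-constant volume
  same <- replicate(5, out$label_frames[[24]], simplify = FALSE)
  v2 <- stack_predictions(same, spacing = 2, closing_radius = 0)
  for (z in 2:5) expect_identical(v2$values[z, , ], v2$values[1, , ])
  expect_error(stack_predictions(out$label_frames[1]), "at least 2")
  expect_error(stack_predictions(list(matrix(0L, 4, 4), matrix(0L, 5, 5))),
               "differ in shape")
})

test_that("morphological closing only adds background voxels", {
  out <- make_ellipsoid_sweep(n = 16)
  v0 <- stack_predictions(out$label_frames, closing_radius = 0)
  v1 <- stack_predictions(out$label_frames, closing_radius = 1)
  expect_true(all(v1$values[v0$values != 0] == v0$values[v0$values != 0]))
  expect_gte(sum(v1$values == 1), sum(v0$values == 1))
})

test_that("extracted ellipsoid mesh recovers the analytic volume and topology", {
  out <- make_ellipsoid_sweep(n = 48, a = 20, b = 15, cz = 23.5, c_ax = 22)
  vol <- stack_predictions(out$label_frames, spacing = 1, closing_radius = 0)
  mesh <- extract_mesh(vol, 1)
  expect_s3_class(mesh, "sono_mesh")
  analytic <- 4 / 3 * pi * 20 * 15 * 22
  expect_lt(abs(mesh_volume(mesh) - analytic) / analytic, 0.1)
  expect_equal(mesh_euler(mesh), 2)       # sphere topology
  # anisotropic spacing scales the volume accordingly
  vol2 <- stack_predictions(out$label_frames, spacing = c(2, 1, 1),
                            closing_radius = 0)
  mesh2 <- extract_mesh(vol2, 1)
  expect_lt(abs(mesh_volume(mesh2) - 2 * analytic) / (2 * analytic), 0.1)
})

test_that("absent classes give empty meshes with a warning", {
  out <- make_ellipsoid_sweep(n = 8)
  vol <- stack_predictions(out$label_frames, closing_radius = 0)
  expect_warning(m <- extract_mesh(vol, 5), "absent")
  expect_equal(nrow(m$vertices), 0)
  expect_equal(mesh_volume(m), 0)
})

test_that("export writes NIfTI, one PLY/STL per class, and the palette scene", {
  out <- make_ellipsoid_sweep(n = 12)
  vol <- stack_predictions(out$label_frames, spacing = c(2, 1, 1),
                           closing_radius = 0)
  mesh <- extract_mesh(vol, 1)
  td <- withr::local_tempdir()
  paths <- export_recon(vol, list(mesh), td)
  # NIfTI round-trip: identical voxels and spacing
  back <- read_volume(file.path(td, "labels.nii"))
  expect_equal(back$values, vol$values)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  # PLY round-trip: identical mesh up to float formatting
  ply <- read_ply(file.path(td, "thyroid.ply"))
  expect_equal(nrow(ply$vertices), nrow(mesh$vertices))
  expect_equal(ply$faces, unname(mesh$faces))
  expect_equal(unname(as.matrix(ply$vertices)), unname(mesh$vertices),
               tolerance = 1e-4)
  expect_true(file.exists(file.path(td, "thyroid.stl")))
  scene <- jsonlite::read_json(file.path(td, "scene.json"),
                               simplifyVector = TRUE)
  expect_equal(scene$class_name, "thyroid")
  expect_equal(scene$color, unname(class_palette()["thyroid"]))
})

test_that("the documented palette covers the five foreground structures", {
  pal <- class_palette()
  expect_setequal(names(pal), setdiff(sono_classes(), "background"))
  # red carotid, blue trachea, green thyroid, yellow NoV, purple esophagus
  hex <- function(x, k) strtoi(substr(x, k, k + 1), 16L)
  expect_gt(hex(pal["carotid"], 2), hex(pal["carotid"], 6))    # R > B
  expect_gt(hex(pal["trachea"], 6), hex(pal["trachea"], 2))    # B > R
  expect_gt(hex(pal["thyroid"], 4), hex(pal["thyroid"], 2))    # G > R
})
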