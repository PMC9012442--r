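two_cube_volume <- function(noise_sd = 0) {
  pose <- structure(list(box_mesh(14, 14, 14, "A"),
                         transform_mesh(box_mesh(14, 14, 14, "B"),
                                        rigid_transform(diag(3), c(30, 0, 0)))),
                    class = "spine_pose")
  md <- hu_model(noise = noise_sd > 0, noise_sd = noise_sd)
  voxelize(pose, md, spacing = c(1, 1, 1), soft_margin = 4, pad = 2, seed = 2)
}

test_that("the HU window is inclusive at both ends", {
  vol <- ct_volume(array(c(699.9, 700, 1500, 3000, 3000.1, -1000), c(6, 1, 1)))
  m <- threshold_mask(vol)
  expect_equal(as.vector(m$mask), c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(m$provenance$hu_lo, 700)
})

test_that("an all-background volume yields an empty mask and labeling refuses it", {
  vol <- ct_volume(array(-1000, c(4, 4, 4)))
  expect_warning(m <- threshold_mask(vol), "empty")
  expect_false(any(m$mask))
  suppressWarnings(m <- threshold_mask(vol))
  expect_error(label_components(m), "empty")
})

test_that("separated components are labeled in cranial order", {
  vol <- two_cube_volume()
  lab <- label_components(threshold_mask(vol), expected_n = 2)
  expect_length(lab$voxel_counts, 2)
  # label 1 must be the more cranial (+x) component
  i1 <- which(lab$labels == 1, arr.ind = TRUE)
  i2 <- which(lab$labels == 2, arr.ind = TRUE)
  expect_gt(mean(i1[, 1]), mean(i2[, 1]))
})

test_that("min_voxels above the largest component is an error", {
  vol <- two_cube_volume()
  expect_error(label_components(threshold_mask(vol), min_voxels = 1e6),
               "min_voxels")
})

test_that("an unexpected component count errors after one opening attempt", {
  vol <- two_cube_volume()
  expect_error(label_components(threshold_mask(vol), expected_n = 3),
               "mismatch")
})

test_that("a one-voxel bridge is split by the opening rule", {
  m <- array(FALSE, c(21, 7, 7))
  m[2:8, 2:6, 2:6] <- TRUE    # block 1
  m[14:20, 2:6, 2:6] <- TRUE  # block 2
  m[9:13, 4, 4] <- TRUE       # thin bridge
  mask <- structure(list(mask = m, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         provenance = list(hu_lo = 700, hu_hi = 3000)),
                    class = "bone_mask")
  lab <- label_components(mask, min_voxels = 20, expected_n = 2)
  expect_length(lab$voxel_counts, 2)
  expect_true(lab$provenance$opening_applied)
})

test_that("noise-free phantom volume segments into 9 faithful components", {
  pose <- default_pose()
  vol <- voxelize(pose, hu_model(noise = FALSE), spacing = c(1, 1, 1),
                  soft_margin = 10, pad = 3)
  lab <- label_components(threshold_mask(vol), expected_n = 9)
  expect_length(lab$voxel_counts, 9)
  for (k in seq_len(9)) {
    overlap <- mean(vol$labels[lab$labels == k] == k)
    expect_gte(overlap, 0.99)
  }
  # noise-free mask equals the reference bone grid up to partial-volume shells
  expect_gte(mean((lab$labels > 0) == (vol$labels > 0)), 0.995)
})

test_that("segmentation labels are stable under moderate HU noise", {
  # spec-level check: with noise sd <= 50 the component structure and the
  # per-label voxel sets match the noise-free segmentation (boundary voxels
  # whose partial-volume HU straddles the window may flip; >= 99% agreement)
  pose <- small_pose()
  ref <- voxelize(pose, hu_model(noise = FALSE), spacing = c(1.5, 1.5, 1.5),
                  soft_margin = 8, pad = 3)
  lab_ref <- label_components(threshold_mask(ref), expected_n = 3)
  for (seed in 1:5) {
    md <- hu_model(bone_sd = 50, soft_tissue_sd = 30, noise_sd = 50)
    vol <- voxelize(pose, md, spacing = c(1.5, 1.5, 1.5),
                    soft_margin = 8, pad = 3, seed = seed)
    lab <- label_components(threshold_mask(vol), expected_n = 3)
    expect_length(lab$voxel_counts, 3)
    expect_gte(mean(lab$labels == lab_ref$labels), 0.99)
  }
})

test_that("a voxelized cube surfaces to the analytic area and is closed", {
  vol <- voxelize(structure(list(box_mesh(20, 20, 20)), class = "spine_pose"),
                  hu_model(noise = FALSE), spacing = c(1, 1, 1),
                  soft_margin = 4, pad = 2)
  lab <- label_components(threshold_mask(vol), expected_n = 1)
  m <- extract_surface(lab, 1, wrap_radius = 0)
  expect_true(mesh_is_watertight(m))
  # Euler characteristic 2 for a genus-0 closed surface
  nE <- nrow(m$faces) * 3 / 2
  expect_equal(nrow(m$vertices) - nE + nrow(m$faces), 2)
  expect_lt(abs(mesh_area(m) - 2400) / 2400, 0.1)
  # vertices stay within the label bounding box +/- one voxel
  idx <- which(lab$labels == 1, arr.ind = TRUE)
  lo <- (apply(idx, 2, min) - 1) * lab$spacing + lab$origin - lab$spacing
  hi <- (apply(idx, 2, max) - 1) * lab$spacing + lab$origin + lab$spacing
  expect_true(all(sweep(m$vertices, 2, lo, ">=")))
  expect_true(all(sweep(m$vertices, 2, hi, "<=")))
  expect_error(extract_surface(lab, 5), "absent")
})

test_that("smoothing contracts: identity at 0, bounded drift, volume preserved", {
  vol <- voxelize(structure(list(box_mesh(20, 20, 20)), class = "spine_pose"),
                  hu_model(noise = FALSE), spacing = c(1, 1, 1),
                  soft_margin = 4, pad = 2)
  lab <- label_components(threshold_mask(vol), expected_n = 1)
  m <- extract_surface(lab, 1)
  expect_identical(smooth_mesh(m, iterations = 0), m)
  vdiag <- sqrt(3)
  sm <- smooth_mesh(m, iterations = 10, max_displacement = vdiag)
  expect_lte(hausdorff_distance(m, sm, sample_n = 2000), vdiag + 1e-9)
  expect_lt(abs(mesh_volume(sm) - mesh_volume(m)) / mesh_volume(m), 0.01)
  # plain Laplacian (non volume-preserving) shrinks
  sh <- smooth_mesh(m, iterations = 10, volume_preserving = FALSE)
  expect_lt(mesh_volume(sh), mesh_volume(m))
})

test_that("smoothing moves a noisy sphere closer to the analytic sphere", {
  s <- sphere_mesh(radius = 10, subdiv = 3)
  set.seed(6)
  noisy <- vertebra_mesh(s$vertices + matrix(rnorm(length(s$vertices), 0, 0.3),
                                             ncol = 3), s$faces)
  sm <- smooth_mesh(noisy, iterations = 10)
  dev <- function(m) mean(abs(sqrt(rowSums(m$vertices^2)) - 10))
  expect_lt(dev(sm), dev(noisy))
})

test_that("end-to-end segmentation recovers landmarks within 1.5 voxel diagonals", {
  pose <- default_pose()
  art <- articulate(pose, joint_config(), "flexion", "pre")
  vol <- voxelize(art$pose, hu_model(noise = FALSE), spacing = c(1.5, 1.5, 1.5))
  seg <- segment_vertebrae(vol)
  err <- sqrt(rowSums((attr(seg, "landmarks") - attr(art$pose, "landmarks"))^2))
  expect_lt(max(err), 1.5 * sqrt(3) * 1.5)
})
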