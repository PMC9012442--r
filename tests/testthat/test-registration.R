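test_that("Kabsch returns the identity for already-aligned points", {
  set.seed(1)
  p <- matrix(rnorm(30), 10, 3)
  tr <- kabsch(p, p)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-9)
  expect_equal(tr$translation, c(0, 0, 0), tolerance = 1e-9)
})

test_that("Kabsch exactly recovers constructed rigid motions", {
  set.seed(2)
  for (i in 1:10) {
    R0 <- random_rotation()
    t0 <- rnorm(3, sd = 30)
    src <- matrix(rnorm(60, sd = 20), 20, 3)
    dst <- sweep(src %*% t(R0), 2, t0, "+")
    tr <- kabsch(src, dst)
    expect_equal(tr$rotation, R0, tolerance = 1e-9)
    expect_equal(tr$translation, t0, tolerance = 1e-9)
    expect_equal(det(tr$rotation), 1, tolerance = 1e-9)
  }
})

test_that("weighted Kabsch follows the weights", {
  set.seed(12)
  R0 <- rot_y(10); t0 <- c(1, 2, 3)
  src <- matrix(rnorm(30, sd = 20), 10, 3)
  dst <- sweep(src %*% t(R0), 2, t0, "+")
  dst[1, ] <- dst[1, ] + 50       # gross outlier
  w <- c(0, rep(1, 9))            # ignored by weight
  tr <- kabsch(src, dst, weights = w)
  expect_equal(tr$rotation, R0, tolerance = 1e-9)
  expect_equal(tr$translation, t0, tolerance = 1e-9)
})

test_that("degenerate point configurations are rejected", {
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(kabsch(line, line + 1), "degenerate")
  expect_error(kabsch(matrix(1, 2, 3), matrix(1, 2, 3)), "3 correspondences")
})

test_that("noisy correspondences leave a residual below 2 sigma", {
  set.seed(3)
  sigma <- 0.5
  rms <- replicate(20, {
    R0 <- random_rotation(); t0 <- rnorm(3, sd = 10)
    src <- matrix(rnorm(300, sd = 20), 100, 3)
    dst <- sweep(src %*% t(R0), 2, t0, "+") +
      matrix(rnorm(300, sd = sigma), 100, 3)
    tr <- kabsch(src, dst)
    sqrt(mean(rowSums((apply_transform(tr, src) - dst)^2)))
  })
  expect_true(all(rms < 2 * sigma * sqrt(3)))
  expect_true(all(rms > 0))
})

test_that("ICP on an identical mesh stays at the identity", {
  m <- default_pose()[[4]]
  reg <- icp(m, m, init = transform_identity(), sample_n = 1000, seed = 1)
  expect_true(reg$converged)
  expect_lt(reg$rms_residual, 1e-6)
  expect_equal(reg$transform$rotation, diag(3), tolerance = 1e-6)
})

test_that("ICP recovers random rigid displacements to <0.01 mm / <0.01 deg", {
  m <- default_pose()[[3]]
  set.seed(4)
  for (i in 1:5) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    tr0 <- compose_transforms(
      rigid_transform(diag(3), runif(3, -20, 20)),
      rotation_about(mesh_centroid(m), ax, runif(1, -25, 25)))
    reg <- icp(m, transform_mesh(m, tr0), sample_n = 2000, seed = i)
    expect_true(reg$converged)
    expect_lt(max(abs(reg$transform$translation - tr0$translation)), 0.01)
    expect_lt(axis_angle(t(tr0$rotation) %*% reg$transform$rotation)$angle_deg,
              0.01)
  }
})

test_that("independently re-voxelized copies align to sub-voxel residual", {
  m <- default_pose()[[5]]
  surf_of <- function(mesh, seed) {
    pose <- structure(list(mesh), class = "spine_pose")
    vol <- voxelize(pose, hu_model(), spacing = c(1.5, 1.5, 1.5),
                    soft_margin = 6, pad = 2, seed = seed)
    lab <- label_components(threshold_mask(vol), expected_n = 1)
    smooth_mesh(extract_surface(lab, 1), max_displacement = 1.5 * sqrt(3))
  }
  a <- surf_of(m, 1)
  tr0 <- compose_transforms(rigid_transform(diag(3), c(8, -4, 6)),
                            rotation_about(mesh_centroid(m), c(0, 1, 0), 9))
  b <- surf_of(transform_mesh(m, tr0), 2)
  reg <- icp(a, b, sample_n = 2000, seed = 5)
  expect_true(reg$converged)
  expect_lt(reg$rms_residual, 1.5 * sqrt(3))  # below one voxel diagonal
})

test_that("anchor superimposition preserves within-phase geometry exactly", {
  pose <- default_pose()
  art <- articulate_condition(pose, joint_config(), "pre")
  # displace flexion/extension by arbitrary scanner poses
  poses <- list(
    resting = art$poses$resting,
    flexion = transform_pose(art$poses$flexion,
                             rotation_about(c(100, 0, 0), c(1, 1, 0), 7)),
    extension = transform_pose(art$poses$extension,
                               rigid_transform(rot_z(-5), c(10, 20, -5))))
  sup <- superimpose_anchor(poses, sample_n = 1500, seed = 2)
  # reference phase untouched
  expect_equal(sup$transforms$resting$rotation, diag(3))
  expect_identical(sup$poses$resting[[1]]$vertices, poses$resting[[1]]$vertices)
  # inter-DSP distances within each phase unchanged to 1e-9 (rigid invariance)
  for (ph in c("flexion", "extension")) {
    before <- inter_dsp_distances(pose_landmarks(poses[[ph]]))
    after <- inter_dsp_distances(pose_landmarks(sup$poses[[ph]]))
    expect_equal(after, before, tolerance = 1e-9)
  }
  # anchors coincide after superimposition (analytic meshes: near-exact)
  hd <- hausdorff_distance(sup$poses$flexion[[1]], sup$poses$resting[[1]],
                           sample_n = 2000)
  expect_lt(hd, 0.01)
})

test_that("bone registration across phases matches the ground-truth joint product", {
  pose <- default_pose()
  art <- articulate_condition(pose, joint_config(), "pre")
  reg <- register_bone_across_phases("L1", art$poses$flexion,
                                     art$poses$extension,
                                     sample_n = 2000, seed = 3)
  truth <- compose_transforms(
    art$truth$phases$extension$transforms[[9]],
    invert_transform(art$truth$phases$flexion$transforms[[9]]))
  expect_lt(axis_angle(t(truth$rotation) %*% reg$transform$rotation)$angle_deg,
            0.05)
  cen <- mesh_centroid(art$poses$flexion[[9]])
  expect_lt(max(abs(apply_transform(reg$transform, cen) -
                    apply_transform(truth, cen))), 0.05)
  # same phase twice: identity
  reg0 <- register_bone_across_phases("L1", art$poses$flexion,
                                      art$poses$flexion,
                                      init = transform_identity(),
                                      sample_n = 1000, seed = 3)
  expect_lt(axis_angle(reg0$transform$rotation)$angle_deg, 1e-5)
  # inverse consistency
  rev <- register_bone_across_phases("L1", art$poses$extension,
                                     art$poses$flexion,
                                     sample_n = 2000, seed = 3)
  comp <- compose_transforms(rev$transform, reg$transform)
  # two independent registrations agree to the ICP convergence accuracy
  expect_lt(axis_angle(comp$rotation)$angle_deg, 0.01)
  expect_lt(max(abs(comp$translation)), 0.01)
})

test_that("superimposition is equivariant under a common global transform", {
  pose <- build_template(small_template())
  art <- articulate_condition(pose, joint_config(), "pre")
  G <- compose_transforms(rigid_transform(diag(3), c(40, -10, 25)),
                          rotation_about(c(0, 0, 0), c(0.2, 1, 0.4), 17))
  measure <- function(poses) {
    sup <- superimpose_anchor(poses, anchor_label = "V1", sample_n = 1200,
                              seed = 4)
    unlist(lapply(sup$poses, function(p) inter_dsp_distances(pose_landmarks(p))))
  }
  m0 <- measure(art$poses)
  m1 <- measure(lapply(art$poses, transform_pose, tr = G))
  expect_equal(m1, m0, tolerance = 1e-6)
})
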