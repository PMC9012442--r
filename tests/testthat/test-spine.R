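test_that("default template reproduces the resting geometry", {
  pose <- default_pose()
  lm <- attr(pose, "landmarks")
  expect_length(pose, 9)
  expect_equal(unname(inter_dsp_distances(lm)), rep(39.9, 8), tolerance = 1e-9)
  expect_equal(total_length(lm), 310.0, tolerance = 1e-9)
  expect_true(all(vapply(pose, mesh_is_watertight, TRUE)))
  # chord never exceeds the summed gaps
  expect_lte(total_length(lm), 8 * 39.9)
  # every vertebra has a distinguishable dorsal process
  tpl <- attr(pose, "template")
  expect_gte(tpl$dsp_height, 2 * tpl$body_size[3])
})

test_that("stored landmarks are exactly what the landmark rule selects", {
  pose <- default_pose()
  expect_equal(unname(pose_landmarks(pose)),
               unname(attr(pose, "landmarks")), tolerance = 1e-9)
})

test_that("a two-vertebra chain has a single gap equal to resting_gap", {
  tpl <- spine_template(n_vertebrae = 2, resting_gap = 41.3,
                        target_total_length = 41.3)
  pose <- build_template(tpl)
  expect_length(pose, 2)
  expect_equal(unname(inter_dsp_distances(attr(pose, "landmarks"))), 41.3,
               tolerance = 1e-9)
})

test_that("impossible chain geometry is rejected with a diagnostic", {
  expect_error(build_template(spine_template(target_total_length = 400)),
               "unreachable")
  expect_error(spine_template(body_size = c(-1, 40, 45)), "dimensions")
  expect_error(spine_template(labels = rep("T11", 9)), "unique")
  # vertebrae jammed together overlap
  expect_error(build_template(spine_template(resting_gap = 15,
                                             target_total_length = 115)),
               "interpenetrate")
})

test_that("resting articulation is the identity", {
  pose <- default_pose()
  art <- articulate(pose, joint_config(), "resting", "pre")
  for (tr in art$truth$transforms) {
    expect_equal(tr$rotation, diag(3), tolerance = 1e-12)
    expect_equal(tr$translation, c(0, 0, 0), tolerance = 1e-12)
  }
  expect_equal(art$truth$inter_dsp,
               unname(inter_dsp_distances(attr(pose, "landmarks"))),
               tolerance = 1e-12)
})

test_that("flexion closes and extension opens every interspinous space", {
  pose <- default_pose()
  rest <- unname(inter_dsp_distances(attr(pose, "landmarks")))
  fl <- articulate(pose, joint_config(), "flexion", "pre")$truth$inter_dsp
  ex <- articulate(pose, joint_config(), "extension", "pre")$truth$inter_dsp
  expect_true(all(fl < rest))
  expect_true(all(ex > rest))
})

test_that("articulation is rigid per vertebra (pairwise distances preserved)", {
  pose <- default_pose()
  art <- articulate(pose, joint_config(), "flexion", "post")
  set.seed(2)
  for (k in c(1, 5, 9)) {
    v0 <- pose[[k]]$vertices
    v1 <- art$pose[[k]]$vertices
    i <- sample(nrow(v0), 12)
    j <- sample(nrow(v0), 12)
    d0 <- sqrt(rowSums((v0[i, ] - v0[j, ])^2))
    d1 <- sqrt(rowSums((v1[i, ] - v1[j, ])^2))
    expect_equal(d1, d0, tolerance = 1e-9)
  }
})

test_that("single-joint landmark displacement follows the chord formula", {
  tpl <- spine_template(n_vertebrae = 2, target_total_length = 39.9)
  pose <- build_template(tpl)
  theta <- 2.5
  jc <- joint_config(theta, theta)
  art <- articulate(pose, jc, "flexion", "pre")
  lm0 <- attr(pose, "landmarks")[2, ]
  lm1 <- art$truth$landmarks[2, ]
  pivot <- art$truth$pivots[1, ]
  r <- sqrt(sum((lm0 - pivot)^2))
  expect_equal(sqrt(sum((lm1 - lm0)^2)), abs(2 * sin(theta * pi / 360)) * r,
               tolerance = 1e-9)
})

test_that("ground truth is self-consistent with its own transforms", {
  pose <- default_pose()
  art <- articulate(pose, joint_config(), "extension", "post")
  lm0 <- attr(pose, "landmarks")
  lm_re <- t(vapply(seq_len(9), function(k)
    apply_transform(art$truth$transforms[[k]], lm0[k, ]), numeric(3)))
  expect_equal(lm_re, unname(art$truth$landmarks), tolerance = 1e-9)
  expect_equal(unname(inter_dsp_distances(lm_re)), art$truth$inter_dsp,
               tolerance = 1e-9)
  expect_equal(total_length(lm_re), art$truth$total_length, tolerance = 1e-9)
})

test_that("ground truth matches the kinematics module applied to the meshes", {
  pose <- default_pose()
  art <- articulate(pose, joint_config(), "flexion", "post")
  lm_mesh <- pose_landmarks(art$pose)
  expect_equal(unname(lm_mesh), unname(art$truth$landmarks), tolerance = 1e-6)
  expect_equal(unname(inter_dsp_distances(lm_mesh)), art$truth$inter_dsp,
               tolerance = 1e-6)
})

test_that("desmotomy strictly widens every per-space flexion change", {
  pose <- default_pose()
  rest <- unname(inter_dsp_distances(attr(pose, "landmarks")))
  pre <- articulate(pose, joint_config(), "flexion", "pre")$truth$inter_dsp
  post <- articulate(pose, joint_config(), "flexion", "post")$truth$inter_dsp
  expect_true(all(abs(post - rest) > abs(pre - rest)))
})

test_that("per-space ROM and L1 excursions increase monotonically with the multiplier", {
  pose <- default_pose()
  jc0 <- joint_config()
  mults <- c(1, 1.2, 1.4, 1.6, 1.8)
  rom <- dv <- cc <- ml <- matrix(NA, length(mults), 1)
  roms <- matrix(NA, length(mults), 8)
  for (i in seq_along(mults)) {
    jc <- joint_config(jc0$flexion_amplitude_deg, jc0$extension_amplitude_deg,
                       mults[i], jc0$pivot_offset)
    tr <- articulate_condition(pose, jc, "post")$truth
    roms[i, ] <- tr$rom
    dv[i] <- tr$l1_motion$dorsoventral
    cc[i] <- tr$l1_motion$craniocaudal
    ml[i] <- tr$l1_motion$ml_axis_angle_deg
  }
  expect_true(all(diff(roms) > 0))   # every space, strictly
  expect_true(all(diff(dv) > 0))
  expect_true(all(diff(cc) > 0))
  expect_true(all(diff(ml) > 0))
})

test_that("specimen sampling is reproducible and respects its contract", {
  s1 <- sample_specimens(specimen_sampler(7, seed = 1))
  s2 <- sample_specimens(specimen_sampler(7, seed = 1))
  expect_identical(s1, s2)
  expect_length(s1, 7)
  s3 <- sample_specimens(specimen_sampler(7, seed = 2))
  expect_false(identical(s1, s3))
  # zero dispersion reproduces the template and joints exactly
  zero <- as.list(stats::setNames(
    rep(0, 9), c("resting_gap", "gap_space", "length_ratio", "dsp_height",
                 "body_scale", "flexion_deg", "extension_deg",
                 "amplitude_space_deg", "multiplier")))
  s0 <- sample_specimens(specimen_sampler(3, zero, seed = 9))
  for (sp in s0) {
    expect_equal(sp$template$resting_gap, 39.9)
    expect_equal(sp$template$dsp_height, 120)
    expect_equal(unique(round(sp$joints$flexion_amplitude_deg, 9)),
                 round(joint_config()$flexion_amplitude_deg, 9))
    expect_equal(sp$joints$isld_flexion_multiplier,
                 joint_config()$isld_flexion_multiplier)
  }
})

test_that("poses serialize to STL/PLY plus a JSON manifest", {
  pose <- build_template(small_template())
  dir <- file.path(tempdir(), "pose_out")
  mpath <- write_pose(pose, dir, format = "ply")
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  expect_equal(man$labels, c("V1", "V2", "V3"))
  expect_equal(man$phase, "resting")
  tm <- man$transforms_row_major
  expect_equal(dim(tm), c(3L, 16L))
  m1 <- read_mesh(file.path(dir, man$files[1]))
  expect_equal(mesh_volume(m1), mesh_volume(pose[[1]]), tolerance = 1e-9)
  # row-major 4x4 ground-truth transform reproduces the stored transform
  M <- matrix(tm[2, ], 4, 4, byrow = TRUE)
  expect_equal(transform_from_matrix(M)$translation,
               attr(pose, "transforms")[[2]]$translation, tolerance = 1e-9)
})
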