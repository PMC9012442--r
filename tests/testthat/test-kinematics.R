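test_that("the craniodorsal landmark of a box is its cranial-dorsal corner", {
  lmk <- craniodorsal_landmark(box_mesh(20, 30, 10))
  expect_equal(lmk$position[1], 20)
  expect_equal(lmk$position[3], 10)
  expect_error(craniodorsal_landmark(box_mesh(), dorsal_fraction = 0), "dorsal_fraction")
})

test_that("the same vertex is selected after moderate mediolateral rotations", {
  m <- default_pose()[[4]]
  lmk0 <- craniodorsal_landmark(m)
  for (ang in c(-12, -6, 6, 12)) {
    tr <- rotation_about(mesh_centroid(m), c(0, 1, 0), ang)
    mt <- transform_mesh(m, tr)
    # brute-force re-selection on the rotated mesh
    lmk1 <- craniodorsal_landmark(mt)
    expect_equal(lmk1$vertex, lmk0$vertex)
    expect_equal(lmk1$position, apply_transform(tr, lmk0$position),
                 tolerance = 1e-9)
  }
})

test_that("inter-DSP distances and total length follow their closed forms", {
  lm <- rbind(c(0, 0, 0), c(35.87, 0, 0), c(35.87, 0, 10))
  d <- inter_dsp_distances(lm)
  expect_equal(d, c(35.87, 10))
  expect_equal(total_length(lm), sqrt(35.87^2 + 100))
  expect_lte(total_length(lm), sum(d))      # triangle inequality
  expect_equal(inter_dsp_distances(rbind(c(1, 2, 3), c(1, 2, 3))), 0)
  expect_equal(total_length(lm[1:2, ]), inter_dsp_distances(lm[1:2, ]))
  # straight chain of 8 gaps
  chain <- cbind(39.9 * (0:8), 0, 0)
  expect_equal(total_length(chain), 319.2)
  expect_error(inter_dsp_distances(lm[1, , drop = FALSE]), "2 landmarks")
  # invariance under a global rigid transform
  set.seed(9)
  tr <- rigid_transform(random_rotation(), rnorm(3, sd = 100))
  expect_equal(inter_dsp_distances(apply_transform(tr, lm)),
               inter_dsp_distances(lm), tolerance = 1e-9)
})

test_that("per-space ROM is the absolute flexion-extension difference", {
  expect_equal(rom_per_space(30, 30), 0)
  expect_equal(rom_per_space(c(34.3, 30), c(27.4, 48)), c(6.9, 18))
  expect_error(rom_per_space(-1, 5), "non-negative")
  expect_error(rom_per_space(c(1, 2), 3), "pair")
})

test_that("motion decomposition matches closed forms and a brute-force angle", {
  d0 <- decompose_motion(transform_identity())
  expect_equal(unlist(d0[1:5]), c(dorsoventral = 0, craniocaudal = 0,
                                  mediolateral = 0, total_angle_deg = 0,
                                  ml_axis_angle_deg = 0))
  # pure 30 deg rotation about y through a centroid: no centroid translation
  cen <- c(10, 20, 30)
  tr <- rotation_about(cen, c(0, 1, 0), 30)
  d <- decompose_motion(tr, centroid = cen)
  expect_equal(d$total_angle_deg, 30, tolerance = 1e-9)
  expect_equal(d$ml_axis_angle_deg, 30, tolerance = 1e-9)
  expect_equal(unname(unlist(d[1:3])), c(0, 0, 0), tolerance = 1e-9)
  # brute force: max angle between v and Rv over sampled directions
  set.seed(10)
  for (i in 1:5) {
    R0 <- random_rotation()
    d <- decompose_motion(rigid_transform(R0, rnorm(3)))
    vs <- matrix(rnorm(3 * 20000), ncol = 3)
    vs <- vs / sqrt(rowSums(vs^2))
    ang <- acos(pmin(1, pmax(-1, rowSums(vs * (vs %*% t(R0)))))) * 180 / pi
    expect_lt(abs(d$total_angle_deg - max(ang)), 1e-3)
  }
  expect_error(decompose_motion(
    structure(list(rotation = matrix(1, 3, 3), translation = 0:2),
              class = "rigid_transform")), "rotation")
})

test_that("centroid-referenced translation is origin-independent", {
  set.seed(13)
  m <- default_pose()[[9]]
  tr <- compose_transforms(rigid_transform(diag(3), c(5, 2, -7)),
                           rotation_about(mesh_centroid(m), c(0, 1, 0), 12))
  d1 <- decompose_motion(tr, centroid = mesh_centroid(m))
  # same physical motion expressed in a shifted world frame
  G <- rigid_transform(diag(3), c(100, -50, 30))
  tr2 <- compose_transforms(G, compose_transforms(tr, invert_transform(G)))
  d2 <- decompose_motion(tr2, centroid = apply_transform(G, mesh_centroid(m)))
  expect_equal(unlist(d1[1:5]), unlist(d2[1:5]), tolerance = 1e-9)
})

test_that("effect summaries reproduce the published worked examples", {
  # per-space ROM: 17.9 -> 23.5 mm gives a 5.6 mm change
  e <- summarize_effects(17.9, 23.5, "rom")
  expect_equal(e$change, 5.6, tolerance = 1e-9)
  # craniocaudal excursion: 22.9 -> 29.8 mm is +6.9 mm and 30.1%
  e <- summarize_effects(22.9, 29.8, "craniocaudal")
  expect_equal(e$change, 6.9, tolerance = 1e-9)
  expect_equal(round(e$percent, 1), 30.1)
  expect_equal(round(e$percent / 8, 1), 3.8)   # per-site craniocaudal effect
  # dorsoventral per-site effect from the printed 47.0% over 8 sites
  expect_equal(round(47.0 / 8, 1), 5.9)
  e <- summarize_effects(32.6, 48.0, "dorsoventral", n_sites = 8)
  expect_equal(round(e$per_site_percent, 1), 5.9)
  # total length: +3.8 mm on 310.0 mm is 1.2%
  e <- summarize_effects(310.0, 313.8, "total_length")
  expect_equal(round(e$percent, 1), 1.2)
  # no change
  e <- summarize_effects(c(a = 1, b = 2), c(a = 1, b = 2))
  expect_equal(e$change, 0)
  expect_equal(e$percent, 0)
})

test_that("per-specimen and group-mean percent conventions are both emitted", {
  pre <- c(10, 20)
  post <- c(15, 22)
  e <- summarize_effects(pre, post)
  expect_equal(e$percent, mean(c(50, 10)))
  expect_equal(e$percent_of_means, 100 * mean(post - pre) / mean(pre))
  # the two conventions genuinely differ on heterogeneous baselines
  expect_false(isTRUE(all.equal(e$percent, e$percent_of_means)))
})

test_that("unpaired specimens are rejected by name", {
  expect_error(summarize_effects(c(a = 1, b = 2), c(a = 1, c = 3)), "b")
  expect_error(summarize_effects(1:3, 1:2), "pair")
})
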