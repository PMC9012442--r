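#' Spine phantom template
#'
#' Parameters of the stylized nine-vertebra (T11-L1) thoracolumbar spine
#' phantom. Each vertebra is a watertight solid made of a vertebral-body block
#' and a tapering dorsal spinous process (DSP) blade; all downstream geometry
#' (segmentation, registration, kinematics) is agnostic to the stylization.
#'
#' The anatomical frame is +x cranial, +y left (mediolateral), +z dorsal.
#' Consecutive craniodorsal landmarks are separated by \code{resting_gap} mm;
#' when \code{target_total_length} is smaller than the summed gaps the chain is
#' bent into a circular (dorsally convex) arc so that the straight-line
#' T11-L1 landmark distance equals the target, reproducing the mild curvature
#' of the segment.
#'
#' @param n_vertebrae number of vertebrae (default 9: T11..T18, L1).
#' @param body_size mm triple: vertebral-body block length (craniocaudal),
#'   width (mediolateral), height (dorsoventral).
#' @param dsp_height DSP blade height above the body block, mm.
#' @param dsp_cranial_taper dimensionless cranial lean of the blade tip
#'   (tip shifted cranially by \code{dsp_cranial_taper * dsp_height}).
#' @param resting_gap resting distance between consecutive craniodorsal
#'   landmarks, mm.
#' @param target_total_length straight-line T11-L1 landmark distance, mm.
#' @param gap_profile optional per-space relative gap pattern (length
#'   \code{n_vertebrae - 1}, rescaled to mean 1).
#' @param labels vertebra labels, cranial to caudal.
#' @return object of class \code{spine_template}.
#' @export
spine_template <- function(n_vertebrae = 9,
                           body_size = c(18, 40, 45),
                           dsp_height = 120,
                           dsp_cranial_taper = 0.36,
                           resting_gap = 39.9,
                           target_total_length = 310.0,
                           gap_profile = NULL,
                           labels = NULL) {
  if (n_vertebrae < 2) stop("n_vertebrae must be >= 2")
  if (any(c(body_size, dsp_height, resting_gap, target_total_length) <= 0))
    stop("all dimensions must be > 0")
  if (is.null(labels)) {
    labels <- if (n_vertebrae == 9) {
      c(paste0("T", 11:18), "L1")
    } else paste0("V", seq_len(n_vertebrae))
  }
  if (anyDuplicated(labels) || length(labels) != n_vertebrae)
    stop("labels must be unique, one per vertebra")
  if (is.null(gap_profile)) gap_profile <- rep(1, n_vertebrae - 1)
  if (length(gap_profile) != n_vertebrae - 1 || any(gap_profile <= 0))
    stop("gap_profile must be positive, one value per interspinous space")
  gap_profile <- gap_profile / mean(gap_profile)
  structure(list(n_vertebrae = as.integer(n_vertebrae),
                 body_size = as.numeric(body_size),
                 dsp_height = dsp_height,
                 dsp_cranial_taper = dsp_cranial_taper,
                 resting_gap = resting_gap,
                 target_total_length = target_total_length,
                 gap_profile = gap_profile,
                 labels = labels),
            class = "spine_template")
}

quad_tris <- function(a, b, c, d) rbind(c(a, b, c), c(a, c, d))

# Canonical single-vertebra solid in its local frame: body block
# [0,L]x[-W/2,W/2]x[0,H] plus a DSP blade prism on top. Returns the mesh and
# the local craniodorsal landmark (the unique most cranial dorsal vertex).
vertebra_solid <- function(template) {
  L <- template$body_size[1]
  W2 <- template$body_size[2] / 2
  H <- template$body_size[3]
  Hd <- template$dsp_height
  Ht <- H + Hd
  D2 <- min(0.2 * template$body_size[2], W2 * 0.9)  # blade half-width
  xbl <- 0.22 * L
  xbh <- 0.72 * L
  lean <- template$dsp_cranial_taper * Hd
  xth <- xbh + lean      # apex (craniodorsal landmark) x
  shelf <- 0.23 * L      # flat landing caudal of the apex: keeps the landmark
                         # voxel-stable under rasterization
  xtl <- xth - 0.72 * L
  ys <- 0.3 * L          # mediolateral slant of the apex edge -> unique max-x
  yz <- 0.075 * Hd       # dorsoventral droop across the apex edge: the +y
                         # corner is the strict dorsal maximum (tie-breaks)
  drop <- 0.09 * Hd      # caudal droop of the blade top behind the shelf

  V <- rbind(
    c(0, -W2, 0), c(L, -W2, 0), c(L, W2, 0), c(0, W2, 0),        # b1..b4
    c(0, -W2, H), c(L, -W2, H), c(L, W2, H), c(0, W2, H),        # t1..t4
    c(xbl, -D2, H), c(xbh, -D2, H), c(xbh, D2, H), c(xbl, D2, H),# p1..p4
    c(xth - ys, -D2, Ht - yz), c(xth, D2, Ht),                   # A-, A+
    c(xth - ys - shelf, -D2, Ht - yz), c(xth - shelf, D2, Ht),   # S-, S+
    c(xtl, -D2, Ht - drop), c(xtl, D2, Ht - drop))               # q1, q4
  b <- 1:4; t <- 5:8; p <- 9:12
  Am <- 13L; Ap <- 14L; Sm <- 15L; Sp <- 16L; q1 <- 17L; q4 <- 18L
  F <- rbind(
    quad_tris(b[1], b[4], b[3], b[2]),                 # bottom (-z)
    quad_tris(b[1], t[1], t[4], b[4]),                 # caudal wall (-x)
    quad_tris(b[2], b[3], t[3], t[2]),                 # cranial wall (+x)
    quad_tris(b[1], b[2], t[2], t[1]),                 # right wall (-y)
    quad_tris(b[4], t[4], t[3], b[3]),                 # left wall (+y)
    quad_tris(t[1], t[2], p[2], p[1]),                 # top frame (+z)
    quad_tris(t[2], t[3], p[3], p[2]),
    quad_tris(t[3], t[4], p[4], p[3]),
    quad_tris(t[4], t[1], p[1], p[4]),
    quad_tris(p[2], p[3], Ap, Am),                     # blade cranial wall
    quad_tris(Am, Ap, Sp, Sm),                         # apex shelf (+z)
    quad_tris(Sm, Sp, q4, q1),                         # droop top (+z)
    quad_tris(p[1], q1, q4, p[4]),                     # blade caudal wall
    # caps: convex pentagons, fanned from the base cranial corner
    rbind(c(p[1], p[2], Am), c(p[1], Am, Sm), c(p[1], Sm, q1)),   # -y cap
    rbind(c(p[4], q4, Sp), c(p[4], Sp, Ap), c(p[4], Ap, p[3])))   # +y cap
  list(mesh = vertebra_mesh(V, F),
       landmark = c(xth, D2, Ht),
       profile_body = cbind(c(0, L, L, 0), c(0, 0, H, H)),
       profile_blade = cbind(c(xbl, xbh, xth, xth - shelf, xtl),
                             c(H, H, Ht, Ht, Ht - drop)))
}

# Separating-axis overlap test for two convex 2D polygons (rows = vertices).
sat_overlap_2d <- function(P, Q) {
  axes <- function(M) {
    e <- rbind(diff(M), M[1, ] - M[nrow(M), ])
    a <- cbind(-e[, 2], e[, 1])
    a / sqrt(rowSums(a^2))
  }
  for (ax in list(axes(P), axes(Q))) {
    for (i in seq_len(nrow(ax))) {
      p <- P %*% ax[i, ]; q <- Q %*% ax[i, ]
      if (max(p) <= min(q) || max(q) <= min(p)) return(FALSE)
    }
  }
  TRUE
}

#' Build the resting-phase spine pose
#'
#' Instantiates one vertebra solid per level and places them along a straight
#' or circular-arc chain so that consecutive craniodorsal landmarks are
#' \code{resting_gap} (times \code{gap_profile}) apart and the T11-L1 chord
#' equals \code{target_total_length}.
#'
#' @param template a \code{spine_template}.
#' @return object of class \code{spine_pose}: a list of \code{vertebra_mesh}
#'   objects with attributes \code{template}, \code{landmarks} (ground-truth
#'   craniodorsal landmark per vertebra), \code{transforms} (local-to-world
#'   \code{rigid_transform} per vertebra), \code{phase} and \code{condition}.
#' @examples
#' pose <- build_template(spine_template())
#' length(pose)                       # 9 meshes
#' inter_dsp_distances(attr(pose, "landmarks"))
#' @export
build_template <- function(template = spine_template()) {
  stopifnot(inherits(template, "spine_template"))
  n <- template$n_vertebrae
  gaps <- template$resting_gap * template$gap_profile
  total <- sum(gaps)
  target <- template$target_total_length
  if (target > total + 1e-9)
    stop("target_total_length exceeds the summed resting gaps; chain unreachable")
  sol <- vertebra_solid(template)
  q_lm <- sol$landmark

  if (abs(target - total) <= 1e-9) {
    phis <- rep(0, n)
    lm <- cbind(total - c(0, cumsum(gaps)), 0, q_lm[3])
  } else {
    # circle radius such that the polyline of chords has chord `target`;
    # the arc center sits dorsal of the landmarks, so the vertebral bodies
    # (ventral of the landmark circle) spread apart rather than converge
    f <- function(R) {
      ang <- 2 * asin(pmin(1, gaps / (2 * R)))
      2 * R * sin(sum(ang) / 2) - target
    }
    lo <- max(gaps) / 2 * 1.0001
    R <- stats::uniroot(f, c(lo, 1e7), tol = 1e-10)$root
    ang <- 2 * asin(gaps / (2 * R))
    phis <- -sum(ang) / 2 + c(0, cumsum(ang))  # cranial (-) to caudal (+)
    lm <- cbind(-R * sin(phis), 0, q_lm[3] + R - R * cos(phis))
  }

  # vertebrae keep an upright orientation along the curved chain: the arc
  # fixes the landmark positions, not the bone orientations, so the
  # craniodorsal-vertex rule stays stable across the loading phases
  meshes <- vector("list", n)
  trs <- vector("list", n)
  for (k in seq_len(n)) {
    tr <- rigid_transform(diag(3), lm[k, ] - q_lm)
    trs[[k]] <- tr
    meshes[[k]] <- transform_mesh(sol$mesh, tr)
    meshes[[k]]$label <- template$labels[k]
  }
  pose <- structure(meshes, class = "spine_pose",
                    template = template, landmarks = lm,
                    transforms = trs, local_landmark = q_lm,
                    profiles = list(body = sol$profile_body,
                                    blade = sol$profile_blade),
                    phase = "resting", condition = "pre")
  check_pose_clearance(pose)
  pose
}

# 2D sagittal-profile interpenetration check between consecutive vertebrae.
check_pose_clearance <- function(pose, context = "build_template") {
  prof <- attr(pose, "profiles")
  trs <- attr(pose, "transforms")
  n <- length(pose)
  to_xz <- function(P2, tr) {
    P3 <- cbind(P2[, 1], 0, P2[, 2])
    W <- apply_transform(tr, P3)
    W[, c(1, 3)]
  }
  for (k in seq_len(n - 1)) {
    a_body <- to_xz(prof$body, trs[[k]]); a_blade <- to_xz(prof$blade, trs[[k]])
    b_body <- to_xz(prof$body, trs[[k + 1]]); b_blade <- to_xz(prof$blade, trs[[k + 1]])
    hit <- sat_overlap_2d(a_body, b_body) || sat_overlap_2d(a_body, b_blade) ||
      sat_overlap_2d(a_blade, b_body) || sat_overlap_2d(a_blade, b_blade)
    if (hit)
      stop(sprintf("%s: vertebrae %d and %d interpenetrate at interspinous space %d",
                   context, k, k + 1, k))
  }
  invisible(TRUE)
}

#' @export
print.spine_pose <- function(x, ...) {
  labs <- vapply(x, function(m) if (is.null(m$label)) "?" else m$label, "")
  cat(sprintf("spine_pose: %d vertebrae (%s..%s), phase=%s, condition=%s\n",
              length(x), labs[1], labs[length(labs)],
              attr(x, "phase"), attr(x, "condition")))
  invisible(x)
}

#' Joint configuration for flexion/extension articulation
#'
#' Per-space rotations about the mediolateral (y) axis. Flexion closes the
#' interspinous gaps (ratchet on the dorsal aspect compressing the DSPs);
#' extension opens them. After desmotomy (\code{condition = "post"}) the
#' flexion amplitude is multiplied by \code{isld_flexion_multiplier};
#' extension is unchanged, matching the observed asymmetry of the procedure.
#' Defaults are calibrated (see \code{scripts/calibrate_defaults.R}) so the
#' default template's mean per-space range of motion is 17.9 mm pre and
#' 23.5 mm post desmotomy.
#'
#' @param flexion_amplitude_deg per-joint flexion rotation, degrees (scalar or
#'   one value per space).
#' @param extension_amplitude_deg per-joint extension rotation, degrees.
#' @param isld_flexion_multiplier dimensionless multiplier (>= 1) applied to
#'   flexion amplitudes post-desmotomy.
#' @param pivot_offset ventral offset of the rotation pivot from the DSP tip
#'   (mm). The default (450 mm) places a virtual center of rotation well
#'   ventral of the column, so each interspinous space closes mostly by
#'   shear with a small per-joint rotation, keeping the cumulative vertebral
#'   tilt (and hence the global L1 rotation) in the anatomically observed
#'   range of roughly 12-22 degrees between flexion and extension.
#' @return object of class \code{joint_config}.
#' @export
joint_config <- function(flexion_amplitude_deg = 1.183326,
                         extension_amplitude_deg = 1.167297,
                         isld_flexion_multiplier = 1.639650,
                         pivot_offset = 450) {
  if (any(flexion_amplitude_deg < 0) || any(extension_amplitude_deg < 0))
    stop("amplitudes must be >= 0")
  if (any(isld_flexion_multiplier < 1))
    stop("isld_flexion_multiplier must be >= 1")
  structure(list(flexion_amplitude_deg = flexion_amplitude_deg,
                 extension_amplitude_deg = extension_amplitude_deg,
                 isld_flexion_multiplier = isld_flexion_multiplier,
                 pivot_offset = pivot_offset),
            class = "joint_config")
}

joint_pivots <- function(pose, joints) {
  tpl <- attr(pose, "template")
  lm <- attr(pose, "landmarks")
  trs <- attr(pose, "transforms")
  off <- joints$pivot_offset
  if (is.null(off)) off <- tpl$dsp_height + tpl$body_size[3] / 2  # body center line
  n <- length(pose)
  piv <- matrix(0, n - 1, 3)
  for (j in seq_len(n - 1)) {
    dorsal <- as.numeric(trs[[j]]$rotation %*% c(0, 0, 1) +
                         trs[[j + 1]]$rotation %*% c(0, 0, 1))
    dorsal <- dorsal / sqrt(sum(dorsal^2))
    piv[j, ] <- (lm[j, ] + lm[j + 1, ]) / 2 - off * dorsal
  }
  piv
}

#' Articulate a spine pose into an imaging phase
#'
#' Forward-kinematic chain: vertebra \code{i} carries the composed product of
#' the joint rotations at spaces 1..i-1, each about that space's mediolateral
#' pivot (evaluated in the resting frame). T11 stays fixed. The resting phase
#' returns identity transforms; flexion decreases the inter-DSP distances and
#' extension increases them.
#'
#' @param pose resting-frame \code{spine_pose} from \code{build_template}.
#' @param joints a \code{joint_config}.
#' @param phase \code{"resting"}, \code{"flexion"} or \code{"extension"}.
#' @param condition \code{"pre"} or \code{"post"} (desmotomy).
#' @return list with elements \code{pose} (articulated \code{spine_pose}) and
#'   \code{truth} (ground truth: per-vertebra \code{rigid_transform}s mapping
#'   resting to phase coordinates, landmark positions, inter-DSP distances and
#'   total length).
#' @export
articulate <- function(pose, joints = joint_config(),
                       phase = c("resting", "flexion", "extension"),
                       condition = c("pre", "post")) {
  phase <- match.arg(phase)
  condition <- match.arg(condition)
  stopifnot(inherits(pose, "spine_pose"), inherits(joints, "joint_config"))
  if (attr(pose, "phase") != "resting")
    stop("articulate expects the canonical resting pose")
  n <- length(pose)
  ns <- n - 1
  fl <- rep_len(joints$flexion_amplitude_deg, ns)
  ex <- rep_len(joints$extension_amplitude_deg, ns)
  if (condition == "post") fl <- fl * rep_len(joints$isld_flexion_multiplier, ns)
  theta <- switch(phase,
                  resting = rep(0, ns),
                  flexion = fl,
                  extension = -ex)
  piv <- joint_pivots(pose, joints)
  lm0 <- attr(pose, "landmarks")

  G <- vector("list", n)
  G[[1]] <- transform_identity()
  for (k in seq_len(ns)) {
    Rk <- rotation_about(piv[k, ], c(0, 1, 0), theta[k])
    G[[k + 1]] <- compose_transforms(G[[k]], Rk)
  }

  meshes <- vector("list", n)
  trs <- vector("list", n)
  lm <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    meshes[[k]] <- transform_mesh(pose[[k]], G[[k]])
    trs[[k]] <- compose_transforms(G[[k]], attr(pose, "transforms")[[k]])
    lm[k, ] <- apply_transform(G[[k]], lm0[k, ])
  }
  out <- structure(meshes, class = "spine_pose",
                   template = attr(pose, "template"), landmarks = lm,
                   transforms = trs, local_landmark = attr(pose, "local_landmark"),
                   profiles = attr(pose, "profiles"),
                   phase = phase, condition = condition)
  check_pose_clearance(out, context = sprintf("articulate(%s, %s)", phase, condition))
  gaps <- inter_dsp_distances(lm)
  truth <- list(phase = phase, condition = condition,
                transforms = G, landmarks = lm,
                inter_dsp = gaps, total_length = total_length(lm),
                theta_deg = theta, pivots = piv)
  list(pose = out, truth = truth)
}

#' Articulate all three phases and derive condition-level ground truth
#'
#' Convenience wrapper producing the resting, flexion and extension poses of
#' one condition plus the ground-truth kinematics the measurement pipeline is
#' validated against: per-space range of motion (|flexion - extension|
#' inter-DSP distance) and the L1 flexion-to-extension motion decomposed into
#' anatomical translation components and rotation angles.
#'
#' @inheritParams articulate
#' @return list with \code{poses} (named list resting/flexion/extension) and
#'   \code{truth} (per-phase truths plus \code{rom}, \code{l1_motion}).
#' @export
articulate_condition <- function(pose, joints = joint_config(),
                                 condition = c("pre", "post")) {
  condition <- match.arg(condition)
  ph <- lapply(c(resting = "resting", flexion = "flexion", extension = "extension"),
               function(p) articulate(pose, joints, p, condition))
  n <- length(pose)
  Tfe <- compose_transforms(ph$extension$truth$transforms[[n]],
                            invert_transform(ph$flexion$truth$transforms[[n]]))
  cen <- mesh_centroid(ph$flexion$pose[[n]])
  l1 <- decompose_motion(Tfe, centroid = cen)
  rom <- abs(ph$flexion$truth$inter_dsp - ph$extension$truth$inter_dsp)
  list(poses = lapply(ph, `[[`, "pose"),
       truth = list(condition = condition,
                    phases = lapply(ph, `[[`, "truth"),
                    rom = rom,
                    l1_motion = l1,
                    l1_transform = Tfe))
}

#' Specimen sampler
#'
#' Draws per-specimen template/joint parameter sets around the defaults,
#' standing in for between-horse anatomical variability. Deterministic for a
#' fixed seed. \code{between_specimen_sd} entries (all optional):
#' \code{resting_gap} (mm), \code{gap_space} (per-space mm jitter),
#' \code{length_ratio} (jitter of the chord-to-polyline ratio),
#' \code{dsp_height} (mm), \code{body_scale} (relative),
#' \code{flexion_deg}, \code{extension_deg} (deg), \code{amplitude_space_deg}
#' (per-space deg jitter), \code{multiplier} (dimensionless).
#'
#' @param n_specimens number of specimens (default 7).
#' @param between_specimen_sd named list of standard deviations; see Details.
#' @param seed integer seed.
#' @return object of class \code{specimen_sampler}.
#' @export
specimen_sampler <- function(n_specimens = 7,
                             between_specimen_sd = list(),
                             seed = 1L) {
  sd_def <- list(resting_gap = 2.84, gap_space = 0.8, length_ratio = 0.004,
                 dsp_height = 4, body_scale = 0.03,
                 flexion_deg = 0.12, extension_deg = 0.12,
                 amplitude_space_deg = 0.06, multiplier = 0.06)
  sd_def[names(between_specimen_sd)] <- between_specimen_sd
  structure(list(n_specimens = as.integer(n_specimens),
                 between_specimen_sd = sd_def, seed = as.integer(seed)),
            class = "specimen_sampler")
}

#' Sample per-specimen parameter sets
#'
#' @param sampler a \code{specimen_sampler}.
#' @param template base \code{spine_template}.
#' @param joints base \code{joint_config}.
#' @return list of length \code{n_specimens}; each element has \code{template}
#'   and \code{joints}.
#' @export
sample_specimens <- function(sampler = specimen_sampler(),
                             template = spine_template(),
                             joints = joint_config()) {
  stopifnot(inherits(sampler, "specimen_sampler"))
  sdv <- sampler$between_specimen_sd
  n <- sampler$n_specimens
  ns <- template$n_vertebrae - 1
  base_ratio <- template$target_total_length /
    (template$resting_gap * template$n_vertebrae - template$resting_gap)
  # draws beyond 2.5 sd are truncated: the stylized geometry admits a finite
  # articulation envelope before adjacent vertebrae would interpenetrate
  rtr <- function(k, mean, sd, trunc = 2.5)
    mean + sd * pmax(pmin(stats::rnorm(k), trunc), -trunc)
  draw_one <- function() {
      gap <- rtr(1, template$resting_gap, sdv$resting_gap, 2.2)
      prof <- template$gap_profile *
        pmax(0.5, 1 + rtr(ns, 0, sdv$gap_space / gap))
      ratio <- min(0.995, base_ratio + rtr(1, 0, sdv$length_ratio))
      tpl <- spine_template(
        n_vertebrae = template$n_vertebrae,
        body_size = template$body_size * max(0.8, 1 + rtr(1, 0, sdv$body_scale)),
        dsp_height = max(20, rtr(1, template$dsp_height, sdv$dsp_height)),
        dsp_cranial_taper = template$dsp_cranial_taper,
        resting_gap = gap,
        target_total_length = ratio * gap * ns * mean(prof),
        gap_profile = prof,
        labels = template$labels)
      fl <- pmax(0, rep_len(joints$flexion_amplitude_deg, ns) +
                   rtr(1, 0, sdv$flexion_deg) +
                   rtr(ns, 0, sdv$amplitude_space_deg))
      ex <- pmax(0, rep_len(joints$extension_amplitude_deg, ns) +
                   rtr(1, 0, sdv$extension_deg) +
                   rtr(ns, 0, sdv$amplitude_space_deg))
      mult <- max(1, joints$isld_flexion_multiplier + rtr(1, 0, sdv$multiplier, 2))
      list(template = tpl,
           joints = joint_config(fl, ex, mult, joints$pivot_offset))
  }
  with_local_seed(sampler$seed, {
    lapply(seq_len(n), function(i) {
      # rejection sampling: a draw whose most-flexed (post-desmotomy) pose
      # would make adjacent vertebrae interpenetrate is discarded
      for (attempt in 1:25) {
        sp <- draw_one()
        ok <- tryCatch({
          articulate(build_template(sp$template), sp$joints, "flexion", "post")
          TRUE
        }, error = function(e) FALSE)
        if (ok) return(sp)
      }
      stop("could not draw a geometrically valid specimen in 25 attempts; ",
           "reduce the sampler standard deviations")
    })
  })
}

#' Write a spine pose to disk
#'
#' One STL or PLY file per vertebra plus a JSON manifest recording labels,
#' phase, condition and (when present) the ground-truth local-to-world 4x4
#' matrices in row-major order, mm units.
#'
#' @param pose a \code{spine_pose}.
#' @param dir output directory (created if needed).
#' @param format \code{"stl"} or \code{"ply"}.
#' @return the manifest path, invisibly.
#' @export
write_pose <- function(pose, dir, format = c("stl", "ply")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tpl <- attr(pose, "template")
  files <- character(length(pose))
  for (k in seq_along(pose)) {
    files[k] <- file.path(dir, sprintf("%02d_%s.%s", k, tpl$labels[k], format))
    write_mesh(pose[[k]], files[k])
  }
  trs <- attr(pose, "transforms")
  manifest <- list(
    labels = tpl$labels, phase = attr(pose, "phase"),
    condition = attr(pose, "condition"), units = "mm",
    coordinate_convention = "voxel centers at 0-based index * spacing + origin",
    files = basename(files),
    transforms_row_major = lapply(trs, function(tr)
      as.numeric(t(transform_to_matrix(tr)))))
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}
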