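#' Simulated-study configuration
#'
#' Bundles every parameter of a simulated desmotomy study: the specimen
#' sampler (seven specimens by default), the phantom template and joint
#' calibration, the imaging model and grid resolution, the registration
#' settings, and the per-phase scanner-pose jitter that the anchor
#' superimposition has to undo.
#'
#' The default template carries a mild cranial-to-caudal widening of the
#' interspinous gaps (\code{gap_profile}), giving the vertebral-space
#' heterogeneity the repeated-measures ANOVA is sensitive to.
#'
#' @param n_specimens number of simulated specimens.
#' @param seed master seed; every stochastic step derives its seed from it.
#' @param imaging run the full imaging route (voxelize, segment, register);
#'   \code{FALSE} measures the articulated meshes directly.
#' @param spacing isotropic voxel spacing for the study volumes, mm.
#' @param hu_model an \code{hu_model}.
#' @param template base \code{spine_template}.
#' @param joints base \code{joint_config}.
#' @param sampler_sd overrides for \code{specimen_sampler} sds.
#' @param soft_margin soft-tissue envelope margin, mm.
#' @param scan_rot_deg,scan_trans_mm scanner-pose jitter amplitudes per phase.
#' @param icp_sample_n,icp_max_iter,icp_tol ICP settings for the study.
#' @param hausdorff_sample_n surface samples for the L1 Hausdorff distance.
#' @param wrap_radius,smooth_iterations,min_voxels segmentation settings.
#' @param swap_phase_labels swap the flexion/extension labels in every output
#'   (the opposite reading of the loading-phase convention).
#' @return object of class \code{study_config}.
#' @export
study_config <- function(n_specimens = 7, seed = 1L, imaging = TRUE,
                         spacing = 1.5, hu_model = spinekin::hu_model(),
                         template = spine_template(gap_profile = seq(0.96, 1.04, length.out = 8)),
                         joints = joint_config(),
                         sampler_sd = list(),
                         soft_margin = 30,
                         scan_rot_deg = 4, scan_trans_mm = 15,
                         icp_sample_n = 1500, icp_max_iter = 60, icp_tol = 1e-4,
                         hausdorff_sample_n = 2000,
                         wrap_radius = 2, smooth_iterations = 10,
                         min_voxels = 50,
                         swap_phase_labels = FALSE) {
  structure(list(n_specimens = as.integer(n_specimens), seed = as.integer(seed),
                 imaging = imaging, spacing = spacing, hu_model = hu_model,
                 template = template, joints = joints, sampler_sd = sampler_sd,
                 soft_margin = soft_margin, scan_rot_deg = scan_rot_deg,
                 scan_trans_mm = scan_trans_mm, icp_sample_n = icp_sample_n,
                 icp_max_iter = icp_max_iter, icp_tol = icp_tol,
                 hausdorff_sample_n = hausdorff_sample_n,
                 wrap_radius = wrap_radius,
                 smooth_iterations = smooth_iterations,
                 min_voxels = min_voxels,
                 swap_phase_labels = swap_phase_labels),
            class = "study_config")
}

#' Apply a rigid transform to a whole pose
#'
#' Transforms every mesh and the landmark/transform attributes coherently.
#'
#' @param pose a \code{spine_pose}.
#' @param tr a \code{rigid_transform}.
#' @return transformed \code{spine_pose}.
#' @export
transform_pose <- function(pose, tr) {
  out <- pose
  for (i in seq_along(out)) out[[i]] <- transform_mesh(pose[[i]], tr)
  lm <- attr(pose, "landmarks")
  if (!is.null(lm)) attr(out, "landmarks") <- apply_transform(tr, lm)
  trs <- attr(pose, "transforms")
  if (!is.null(trs))
    attr(out, "transforms") <- lapply(trs, function(g) compose_transforms(tr, g))
  out
}

random_rigid <- function(rot_deg, trans_mm, seed) {
  with_local_seed(seed, {
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- stats::runif(1, -rot_deg, rot_deg)
    tt <- stats::runif(3, -trans_mm, trans_mm)
    compose_transforms(rigid_transform(diag(3), tt),
                       rotation_about(c(0, 0, 0), ax, ang))
  })
}

measure_phases <- function(phases, l1_label, config, seed) {
  lm <- lapply(phases, function(p) {
    l <- attr(p, "landmarks")
    if (is.null(l)) pose_landmarks(p) else l
  })
  gaps <- lapply(lm, inter_dsp_distances)
  n <- length(phases$resting)
  reg_fr <- register_bone_across_phases(l1_label, phases$flexion, phases$resting,
                                        sample_n = config$icp_sample_n,
                                        max_iter = config$icp_max_iter,
                                        tol = config$icp_tol, seed = seed)
  reg_re <- register_bone_across_phases(l1_label, phases$resting, phases$extension,
                                        sample_n = config$icp_sample_n,
                                        max_iter = config$icp_max_iter,
                                        tol = config$icp_tol, seed = seed + 1L)
  Tfe <- compose_transforms(reg_re$transform, reg_fr$transform)
  kf <- find_label(phases$flexion, l1_label)
  ke <- find_label(phases$extension, l1_label)
  l1 <- decompose_motion(Tfe, centroid = mesh_centroid(phases$flexion[[kf]]))
  hd <- hausdorff_distance(phases$flexion[[kf]], phases$extension[[ke]],
                           sample_n = config$hausdorff_sample_n, seed = seed + 2L)
  list(landmarks = lm, gaps = gaps,
       total_length = total_length(lm$resting),
       rom = rom_per_space(gaps$flexion, gaps$extension),
       l1 = l1, hausdorff_l1 = hd)
}

#' Run a complete simulated desmotomy study
#'
#' Samples specimens, articulates each into resting/flexion/extension phases
#' pre and post desmotomy, and measures them. On the imaging route every
#' phase is voxelized into a noisy CT volume under a random scanner pose,
#' segmented back into labeled vertebra surfaces, and superimposed on the T11
#' anchor by ICP before measurement; otherwise the articulated meshes are
#' measured directly. Ground-truth kinematics are carried along for
#' validation. Fully deterministic for a fixed \code{seed}.
#'
#' @param config a \code{study_config}.
#' @param progress print per-specimen progress lines.
#' @return object of class \code{isld_study}: \code{spaces} (long data.frame:
#'   specimen, condition, space, resting/flexion/extension inter-DSP distance,
#'   rom, truth_rom), \code{global} (one row per specimen x condition with L1
#'   excursion components, rotations, Hausdorff, total length, and their
#'   ground truths), \code{config}.
#' @export
run_study <- function(config = study_config(), progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  labels <- config$template$labels
  l1_label <- labels[length(labels)]
  anchor <- labels[1]
  specs <- sample_specimens(
    specimen_sampler(config$n_specimens, config$sampler_sd,
                     seed = config$seed),
    config$template, config$joints)

  spaces <- list()
  globals <- list()
  for (i in seq_len(config$n_specimens)) {
    base_pose <- build_template(specs[[i]]$template)
    for (cond in c("pre", "post")) {
      art <- articulate_condition(base_pose, specs[[i]]$joints, cond)
      truth <- art$truth
      seed0 <- config$seed * 1000L + i * 64L + (if (cond == "post") 32L else 0L)
      if (config$imaging) {
        phases <- list()
        lm_err <- 0
        for (pk in seq_along(art$poses)) {
          ph <- names(art$poses)[pk]
          jit <- random_rigid(config$scan_rot_deg, config$scan_trans_mm,
                              seed0 + pk)
          posed <- transform_pose(art$poses[[ph]], jit)
          vol <- voxelize(posed, config$hu_model,
                          spacing = rep(config$spacing, 3),
                          seed = seed0 + 8L + pk,
                          soft_margin = config$soft_margin)
          phases[[ph]] <- segment_vertebrae(
            vol, labels = labels,
            min_voxels = config$min_voxels,
            wrap_radius = config$wrap_radius,
            smooth_iterations = config$smooth_iterations)
          # per-volume landmark recovery, measured in the scan frame
          # (registration accuracy is validated separately)
          ref <- apply_transform(jit, truth$phases[[ph]]$landmarks)
          lm_err <- max(lm_err, sqrt(rowSums(
            (attr(phases[[ph]], "landmarks") - ref)^2)))
        }
        sup <- superimpose_anchor(phases, anchor_label = anchor,
                                  reference_phase = "resting",
                                  sample_n = config$icp_sample_n,
                                  max_iter = config$icp_max_iter,
                                  tol = config$icp_tol, seed = seed0 + 16L)
        meas <- measure_phases(sup$poses, l1_label, config, seed0 + 20L)
      } else {
        meas <- measure_phases(art$poses, l1_label, config, seed0 + 20L)
        lm_err <- max(vapply(names(meas$landmarks), function(ph)
          max(sqrt(rowSums((meas$landmarks[[ph]] -
                            truth$phases[[ph]]$landmarks)^2))), 0))
      }
      ns <- length(labels) - 1
      spaces[[length(spaces) + 1]] <- data.frame(
        specimen = i, condition = cond, space = seq_len(ns),
        d_resting = meas$gaps$resting,
        d_flexion = meas$gaps$flexion,
        d_extension = meas$gaps$extension,
        rom = meas$rom,
        truth_rom = truth$rom,
        truth_d_resting = truth$phases$resting$inter_dsp,
        stringsAsFactors = FALSE)
      globals[[length(globals) + 1]] <- data.frame(
        specimen = i, condition = cond,
        total_length = meas$total_length,
        l1_dorsoventral = meas$l1$dorsoventral,
        l1_craniocaudal = meas$l1$craniocaudal,
        l1_mediolateral = meas$l1$mediolateral,
        l1_rotation_total = meas$l1$total_angle_deg,
        l1_rotation_ml = meas$l1$ml_axis_angle_deg,
        hausdorff_l1 = meas$hausdorff_l1,
        landmark_err_max = lm_err,
        truth_total_length = truth$phases$resting$total_length,
        truth_l1_dorsoventral = truth$l1_motion$dorsoventral,
        truth_l1_craniocaudal = truth$l1_motion$craniocaudal,
        truth_l1_rotation_total = truth$l1_motion$total_angle_deg,
        truth_l1_rotation_ml = truth$l1_motion$ml_axis_angle_deg,
        stringsAsFactors = FALSE)
      if (progress)
        message(sprintf("specimen %d %s: mean ROM %.1f mm (truth %.1f)",
                        i, cond, mean(meas$rom), mean(truth$rom)))
    }
  }
  spaces <- do.call(rbind, spaces)
  globals <- do.call(rbind, globals)
  rownames(spaces) <- rownames(globals) <- NULL
  if (config$swap_phase_labels) {
    fl <- spaces$d_flexion
    spaces$d_flexion <- spaces$d_extension
    spaces$d_extension <- fl
  }
  structure(list(spaces = spaces, global = globals, config = config),
            class = "isld_study")
}

#' @export
print.isld_study <- function(x, ...) {
  cat(sprintf("isld_study: %d specimens, %s route, spacing %g mm\n",
              x$config$n_specimens,
              if (x$config$imaging) "imaging" else "ground-truth mesh",
              x$config$spacing))
  rom <- tapply(x$spaces$rom, x$spaces$condition, mean)
  cat(sprintf("  mean per-space ROM: pre %.1f mm, post %.1f mm\n",
              rom["pre"], rom["post"]))
  invisible(x)
}

per_specimen_metrics <- function(study) {
  sp <- study$spaces
  gl <- study$global
  rom <- stats::aggregate(rom ~ specimen + condition, sp, mean)
  rest <- stats::aggregate(d_resting ~ specimen + condition, sp, mean)
  m <- merge(merge(rom, rest), gl)
  m[order(m$condition, m$specimen), ]
}

study_metric_pair <- function(study, metric) {
  m <- per_specimen_metrics(study)
  pre <- m[m$condition == "pre", ]
  post <- m[m$condition == "post", ]
  if (!identical(pre$specimen, post$specimen))
    stop("unpaired specimens: ",
         paste(union(setdiff(pre$specimen, post$specimen),
                     setdiff(post$specimen, pre$specimen)), collapse = ", "))
  list(pre = stats::setNames(pre[[metric]], pre$specimen),
       post = stats::setNames(post[[metric]], post$specimen))
}

#' Analyze a simulated study with the paired workflow
#'
#' Per-specimen pre/post pairs for every mobility metric are summarized
#' (\code{summarize_effects}) and tested through the normality-gated paired
#' comparison; the per-space ROM table additionally gets the within-subject
#' two-way ANOVA (space x condition) with Tukey post-hoc contrasts, and the
#' resting inter-DSP comparison a post-hoc power analysis.
#'
#' @param study an \code{isld_study}.
#' @param alpha significance level.
#' @return object of class \code{isld_analysis}: \code{effects} (stacked
#'   \code{effect_summary} rows), \code{tests} (named \code{test_result}
#'   list), \code{anova} (\code{rm_anova}), \code{power_resting},
#'   \code{alpha}.
#' @export
analyze_study <- function(study, alpha = 0.05) {
  stopifnot(inherits(study, "isld_study"))
  metrics <- c(rom = "rom", resting_inter_dsp = "d_resting",
               total_length = "total_length",
               l1_dorsoventral = "l1_dorsoventral",
               l1_craniocaudal = "l1_craniocaudal",
               l1_rotation_total = "l1_rotation_total",
               l1_rotation_ml = "l1_rotation_ml",
               hausdorff_l1 = "hausdorff_l1")
  effects <- list()
  tests <- list()
  for (nm in names(metrics)) {
    pair <- study_metric_pair(study, metrics[[nm]])
    effects[[nm]] <- summarize_effects(pair$pre, pair$post, metric = nm,
                                       n_sites = nrow(study$spaces) /
                                         (2 * study$config$n_specimens))
    tests[[nm]] <- paired_compare(pair$pre, pair$post, alpha = alpha)
  }
  an <- rm_anova_spaces(data.frame(specimen = study$spaces$specimen,
                                   space = study$spaces$space,
                                   condition = study$spaces$condition,
                                   value = study$spaces$rom),
                        alpha = alpha)
  rest <- study_metric_pair(study, "d_resting")
  d <- rest$post - rest$pre
  es <- if (stats::sd(d) > 0) mean(d) / stats::sd(d) else 0
  pw <- power_paired(max(abs(es), 1e-6), n = length(d), alpha = alpha)
  structure(list(effects = do.call(rbind, effects), tests = tests,
                 anova = an, power_resting = c(effect_size = es, power = pw$power),
                 alpha = alpha),
            class = "isld_analysis")
}

#' @export
print.isld_analysis <- function(x, ...) {
  cat("Desmotomy study analysis\n")
  print(x$effects)
  for (nm in names(x$tests)) {
    cat(sprintf("%-18s ", nm))
    print(x$tests[[nm]])
  }
  print(x$anova)
  cat(sprintf("post-hoc power of the resting comparison: %.3f (d = %.4f)\n",
              x$power_resting["power"], x$power_resting["effect_size"]))
  invisible(x)
}

#' Write the study report
#'
#' Emits the measurement tables as CSV, the effect/test/ANOVA summary as JSON
#' and a plain-text log. Rerunning with the same configuration and seed is
#' bit-identical.
#'
#' @param study an \code{isld_study}.
#' @param dir output directory (created if needed).
#' @param analysis optional precomputed \code{isld_analysis}.
#' @return named vector of file paths, invisibly.
#' @export
build_report <- function(study, dir, analysis = NULL) {
  validate_study_records(study)
  if (is.null(analysis)) analysis <- analyze_study(study)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(spaces = file.path(dir, "spaces.csv"),
             global = file.path(dir, "global.csv"),
             effects = file.path(dir, "effects.csv"),
             summary = file.path(dir, "summary.json"),
             log = file.path(dir, "report.log"))
  utils::write.csv(study$spaces, paths["spaces"], row.names = FALSE)
  utils::write.csv(study$global, paths["global"], row.names = FALSE)
  utils::write.csv(analysis$effects, paths["effects"], row.names = FALSE)
  summary <- list(
    n_specimens = study$config$n_specimens,
    seed = study$config$seed,
    imaging = study$config$imaging,
    spacing_mm = study$config$spacing,
    effects = analysis$effects,
    tests = lapply(analysis$tests, function(t)
      t[c("test", "statistic", "p_value", "effect_size", "route", "significant")]),
    anova = analysis$anova$table,
    power_resting = as.list(analysis$power_resting))
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  log <- c(sprintf("specimens: %d, seed: %d, route: %s, spacing: %g mm",
                   study$config$n_specimens, study$config$seed,
                   if (study$config$imaging) "imaging" else "mesh",
                   study$config$spacing),
           vapply(names(analysis$tests), function(nm) {
             t <- analysis$tests[[nm]]
             sprintf("%s: %s route, %s, p = %.6g", nm, t$route, t$test, t$p_value)
           }, ""))
  writeLines(log, paths["log"])
  invisible(paths)
}

validate_study_records <- function(study) {
  sp <- study$spaces
  ns <- length(unique(sp$space))
  for (i in unique(sp$specimen)) for (cond in c("pre", "post")) {
    sub <- sp[sp$specimen == i & sp$condition == cond, ]
    if (nrow(sub) != ns)
      stop("incomplete records for specimen ", i, ", condition ", cond)
    bad <- c("resting", "flexion", "extension")[
      c(any(!is.finite(sub$d_resting)), any(!is.finite(sub$d_flexion)),
        any(!is.finite(sub$d_extension)))]
    if (length(bad))
      stop("missing phase ", paste(bad, collapse = "/"),
           " for specimen ", i, ", condition ", cond)
  }
  invisible(TRUE)
}

#' Read a study configuration from YAML
#'
#' Recognized top-level keys mirror the \code{study_config} arguments
#' (\code{n_specimens}, \code{seed}, \code{imaging}, \code{spacing},
#' \code{soft_margin}, \code{swap_phase_labels}, ...), plus nested blocks
#' \code{template} (\code{resting_gap}, \code{target_total_length},
#' \code{dsp_height}, \code{gap_profile}), \code{joints}
#' (\code{flexion_amplitude_deg}, \code{extension_amplitude_deg},
#' \code{isld_flexion_multiplier}, \code{pivot_offset}), \code{hu}
#' (\code{hu_model} arguments) and \code{sampler_sd}.
#'
#' @param path YAML file.
#' @return a \code{study_config}.
#' @export
study_config_from_yaml <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("n_specimens", "seed", "imaging", "spacing", "soft_margin",
              "scan_rot_deg", "scan_trans_mm", "icp_sample_n", "icp_max_iter",
              "icp_tol", "hausdorff_sample_n", "wrap_radius",
              "smooth_iterations", "min_voxels", "swap_phase_labels"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$template)) {
    tpl_args <- y$template
    if (is.null(tpl_args$gap_profile))
      tpl_args$gap_profile <- seq(0.96, 1.04, length.out = 8)
    args$template <- do.call(spine_template, tpl_args)
  }
  if (!is.null(y$joints)) args$joints <- do.call(joint_config, y$joints)
  if (!is.null(y$hu)) args$hu_model <- do.call(hu_model, y$hu)
  if (!is.null(y$sampler_sd)) args$sampler_sd <- y$sampler_sd
  do.call(study_config, args)
}
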