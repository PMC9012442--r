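#' Craniodorsal landmark of a vertebra
#'
#' The single repeatable measurement point per vertebra: among vertices whose
#' dorsal (z) coordinate lies in the top \code{dorsal_fraction} of the mesh's
#' z-extent (the spinous process), the vertex maximizing the cranial (x)
#' coordinate; ties broken by larger z, then by lowest vertex index.
#'
#' @param mesh a \code{vertebra_mesh}.
#' @param dorsal_fraction fraction of the dorsal z-extent searched (default
#'   0.4, restricting the search to the spinous process).
#' @return object of class \code{landmark}: \code{position} (mm 3-vector),
#'   \code{vertex} (index), \code{label}, \code{dorsal_fraction}.
#' @export
craniodorsal_landmark <- function(mesh, dorsal_fraction = 0.4) {
  stopifnot(inherits(mesh, "vertebra_mesh"))
  v <- mesh$vertices
  if (nrow(v) == 0) stop("empty mesh")
  if (dorsal_fraction <= 0 || dorsal_fraction > 1)
    stop("dorsal_fraction must be in (0, 1]")
  zr <- range(v[, 3])
  zcut <- zr[2] - dorsal_fraction * (zr[2] - zr[1])
  cand <- which(v[, 3] >= zcut)
  if (length(cand) == 0) stop("degenerate dorsal_fraction: no candidate vertices")
  xs <- v[cand, 1]
  best <- cand[xs == max(xs)]
  if (length(best) > 1) {
    zs <- v[best, 3]
    best <- best[zs == max(zs)]
    best <- best[1]  # lowest index among remaining ties
  }
  structure(list(position = as.numeric(v[best, ]), vertex = best,
                 label = mesh$label, dorsal_fraction = dorsal_fraction),
            class = "landmark")
}

#' Landmark positions of a spine pose
#'
#' @param pose a \code{spine_pose} (list of meshes, cranial to caudal).
#' @param dorsal_fraction passed to \code{craniodorsal_landmark}.
#' @return n x 3 matrix of landmark positions, rownames = labels.
#' @export
pose_landmarks <- function(pose, dorsal_fraction = 0.4) {
  lm <- t(vapply(pose, function(m)
    craniodorsal_landmark(m, dorsal_fraction)$position, numeric(3)))
  rownames(lm) <- vapply(pose, function(m)
    if (is.null(m$label)) "" else m$label, "")
  lm
}

#' Inter-spinous-process distances
#'
#' Euclidean distance between consecutive craniodorsal landmarks, cranial to
#' caudal (8 values for the 9-vertebra segment).
#'
#' @param landmarks n x 3 matrix of landmark positions ordered cranial to
#'   caudal (a list of \code{landmark} objects is also accepted).
#' @return numeric vector of length n - 1, mm.
#' @export
inter_dsp_distances <- function(landmarks) {
  lm <- landmark_matrix(landmarks)
  if (nrow(lm) < 2) stop("at least 2 landmarks required")
  sqrt(rowSums((lm[-1, , drop = FALSE] - lm[-nrow(lm), , drop = FALSE])^2))
}

#' Total segment length
#'
#' Straight-line distance between the first (T11) and last (L1) craniodorsal
#' landmarks.
#'
#' @inheritParams inter_dsp_distances
#' @return mm scalar.
#' @export
total_length <- function(landmarks) {
  lm <- landmark_matrix(landmarks)
  if (nrow(lm) < 2) stop("at least 2 landmarks required")
  sqrt(sum((lm[nrow(lm), ] - lm[1, ])^2))
}

landmark_matrix <- function(landmarks) {
  if (is.list(landmarks) && !is.matrix(landmarks))
    landmarks <- t(vapply(landmarks, function(l)
      if (inherits(l, "landmark")) l$position else as.numeric(l), numeric(3)))
  as.matrix(landmarks)
}

#' Per-space range of motion
#'
#' The dorsoventral range of motion of one interspinous space is the absolute
#' difference of its inter-DSP distance between the flexion and extension
#' phases; study-level values average over spaces and specimens.
#'
#' @param d_flexion,d_extension inter-DSP distances (mm, non-negative;
#'   vectors are paired per space).
#' @return |d_flexion - d_extension| per space, mm.
#' @export
rom_per_space <- function(d_flexion, d_extension) {
  if (any(d_flexion < 0) || any(d_extension < 0))
    stop("inter-DSP distances must be non-negative")
  if (length(d_flexion) != length(d_extension))
    stop("flexion and extension distances must pair per space")
  abs(d_flexion - d_extension)
}

#' Decompose a rigid motion into anatomical components
#'
#' Translation components are reported for the motion of the bone's centroid
#' (\code{(R - I) c + t}), making them independent of the arbitrary coordinate
#' origin: dorsoventral = |z|, craniocaudal = |x|, mediolateral = |y|. The
#' total rotation angle is \code{acos((tr(R) - 1)/2)}; the mediolateral-axis
#' rotation is the axis-angle rotation projected on the y axis
#' (angle times |axis . y|).
#'
#' @param tr a \code{rigid_transform}.
#' @param centroid reference point (mm), typically the moving bone's centroid.
#' @return named list: \code{dorsoventral}, \code{craniocaudal},
#'   \code{mediolateral} (mm), \code{total_angle_deg},
#'   \code{ml_axis_angle_deg}, plus the signed \code{translation} vector at
#'   the centroid.
#' @export
decompose_motion <- function(tr, centroid = c(0, 0, 0)) {
  stopifnot(is_rigid_transform(tr))
  aa <- axis_angle(tr$rotation)  # also validates orthonormality
  t_eff <- as.numeric((tr$rotation - diag(3)) %*% centroid + tr$translation)
  list(dorsoventral = abs(t_eff[3]),
       craniocaudal = abs(t_eff[1]),
       mediolateral = abs(t_eff[2]),
       total_angle_deg = aa$angle_deg,
       ml_axis_angle_deg = aa$angle_deg * abs(aa$axis[2]),
       translation = t_eff)
}

#' Pre/post effect summary
#'
#' Paired pre/post summary for one metric: means and standard deviations, the
#' mean per-specimen absolute change, the mean per-specimen percent change,
#' and the per-site effect (percent change divided by the number of desmotomy
#' sites). The group-mean percent convention
#' (100 * (mean(post) - mean(pre)) / mean(pre)) is emitted alongside;
#' per-specimen is primary. Values are exact; rounding to 1 decimal happens
#' only in the print method.
#'
#' @param pre,post per-specimen values, paired by position (or by names when
#'   both are named).
#' @param metric metric name.
#' @param n_sites number of desmotomy sites the effect spans (default 8).
#' @return one-row data.frame of class \code{effect_summary}.
#' @examples
#' summarize_effects(17.9, 23.5, "rom")$change          # 5.6
#' summarize_effects(22.9, 29.8, "craniocaudal")$percent # 30.13...
#' @export
summarize_effects <- function(pre, post, metric = "metric", n_sites = 8) {
  if (!is.null(names(pre)) && !is.null(names(post))) {
    miss <- c(setdiff(names(pre), names(post)), setdiff(names(post), names(pre)))
    if (length(miss))
      stop("unpaired specimens: ", paste(unique(miss), collapse = ", "))
    post <- post[names(pre)]
  } else if (length(pre) != length(post)) {
    stop("pre and post must pair per specimen (lengths ", length(pre),
         " vs ", length(post), ")")
  }
  diffs <- post - pre
  pct <- ifelse(pre > 0, 100 * diffs / pre, NA_real_)
  out <- data.frame(
    metric = metric,
    n = length(pre),
    pre_mean = mean(pre), pre_sd = stats::sd(pre),
    post_mean = mean(post), post_sd = stats::sd(post),
    change = mean(diffs), change_sd = stats::sd(diffs),
    percent = mean(pct), percent_sd = stats::sd(pct),
    percent_of_means = if (mean(pre) > 0) 100 * mean(diffs) / mean(pre) else NA_real_,
    per_site_percent = mean(pct) / n_sites,
    n_sites = n_sites,
    stringsAsFactors = FALSE)
  class(out) <- c("effect_summary", "data.frame")
  out
}

#' @export
print.effect_summary <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%s: pre %.1f +/- %.1f, post %.1f +/- %.1f, change %.1f (%.1f%%), %.1f%% per site\n",
                x$metric[i], x$pre_mean[i], x$pre_sd[i], x$post_mean[i],
                x$post_sd[i], x$change[i], x$percent[i], x$per_site_percent[i]))
  }
  invisible(x)
}
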