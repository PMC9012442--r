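#' Bone mask by Hounsfield-unit thresholding
#'
#' Selects every voxel whose HU lies inside the bone window, both ends
#' inclusive. The window used is recorded as provenance.
#'
#' @param volume a \code{ct_volume}.
#' @param hu_lo,hu_hi window bounds in HU (defaults +700 and +3000, the
#'   standard bone window for spinous-process segmentation).
#' @return object of class \code{bone_mask}: logical array with attributes
#'   \code{spacing}, \code{origin} and \code{provenance}.
#' @examples
#' vol <- ct_volume(array(c(699.9, 700, 3000, 3000.1), c(4, 1, 1)))
#' sum(threshold_mask(vol)$mask)  # 2: both ends inclusive
#' @export
threshold_mask <- function(volume, hu_lo = 700, hu_hi = 3000) {
  stopifnot(inherits(volume, "ct_volume"))
  if (hu_lo >= hu_hi) stop("hu_lo must be < hu_hi")
  m <- volume$hu >= hu_lo & volume$hu <= hu_hi
  if (!any(m))
    warning("empty bone mask: no voxel within the HU window [", hu_lo, ", ", hu_hi, "]")
  structure(list(mask = m, spacing = volume$spacing, origin = volume$origin,
                 provenance = list(hu_lo = hu_lo, hu_hi = hu_hi)),
            class = "bone_mask")
}

#' Label individual vertebrae in a bone mask
#'
#' Connected components above \code{min_voxels}, relabeled in cranial-to-caudal
#' order (decreasing centroid +x, the cranial axis, so label 1 is the most
#' cranial vertebra). When \code{expected_n} is given and the count differs,
#' one morphological opening iteration (3^3 box) is applied to split
#' noise-bridged components before relabeling; a persistent mismatch is an
#' error listing the component counts.
#'
#' @param mask a \code{bone_mask}.
#' @param connectivity 6, 18 or 26 (default 26).
#' @param min_voxels minimum component size kept.
#' @param expected_n expected number of vertebrae, or NULL to accept any.
#' @return object of class \code{labeled_vertebrae}: integer array
#'   \code{labels} (0 background, 1..n cranial to caudal), \code{voxel_counts},
#'   \code{spacing}, \code{origin}, \code{provenance}.
#' @export
label_components <- function(mask, connectivity = 26, min_voxels = 50,
                             expected_n = NULL) {
  stopifnot(inherits(mask, "bone_mask"))
  if (!connectivity %in% c(6, 18, 26)) stop("connectivity must be 6, 18 or 26")
  if (!any(mask$mask)) stop("refusing to label an empty bone mask")
  opened <- FALSE
  m <- mask$mask
  relabel <- function(m) {
    lab <- cpp_label_components(m, dim(m), as.integer(connectivity))
    counts <- tabulate(lab[lab > 0L])
    keep <- which(counts >= min_voxels)
    if (length(keep) == 0)
      stop("min_voxels (", min_voxels, ") exceeds the largest component (",
           max(counts), " voxels)")
    # order components cranial -> caudal by centroid along +x (cranial axis)
    nx <- dim(m)[1]
    xs <- slice.index(array(0, dim(m)), 1)
    cx <- vapply(keep, function(k) mean(xs[lab == k]), 0)
    ord <- keep[order(cx, decreasing = TRUE)]
    out <- array(0L, dim(m))
    for (i in seq_along(ord)) out[lab == ord[i]] <- i
    list(labels = out, counts = counts[ord], n_raw = length(counts))
  }
  res <- relabel(m)
  if (!is.null(expected_n) && length(res$counts) != expected_n) {
    m2 <- cpp_box_morph(cpp_box_morph(m, dim(m), 1L, FALSE), dim(m), 1L, TRUE)
    res2 <- relabel(m2)
    opened <- TRUE
    if (length(res2$counts) != expected_n)
      stop("component count mismatch: expected ", expected_n, ", found ",
           length(res$counts), " (", length(res2$counts),
           " after one opening iteration); sizes: ",
           paste(res$counts, collapse = ", "))
    res <- res2
  }
  structure(list(labels = res$labels, voxel_counts = res$counts,
                 spacing = mask$spacing, origin = mask$origin,
                 provenance = c(mask$provenance,
                                list(connectivity = connectivity,
                                     min_voxels = min_voxels,
                                     opening_applied = opened,
                                     components_raw = res$n_raw))),
            class = "labeled_vertebrae")
}

#' @export
print.labeled_vertebrae <- function(x, ...) {
  cat(sprintf("labeled_vertebrae: %d components (%s voxels)%s\n",
              length(x$voxel_counts), paste(x$voxel_counts, collapse = ", "),
              if (isTRUE(x$provenance$opening_applied)) ", opening applied" else ""))
  invisible(x)
}

#' Extract the surface of one labeled vertebra
#'
#' Morphological closing (\code{wrap_radius} voxels, the "wrap" step) fills
#' surface pits, then the boundary of the binary label field is triangulated
#' as a watertight surface at the voxel faces, vertices in physical mm
#' coordinates (voxel centers at 0-based index times spacing plus origin).
#'
#' @param labeled a \code{labeled_vertebrae}.
#' @param label_id label to extract (1..n).
#' @param wrap_radius closing radius in voxels (0 disables).
#' @param label optional vertebra name attached to the mesh.
#' @return a watertight \code{vertebra_mesh}.
#' @export
extract_surface <- function(labeled, label_id, wrap_radius = 2, label = NULL) {
  stopifnot(inherits(labeled, "labeled_vertebrae"))
  m <- labeled$labels == as.integer(label_id)
  if (!any(m)) stop("label ", label_id, " absent from the labeled volume")
  # crop to the label bounding box (plus closing margin) before morphology
  idx <- which(m, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - wrap_radius - 1L, 1L)
  hi <- pmin(apply(idx, 2, max) + wrap_radius + 1L, dim(m))
  m <- m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  origin <- labeled$origin + (lo - 1L) * labeled$spacing
  if (wrap_radius > 0) {
    m <- cpp_box_morph(cpp_box_morph(m, dim(m), as.integer(wrap_radius), TRUE),
                       dim(m), as.integer(wrap_radius), FALSE)
  }
  surf <- cpp_boundary_surface(array(as.integer(m), dim(m)), dim(m), 1L,
                               origin, labeled$spacing)
  vertebra_mesh(surf$vertices, surf$faces, label = label)
}

#' Smooth a surface mesh
#'
#' Taubin lambda-mu smoothing: a shrink pass with weight \code{relaxation}
#' followed by an inflate pass, which keeps the enclosed volume nearly
#' constant. With \code{volume_preserving = FALSE} only the shrink pass runs
#' (plain Laplacian smoothing).
#'
#' @param mesh a \code{vertebra_mesh}.
#' @param iterations smoothing iterations (0 returns the input unchanged).
#' @param relaxation Laplacian step weight in (0, 1).
#' @param volume_preserving use the Taubin inflate pass.
#' @param max_displacement optional cap (mm) on the total displacement of any
#'   vertex; segmentation uses one voxel diagonal, bounding the bias the
#'   smoother can introduce at sharp ridges.
#' @return smoothed \code{vertebra_mesh} (same topology).
#' @export
smooth_mesh <- function(mesh, iterations = 10, relaxation = 0.5,
                        volume_preserving = TRUE, max_displacement = Inf) {
  stopifnot(inherits(mesh, "vertebra_mesh"))
  if (iterations == 0) return(mesh)
  if (relaxation <= 0 || relaxation >= 1) stop("relaxation must be in (0, 1)")
  mu <- if (volume_preserving) 1 / (0.1 - 1 / relaxation) else 0
  v <- cpp_taubin_smooth(mesh$vertices, mesh$faces, as.integer(iterations),
                         relaxation, mu)
  if (is.finite(max_displacement)) {
    d <- v - mesh$vertices
    len <- sqrt(rowSums(d^2))
    f <- pmin(1, max_displacement / pmax(len, 1e-300))
    v <- mesh$vertices + d * f
  }
  vertebra_mesh(v, mesh$faces, mesh$label)
}

#' Segment a CT volume into labeled vertebra surfaces
#'
#' Convenience pipeline: HU threshold, connected components with expected
#' count, per-label closing + surfacing + smoothing. Mirrors the manual
#' mask/3D-part/wrap-and-smooth workflow of clinical modeling suites.
#'
#' @param volume a \code{ct_volume}.
#' @param labels vertebra names assigned cranial to caudal.
#' @param hu_lo,hu_hi HU window.
#' @param connectivity,min_voxels passed to \code{label_components}.
#' @param wrap_radius,smooth_iterations surface cleanup parameters.
#' @return a \code{spine_pose}-like list of \code{vertebra_mesh} objects with
#'   attribute \code{provenance}.
#' @export
segment_vertebrae <- function(volume, labels = c(paste0("T", 11:18), "L1"),
                              hu_lo = 700, hu_hi = 3000,
                              connectivity = 26, min_voxels = 50,
                              wrap_radius = 2, smooth_iterations = 10) {
  mask <- threshold_mask(volume, hu_lo, hu_hi)
  lab <- label_components(mask, connectivity, min_voxels,
                          expected_n = length(labels))
  vdiag <- sqrt(sum(volume$spacing^2))
  raw <- lapply(seq_along(labels), function(k)
    extract_surface(lab, k, wrap_radius, label = labels[k]))
  # craniodorsal landmarks are measured on the voxel-accurate (unsmoothed)
  # surface: smoothing is for registration and surface distances, and even
  # bounded smoothing biases sharp ridges systematically
  landmarks <- t(vapply(raw, function(m) craniodorsal_landmark(m)$position,
                        numeric(3)))
  rownames(landmarks) <- labels
  meshes <- lapply(raw, smooth_mesh, iterations = smooth_iterations,
                   max_displacement = vdiag)
  structure(meshes, class = "spine_pose", phase = NA_character_,
            condition = NA_character_, landmarks = landmarks,
            provenance = lab$provenance)
}
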