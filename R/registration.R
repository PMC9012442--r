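#' Kabsch rigid alignment of corresponding points
#'
#' Returns the proper rigid transform minimizing the (weighted) sum of squared
#' distances between corresponding points; reflections are excluded by the
#' determinant correction of the SVD solution.
#'
#' @param src,dst n x 3 matrices of corresponding points (n >= 3,
#'   non-collinear).
#' @param weights optional non-negative weights (default uniform).
#' @return a \code{rigid_transform} mapping \code{src} onto \code{dst}.
#' @examples
#' R0 <- rot_y(20); t0 <- c(3, -1, 2)
#' src <- matrix(rnorm(30), 10, 3)
#' dst <- sweep(src %*% t(R0), 2, t0, "+")
#' kabsch(src, dst)  # recovers the 20 degree rotation and t0
#' @export
kabsch <- function(src, dst, weights = NULL) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) != nrow(dst) || ncol(src) != 3 || ncol(dst) != 3)
    stop("src and dst must be matching n x 3 matrices")
  n <- nrow(src)
  if (n < 3) stop("at least 3 correspondences required")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0)
    stop("invalid weights")
  w <- weights / sum(weights)
  cs <- colSums(src * w); cd <- colSums(dst * w)
  X <- sweep(src, 2, cs); Y <- sweep(dst, 2, cd)
  H <- t(X * w) %*% Y
  sv <- svd(H)
  # degenerate (collinear/coincident) configurations leave the rotation
  # about the point axis undetermined
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300))
    stop("degenerate (collinear or coincident) point configuration")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, as.numeric(cd - R %*% cs))
}

#' Principal-axes initialization for surface registration
#'
#' Aligns centroids and the principal axes of two point clouds; axis signs are
#' disambiguated by third moments (skewness) along each axis, and the rotation
#' is forced proper.
#'
#' @param src_pts,dst_pts point matrices.
#' @param rotate align principal axes (otherwise translation only).
#' @return a \code{rigid_transform}.
#' @export
init_principal_axes <- function(src_pts, dst_pts, rotate = TRUE) {
  cs <- colMeans(src_pts); cd <- colMeans(dst_pts)
  if (!rotate)
    return(rigid_transform(diag(3), cd - cs))
  ax <- function(P) {
    V <- eigen(stats::cov(P), symmetric = TRUE)$vectors
    if (det(V) < 0) V[, 3] <- -V[, 3]
    V
  }
  Vs <- ax(src_pts); Vd <- ax(dst_pts)
  # principal-axis signs are arbitrary: evaluate the four proper sign
  # combinations and keep the one with the lowest nearest-neighbour rms
  ns <- min(nrow(src_pts), 400L)
  sub <- src_pts[seq(1, nrow(src_pts), length.out = ns), , drop = FALSE]
  best <- NULL; best_rms <- Inf
  for (sgn in list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))) {
    R <- Vd %*% diag(sgn) %*% t(Vs)
    tr <- rigid_transform(R, as.numeric(cd - R %*% cs))
    d <- cpp_nn_dist(apply_transform(tr, sub), dst_pts)$dist
    rms <- sqrt(mean(d^2))
    if (rms < best_rms) { best_rms <- rms; best <- tr }
  }
  best
}

#' Iterative closest point rigid registration
#'
#' Point-to-point ICP on uniformly sampled surface points: nearest-neighbour
#' correspondences, Kabsch update, until the RMS residual decrease falls below
#' \code{tol} or \code{max_iter} is reached. The RMS residual is non-increasing
#' across iterations (asserted). Deterministic for a fixed sampling seed.
#'
#' @param src_mesh,dst_mesh \code{vertebra_mesh} objects (plain point matrices
#'   are also accepted).
#' @param init initial \code{rigid_transform} (default: centroid + principal
#'   axes via \code{init_principal_axes}).
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the RMS decrease, mm.
#' @param sample_n surface samples per mesh.
#' @param trim_fraction fraction of worst correspondences dropped each
#'   iteration (0 for complete surfaces).
#' @param seed sampling seed.
#' @param refine_iter point-to-surface polishing iterations after the
#'   point-to-point phase (closest point on triangle; removes the sampling
#'   floor of nearest-neighbour correspondences). 0 disables; ignored when
#'   the target is a bare point set.
#' @return object of class \code{registration_result}: \code{transform}
#'   (mapping source to target coordinates), \code{rms_residual} (mm),
#'   \code{iterations}, \code{converged}, \code{diagnostic}.
#' @export
icp <- function(src_mesh, dst_mesh, init = NULL, max_iter = 100, tol = 1e-6,
                sample_n = 5000, trim_fraction = 0, seed = 1L,
                refine_iter = 15) {
  pts_of <- function(m, sd) {
    if (inherits(m, "vertebra_mesh")) {
      if (nrow(m$faces) == 0) stop("empty mesh")
      sample_surface(m, sample_n, seed = sd)
    } else as.matrix(m)
  }
  P <- pts_of(src_mesh, seed)
  Q <- pts_of(dst_mesh, seed)
  if (is.null(init)) init <- init_principal_axes(P, Q)
  tr <- init
  keep_n <- max(3L, as.integer(round(nrow(P) * (1 - trim_fraction))))
  rms_prev <- Inf
  it <- 0L
  converged <- FALSE
  rms <- NA_real_
  while (it < max_iter) {
    it <- it + 1L
    Pt <- apply_transform(tr, P)
    nn <- cpp_nn_dist(Pt, Q)
    ord <- if (keep_n < nrow(P)) order(nn$dist)[seq_len(keep_n)] else seq_len(nrow(P))
    rms <- sqrt(mean(nn$dist[ord]^2))
    if (trim_fraction == 0 && rms > rms_prev + 1e-9)
      stop("internal error: ICP residual increased")  # contract: monotone
    if (rms_prev - rms < tol) { converged <- TRUE; break }
    rms_prev <- rms
    # Kabsch on the original source points against the current matches
    # replaces (not composes) the transform estimate
    tr <- kabsch(P[ord, , drop = FALSE], Q[nn$index[ord], , drop = FALSE])
  }
  if (refine_iter > 0 && inherits(dst_mesh, "vertebra_mesh")) {
    keep_n2 <- max(3L, as.integer(round(nrow(P) * (1 - trim_fraction))))
    for (r in seq_len(refine_iter)) {
      Pt <- apply_transform(tr, P)
      cp <- cpp_closest_point_on_mesh(Pt, dst_mesh$vertices, dst_mesh$faces)
      ord <- if (keep_n2 < nrow(P)) order(cp$dist)[seq_len(keep_n2)] else seq_len(nrow(P))
      rms_new <- sqrt(mean(cp$dist[ord]^2))
      if (abs(rms - rms_new) < tol * 1e-3 && r > 1) { rms <- rms_new; break }
      rms <- rms_new
      tr <- kabsch(P[ord, , drop = FALSE], cp$points[ord, , drop = FALSE])
      it <- it + 1L
    }
    Pt <- apply_transform(tr, P)
    cp <- cpp_closest_point_on_mesh(Pt, dst_mesh$vertices, dst_mesh$faces)
    rms <- sqrt(mean(sort(cp$dist)[seq_len(keep_n2)]^2))
    converged <- TRUE
  }
  scale <- max(apply(Q, 2, function(x) diff(range(x))))
  diagnostic <- if (!converged) {
    "maximum iterations reached before tolerance"
  } else if (rms > 0.25 * scale) {
    converged <- FALSE
    "residual comparable to object size: inputs may not overlap after init"
  } else "ok"
  structure(list(transform = tr, rms_residual = rms, iterations = it,
                 converged = converged, diagnostic = diagnostic),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration: rms %.4g mm after %d iterations (%s)\n",
              x$rms_residual, x$iterations,
              if (x$converged) "converged" else x$diagnostic))
  print(x$transform)
  invisible(x)
}

find_label <- function(pose, label) {
  labs <- vapply(pose, function(m) if (is.null(m$label)) NA_character_ else m$label, "")
  k <- which(labs == label)
  if (length(k) != 1) stop("vertebra '", label, "' not found in pose")
  k
}

#' Superimpose imaging phases on an anchor vertebra
#'
#' Registers the anchor vertebra (default T11) of every phase onto the anchor
#' of the reference phase by ICP and applies each phase's anchor transform to
#' every vertebra of that phase, preserving the spatial relationship within
#' the phase exactly. Motion is thereafter expressed relative to the anchor.
#'
#' @param poses named list of \code{spine_pose} objects (one per phase).
#' @param anchor_label anchor vertebra label.
#' @param reference_phase name of the phase left unchanged.
#' @param ... passed to \code{icp}.
#' @return list with \code{poses} (aligned), \code{transforms} (per-phase
#'   anchor \code{rigid_transform}) and \code{registrations} (per-phase
#'   \code{registration_result}).
#' @export
superimpose_anchor <- function(poses, anchor_label = "T11",
                               reference_phase = "resting", ...) {
  stopifnot(is.list(poses), !is.null(names(poses)))
  if (!reference_phase %in% names(poses))
    stop("reference phase '", reference_phase, "' missing")
  ref_mesh <- poses[[reference_phase]][[find_label(poses[[reference_phase]], anchor_label)]]
  out_poses <- poses
  transforms <- vector("list", length(poses))
  names(transforms) <- names(poses)
  regs <- transforms
  for (ph in names(poses)) {
    if (ph == reference_phase) {
      transforms[[ph]] <- transform_identity()
      regs[[ph]] <- NULL
      next
    }
    k <- find_label(poses[[ph]], anchor_label)
    reg <- icp(poses[[ph]][[k]], ref_mesh, ...)
    if (!reg$converged)
      stop("anchor registration failed for phase '", ph, "': ", reg$diagnostic)
    transforms[[ph]] <- reg$transform
    regs[[ph]] <- reg
    for (i in seq_along(out_poses[[ph]]))
      out_poses[[ph]][[i]] <- transform_mesh(poses[[ph]][[i]], reg$transform)
    for (at in c("landmarks")) {
      lm <- attr(poses[[ph]], at)
      if (!is.null(lm)) attr(out_poses[[ph]], at) <- apply_transform(reg$transform, lm)
    }
  }
  list(poses = out_poses, transforms = transforms, registrations = regs)
}

#' Register one bone between two (anchor-superimposed) phases
#'
#' ICP of the named bone from \code{pose_a} to \code{pose_b}; with both poses
#' expressed in the anchor frame the returned transform is the bone's motion
#' between the phases.
#'
#' @param bone_label vertebra label (e.g. \code{"L1"}).
#' @param pose_a,pose_b \code{spine_pose} objects.
#' @param ... passed to \code{icp}.
#' @return a \code{registration_result}.
#' @export
register_bone_across_phases <- function(bone_label, pose_a, pose_b, ...) {
  ka <- find_label(pose_a, bone_label)
  kb <- find_label(pose_b, bone_label)
  icp(pose_a[[ka]], pose_b[[kb]], ...)
}
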