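#' Triangulated surface meshes
#'
#' Meshes are stored as a vertex matrix (mm, rows = points) and a 1-based
#' face index matrix with outward-oriented (counter-clockwise from outside)
#' triangles. \code{label} carries the vertebral level (\code{"T11"} ...
#' \code{"L1"}) through the pipeline.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param label optional character label.
#' @return object of class \code{vertebra_mesh}.
#' @export
vertebra_mesh <- function(vertices, faces, label = NULL) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces, label = label),
            class = "vertebra_mesh")
}

#' @export
print.vertebra_mesh <- function(x, ...) {
  cat(sprintf("vertebra_mesh%s: %d vertices, %d faces, volume %.1f mm^3\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              nrow(x$vertices), nrow(x$faces), mesh_volume(x)))
  invisible(x)
}

#' Mesh measures
#'
#' \code{mesh_volume} uses the divergence theorem (signed tetrahedra); it is
#' exact for closed, consistently oriented surfaces. \code{mesh_area} sums
#' triangle areas. \code{mesh_centroid} is the volume centroid.
#'
#' @param mesh a \code{vertebra_mesh}.
#' @return scalar mm^3 / mm^2, or length-3 mm vector.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(rowSums(a * cr)) / 6
}

#' @rdname mesh_volume
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' @rdname mesh_volume
#' @export
mesh_centroid <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  w <- rowSums(a * cr) / 6
  num <- colSums((a + b + c_) / 4 * w)
  as.numeric(num / sum(w))
}

#' Watertightness check
#'
#' A closed orientable surface has every edge shared by exactly two faces with
#' opposite orientation.
#'
#' @param mesh a \code{vertebra_mesh}.
#' @return logical.
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(FALSE)
  ed <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  tab <- table(key)
  if (any(tab != 2)) return(FALSE)
  # opposite orientation: each directed edge appears exactly once
  dkey <- paste(ed[, 1], ed[, 2])
  !any(duplicated(dkey))
}

#' Transform a mesh rigidly
#'
#' @param mesh a \code{vertebra_mesh}.
#' @param tr a \code{rigid_transform}.
#' @return transformed \code{vertebra_mesh}.
#' @export
transform_mesh <- function(mesh, tr) {
  vertebra_mesh(apply_transform(tr, mesh$vertices), mesh$faces, mesh$label)
}

#' Uniform surface sampling
#'
#' Area-weighted triangle selection with uniform barycentric coordinates;
#' deterministic for a fixed seed.
#'
#' @param mesh a \code{vertebra_mesh}.
#' @param n number of sample points.
#' @param seed integer RNG seed (local to the call).
#' @return n x 3 matrix of surface points.
#' @export
sample_surface <- function(mesh, n, seed = 1L) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- sqrt(rowSums(cr^2))
  pts <- with_local_seed(seed, {
    tri <- sample.int(nrow(f), n, replace = TRUE, prob = area)
    r1 <- sqrt(stats::runif(n))
    r2 <- stats::runif(n)
    u <- 1 - r1
    w <- r1 * r2
    v[f[tri, 1], , drop = FALSE] * u +
      v[f[tri, 2], , drop = FALSE] * (r1 * (1 - r2)) +
      v[f[tri, 3], , drop = FALSE] * w
  })
  pts
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Write and read meshes as STL or PLY
#'
#' ASCII formats; the format is chosen from the file extension. PLY preserves
#' vertex coordinates at full double precision; STL duplicates vertices
#' per facet, so reading an STL merges exactly coincident vertices.
#'
#' @param mesh a \code{vertebra_mesh}.
#' @param path output file, extension \code{.stl} or \code{.ply}.
#' @return \code{write_mesh}: the path, invisibly. \code{read_mesh}: a
#'   \code{vertebra_mesh}.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices; f <- mesh$faces
  if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property double x", "property double y", "property double z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else if (ext == "stl") {
    con <- file(path, "w")
    on.exit(close(con))
    nm <- if (is.null(mesh$label)) "mesh" else mesh$label
    writeLines(sprintf("solid %s", nm), con)
    e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    nr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    nn <- sqrt(rowSums(nr^2)); nn[nn == 0] <- 1
    nr <- nr / nn
    for (t in seq_len(nrow(f))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g", nr[t, 1], nr[t, 2], nr[t, 3]), con)
      writeLines("    outer loop", con)
      for (cc in 1:3)
        writeLines(sprintf("      vertex %.17g %.17g %.17g",
                           v[f[t, cc], 1], v[f[t, cc], 2], v[f[t, cc], 3]), con)
      writeLines(c("    endloop", "  endfacet"), con)
    }
    writeLines(sprintf("endsolid %s", nm), con)
  } else stop("unsupported mesh format: ", ext)
  invisible(path)
}

#' @rdname write_mesh
#' @param label optional label attached to the mesh read back.
#' @export
read_mesh <- function(path, label = NULL) {
  if (!file.exists(path)) stop("mesh file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "ply") {
    hd_end <- which(lines == "end_header")[1]
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)[1]))
    nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)[1]))
    vl <- lines[(hd_end + 1):(hd_end + nv)]
    fl <- lines[(hd_end + nv + 1):(hd_end + nv + nf)]
    v <- matrix(scan(text = vl, quiet = TRUE), ncol = 3, byrow = TRUE)
    fr <- matrix(scan(text = fl, quiet = TRUE), ncol = 4, byrow = TRUE)
    vertebra_mesh(v, fr[, 2:4, drop = FALSE] + 1L, label)
  } else if (ext == "stl") {
    vx <- grep("^\\s*vertex", lines, value = TRUE)
    coords <- matrix(scan(text = gsub("vertex", "", vx), quiet = TRUE),
                     ncol = 3, byrow = TRUE)
    key <- apply(coords, 1, paste, collapse = "|")
    uk <- !duplicated(key)
    vmap <- match(key, key[uk])
    v <- coords[uk, , drop = FALSE]
    f <- matrix(vmap, ncol = 3, byrow = TRUE)
    vertebra_mesh(v, f, label)
  } else stop("unsupported mesh format: ", ext)
}

#' Hausdorff distance between surfaces
#'
#' Directed distance is the maximum over sampled points of one surface of the
#' point-to-triangle distance to the other; the symmetric value is the larger
#' of the two directions. \code{mode = "vertex"} uses the exact vertex sets of
#' both meshes (point-to-point), which admits a brute-force oracle.
#'
#' @param mesh_a,mesh_b \code{vertebra_mesh} objects (for \code{mode="vertex"},
#'   any n x 3 matrices are also accepted).
#' @param symmetric return the symmetric distance (default) or the directed
#'   a-to-b distance.
#' @param sample_n surface sample count per mesh in \code{mode = "surface"}.
#' @param mode \code{"surface"} (sampled point to triangle) or \code{"vertex"}.
#' @param seed sampling seed.
#' @return distance in mm.
#' @export
hausdorff_distance <- function(mesh_a, mesh_b, symmetric = TRUE,
                               sample_n = 10000, mode = c("surface", "vertex"),
                               seed = 1L) {
  mode <- match.arg(mode)
  pts_of <- function(m) if (inherits(m, "vertebra_mesh")) m$vertices else as.matrix(m)
  if (mode == "vertex") {
    A <- pts_of(mesh_a); B <- pts_of(mesh_b)
    if (nrow(A) == 0 || nrow(B) == 0) stop("empty point set")
    dab <- max(cpp_nn_dist(A, B)$dist)
    if (!symmetric) return(dab)
    return(max(dab, max(cpp_nn_dist(B, A)$dist)))
  }
  if (nrow(mesh_a$faces) == 0 || nrow(mesh_b$faces) == 0) stop("empty mesh")
  pa <- sample_surface(mesh_a, sample_n, seed = seed)
  dab <- max(cpp_point_mesh_dist(pa, mesh_b$vertices, mesh_b$faces))
  if (!symmetric) return(dab)
  pb <- sample_surface(mesh_b, sample_n, seed = seed + 1L)
  dba <- max(cpp_point_mesh_dist(pb, mesh_a$vertices, mesh_a$faces))
  max(dab, dba)
}
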