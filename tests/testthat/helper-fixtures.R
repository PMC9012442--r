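# Shared fixtures, built in code. Heavy objects are memoised for the session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# axis-aligned box mesh [0,a]x[0,b]x[0,c], watertight, outward-oriented
box_mesh <- function(a = 20, b = 20, c = 20, label = NULL) {
  v <- rbind(c(0, 0, 0), c(a, 0, 0), c(a, b, 0), c(0, b, 0),
             c(0, 0, c), c(a, 0, c), c(a, b, c), c(0, b, c))
  f <- rbind(c(1, 4, 3), c(1, 3, 2),   # bottom
             c(5, 6, 7), c(5, 7, 8),   # top
             c(1, 2, 6), c(1, 6, 5),   # front (-y)
             c(2, 3, 7), c(2, 7, 6),   # +x
             c(3, 4, 8), c(3, 8, 7),   # back (+y)
             c(4, 1, 5), c(4, 5, 8))   # -x
  vertebra_mesh(v, f, label)
}

# icosphere-ish mesh: subdivided octahedron projected on a sphere
sphere_mesh <- function(radius = 10, center = c(0, 0, 0), subdiv = 3) {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  for (s in seq_len(subdiv)) {
    nf <- nrow(f)
    newf <- matrix(0L, 4 * nf, 3)
    mid_cache <- new.env(parent = emptyenv())
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    for (t in seq_len(nf)) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[4 * t - 3, ] <- c(a, ab, ca)
      newf[4 * t - 2, ] <- c(ab, b, bc)
      newf[4 * t - 1, ] <- c(ca, bc, cc)
      newf[4 * t, ] <- c(ab, bc, ca)
    }
    f <- newf
  }
  vertebra_mesh(sweep(v * radius, 2, center, "+"), f, "sphere")
}

random_rotation <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  rotation_about(c(0, 0, 0), ax, stats::runif(1, -180, 180))$rotation
}

default_pose <- function() memo("default_pose", build_template(spine_template()))

# small 3-vertebra template: cheap voxelization fixtures
small_template <- function() spine_template(n_vertebrae = 3, target_total_length = 79.6)

small_pose <- function() memo("small_pose", build_template(small_template()))

# full 7-specimen ground-truth-route study (fast)
truth_study <- function() memo("truth_study", run_study(
  study_config(n_specimens = 7, seed = 42, imaging = FALSE)))

# full 7-specimen imaging-route study at 1.5 mm (minutes; used by the
# end-to-end acceptance checks)
imaging_study <- function() memo("imaging_study", run_study(
  study_config(n_specimens = 7, seed = 42, imaging = TRUE, spacing = 1.5)))
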