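# Shared in-code fixtures for the test suite.

fixture_tetrahedron <- function() {
  surface_mesh(
    vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    faces = rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)),
    name = "tetrahedron")
}

# random point cloud wrapped as a mesh (one dummy face keeps the class
# invariants; only vertices matter for neighbor searches)
fixture_cloud <- function(n = 200, scale = 10, seed = 42) {
  set.seed(seed)
  surface_mesh(matrix(stats::runif(3 * n) * scale, n, 3L),
               matrix(c(1L, 2L, 3L), 1L), name = "cloud")
}

# random normals/areas on a cloud for kernel tests with gates off
fixture_random_frame <- function(n, seed = 1) {
  set.seed(seed)
  nrm <- matrix(stats::rnorm(3 * n), n, 3L)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  structure(list(normals = nrm, areas = rep(1, n),
                 valid_mask = rep(TRUE, n)),
            class = "vertex_frame")
}

# thin triangulated strip along x: vertices 1..(n+1) on y = 0 at x = 0..n
fixture_strip <- function(n = 10) {
  v <- rbind(cbind(0:n, 0, 0), cbind(0:n, 1, 0))
  f <- do.call(rbind, lapply(seq_len(n), function(i)
    rbind(c(i, i + 1L, i + n + 1L), c(i + 1L, i + n + 2L, i + n + 1L))))
  surface_mesh(v, f, name = "strip")
}

expect_rel_equal <- function(actual, expected, tol) {
  denom <- pmax(abs(expected), .Machine$double.eps)
  expect_lt(max(abs(actual - expected) / denom), tol)
}

# independent signed-volume computation (divergence theorem, per-face det)
signed_volume_of <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  s <- 0
  for (k in seq_len(nrow(f))) {
    s <- s + det(rbind(v[f[k, 1L], ], v[f[k, 2L], ], v[f[k, 3L], ]))
  }
  s / 6
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3L, 3L)
}
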