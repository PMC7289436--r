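test_that("kappa derives from lambda0, p0 and sigma", {
  p <- ephaptic_params()
  expect_equal(p$kappa, 1e3 * 1 * 0.5 / (2 * pi * 0.40))
  expect_equal(round(p$kappa, 2), 198.94)
  expect_equal(ephaptic_params(p0 = 1)$kappa, 2 * p$kappa)
  expect_error(ephaptic_params(sigma = 0), "sigma")
})

test_that("null geometries: flat sheet and convex sphere give zero maps", {
  sh <- make_flat_sheet(10, 1)
  fr <- compute_vertex_frame(sh)
  res <- emod_local(sh, fr, neighbors_within(sh, 5))
  expect_true(all(res$per_vertex == 0))
  expect_equal(res$global_index, 0)

  # on a sphere of radius R any pair at chord r has n_x.n_y = 1 - r^2/(2R^2),
  # positive whenever r < R*sqrt(2); with R = 10 > 5/sqrt(2) the orientation
  # gate removes every pair within l0 = 5
  sph <- make_sphere(10, 3)
  frs <- compute_vertex_frame(sph, "outward")
  ress <- emod_local(sph, frs, neighbors_within(sph, 5))
  expect_true(all(ress$per_vertex == 0))
})

test_that("parallel plates reproduce the closed-form disc integral", {
  # interior vertex of two discs at separation d with l0 gate:
  # integral of kappa * dA / (d^2 + rho^2)^(3/2) over the opposing plate
  # = 2 pi kappa (1/d - 1/l0)
  d <- 2.5; l0 <- 5
  pl <- make_parallel_plates(d, side = 16, spacing = 0.5)
  fr <- compute_vertex_frame(pl)
  res <- emod_local(pl, fr, neighbors_within(pl, l0),
                    ephaptic_params(l0 = l0), use_area = TRUE)
  closed <- 2 * pi * ephaptic_params()$kappa * (1 / d - 1 / l0)
  v <- pl$vertices
  margin <- sqrt(l0^2 - d^2)     # contributions reach this far laterally
  interior <- v[, 1L] > margin & v[, 1L] < 16 - margin &
              v[, 2L] > margin & v[, 2L] < 16 - margin
  expect_true(any(interior))
  expect_rel_equal(res$per_vertex[interior], rep(closed, sum(interior)), 0.02)
  # the global mean over interior vertices matches too
  expect_rel_equal(mean(res$per_vertex[interior]), closed, 0.02)
  # separation beyond l0 gives an all-zero map
  far <- make_parallel_plates(6, side = 10, spacing = 1)
  frf <- compute_vertex_frame(far)
  expect_true(all(emod_local(far, frf, neighbors_within(far, 5))$per_vertex
                  == 0))
})

test_that("mesh-density sensitivity: use_area stable, bare sum scales ~x4", {
  d <- 2.5
  res_at <- function(sp, use_area) {
    pl <- make_parallel_plates(d, side = 12, spacing = sp)
    fr <- compute_vertex_frame(pl)
    r <- emod_local(pl, fr, neighbors_within(pl, 5),
                    use_area = use_area)
    v <- pl$vertices
    m <- sqrt(25 - d^2)
    mean(r$per_vertex[v[, 1L] > m & v[, 1L] < 12 - m &
                      v[, 2L] > m & v[, 2L] < 12 - m])
  }
  a1 <- res_at(1, TRUE); a2 <- res_at(0.5, TRUE)
  expect_lt(abs(a2 - a1) / a1, 0.01)
  b1 <- res_at(1, FALSE); b2 <- res_at(0.5, FALSE)
  expect_gt(b2 / b1, 3.5)
  expect_lt(b2 / b1, 4.5)
})

test_that("emod_local equals the brute-force oracle on phantoms", {
  phantoms <- list(
    make_sulcus_phantom(2.5, 12, 14, spacing = 0.5),
    make_sulcus_phantom(1.2, 8, 8, gyral_cap = TRUE, spacing = 0.4),
    make_parallel_plates(2.5, 14, 0.5),
    make_sphere(10, 2))
  for (use_area in c(FALSE, TRUE)) {
    for (mesh in phantoms) {
      expect_lte(n_vertices(mesh), 2000L)
      fr <- compute_vertex_frame(mesh)
      a <- emod_local(mesh, fr, neighbors_within(mesh, 5),
                      use_area = use_area)
      b <- emod_brute_force(mesh, fr, use_area = use_area)
      denom <- pmax(abs(b$per_vertex), 1e-9)
      expect_lt(max(abs(a$per_vertex - b$per_vertex) / denom), 1e-9)
    }
  }
})

test_that("gates-off custom kernel agrees with a third accumulation", {
  cloud <- fixture_cloud(n = 120, scale = 6, seed = 9)
  fr <- fixture_random_frame(120, seed = 2)
  spec <- support_spec(orientation_gate = FALSE, distance_gate = FALSE,
                       custom_weight = function(dot, r) rep(1, length(dot)))
  res <- emod_brute_force(cloud, fr, spec = spec)
  # independent accumulation: full matrix algebra, no loops shared with
  # either implementation
  v <- cloud$vertices
  D <- as.matrix(stats::dist(v))
  dot <- tcrossprod(fr$normals)
  K <- -ephaptic_params()$kappa * dot / D^3
  diag(K) <- 0
  K[D <= 1e-6] <- 0
  expected <- rowSums(K)
  expect_rel_equal(res$per_vertex, expected, 1e-9)
  # and emod_local with a pair list covering every pair
  big <- neighbors_within(cloud, 1e6)
  res2 <- emod_local(cloud, fr, big,
                     ephaptic_params(l0 = 1e6), spec)
  expect_rel_equal(res2$per_vertex, expected, 1e-9)
})

test_that("orientation-gated index is nonnegative and flip-invariant", {
  su <- make_sulcus_phantom(2, 10, 10, spacing = 0.45)
  fr <- compute_vertex_frame(su)
  res <- emod_local(su, fr, neighbors_within(su, 5))
  expect_true(all(res$per_vertex >= 0))
  expect_gt(max(res$per_vertex), 0)
  fr_flip <- fr
  fr_flip$normals <- -fr$normals
  res_flip <- emod_local(su, fr_flip, neighbors_within(su, 5))
  expect_identical(res_flip$per_vertex, res$per_vertex)
})

test_that("rigid motions leave the index unchanged", {
  su <- make_sulcus_phantom(2, 10, 10, spacing = 0.45)
  fr <- compute_vertex_frame(su)
  res <- emod_local(su, fr, neighbors_within(su, 5))
  moved <- su
  moved$vertices <- su$vertices %*% rotation_z(0.8) +
    matrix(c(-4, 2, 6), n_vertices(su), 3L, byrow = TRUE)
  res2 <- emod_local(moved, compute_vertex_frame(moved),
                     neighbors_within(moved, 5))
  denom <- pmax(abs(res$per_vertex), 1e-9)
  expect_lt(max(abs(res2$per_vertex - res$per_vertex) / denom), 1e-9)
})

test_that("coordinate scaling laws hold exactly", {
  su <- make_sulcus_phantom(2, 10, 10, spacing = 0.45)
  fr <- compute_vertex_frame(su)
  s <- 2
  scaled <- su
  scaled$vertices <- su$vertices * s
  fr_s <- compute_vertex_frame(scaled)
  for (use_area in c(FALSE, TRUE)) {
    base <- emod_local(su, fr, neighbors_within(su, 5),
                       ephaptic_params(l0 = 5), use_area = use_area)
    big <- emod_local(scaled, fr_s, neighbors_within(scaled, 5 * s),
                      ephaptic_params(l0 = 5 * s), use_area = use_area)
    fac <- if (use_area) s^-1 else s^-3
    nz <- base$per_vertex != 0
    expect_rel_equal(big$per_vertex[nz], base$per_vertex[nz] * fac, 1e-9)
  }
})

test_that("index is linear in kappa (p0 doubling doubles the map)", {
  su <- make_sulcus_phantom(2, 10, 8, spacing = 0.45)
  fr <- compute_vertex_frame(su)
  pr <- neighbors_within(su, 5)
  a <- emod_local(su, fr, pr, ephaptic_params(p0 = 0.5))
  b <- emod_local(su, fr, pr, ephaptic_params(p0 = 1.0))
  expect_equal(b$per_vertex, 2 * a$per_vertex)
})

test_that("global index is the mean over valid vertices", {
  su <- make_sulcus_phantom(2, 10, 8, spacing = 0.45)
  fr <- compute_vertex_frame(su)
  res <- emod_local(su, fr, neighbors_within(su, 5))
  expect_rel_equal(res$global_index,
                   mean(res$per_vertex[res$valid_mask]), 1e-12)
  expect_equal(emod_global(res), res$global_index)
})

test_that("l0 sweep is non-decreasing and saturates beyond the mesh extent", {
  su <- make_sulcus_phantom(2, 10, 10, spacing = 0.45)
  fr <- compute_vertex_frame(su)
  sw <- emod_l0_sweep(su, fr, l0_values = c(1, 5, 10, 200))
  expect_equal(nrow(sw), 4L)
  expect_false(is.unsorted(sw$global_index))
  # l0 below the cross-wall width gives zero
  expect_equal(sw$global_index[1L], 0)
  # l0 far beyond the phantom equals no distance gate at all
  no_gate <- emod_local(su, fr, neighbors_within(su, 1e6),
                        ephaptic_params(l0 = 1e6),
                        support_spec(distance_gate = FALSE))
  expect_rel_equal(sw$global_index[4L], no_gate$global_index, 1e-9)
})

test_that("mismatched pair-list l0 is rejected rather than truncated", {
  su <- make_sulcus_phantom(2, 10, 8, spacing = 0.45)
  fr <- compute_vertex_frame(su)
  pr10 <- neighbors_within(su, 10)
  expect_error(emod_local(su, fr, pr10, ephaptic_params(l0 = 5)),
               "rebuild|l0")
  pr3 <- neighbors_within(su, 3)
  expect_error(emod_local(su, fr, pr3, ephaptic_params(l0 = 5)),
               "rebuild|l0")
})

test_that("variant registry: EMOD1 fixed, placeholders demand a definition", {
  expect_identical(emod_variant("EMOD1")$name, "EMOD1")
  expect_error(emod_variant("EMOD1", distance_gate = FALSE), "fully")
  expect_error(emod_variant("EMOD0"), "no published support")
  spec <- emod_variant("EMOD0", orientation_gate = FALSE,
                       distance_gate = TRUE)
  expect_identical(spec$name, "EMOD0")
  expect_false(spec$orientation_gate)
  expect_error(support_spec(FALSE, FALSE, NULL), "at least one")
})
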