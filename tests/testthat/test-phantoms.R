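test_that("sulcus phantom geometry is recoverable from the mesh", {
  for (w in c(1, 2.5)) {
    sp <- if (w < 2) 0.3 else 0.5
    su <- make_sulcus_phantom(width = w, depth = 10, length = 10,
                              spacing = sp)
    v <- su$vertices
    lab <- attr(su, "labels")
    # wall-to-wall separation: facing grid vertices are exactly `width`
    # apart, so the minimal cross-wall distance equals width
    wn <- which(lab == "wall_neg"); wp <- which(lab == "wall_pos")
    dmin <- min(vapply(wn, function(i)
      min(sqrt(rowSums((v[wp, , drop = FALSE] -
        matrix(v[i, ], length(wp), 3L, byrow = TRUE))^2))), numeric(1L)))
    expect_lt(abs(dmin - w), sp / 2)
    # advertised depth and length recoverable
    expect_lt(abs((max(v[, 3L]) - min(v[, 3L])) - 10), sp / 2)
    expect_lt(abs((max(v[, 2L]) - min(v[, 2L])) - 10), sp / 2)
  }
})

test_that("facing interior wall normals are anti-parallel", {
  su <- make_sulcus_phantom(2, 12, 10, spacing = 0.5)
  fr <- compute_vertex_frame(su)
  v <- su$vertices
  lab <- attr(su, "labels")
  # interior: away from the fundus junction, the free top edge and the ends
  interior <- function(side) which(lab == side & v[, 3L] < -1 &
    v[, 3L] > -8 & v[, 2L] > 2 & v[, 2L] < 8)
  wn <- interior("wall_neg"); wp <- interior("wall_pos")
  key <- function(i) paste(round(v[i, 2L], 9), round(v[i, 3L], 9))
  m <- match(key(wn), key(wp))
  expect_true(all(!is.na(m)))
  dots <- rowSums(fr$normals[wn, , drop = FALSE] *
                  fr$normals[wp[m], , drop = FALSE])
  expect_true(all(abs(dots + 1) < 1e-6))
  # and the normals point INTO the gap (toward the opposite wall)
  expect_true(all(fr$normals[wn, 1L] > 0.99))
  expect_true(all(fr$normals[wp[m], 1L] < -0.99))
})

test_that("phantoms pass repair unchanged", {
  for (mesh in list(make_sulcus_phantom(2, 10, 8, spacing = 0.45),
                    make_sulcus_phantom(2, 10, 8, gyral_cap = TRUE,
                                        spacing = 0.45),
                    make_parallel_plates(2.5, 8, 1),
                    make_sphere(5, 2),
                    make_flat_sheet(6, 1))) {
    r <- repair_mesh(mesh)
    expect_identical(r$vertices, mesh$vertices)
    expect_identical(r$faces, mesh$faces)
  }
})

test_that("wide sulcus yields a zero index under the 5 mm gate", {
  su <- make_sulcus_phantom(width = 6, depth = 14, length = 10, spacing = 1)
  fr <- compute_vertex_frame(su)
  res <- emod_local(su, fr, neighbors_within(su, 5))
  v <- su$vertices
  lab <- attr(su, "labels")
  interior_wall <- lab %in% c("wall_neg", "wall_pos") &
    v[, 3L] < -2 & v[, 3L] > -9 & v[, 2L] > 2 & v[, 2L] < 8
  expect_true(all(res$per_vertex[interior_wall] == 0))
})

test_that("fine sulcus walls reproduce the parallel-plate closed form", {
  su <- make_sulcus_phantom(width = 2.5, depth = 15, length = 20,
                            spacing = 0.5)
  fr <- compute_vertex_frame(su)
  res <- emod_local(su, fr, neighbors_within(su, 5),
                    use_area = TRUE)
  closed <- 2 * pi * ephaptic_params()$kappa * (1 / 2.5 - 1 / 5)
  v <- su$vertices
  lab <- attr(su, "labels")
  deep <- lab == "wall_neg" & v[, 2L] > 5 & v[, 2L] < 15 &
    v[, 3L] < -5 & v[, 3L] > -9
  expect_true(any(deep))
  expect_rel_equal(res$per_vertex[deep], rep(closed, sum(deep)), 0.05)
})

test_that("sphere area matches the analytic value", {
  sph <- make_sphere(10, 3)
  expect_lt(abs(mesh_area(sph) - 4 * pi * 100) / (4 * pi * 100), 0.01)
  expect_true(signed_volume_of(sph) > 0)     # outward winding
})

test_that("subdivision preserves topology class and total area limit", {
  sph <- make_sphere(10, 1)
  sub <- subdivide_mesh(sph)
  expect_equal(n_faces(sub), 4L * n_faces(sph))
  # midpoint subdivision of a flat mesh preserves area exactly
  sh <- make_flat_sheet(4, 1)
  expect_rel_equal(mesh_area(subdivide_mesh(sh)), mesh_area(sh), 1e-12)
})

test_that("infeasible sulcus specs are rejected", {
  expect_error(make_sulcus_phantom(width = 2, depth = 1, length = 5),
               "depth")
  expect_error(make_sulcus_phantom(width = 2, depth = 10, length = 5,
                                   spacing = 1.2), "spacing")
})

test_that("synthetic cohorts are deterministic and age-widening", {
  a <- make_synthetic_cohort(n_subjects = 8, seed = 5)
  b <- make_synthetic_cohort(n_subjects = 8, seed = 5)
  expect_identical(a$table, b$table)
  for (s in seq_len(8))
    expect_identical(a$meshes[[s]]$vertices, b$meshes[[s]]$vertices)
  # different seed changes the draw
  c_ <- make_synthetic_cohort(n_subjects = 8, seed = 6)
  expect_false(identical(a$table$age, c_$table$age))
  # widths follow the widening model on average
  big <- make_synthetic_cohort(n_subjects = 60, seed = 11)
  expect_gt(stats::cor(big$table$age, big$table$width), 0.8)
  expect_true(all(big$table$width > 0))
  # shared topology across subjects
  nv <- vapply(a$meshes, n_vertices, integer(1L))
  expect_true(all(nv == nv[1L]))
})

test_that("zero-slope, zero-noise cohorts have identical geometry", {
  co <- make_synthetic_cohort(n_subjects = 5, slope = 0, noise_sd = 0,
                              seed = 2)
  for (s in 2:5)
    expect_identical(co$meshes[[s]]$vertices, co$meshes[[1L]]$vertices)
  run <- cohort_emod(co)
  expect_equal(stats::var(run$table$emod1), 0)
})

test_that("widening cohorts show a negative index-age relation", {
  co <- make_synthetic_cohort(n_subjects = 12, seed = 3)
  run <- cohort_emod(co)
  expect_lt(stats::cor(run$table$emod1, run$table$age), 0)
  # monotone width -> index relation on noiseless phantoms
  widths <- c(1.0, 1.6, 2.2, 2.8, 3.4)
  idx <- vapply(widths, function(w) {
    m <- make_sulcus_phantom(width = w, depth = 12, length = 12,
                             spacing = 0.35,
                             segments = list(wall = 12L, fundus = 6L,
                                             cap = 3L, axial = 12L))
    fr <- compute_vertex_frame(m)
    emod_local(m, fr, neighbors_within(m, 5))$global_index
  }, numeric(1L))
  expect_true(all(diff(idx) < 0))
})
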