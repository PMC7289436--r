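#' Repair a surface mesh
#'
#' Merges duplicate vertices (within a coordinate tolerance), drops
#' degenerate and duplicate faces, and makes the triangle winding consistent
#' across each connected component. On closed meshes the winding is further
#' oriented globally outward (positive signed volume). The vertex count
#' never increases, and the operation is idempotent.
#'
#' @param mesh A [surface_mesh].
#' @param tol Vertex-merge tolerance in mm.
#' @return The repaired [surface_mesh]; unreferenced vertices are dropped.
#' @export
repair_mesh <- function(mesh, tol = 1e-9) {
  v <- mesh$vertices
  f <- mesh$faces

  # merge coincident vertices: quantize coordinates on a tol-grid
  key <- paste(round(v[, 1L] / tol), round(v[, 2L] / tol),
               round(v[, 3L] / tol))
  first <- match(key, key)                  # representative per group
  remap <- match(first, unique(first))      # compact new indices
  v <- v[unique(first), , drop = FALSE]
  if (nrow(f) > 0L)
    f <- matrix(remap[f], ncol = 3L)

  if (nrow(f) > 0L) {
    # degenerate faces: repeated vertex after merging, or (near) zero area
    keep <- f[, 1L] != f[, 2L] & f[, 1L] != f[, 3L] & f[, 2L] != f[, 3L]
    f <- f[keep, , drop = FALSE]
    if (nrow(f) > 0L) {
      areas <- face_areas(list(vertices = v, faces = f))
      f <- f[areas > (tol * 10), , drop = FALSE]
    }
    # duplicate faces irrespective of winding/rotation
    if (nrow(f) > 0L) {
      fk <- apply(f, 1L, function(r) paste(sort(r), collapse = " "))
      f <- f[!duplicated(fk), , drop = FALSE]
    }
  }
  if (nrow(f) == 0L)
    stop("mesh could not be repaired into at least one valid face")

  # drop vertices no longer referenced by any face
  used <- sort(unique(as.vector(f)))
  if (length(used) < nrow(v)) {
    remap2 <- integer(nrow(v))
    remap2[used] <- seq_along(used)
    v <- v[used, , drop = FALSE]
    f <- matrix(remap2[f], ncol = 3L)
  }

  f <- orient_faces(v, f)
  out <- surface_mesh(v, f, name = mesh$name)
  if (is_closed_mesh(out) && signed_volume(out) < 0)
    out$faces <- out$faces[, c(1L, 3L, 2L)]
  out
}

# Make triangle winding consistent by breadth-first propagation across
# shared edges: two adjacent triangles are consistently wound when they
# traverse their shared edge in opposite directions.
orient_faces <- function(v, f) {
  nf <- nrow(f)
  if (nf <= 1L) return(f)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  fidx <- rep(seq_len(nf), 3L)
  keys <- ekey(edges[, 1L], edges[, 2L])
  by_edge <- split(seq_along(keys), keys)

  visited <- logical(nf)
  flipped <- logical(nf)
  for (seed in seq_len(nf)) {
    if (visited[seed]) next
    visited[seed] <- TRUE
    queue <- seed
    while (length(queue)) {
      cur <- queue[[1L]]
      queue <- queue[-1L]
      curf <- if (flipped[cur]) f[cur, c(1L, 3L, 2L)] else f[cur, ]
      cur_dir <- rbind(curf[c(1L, 2L)], curf[c(2L, 3L)], curf[c(3L, 1L)])
      for (r in 1:3) {
        k <- ekey(cur_dir[r, 1L], cur_dir[r, 2L])
        for (slot in by_edge[[k]]) {
          nb <- fidx[slot]
          if (nb == cur || visited[nb]) next
          nbf <- f[nb, ]
          nb_dir <- rbind(nbf[c(1L, 2L)], nbf[c(2L, 3L)], nbf[c(3L, 1L)])
          same <- any(nb_dir[, 1L] == cur_dir[r, 1L] &
                      nb_dir[, 2L] == cur_dir[r, 2L])
          # cur_dir is already in corrected orientation: consistent winding
          # means the neighbor (as stored) traverses the shared edge in the
          # opposite direction, so same-direction neighbors must flip
          flipped[nb] <- same
          visited[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
  }
  if (any(flipped))
    f[flipped, ] <- f[flipped, c(1L, 3L, 2L), drop = FALSE]
  f
}
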