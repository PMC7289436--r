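#' Radius-limited vertex pairs
#'
#' Finds every ordered vertex pair `(i, j)` with Euclidean distance
#' `0 < r < l0` (strict on both sides: the gate implements the Heaviside
#' convention with zero at the boundary, and pairs closer than `min_dist`
#' are excluded to guard the `1/r^3` kernel against merged-vertex residue).
#' Uses a uniform-grid spatial index; the result is identical to a
#' brute-force all-pairs scan.
#'
#' The pair list is symmetric: `(i, j, r)` is present iff `(j, i, r)` is.
#'
#' @param mesh A [surface_mesh] (only vertices are used).
#' @param l0 Interaction radius in mm (strict upper bound).
#' @param min_dist Strict lower distance bound in mm.
#' @return An object of class `pair_list`: data.frame with integer columns
#'   `i`, `j` and numeric `r` (mm), sorted by `(i, j)`, with attribute `l0`.
#' @export
neighbors_within <- function(mesh, l0, min_dist = 1e-6) {
  stopifnot(l0 > 0)
  v <- mesh$vertices
  n <- nrow(v)
  cell <- pmax(l0, 1e-12)
  ix <- floor(v[, 1L] / cell)
  iy <- floor(v[, 2L] / cell)
  iz <- floor(v[, 3L] / cell)
  key <- paste(ix, iy, iz)
  cells <- split(seq_len(n), key)
  ckey <- do.call(rbind, strsplit(names(cells), " "))
  cxyz <- matrix(as.numeric(ckey), ncol = 3L)

  # index cells on a hash for 27-neighborhood lookup
  cenv <- new.env(hash = TRUE, parent = emptyenv())
  for (ci in seq_along(cells)) assign(names(cells)[ci], ci, envir = cenv)

  out_i <- vector("list", length(cells))
  out_j <- vector("list", length(cells))
  out_r <- vector("list", length(cells))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (ci in seq_along(cells)) {
    pts <- cells[[ci]]
    cand <- integer(0)
    for (o in seq_len(nrow(offs))) {
      k <- paste(cxyz[ci, 1L] + offs[o, 1L], cxyz[ci, 2L] + offs[o, 2L],
                 cxyz[ci, 3L] + offs[o, 3L])
      cj <- get0(k, envir = cenv, ifnotfound = NULL)
      if (!is.null(cj)) cand <- c(cand, cells[[cj]])
    }
    # distances from pts (rows) to cand (cols)
    a <- v[pts, , drop = FALSE]
    b <- v[cand, , drop = FALSE]
    d2 <- outer(rowSums(a * a), rowSums(b * b), "+") - 2 * tcrossprod(a, b)
    d2[d2 < 0] <- 0
    # loose pre-filter on the fast (but re-associated) distances, then an
    # exact recomputation so the gate is bit-identical to the O(N^2) scan
    slack <- 1e-7 * (1 + l0)
    hit <- which(sqrt(d2) < l0 + slack & d2 > 0, arr.ind = TRUE)
    if (nrow(hit)) {
      pi_ <- pts[hit[, 1L]]
      pj <- cand[hit[, 2L]]
      rex <- sqrt((v[pj, 1L] - v[pi_, 1L])^2 + (v[pj, 2L] - v[pi_, 2L])^2 +
                  (v[pj, 3L] - v[pi_, 3L])^2)
      keep <- rex > min_dist & rex < l0
      out_i[[ci]] <- pi_[keep]
      out_j[[ci]] <- pj[keep]
      out_r[[ci]] <- rex[keep]
    }
  }
  i <- unlist(out_i, use.names = FALSE)
  j <- unlist(out_j, use.names = FALSE)
  r <- unlist(out_r, use.names = FALSE)
  if (is.null(i)) { i <- integer(0); j <- integer(0); r <- numeric(0) }
  keep <- i != j
  i <- i[keep]; j <- j[keep]; r <- r[keep]
  ord <- order(i, j)
  pairs <- data.frame(i = as.integer(i[ord]), j = as.integer(j[ord]),
                      r = r[ord])
  structure(pairs, l0 = l0, min_dist = min_dist,
            class = c("pair_list", "data.frame"))
}

#' Brute-force all-pairs radius scan
#'
#' Reference O(N^2) implementation of [neighbors_within()], used as its
#' testing oracle.
#'
#' @inheritParams neighbors_within
#' @return A `pair_list`, as [neighbors_within()].
#' @export
neighbors_brute_force <- function(mesh, l0, min_dist = 1e-6) {
  stopifnot(l0 > 0)
  v <- mesh$vertices
  n <- nrow(v)
  ii <- jj <- vector("list", n)
  rr <- vector("list", n)
  for (i in seq_len(n)) {
    d <- sqrt((v[, 1L] - v[i, 1L])^2 + (v[, 2L] - v[i, 2L])^2 +
              (v[, 3L] - v[i, 3L])^2)
    sel <- which(d > min_dist & d < l0 & seq_len(n) != i)
    ii[[i]] <- rep.int(i, length(sel))
    jj[[i]] <- sel
    rr[[i]] <- d[sel]
  }
  pairs <- data.frame(i = as.integer(unlist(ii)), j = as.integer(unlist(jj)),
                      r = unlist(rr))
  ord <- order(pairs$i, pairs$j)
  pairs <- pairs[ord, , drop = FALSE]
  rownames(pairs) <- NULL
  structure(pairs, l0 = l0, min_dist = min_dist,
            class = c("pair_list", "data.frame"))
}

#' Geodesic distances along mesh edges
#'
#' Shortest-path distance from a source vertex along the mesh edge graph
#' (Dijkstra; edge weight = Euclidean edge length). Vertices that are
#' unreachable or farther than `max_dist` are reported as `Inf`.
#'
#' @param mesh A [surface_mesh].
#' @param source Source vertex index (1-based).
#' @param max_dist Maximum distance in mm (`Inf` for no limit).
#' @return Numeric vector of per-vertex distances in mm.
#' @export
geodesic_distances <- function(mesh, source, max_dist = Inf) {
  nv <- nrow(mesh$vertices)
  source <- as.integer(source)
  if (length(source) != 1L || is.na(source) || source < 1L || source > nv)
    stop("source index out of range: ", source)
  g <- mesh_edge_graph(mesh)
  d <- as.numeric(igraph::distances(g, v = source, algorithm = "dijkstra"))
  d[d > max_dist] <- Inf
  d
}

# igraph weighted edge graph of a mesh (undirected, unique edges).
mesh_edge_graph <- function(mesh) {
  f <- mesh$faces
  v <- mesh$vertices
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e <- unique(e)
  w <- sqrt(rowSums((v[e[, 1L], , drop = FALSE] -
                     v[e[, 2L], , drop = FALSE])^2))
  igraph::graph_from_edgelist(e, directed = FALSE) |>
    igraph::set_edge_attr("weight", value = w) |>
    igraph::add_vertices(max(0L, nrow(v) - max(e)))
}
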