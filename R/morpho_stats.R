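#' Per-vertex cortical thickness proxy
#'
#' Euclidean distance between corresponding vertices of a white and a pial
#' surface (matched indexing required). This is a simplified proxy of the
#' symmetric white-pial distance used by full surface pipelines.
#'
#' @param white,pial [surface_mesh]es with equal vertex counts and matched
#'   indexing.
#' @return Numeric vector of per-vertex distances in mm.
#' @export
vertex_thickness <- function(white, pial) {
  if (nrow(white$vertices) != nrow(pial$vertices))
    stop("white and pial surfaces have different vertex counts (",
         nrow(white$vertices), " vs ", nrow(pial$vertices), ")")
  sqrt(rowSums((pial$vertices - white$vertices)^2))
}

#' Per-vertex gyrification proxy
#'
#' Local gyrification ratio using the mesh's convex hull as the outer
#' surface: for each vertex, the ratio of pial surface area within a
#' Euclidean `radius` of the vertex to outer-hull area within the same
#' radius of the hull point nearest the vertex. On folded surfaces the
#' ratio exceeds 1; on a sphere or flat sheet it is ~1. The hull is
#' midpoint-subdivided until its edges are finer than `radius / 10` so that
#' area-within-radius sums are stable.
#'
#' A full brain surface is closed and its hull wraps it entirely. An open
#' patch (such as a sulcus phantom) is different: its convex hull also
#' wraps *beneath* the fold, which no outer envelope of a cortex does. For
#' open meshes the hull is therefore restricted to its upper side — the
#' faces whose outward normal agrees with the patch's mean orientation —
#' so that the outer surface bridges the sulcal mouth like a
#' morphological-closing wrap would.
#'
#' @param mesh A [surface_mesh].
#' @param radius Region-of-interest radius in mm.
#' @return Numeric vector of per-vertex ratios.
#' @export
gyrification_proxy <- function(mesh, radius = 5) {
  stopifnot(radius > 0)
  v <- mesh$vertices
  frame <- compute_vertex_frame(mesh)
  hull <- convex_hull_3d(v)
  if (!is_closed_mesh(mesh) && is_closed_mesh(hull)) {
    mean_n <- colSums(frame$normals[frame$valid_mask, , drop = FALSE])
    if (sqrt(sum(mean_n^2)) > 1e-8) {
      hn <- face_cross(hull)    # outward (hull is wound outward)
      keep <- as.numeric(hn %*% mean_n) > 0
      if (any(keep))
        hull <- surface_mesh(hull$vertices, hull$faces[keep, , drop = FALSE],
                             name = hull$name)
    }
  }
  # refine the hull so local area sums resolve the ROI
  max_edge <- function(m) {
    f <- m$faces
    e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
    max(sqrt(rowSums((m$vertices[e[, 1L], , drop = FALSE] -
                      m$vertices[e[, 2L], , drop = FALSE])^2)))
  }
  it <- 0L
  while (max_edge(hull) > radius / 10 && it < 10L) {
    hull <- subdivide_mesh(hull)
    it <- it + 1L
  }
  hframe <- compute_vertex_frame(hull)
  hv <- hull$vertices

  # area within radius, with a linear partial-coverage ramp half an edge
  # wide at the ROI boundary (a hard cut-off makes the estimate jitter by
  # a boundary-cell area on coarse meshes)
  mean_edge <- function(m) {
    f <- m$faces
    e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
    mean(sqrt(rowSums((m$vertices[e[, 1L], , drop = FALSE] -
                       m$vertices[e[, 2L], , drop = FALSE])^2)))
  }
  area_within <- function(center, pts, areas, h) {
    d <- sqrt((pts[, 1L] - center[1L])^2 + (pts[, 2L] - center[2L])^2 +
              (pts[, 3L] - center[3L])^2)
    w <- pmin(1, pmax(0, (radius + h / 2 - d) / h))
    sum(areas * w)
  }
  h_pial <- mean_edge(mesh)
  h_hull <- mean_edge(hull)

  n <- nrow(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    pial_area <- area_within(v[i, ], v, frame$areas, h_pial)
    hd2 <- (hv[, 1L] - v[i, 1L])^2 + (hv[, 2L] - v[i, 2L])^2 +
           (hv[, 3L] - v[i, 3L])^2
    near <- which.min(hd2)
    hull_area <- area_within(hv[near, ], hv, hframe$areas, h_hull)
    out[i] <- if (hull_area > 0) pial_area / hull_area else NA_real_
  }
  out
}

#' Geodesic Gaussian smoothing of a per-vertex map
#'
#' Gaussian weighting on geodesic distance (Dijkstra along mesh edges)
#' with \eqn{\sigma = \mathrm{FWHM} / 2.355}, truncated at \eqn{3\sigma},
#' weights renormalized per vertex (so constant maps are unchanged).
#' `fwhm = 0` is the identity.
#'
#' @param mesh A [surface_mesh].
#' @param map Numeric per-vertex map.
#' @param fwhm Full width at half maximum in mm.
#' @return Smoothed per-vertex map.
#' @export
smooth_map <- function(mesh, map, fwhm = 10) {
  stopifnot(fwhm >= 0)
  nv <- nrow(mesh$vertices)
  if (length(map) != nv)
    stop("map length does not match mesh vertex count")
  if (fwhm == 0) return(map)
  sig <- fwhm / 2.355
  g <- mesh_edge_graph(mesh)
  D <- igraph::distances(g, algorithm = "dijkstra")
  W <- exp(-D^2 / (2 * sig^2))
  W[D > 3 * sig] <- 0
  sw <- rowSums(W)
  as.numeric(W %*% map) / sw
}

#' Vertex-wise Pearson correlation map
#'
#' Correlates each vertex's values across subjects with a scalar
#' covariate: per-vertex Pearson r, two-sided p-value from the Student-t
#' transform \eqn{t = r\sqrt{(n-2)/(1-r^2)}}, and the Benjamini-Hochberg
#' rejection mask at level `q`. Vertices with (numerically) constant
#' values across subjects are undefined and masked (`NA`).
#'
#' @param subject_maps Subjects x vertices numeric matrix.
#' @param covariate Per-subject scalar (length = number of subjects).
#' @param q FDR level for the significance mask.
#' @return An object of class `correlation_map`: list with `r`, `p`,
#'   `q_mask`, `p_adjusted`, `n`.
#' @export
pearson_map <- function(subject_maps, covariate, q = 0.05) {
  x <- as.matrix(subject_maps)
  y <- as.numeric(covariate)
  n <- nrow(x)
  if (length(y) != n) stop("covariate length must match subject count")
  if (n < 4L) stop("need at least 4 subjects")
  if (stats::sd(y) == 0) stop("covariate is constant")
  xc <- sweep(x, 2L, colMeans(x))
  yc <- y - mean(y)
  sx <- sqrt(colSums(xc^2))
  sy <- sqrt(sum(yc^2))
  r <- as.numeric(crossprod(xc, yc)) / (sx * sy)
  r[sx == 0] <- NA_real_
  r <- pmin(1, pmax(-1, r))
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  fdr <- bh_fdr(p, q)
  structure(list(r = r, p = p, q_mask = fdr$mask,
                 p_adjusted = fdr$p_adjusted, n = n),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("<correlation_map: %d vertices, n = %d, %d significant>\n",
              length(x$r), x$n, sum(x$q_mask, na.rm = TRUE)))
  invisible(x)
}

#' Benjamini-Hochberg FDR control
#'
#' Standard step-up procedure: with ordered p-values \eqn{p_{(1)} \le
#' \dots \le p_{(m)}}, reject all \eqn{p_{(i)}} with \eqn{i \le k} where
#' \eqn{k = \max\{i : p_{(i)} \le (i/m) q\}}. `NA` p-values are neither
#' counted in `m` nor rejected. Adjusted p-values follow
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p_values Numeric p-values in `[0, 1]` (NAs allowed).
#' @param q FDR level.
#' @return List with logical `mask` (rejections) and `p_adjusted`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  p <- as.numeric(p_values)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  mask <- rep(FALSE, length(p))
  if (any(ok)) {
    pv <- p[ok]
    m <- length(pv)
    o <- order(pv)
    below <- pv[o] <= (seq_len(m) / m) * q
    k <- if (any(below)) max(which(below)) else 0L
    rej <- logical(m)
    if (k > 0L) rej[o[seq_len(k)]] <- TRUE
    mask[ok] <- rej
  }
  adj <- rep(NA_real_, length(p))
  adj[ok] <- stats::p.adjust(p[ok], method = "BH")
  list(mask = mask, p_adjusted = adj)
}

#' Polynomial trend fit of a metric against a covariate
#'
#' OLS fit of `y ~ poly(x, order)` (raw polynomial), reporting the
#' coefficients (intercept first), R-squared and the overall-F p-value.
#'
#' @param x Covariate (e.g. age in years).
#' @param y Metric values.
#' @param order Polynomial order, 1 (linear) or 2 (quadratic).
#' @return An object of class `trend_fit`: list with `order`,
#'   `coefficients`, `r_squared`, `p_value`, `n`.
#' @export
fit_trend <- function(x, y, order = 1L) {
  stopifnot(order %in% c(1L, 2L))
  x <- as.numeric(x); y <- as.numeric(y)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) <= order + 1L)
    stop("need more than order + 1 observations")
  fit <- stats::lm(y ~ stats::poly(x, degree = order, raw = TRUE))
  # summary.lm warns on exact fits; those are legitimate inputs here
  sm <- suppressWarnings(summary(fit))
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient trend fit (constant covariate?)")
  fstat <- sm$fstatistic
  pval <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  structure(list(order = order,
                 coefficients = unname(stats::coef(fit)),
                 r_squared = sm$r.squared,
                 p_value = unname(pval),
                 n = length(x)),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit order %d: R^2 %.4f, p %.3g, n %d>\n",
              x$order, x$r_squared, x$p_value, x$n))
  invisible(x)
}
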