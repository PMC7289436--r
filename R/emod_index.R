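#' Physical parameters of the ephaptic index
#'
#' Collects the parameters governing all index computations: the effective
#' neural space constant `lambda0` (mm), the dipole surface density `p0`
#' (nA·m/mm^2), the medium conductivity `sigma` (S/m, grey matter by
#' default) and the coherence radius `l0` (mm). The derived prefactor
#' \eqn{\kappa = \lambda_0 p_0 / (2\pi\sigma)} is recomputed from the
#' components on every construction; in the mm / nA·m / μV unit convention
#' its numeric value at the defaults is 198.94 μV·mm.
#'
#' @param lambda0 Effective space constant in mm.
#' @param p0 Dipole surface density in nA·m/mm^2.
#' @param sigma Conductivity in S/m.
#' @param l0 Interaction (coherence) radius in mm.
#' @return An object of class `ephaptic_params` with the four components
#'   and the derived `kappa` (μV·mm).
#' @export
#' @examples
#' p <- ephaptic_params()
#' p$kappa   # 198.94 uV.mm
ephaptic_params <- function(lambda0 = 1, p0 = 0.5, sigma = 0.40, l0 = 5) {
  stopifnot(lambda0 > 0, p0 > 0, sigma > 0, l0 > 0)
  structure(list(lambda0 = lambda0, p0 = p0, sigma = sigma, l0 = l0,
                 kappa = 1e3 * lambda0 * p0 / (2 * pi * sigma)),
            class = "ephaptic_params")
}

# kappa in uV.mm (r in mm, dA in mm^2 give the index directly in uV)
kappa_uv_mm <- function(params) params$kappa

#' @export
print.ephaptic_params <- function(x, ...) {
  cat(sprintf(
    "<ephaptic_params: lambda0 %.3g mm, p0 %.3g nA.m/mm^2, sigma %.3g S/m,\n",
    x$lambda0, x$p0, x$sigma),
    sprintf(" l0 %.3g mm, kappa %.6g uV.mm>\n", x$l0, x$kappa))
  invisible(x)
}

#' Support function of the pair sum
#'
#' Chooses which ordered pairs contribute to the index and with what
#' weight. EMOD1 uses both gates: the orientation gate
#' \eqn{\Theta[-n_x\cdot n_y]} keeps only pairs whose normals oppose
#' (strictly, \eqn{n_x\cdot n_y < 0}), and the distance gate
#' \eqn{\Theta[l_0 - r]} keeps only pairs closer than `l0` (strictly,
#' \eqn{r < l_0}); the Heaviside convention is \eqn{\Theta[x] = 0} for
#' \eqn{x \le 0} and 1 for \eqn{x > 0}. A `custom_weight` function
#' `w(dot, r)` (receiving the per-pair normal dot products and distances)
#' multiplies the kernel when supplied.
#'
#' @param orientation_gate Apply the orientation gate?
#' @param distance_gate Apply the distance gate?
#' @param custom_weight Optional `function(dot, r)` returning weights.
#' @param name Variant label for provenance metadata.
#' @return An object of class `support_spec`.
#' @export
support_spec <- function(orientation_gate = TRUE, distance_gate = TRUE,
                         custom_weight = NULL, name = NULL) {
  if (!orientation_gate && !distance_gate && is.null(custom_weight))
    stop("at least one gate or a custom weight must be active")
  if (is.null(name))
    name <- if (orientation_gate && distance_gate && is.null(custom_weight))
      "EMOD1" else "custom"
  structure(list(orientation_gate = orientation_gate,
                 distance_gate = distance_gate,
                 custom_weight = custom_weight, name = name),
            class = "support_spec")
}

#' Registry of named index variants
#'
#' `EMOD1` is the fully specified variant (both gates on, signed
#' \eqn{1/r^3} kernel). `EMOD0` and `EMOD1a` are registered as
#' configurable placeholders: their defining support functions are not
#' published, so they must be supplied by the user via `gates`/`weight` —
#' no default formula is invented.
#'
#' @param variant Variant name.
#' @param ... For the placeholder variants, arguments forwarded to
#'   [support_spec()] (required).
#' @return A `support_spec`.
#' @export
emod_variant <- function(variant = c("EMOD1", "EMOD0", "EMOD1a"), ...) {
  variant <- match.arg(variant)
  if (variant == "EMOD1") {
    if (length(list(...)))
      stop("EMOD1 is fully specified; do not pass support arguments")
    return(support_spec(TRUE, TRUE, NULL, name = "EMOD1"))
  }
  args <- list(...)
  if (!length(args))
    stop(variant, " has no published support function; supply ",
         "orientation_gate/distance_gate/custom_weight explicitly")
  spec <- do.call(support_spec, c(args, list(name = variant)))
  spec
}

#' Per-vertex ephaptic modulation index
#'
#' Evaluates, for every valid vertex \eqn{x},
#' \deqn{\varepsilon(x) = -\kappa \sum_{y \ne x} W(x,y)\,
#'   \frac{n_x \cdot n_y}{r^3}\,(\delta A_y)}
#' over the supplied radius-gated pair list, with \eqn{W} given by the
#' support spec. With `use_area = TRUE` the source vertex area
#' \eqn{\delta A_y} (mm^2) enters the sum and the map is in μV; with
#' `use_area = FALSE` (the default, matching how the published maps were
#' computed) the sum carries mm^-3 and the map is reported in model units
#' of μV·mm^-2. Invalid vertices get 0 and are masked in the metadata.
#'
#' Contributions are accumulated in ascending neighbor order for
#' reproducibility.
#'
#' @param mesh A [surface_mesh].
#' @param frame Its [compute_vertex_frame()] result.
#' @param pairs A `pair_list` from [neighbors_within()]. When the distance
#'   gate is active the pair list must have been built with the same `l0`
#'   as `params` (silent truncation is forbidden; a mismatch errors).
#' @param params An [ephaptic_params()].
#' @param spec A [support_spec()]; EMOD1 by default.
#' @param use_area Include the source vertex area in each term?
#' @return An object of class `emod_result`: list with `per_vertex`,
#'   `global_index`, `valid_mask` and `meta`.
#' @export
emod_local <- function(mesh, frame, pairs, params = ephaptic_params(),
                       spec = support_spec(), use_area = FALSE) {
  nv <- nrow(mesh$vertices)
  if (length(frame$areas) != nv)
    stop("frame does not match mesh vertex count")
  if (spec$distance_gate) {
    pl0 <- attr(pairs, "l0")
    if (is.null(pl0) || pl0 != params$l0)
      stop("pair list was built with l0 = ", pl0 %||% NA,
           " but params$l0 = ", params$l0,
           "; rebuild the pairs (silent truncation/omission is forbidden)")
  }
  i <- pairs$i
  j <- pairs$j
  r <- pairs$r
  valid <- frame$valid_mask
  keep <- valid[i] & valid[j]
  i <- i[keep]; j <- j[keep]; r <- r[keep]

  dot <- rowSums(frame$normals[i, , drop = FALSE] *
                 frame$normals[j, , drop = FALSE])
  w <- rep(1, length(i))
  if (spec$orientation_gate) w <- w * (dot < 0)
  if (spec$distance_gate) w <- w * (r < params$l0)
  if (!is.null(spec$custom_weight)) w <- w * spec$custom_weight(dot, r)

  term <- -kappa_uv_mm(params) * w * dot / r^3
  if (use_area) term <- term * frame$areas[j]

  # fixed summation order: ascending (receiver, neighbor) index
  ord <- order(i, j)
  per_vertex <- numeric(nv)
  if (length(i)) {
    s <- rowsum(term[ord], i[ord], reorder = TRUE)
    per_vertex[as.integer(rownames(s))] <- s[, 1L]
  }
  per_vertex[!valid] <- 0
  emod_result(per_vertex, valid, mesh, params, spec, use_area)
}

emod_result <- function(per_vertex, valid, mesh, params, spec, use_area) {
  global_index <- mean(per_vertex[valid])
  structure(list(
    per_vertex = per_vertex,
    global_index = global_index,
    valid_mask = valid,
    meta = list(variant = spec$name, l0 = params$l0, use_area = use_area,
                units = if (use_area) "uV" else "uV.mm^-2",
                lambda0 = params$lambda0, p0 = params$p0,
                sigma = params$sigma, kappa = params$kappa,
                mesh = mesh$name, n_vertices = length(per_vertex),
                n_valid = sum(valid))),
    class = "emod_result")
}

#' @export
print.emod_result <- function(x, ...) {
  cat(sprintf("<emod_result %s: global %.6g %s over %d/%d vertices (l0 = %g mm)>\n",
              x$meta$variant, x$global_index, x$meta$units,
              x$meta$n_valid, x$meta$n_vertices, x$meta$l0))
  invisible(x)
}

#' Global ephaptic index
#'
#' Arithmetic mean of the per-vertex map over valid vertices.
#'
#' @param result An `emod_result`.
#' @return Scalar global index.
#' @export
emod_global <- function(result) {
  if (!any(result$valid_mask)) stop("no valid vertices")
  mean(result$per_vertex[result$valid_mask])
}

#' Brute-force ephaptic index (testing oracle)
#'
#' Direct O(N^2) double loop over all ordered vertex pairs, independent of
#' the spatial index and the vectorized accumulation of [emod_local()].
#' Intended for meshes up to a few thousand vertices.
#'
#' @inheritParams emod_local
#' @param min_dist Strict lower distance bound in mm (as in
#'   [neighbors_within()]).
#' @return An `emod_result`.
#' @export
emod_brute_force <- function(mesh, frame, params = ephaptic_params(),
                             spec = support_spec(), use_area = FALSE,
                             min_dist = 1e-6) {
  v <- mesh$vertices
  nv <- nrow(v)
  valid <- frame$valid_mask
  per_vertex <- numeric(nv)
  kap <- kappa_uv_mm(params)
  idx <- seq_len(nv)
  for (x in idx) {
    if (!valid[x]) next
    # all candidate partners y of this receiver, in ascending index order
    r <- sqrt((v[, 1L] - v[x, 1L])^2 + (v[, 2L] - v[x, 2L])^2 +
              (v[, 3L] - v[x, 3L])^2)
    dot <- as.numeric(frame$normals %*% frame$normals[x, ])
    sel <- valid & idx != x & r > min_dist
    if (spec$orientation_gate) sel <- sel & dot < 0
    if (spec$distance_gate) sel <- sel & r < params$l0
    w <- rep(1, sum(sel))
    if (!is.null(spec$custom_weight))
      w <- w * spec$custom_weight(dot[sel], r[sel])
    term <- -kap * w * dot[sel] / r[sel]^3
    if (use_area) term <- term * frame$areas[sel]
    per_vertex[x] <- sum(term)
  }
  emod_result(per_vertex, valid, mesh, params, spec, use_area)
}

#' Global index across interaction radii
#'
#' Recomputes the index for each `l0`, rebuilding the pair list each time.
#' With the orientation gate on every contribution is nonnegative, so the
#' global index is non-decreasing in `l0`.
#'
#' @inheritParams emod_local
#' @param l0_values Ascending positive radii in mm.
#' @return Data frame with columns `l0` and `global_index`, plus a
#'   `results` attribute holding the per-`l0` `emod_result`s.
#' @export
emod_l0_sweep <- function(mesh, frame, params = ephaptic_params(),
                          l0_values = c(1, 5, 10, 200),
                          spec = support_spec(), use_area = FALSE) {
  stopifnot(all(l0_values > 0), !is.unsorted(l0_values))
  results <- lapply(l0_values, function(l0) {
    p <- ephaptic_params(lambda0 = params$lambda0, p0 = params$p0,
                         sigma = params$sigma, l0 = l0)
    pr <- neighbors_within(mesh, l0)
    emod_local(mesh, frame, pr, p, spec, use_area)
  })
  out <- data.frame(l0 = l0_values,
                    global_index = vapply(results, `[[`, numeric(1L),
                                          "global_index"))
  attr(out, "results") <- results
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
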