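#' Reference tissue conductivities
#'
#' Low-frequency conductivities (S/m) commonly used in quasi-static head
#' modeling. Only a single homogeneous scalar is used in the field
#' computations; the table is reference data for choosing it (grey matter,
#' `gm = 0.40`, is the default throughout).
#'
#' @return Named numeric vector of conductivities in S/m.
#' @export
tissue_conductivities <- function() {
  c(scalp = 0.33, skull = 0.008, csf = 1.79, gm = 0.40, wm = 0.15)
}

# unit conversions at the API boundary (mm / nA.m / uV in, SI internally)
MM_TO_M <- 1e-3
NAM_TO_AM <- 1e-9
V_TO_UV <- 1e6

#' Electric field of a current dipole in a homogeneous medium
#'
#' Quasi-static field of a point current dipole:
#' \deqn{E(x) = \frac{1}{4\pi\sigma r^3}\left(3 (p\cdot\hat r)\hat r - p\right)}
#' equivalently, in polar form with \eqn{p} along \eqn{\hat z},
#' \eqn{\frac{p}{4\pi\sigma r^3}(2\cos\theta\,\hat r + \sin\theta\,\hat\theta)}.
#'
#' @param moment Dipole moment 3-vector in nA·m.
#' @param source Source position in mm (3-vector).
#' @param obs Observation point in mm (3-vector).
#' @param sigma Medium conductivity in S/m.
#' @return Electric field 3-vector in V/m.
#' @export
dipole_field <- function(moment, source, obs, sigma = 0.40) {
  stopifnot(sigma > 0)
  p <- as.numeric(moment) * NAM_TO_AM
  d <- (as.numeric(obs) - as.numeric(source)) * MM_TO_M
  r <- sqrt(sum(d * d))
  if (r < 1e-9)
    stop("observation point coincides with the dipole source (singularity)")
  rhat <- d / r
  (3 * sum(p * rhat) * rhat - p) / (4 * pi * sigma * r^3)
}

#' Electrostatic potential of a current dipole
#'
#' \deqn{\Phi(x) = \frac{p\cdot\hat r}{4\pi\sigma r^2}}
#' The numerical gradient of `dipole_potential` reproduces
#' [dipole_field()] (\eqn{E = -\nabla\Phi}).
#'
#' @inheritParams dipole_field
#' @return Potential in μV.
#' @export
dipole_potential <- function(moment, source, obs, sigma = 0.40) {
  stopifnot(sigma > 0)
  p <- as.numeric(moment) * NAM_TO_AM
  d <- (as.numeric(obs) - as.numeric(source)) * MM_TO_M
  r <- sqrt(sum(d * d))
  if (r < 1e-9)
    stop("observation point coincides with the dipole source (singularity)")
  sum(p * d / r) / (4 * pi * sigma * r^2) * V_TO_UV
}

#' Regular dipole grid patch
#'
#' Builds a set of identical point dipoles emulating a uniformly activated
#' cortical patch: each moment has magnitude
#' `density * extent / n_dipoles` (nA·m) along `normal`, positions on a
#' square grid with the given spacing, centred on `center` in the plane
#' orthogonal to `normal`.
#'
#' @param extent Patch area in mm^2.
#' @param spacing Grid spacing in mm.
#' @param n_dipoles Number of dipoles.
#' @param density Dipole surface density in nA·m/mm^2.
#' @param normal Patch normal 3-vector (dipole direction).
#' @param center Patch centre in mm.
#' @return An object of class `dipole_set`: list with `positions` (mm),
#'   `moments` (nA·m), `density`.
#' @export
make_grid_patch <- function(extent, spacing = 1, n_dipoles, density = 0.5,
                            normal = c(0, 0, 1), center = c(0, 0, 0)) {
  stopifnot(extent > 0, n_dipoles >= 1, density >= 0, spacing > 0)
  normal <- as.numeric(normal)
  normal <- normal / sqrt(sum(normal^2))
  m <- density * extent / n_dipoles     # nA.m per dipole

  # lay the grid row-major on a near-square footprint, then keep the
  # n_dipoles sites nearest the centre (77 on a 60 mm^2 patch is not square)
  side <- ceiling(sqrt(n_dipoles))
  g <- seq_len(side) - (side + 1L) / 2
  xy <- as.matrix(expand.grid(x = g, y = g)) * spacing
  ord <- order(rowSums(xy^2), xy[, 1L], xy[, 2L])
  xy <- xy[ord[seq_len(n_dipoles)], , drop = FALSE]

  # orthonormal frame around the normal
  up <- if (abs(normal[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- cross3(matrix(up, 1L), matrix(normal, 1L))[1L, ]
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(matrix(normal, 1L), matrix(e1, 1L))[1L, ]
  pos <- sweep(xy[, 1L] %o% e1 + xy[, 2L] %o% e2, 2L, center, "+")
  structure(list(positions = pos,
                 moments = matrix(rep(m * normal, each = n_dipoles),
                                  n_dipoles, 3L),
                 density = density),
            class = "dipole_set")
}

#' @export
print.dipole_set <- function(x, ...) {
  mags <- sqrt(rowSums(x$moments^2))
  cat(sprintf(
    "<dipole_set: %d dipoles, |p| = %.4g nA.m, density %.3g nA.m/mm^2>\n",
    nrow(x$positions), mags[1L], x$density))
  invisible(x)
}

#' Superposed field and potential of a dipole set
#'
#' Linear superposition of [dipole_field()] and [dipole_potential()] over
#' all sources, evaluated at each observation point.
#'
#' @param dipoles A `dipole_set` (see [make_grid_patch()]).
#' @param points Observation points, `k x 3` matrix in mm.
#' @param sigma Conductivity in S/m.
#' @return An object of class `field_sample`: list with `points` (mm), `E`
#'   (`k x 3`, V/m), `E_mag` (V/m), `phi` (μV).
#' @export
patch_field <- function(dipoles, points, sigma = 0.40) {
  points <- matrix(as.numeric(points), ncol = 3L)
  k <- nrow(points)
  E <- matrix(0, k, 3L)
  phi <- numeric(k)
  for (i in seq_len(k)) {
    for (s in seq_len(nrow(dipoles$positions))) {
      E[i, ] <- E[i, ] + dipole_field(dipoles$moments[s, ],
                                      dipoles$positions[s, ],
                                      points[i, ], sigma)
      phi[i] <- phi[i] + dipole_potential(dipoles$moments[s, ],
                                          dipoles$positions[s, ],
                                          points[i, ], sigma)
    }
  }
  structure(list(points = points, E = E, E_mag = sqrt(rowSums(E * E)),
                 phi = phi, sigma = sigma),
            class = "field_sample")
}

#' @export
print.field_sample <- function(x, ...) {
  cat(sprintf("<field_sample: %d points, |E| in [%.3g, %.3g] V/m>\n",
              nrow(x$points), min(x$E_mag), max(x$E_mag)))
  invisible(x)
}

#' Export a field sample as a data frame / CSV
#' @param sample A `field_sample`.
#' @param path Optional CSV output path.
#' @return Data frame with point coordinates, E components, `|E|` and phi.
#' @export
field_sample_table <- function(sample, path = NULL) {
  df <- data.frame(x = sample$points[, 1L], y = sample$points[, 2L],
                   z = sample$points[, 3L],
                   Ex = sample$E[, 1L], Ey = sample$E[, 2L],
                   Ez = sample$E[, 3L],
                   E_mag = sample$E_mag, phi_uV = sample$phi)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

#' Membrane perturbation from the lambda-E rule
#'
#' First-order perturbation of an elongated neuron (space-constant vector
#' \eqn{\lambda}, mm) in a locally uniform field \eqn{E} (V/m):
#' \eqn{\delta\Phi = \lambda \cdot E}. mm × V/m = mV, returned in μV.
#'
#' @param E Electric field 3-vector in V/m.
#' @param lambda_vec Space-constant vector in mm.
#' @return Membrane potential perturbation in μV.
#' @export
lambda_e <- function(E, lambda_vec) {
  sum(as.numeric(lambda_vec) * as.numeric(E)) * 1e3
}

#' Pairwise ephaptic impact of one surface dipole on a receiver
#'
#' The impact of a source dipole `p = p0 * dA * n_y` at `source_pos` on a
#' receiver population with `lambda = lambda0 * n_x` at `obs_pos`.
#' `mode = "full"` evaluates the exact dipole field; `mode = "on_top"` uses
#' the axial approximation \eqn{2\lambda_0 p_0 \delta A\, (n_x\cdot n_y) /
#' (4\pi\sigma r^3) = \kappa\, (n_x\cdot n_y)\,\delta A / r^3}. The two
#' agree when the observer sits on the source's dipole axis.
#'
#' @param source_pos,obs_pos Positions in mm (3-vectors).
#' @param source_normal,obs_normal Unit surface normals.
#' @param params An [ephaptic_params()] object.
#' @param mode `"full"` or `"on_top"`.
#' @param dA Source vertex area in mm^2.
#' @return Impact in μV (sign as given by the lambda-E rule; the index
#'   formula applies its own minus sign for the normal convention).
#' @export
pairwise_impact <- function(source_pos, source_normal, obs_pos, obs_normal,
                            params = ephaptic_params(),
                            mode = c("full", "on_top"), dA = 1) {
  mode <- match.arg(mode)
  if (mode == "full") {
    p <- params$p0 * dA * as.numeric(source_normal)   # nA.m
    E <- dipole_field(p, source_pos, obs_pos, params$sigma)
    lambda_e(E, params$lambda0 * as.numeric(obs_normal))
  } else {
    d <- as.numeric(obs_pos) - as.numeric(source_pos)
    r <- sqrt(sum(d * d))                              # mm
    if (r * MM_TO_M < 1e-9)
      stop("observation point coincides with the dipole source (singularity)")
    kappa_uv_mm(params) * sum(source_normal * obs_normal) * dA / r^3
  }
}

#' Power-law decay fit
#'
#' Ordinary least squares on `(log10 r, log10 |v|)`: the slope is the decay
#' exponent. Values must be single-signed (take magnitudes upstream if
#' they are not).
#'
#' @param distances Distances in mm (strictly positive).
#' @param values Field or potential values (all positive or all negative).
#' @param fit_range Optional `c(min, max)` distance interval (inclusive)
#'   restricting the fit.
#' @return An object of class `decay_fit`: list with `exponent`,
#'   `intercept` (log10 units), `r_squared`, `n_points`.
#' @export
fit_power_decay <- function(distances, values, fit_range = NULL) {
  distances <- as.numeric(distances)
  values <- as.numeric(values)
  stopifnot(length(distances) == length(values))
  keep <- distances > 0 & is.finite(distances) & is.finite(values)
  if (!is.null(fit_range))
    keep <- keep & distances >= fit_range[1L] & distances <= fit_range[2L]
  distances <- distances[keep]
  values <- values[keep]
  if (any(values > 0) && any(values < 0))
    stop("values are sign-mixed; fit |values| or restrict fit_range")
  if (any(values == 0))
    stop("zero values cannot be log-fit; restrict fit_range")
  if (length(distances) < 3L)
    stop("need at least 3 positive (distance, value) pairs after filtering")
  lx <- log10(distances)
  ly <- log10(abs(values))
  fit <- stats::lm(ly ~ lx)
  sst <- sum((ly - mean(ly))^2)
  # direct R^2 (summary.lm warns on exact power laws, a legitimate case here)
  r2 <- if (sst > 0) max(0, min(1, 1 - sum(stats::residuals(fit)^2) / sst))
        else 1     # zero-variance response: residuals are 0
  structure(list(exponent = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 n_points = length(distances)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit: exponent %.4f, R^2 %.4f, n = %d>\n",
              x$exponent, x$r_squared, x$n_points))
  invisible(x)
}
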