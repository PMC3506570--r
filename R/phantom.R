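#' @title Synthetic left-ventricle phantom
#' @name phantom_module
#' @description
#' Generates thick-walled annular LV segments with a prescribed transmural
#' helix-angle profile and known per-voxel fiber directions, from which
#' diffusion tensors, synthetic diffusion-weighted signals, and ground
#' truth for every downstream stage are derived. The geometry is a locally
#' cylindrical wall segment — the configuration in which mid-ventricular
#' lateral-wall quantification takes place — rather than a whole heart.
NULL

#' Phantom specification
#'
#' Defaults encode a normal mid-ventricular LV wall: a 24–30 mm annulus
#' (6 mm wall), 48 mm tall, 1 mm isotropic voxels (a 64^3-scale grid), a
#' linear transmural HA profile, physiologic-order eigenvalues
#' `(1.0, 0.7, 0.5) x 1e-3 mm^2/s`, and 5 degrees of per-voxel fiber
#' orientation noise.
#'
#' @param inner_radius,outer_radius endocardial/epicardial radius (mm).
#' @param height axial extent of the wall segment (mm).
#' @param spacing isotropic voxel size (mm) or length-3 vector.
#' @param alpha_endo,alpha_epi HA at the endo-/epicardial surface (deg).
#' @param profile transmural interpolation rule; only `"linear"` is built
#'   in, or supply a function of normalized depth `x` in `[0, 1]` returning
#'   HA in degrees.
#' @param eigenvalues diffusion eigenvalues, non-increasing (mm^2/s).
#' @param orientation_noise_sd SD of the random per-voxel fiber rotation
#'   (degrees).
#' @param taper strength in `[0, 1)` of the optional axial flattening of
#'   |HA| toward base and apex (0 = pure cylinder).
#' @param subendo_noise_sd optional elevated orientation noise (degrees)
#'   for the subendocardial band `x < 0.15`, standing in for papillary and
#'   trabecular incoherence; `NULL` disables it.
#' @param seed RNG seed; identical specs give bitwise-identical phantoms.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(inner_radius = 24, outer_radius = 30, height = 48,
                         spacing = 1, alpha_endo = 60, alpha_epi = -60,
                         profile = "linear",
                         eigenvalues = c(1.0, 0.7, 0.5) * 1e-3,
                         orientation_noise_sd = 5, taper = 0,
                         subendo_noise_sd = NULL, seed = 1L) {
  stopifnot(outer_radius > inner_radius, inner_radius > 0,
            abs(alpha_endo) <= 90, abs(alpha_epi) <= 90,
            all(eigenvalues > 0), all(diff(eigenvalues) <= 0),
            orientation_noise_sd >= 0, taper >= 0, taper < 1)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(all(spacing > 0))
  structure(list(inner_radius = inner_radius, outer_radius = outer_radius,
                 height = height, spacing = as.numeric(spacing),
                 alpha_endo = alpha_endo, alpha_epi = alpha_epi,
                 profile = profile, eigenvalues = as.numeric(eigenvalues),
                 orientation_noise_sd = orientation_noise_sd,
                 taper = taper, subendo_noise_sd = subendo_noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Named phantom presets
#'
#' `"normal-human"`: symmetric +60/-60 degree transmural HA range;
#' `"normal-sheep"`: symmetric +50/-50;
#' `"remote-zone"`: epicardial HA shifted rightward to -37.5 degrees
#' (histology-anchored remote-zone architecture), endocardial unchanged.
#'
#' Presets live as JSON configuration files under
#' `system.file("presets", package = "cardiotract")`, not as code.
#'
#' @param name preset name.
#' @param ... overrides passed on to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
phantom_preset <- function(name = c("normal-human", "normal-sheep",
                                    "remote-zone"), ...) {
  name <- match.arg(name)
  path <- system.file("presets", paste0(name, ".json"),
                      package = "cardiotract", mustWork = TRUE)
  args <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

# transmural HA profile in degrees at normalized depth x
phantom_profile_ha <- function(spec, x) {
  if (is.function(spec$profile)) return(spec$profile(x))
  spec$alpha_endo + x * (spec$alpha_epi - spec$alpha_endo)
}

#' Generate a synthetic LV phantom
#'
#' For each wall voxel at normalized transmural depth
#' `x = (r - inner_radius) / (outer_radius - inner_radius)` (0 = endo,
#' 1 = epi), the fiber direction is the local circumferential direction
#' rotated by `HA(x)` about the radial axis, then perturbed by a random
#' rotation of magnitude `Normal(0, orientation_noise_sd)` about a
#' uniformly random axis. The diffusion tensor is
#' `D = l1 f f' + l2 s s' + l3 n n'` with `s` in-wall orthogonal to `f`
#' and `n` (near-)radial.
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom` object: `tensors` ([tensor_volume()]),
#'   `truth_fibers` (`[nx,ny,nz,3]`), `truth_ha` (3D array, degrees),
#'   `depth` (3D array, normalized transmural depth), `frame`
#'   ([cardiac_frame()]), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$spacing
  wall <- spec$outer_radius - spec$inner_radius
  if (wall / mean(sp[1:2]) < 2)
    stop("generate_phantom: wall thinner than 2 voxels; transmural profile unresolvable")
  margin <- 2L
  nx <- ceiling(2 * spec$outer_radius / sp[1]) + 2L * margin
  ny <- ceiling(2 * spec$outer_radius / sp[2]) + 2L * margin
  nz <- ceiling(spec$height / sp[3])
  cx <- nx * sp[1] / 2
  cy <- ny * sp[2] / 2
  xs <- (seq_len(nx) - 0.5) * sp[1] - cx
  ys <- (seq_len(ny) - 0.5) * sp[2] - cy
  zs <- (seq_len(nz) - 0.5) * sp[3]

  X <- array(xs, c(nx, ny, nz))
  Y <- array(rep(ys, each = nx), c(nx, ny, nz))
  Z <- array(rep(zs, each = nx * ny), c(nx, ny, nz))
  R <- sqrt(X^2 + Y^2)
  mask <- R >= spec$inner_radius & R <= spec$outer_radius

  idx <- which(mask)
  r <- R[idx]
  x_depth <- pmin(1, pmax(0, (r - spec$inner_radius) / wall))
  ha <- phantom_profile_ha(spec, x_depth)
  if (spec$taper > 0) {
    zmid <- spec$height / 2
    ha <- ha * (1 - spec$taper * (2 * (Z[idx] - zmid) / spec$height)^2)
  }

  ct <- X[idx] / r
  st <- Y[idx] / r
  r_hat <- cbind(ct, st, 0)
  c_hat <- cbind(-st, ct, 0)            # l x r with l = +z (base->apex = +z)
  l_hat <- cbind(0, 0, 1)[rep(1L, length(idx)), , drop = FALSE]
  har <- ha * pi / 180
  f <- c_hat * cos(har) + l_hat * sin(har)

  set.seed(spec$seed)
  sd_vec <- rep(spec$orientation_noise_sd, length(idx))
  if (!is.null(spec$subendo_noise_sd))
    sd_vec[x_depth < 0.15] <- spec$subendo_noise_sd
  if (any(sd_vec > 0)) {
    n <- length(idx)
    u <- matrix(stats::rnorm(3 * n), n, 3)
    u <- normalize_rows(u)
    ang <- stats::rnorm(n, 0, sd_vec) * pi / 180
    ca <- cos(ang); sa <- sin(ang)
    udotf <- rowSums(u * f)
    f <- f * ca + cross3(u, f) * sa + u * (udotf * (1 - ca))
    f <- normalize_rows(f)
  }

  # orthonormal triad with n ~ radial, s in-wall orthogonal to f
  s_vec <- normalize_rows(cross3(r_hat, f))
  n_vec <- cross3(f, s_vec)
  ev <- spec$eigenvalues
  t6 <- matrix(NA_real_, nx * ny * nz, 6L)
  comp <- function(a, b) ev[1] * f[, a] * f[, b] +
    ev[2] * s_vec[, a] * s_vec[, b] + ev[3] * n_vec[, a] * n_vec[, b]
  t6[idx, ] <- cbind(comp(1, 1), comp(1, 2), comp(2, 2),
                     comp(1, 3), comp(2, 3), comp(3, 3))
  tv <- tensor_volume(array(t6, c(nx, ny, nz, 6L)), sp, mask)

  frame <- cardiac_frame(c(0, 0, 1),
                         cbind(c(0, spec$height), cx, cy, c(0, spec$height)))
  centers <- cbind(X[idx] + cx, Y[idx] + cy, Z[idx])
  truth_ha_v <- helix_angle(f, frame_at(frame, centers))

  fib <- matrix(NA_real_, nx * ny * nz, 3L)
  fib[idx, ] <- f
  truth_ha <- array(NA_real_, c(nx, ny, nz)); truth_ha[idx] <- truth_ha_v
  depth <- array(NA_real_, c(nx, ny, nz)); depth[idx] <- x_depth

  structure(list(tensors = tv,
                 truth_fibers = array(fib, c(nx, ny, nz, 3L)),
                 truth_ha = truth_ha, depth = depth,
                 frame = frame, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$truth_ha)
  cat(sprintf("LV phantom: %d x %d x %d grid, %d wall voxels, HA %+.1f (endo) to %+.1f (epi) deg\n",
              d[1], d[2], d[3], sum(x$tensors$mask),
              x$spec$alpha_endo, x$spec$alpha_epi))
  invisible(x)
}

#' Simulate diffusion-weighted signals from a phantom
#'
#' Forward model `S_i = S_0 exp(-b g_i' D g_i)` per masked voxel, with
#' optional Gaussian or Rician noise. Voxels outside the mask get the
#' baseline signal in every volume.
#'
#' @param ph a `phantom` or [tensor_volume()].
#' @param bval b-value (s/mm^2) for the diffusion-weighted volumes.
#' @param bvecs 3 x n (or n x 3) unit gradient directions, n >= 6.
#' @param s0 baseline signal.
#' @param noise_sd noise SD in signal units (0 = noiseless).
#' @param noise_model `"gaussian"` or `"rician"`.
#' @param seed RNG seed for the noise.
#' @return A [dwi_set()] whose first volume is the b=0 baseline.
#' @export
simulate_dwi <- function(ph, bval = 2000, bvecs = default_bvecs(),
                         s0 = 1000, noise_sd = 0,
                         noise_model = c("gaussian", "rician"), seed = 1L) {
  tv <- if (inherits(ph, "phantom")) ph$tensors else ph
  stopifnot(inherits(tv, "tensor_volume"), bval > 0)
  noise_model <- match.arg(noise_model)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L && ncol(bvecs) == 3L) bvecs <- t(bvecs)
  nd <- ncol(bvecs)
  stopifnot(nd >= 6L)
  bvecs <- sweep(bvecs, 2L, sqrt(colSums(bvecs^2)), `/`)
  dims <- dim(tv$tensors)[1:3]
  nvox <- prod(dims)
  tmat <- matrix(tv$tensors, nvox, 6L)
  idx <- which(tv$mask)
  # g' D g expanded over the 6 lower-triangular components
  g <- bvecs
  quad <- cbind(g[1, ]^2, 2 * g[1, ] * g[2, ], g[2, ]^2,
                2 * g[1, ] * g[3, ], 2 * g[2, ] * g[3, ], g[3, ]^2)
  att <- exp(-bval * tmat[idx, , drop = FALSE] %*% t(quad))   # n_mask x nd
  vols <- array(s0, dim = c(dims, nd + 1L))
  vmat <- matrix(vols, nvox, nd + 1L)
  vmat[idx, -1L] <- s0 * att
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    if (noise_model == "gaussian") {
      vmat <- vmat + stats::rnorm(length(vmat), 0, noise_sd)
    } else {
      n1 <- stats::rnorm(length(vmat), 0, noise_sd)
      n2 <- stats::rnorm(length(vmat), 0, noise_sd)
      vmat <- sqrt((vmat + n1)^2 + n2^2)
    }
  }
  dwi_set(array(vmat, c(dims, nd + 1L)),
          bvals = c(0, rep(bval, nd)),
          bvecs = cbind(0, bvecs),
          spacing = tv$spacing)
}

#' Default 6-direction gradient scheme
#'
#' The classic dual-gradient six-direction scheme (normalized), sufficient
#' for a full tensor fit.
#'
#' @return 3 x 6 matrix of unit vectors.
#' @export
default_bvecs <- function() {
  g <- cbind(c(1, 1, 0), c(1, -1, 0), c(1, 0, 1),
             c(1, 0, -1), c(0, 1, 1), c(0, 1, -1))
  sweep(g, 2L, sqrt(colSums(g^2)), `/`)
}

#' Generate a synthetic stripe image
#'
#' Sinusoidal stripes whose ridge lines make `angle` degrees with the
#' horizontal axis (counterclockwise, y up), emulating fibers in a
#' tangential histology section. Used as ground truth for the Hessian
#' orientation analysis.
#'
#' @param angle stripe orientation (degrees, in (-90, 90]).
#' @param period stripe period (pixels).
#' @param size image size `c(nrow, ncol)`.
#' @param contrast peak-to-trough amplitude scale in `[0, 1]`.
#' @param noise_sd SD of additive Gaussian noise (same units as intensity,
#'   image spans roughly `0.5 +/- 0.5 * contrast`).
#' @param seed RNG seed.
#' @return Numeric matrix of intensities.
#' @export
generate_stripe_image <- function(angle, period = 12, size = c(192, 192),
                                  contrast = 1, noise_sd = 0, seed = 1L) {
  stopifnot(period > 0, period < min(size))
  nr <- size[1]; nc <- size[2]
  xc <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc)
  yc <- matrix(rep(nr - seq_len(nr) + 0.5, nc), nr, nc)   # y up
  a <- angle * pi / 180
  phase <- (-xc * sin(a) + yc * cos(a)) / period
  img <- 0.5 + 0.5 * contrast * cos(2 * pi * phase)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
  }
  img
}
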