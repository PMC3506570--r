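#' @title Diffusion tensor fitting and eigendecomposition
#' @name tensor_field
#' @description
#' A `tensor_volume` stores one symmetric 3x3 diffusion tensor per voxel as
#' six components in lower-triangular order `(Dxx, Dxy, Dyy, Dxz, Dyz, Dzz)`
#' in a 4D array `[nx, ny, nz, 6]`, together with the voxel spacing (mm) and
#' a logical myocardium mask. Tensors are fit from diffusion-weighted
#' signals by unweighted log-linear least squares and eigendecomposed into
#' per-voxel sorted eigensystems (`lambda1 >= lambda2 >= lambda3`).
NULL

# Index map for the fixed lower-triangular component order.
TENSOR_COMPONENT_ORDER <- c("Dxx", "Dxy", "Dyy", "Dxz", "Dyz", "Dzz")

# 6-vector(s) -> 3x3 symmetric matrix. m: n x 6.
tensor6_to_mat <- function(v) {
  matrix(c(v[1], v[2], v[4],
           v[2], v[3], v[5],
           v[4], v[5], v[6]), 3, 3)
}

mat_to_tensor6 <- function(m) {
  c(m[1, 1], m[1, 2], m[2, 2], m[1, 3], m[2, 3], m[3, 3])
}

#' Construct a diffusion-weighted image set
#'
#' @param volumes 4D array `[nx, ny, nz, nvol]` of signal intensities;
#'   volumes with `bvals == 0` are baselines.
#' @param bvals numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs 3 x nvol matrix (or nvol x 3, auto-detected) of unit
#'   gradient directions; direction of b=0 volumes is ignored.
#' @param spacing voxel size per axis in mm (length 3).
#' @return A `dwi_set` object.
#' @export
dwi_set <- function(volumes, bvals, bvecs, spacing) {
  stopifnot(length(dim(volumes)) == 4L)
  nv <- dim(volumes)[4]
  bvals <- as.numeric(bvals)
  if (length(bvals) != nv)
    stop("dwi_set: length(bvals) != number of volumes")
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L && ncol(bvecs) == 3L) bvecs <- t(bvecs)
  if (nrow(bvecs) != 3L || ncol(bvecs) != nv)
    stop("dwi_set: bvecs must be 3 x n_volumes")
  if (sum(bvals == 0) < 1L) stop("dwi_set: at least one b=0 volume required")
  if (sum(bvals > 0) < 6L)
    stop("dwi_set: at least 6 diffusion-weighted directions required")
  dw <- bvals > 0
  nrm <- sqrt(colSums(bvecs[, dw, drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("dwi_set: diffusion-weighted bvecs must have unit norm (tol 1e-6)")
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  structure(list(volumes = volumes, bvals = bvals, bvecs = bvecs,
                 spacing = spacing),
            class = "dwi_set")
}

#' Construct a tensor volume
#'
#' @param tensors 4D array `[nx, ny, nz, 6]`, lower-triangular component
#'   order `(Dxx, Dxy, Dyy, Dxz, Dyz, Dzz)` in mm^2/s.
#' @param spacing voxel size per axis (mm).
#' @param mask logical/0-1 3D array marking myocardium voxels.
#' @return A `tensor_volume` object.
#' @export
tensor_volume <- function(tensors, spacing, mask) {
  stopifnot(length(dim(tensors)) == 4L, dim(tensors)[4] == 6L)
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  mask <- array(as.logical(mask), dim = dim(tensors)[1:3])
  structure(list(tensors = tensors, spacing = spacing, mask = mask),
            class = "tensor_volume")
}

#' @export
print.tensor_volume <- function(x, ...) {
  d <- dim(x$tensors)
  cat(sprintf("tensor_volume: %d x %d x %d voxels, spacing %s mm, %d in mask\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = "x"),
              sum(x$mask)))
  invisible(x)
}

#' Fit diffusion tensors by log-linear least squares
#'
#' Solves, per masked voxel, the unweighted least-squares system
#' \eqn{\ln(S_i/S_0) = -b_i\, g_i^T D\, g_i} over the diffusion-weighted
#' volumes. Multiple b=0 volumes are averaged before the log transform.
#' Voxels with any non-positive signal are flagged invalid (tensor set to
#' `NA`) rather than fit; downstream tracking treats them as impassable.
#'
#' @param dwi a [dwi_set()].
#' @param mask logical 3D array; voxels outside are left as `NA`.
#' @return A [tensor_volume()] with attribute `n_invalid` (count of flagged
#'   voxels) and `invalid` (logical array).
#' @export
fit_tensor <- function(dwi, mask) {
  stopifnot(inherits(dwi, "dwi_set"))
  dims <- dim(dwi$volumes)[1:3]
  mask <- array(as.logical(mask), dim = dims)
  dw <- dwi$bvals > 0
  g <- dwi$bvecs[, dw, drop = FALSE]
  b <- dwi$bvals[dw]
  # design row: b * (gx^2, 2 gx gy, gy^2, 2 gx gz, 2 gy gz, gz^2),
  # matching the lower-triangular component order.
  B <- cbind(g[1, ]^2, 2 * g[1, ] * g[2, ], g[2, ]^2,
             2 * g[1, ] * g[3, ], 2 * g[2, ] * g[3, ], g[3, ]^2) * b
  if (qr(B)$rank < 6L)
    stop("fit_tensor: gradient scheme is degenerate (design rank < 6)")

  nvox <- prod(dims)
  vmat <- matrix(dwi$volumes, nrow = nvox)  # voxels x volumes
  idx <- which(mask)
  s0 <- rowMeans(vmat[idx, !dw, drop = FALSE])
  sdw <- vmat[idx, dw, drop = FALSE]
  ok <- s0 > 0 & apply(sdw > 0, 1L, all)

  tens <- array(NA_real_, dim = c(dims, 6L))
  tmat <- matrix(tens, nrow = nvox)
  if (any(ok)) {
    y <- -log(sdw[ok, , drop = FALSE] / s0[ok])  # n_ok x n_dir
    # D components: solve B D = y' in least squares for all voxels at once
    coef <- t(qr.solve(B, t(y)))                 # n_ok x 6
    tmat[idx[ok], ] <- coef
  }
  tens <- array(tmat, dim = c(dims, 6L))
  invalid <- array(FALSE, dims)
  invalid[idx[!ok]] <- TRUE
  tv <- tensor_volume(tens, dwi$spacing, mask & !invalid)
  attr(tv, "n_invalid") <- sum(!ok)
  attr(tv, "invalid") <- invalid
  tv
}

#' Eigendecompose a tensor volume
#'
#' Per masked voxel, computes eigenvalues sorted non-increasingly and the
#' associated orthonormal eigenvector triad. Eigenvector sign is left
#' unconstrained; antipodal symmetry is resolved during tracking and HA
#' computation.
#'
#' @param tv a [tensor_volume()].
#' @return An `eigen_field`: list with `values` (`[nx,ny,nz,3]`), `vectors`
#'   (`[nx,ny,nz,3,3]`, last index = eigenvector rank, second-to-last =
#'   xyz component), `spacing`, `mask`.
#' @export
eigendecompose <- function(tv) {
  stopifnot(inherits(tv, "tensor_volume"))
  dims <- dim(tv$tensors)[1:3]
  nvox <- prod(dims)
  tmat <- matrix(tv$tensors, nrow = nvox)
  idx <- which(tv$mask)
  bad <- idx[!apply(is.finite(tmat[idx, , drop = FALSE]), 1L, all)]
  if (length(bad))
    stop(sprintf("eigendecompose: non-finite tensor at masked voxel index %d",
                 bad[1]))
  vals <- matrix(NA_real_, nvox, 3L)
  vecs <- matrix(NA_real_, nvox, 9L)
  for (v in idx) {
    e <- eigen(tensor6_to_mat(tmat[v, ]), symmetric = TRUE)
    vals[v, ] <- e$values            # eigen() returns decreasing order
    vecs[v, ] <- as.vector(e$vectors)
  }
  structure(list(values = array(vals, c(dims, 3L)),
                 vectors = array(vecs, c(dims, 3L, 3L)),
                 spacing = tv$spacing, mask = tv$mask),
            class = "eigen_field")
}

# Reconstruct tensors from an eigen_field (test/oracle helper).
eigen_reconstruct <- function(ef) {
  dims <- dim(ef$values)[1:3]
  nvox <- prod(dims)
  vals <- matrix(ef$values, nvox, 3L)
  vecs <- matrix(ef$vectors, nvox, 9L)
  out <- matrix(NA_real_, nvox, 6L)
  for (v in which(ef$mask)) {
    V <- matrix(vecs[v, ], 3L, 3L)
    D <- V %*% diag(vals[v, ]) %*% t(V)
    out[v, ] <- mat_to_tensor6(D)
  }
  tensor_volume(array(out, c(dims, 6L)), ef$spacing, ef$mask)
}

# Primary eigenvector field as [nx,ny,nz,3] array (NA outside mask).
primary_eigenvector <- function(ef) {
  stopifnot(inherits(ef, "eigen_field"))
  ef$vectors[, , , , 1L]
}
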