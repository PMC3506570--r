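# Shared fixtures, built in code at test time.

# Small, fast LV phantom for unit tests (4 mm wall, 12 voxels tall).
small_phantom_spec <- function(...) {
  args <- utils::modifyList(list(inner_radius = 10, outer_radius = 14,
                                 height = 12, spacing = 1), list(...))
  do.call(phantom_spec, args)
}

# Tangential (circular) unit field about the z axis, sampled on a grid.
# Returns a list(field, center, Rc) usable by track().
circular_field <- function(n = 80, nz = 9, spacing = 1, Rc = 30,
                           band = 12) {
  xs <- (seq_len(n) - 0.5) * spacing - n * spacing / 2
  e1 <- array(NA_real_, c(n, n, nz, 3))
  mask <- array(FALSE, c(n, n, nz))
  for (j in seq_len(n)) {
    x <- xs
    y <- xs[j]
    r <- sqrt(x^2 + y^2)
    sel <- r > Rc - band & r < Rc + band
    mask[, j, ] <- sel
    e1[, j, , 1] <- rep(-y / r, nz)
    e1[, j, , 2] <- rep(x / r, nz)
    e1[, j, , 3] <- 0
  }
  list(field = list(e1 = e1, mask = mask, spacing = rep(spacing, 3)),
       center = c(n * spacing / 2, n * spacing / 2),
       Rc = Rc, nz = nz, spacing = spacing)
}

# Uniform straight field along +x.
uniform_field <- function(n = 20, spacing = 1) {
  e1 <- array(0, c(n, n, n, 3))
  e1[, , , 1] <- 1
  list(e1 = e1, mask = array(TRUE, c(n, n, n)), spacing = rep(spacing, 3))
}

# Random symmetric positive-definite 3x3 tensor.
random_spd <- function() {
  A <- matrix(stats::rnorm(9), 3)
  S <- crossprod(A) + diag(3) * 0.1
  S * 1e-3 / max(abs(S))
}
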