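# Small numeric helpers shared across modules.

# Row-wise cross product of n x 3 matrices.
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Row-wise normalization; rows with norm below tol become NA.
normalize_rows <- function(m, tol = 1e-12) {
  n <- sqrt(rowSums(m^2))
  bad <- n < tol
  n[bad] <- NA_real_
  m / n
}

row_norms <- function(m) sqrt(rowSums(m^2))

# Trapezoidal integral of y over x (x strictly increasing).
trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

# Deterministic 32-bit FNV-1a hash of a character scalar, as hex.
fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 0x811C9DC5
  for (b in bytes) {
    # xor touches only the low byte (b < 256); keep h as a double < 2^32
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit multiply by 16777619 without overflow: split into 16-bit halves
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

# Derive a stream of child seeds from one user seed, kept below 2^31.
derive_seeds <- function(seed, n) {
  (as.integer(seed) * 1000003L + 7919L * seq_len(n)) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
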