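#' @title File formats: NIfTI, FSL gradient tables, VTK polydata, PGM
#' @name io_module
#' @description
#' Minimal, lossless readers/writers for the formats the pipeline
#' consumes and produces. NIfTI-1 support is intentionally small: single
#' file `.nii`/`.nii.gz`, axis-aligned grids (pixdim only; qform/sform
#' orientation is not interpreted), datatypes uint8/int16/int32/float32/
#' float64. Tensor volumes are stored as 4D NIfTI with 6 components per
#' voxel in lower-triangular order `(Dxx, Dxy, Dyy, Dxz, Dyz, Dzz)`,
#' asserted by a header-extension comment tag written by this package.
NULL

NIFTI_TENSOR_TAG <- "cardiotract:tensor:lower_tri:Dxx,Dxy,Dyy,Dxz,Dyz,Dzz"

nifti_dt <- function(code) {
  switch(as.character(code),
         "2" = list(what = "integer", size = 1L, signed = FALSE),
         "4" = list(what = "integer", size = 2L, signed = TRUE),
         "8" = list(what = "integer", size = 4L, signed = TRUE),
         "16" = list(what = "numeric", size = 4L, signed = TRUE),
         "64" = list(what = "numeric", size = 8L, signed = TRUE),
         stop(sprintf("read_nifti: unsupported datatype code %s", code)))
}

open_nii <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3D/4D array as NIfTI-1
#'
#' @param data numeric/logical array (3D or 4D).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing voxel size per spatial axis (mm).
#' @param datatype `"float64"`, `"float32"` or `"uint8"`.
#' @param extension_text optional header-extension comment string.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, spacing = c(1, 1, 1),
                        datatype = c("float64", "float32", "uint8"),
                        extension_text = NULL) {
  datatype <- match.arg(datatype)
  dt_code <- c(float64 = 64L, float32 = 16L, uint8 = 2L)[[datatype]]
  bitpix <- c(float64 = 64L, float32 = 32L, uint8 = 8L)[[datatype]]
  dims <- dim(data)
  stopifnot(length(dims) %in% c(3L, 4L), all(spacing > 0))
  ndim <- length(dims)

  ext_raw <- raw(0)
  if (!is.null(extension_text)) {
    payload <- charToRaw(extension_text)
    esize <- 8L + length(payload)
    esize <- as.integer(ceiling(esize / 16) * 16)   # esize multiple of 16
    ext_raw <- c(writeBin(c(esize, 6L), raw(), size = 4L, endian = "little"),
                 payload, raw(esize - 8L - length(payload)))
  }
  vox_offset <- 352 + length(ext_raw)

  con <- open_nii(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  w(348L, 4L)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # data_type..dim_info
  w(as.integer(c(ndim, dims, rep(1L, 7L - ndim))), 2L)     # dim[8]
  w(rep(0, 3), 4L)                              # intent_p1..p3
  w(c(0L, dt_code, bitpix, 0L), 2L)             # intent_code, datatype, bitpix, slice_start
  w(c(0, spacing, rep(1, 7 - length(spacing)))[1:8], 4L)  # pixdim[8]
  w(as.numeric(vox_offset), 4L)                 # vox_offset
  w(c(1, 0), 4L)                                # scl_slope, scl_inter
  w(0L, 2L); writeBin(raw(2), con)              # slice_end, slice_code, xyzt_units
  w(rep(0, 4), 4L)                              # cal_max, cal_min, slice_duration, toffset
  w(c(0L, 0L), 4L)                              # glmax, glmin
  writeBin(raw(80 + 24), con)                   # descrip, aux_file
  w(c(0L, 0L), 2L)                              # qform_code, sform_code
  w(rep(0, 6), 4L)                              # quatern b,c,d, qoffset x,y,z
  w(rep(0, 12), 4L)                             # srow_x/y/z
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  if (length(ext_raw)) {
    writeBin(as.raw(c(1, 0, 0, 0)), con)
    writeBin(ext_raw, con)
  } else {
    writeBin(raw(4), con)
  }
  vals <- as.numeric(data)
  if (datatype == "uint8") {
    writeBin(as.integer(vals), con, size = 1L, endian = "little")
  } else {
    writeBin(vals, con, size = bitpix %/% 8L, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return List with `data` (array), `spacing` (mm, spatial axes) and
#'   `extension_text` (first comment extension, or `NULL`).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_nifti: no such file: %s", path))
  con <- open_nii(path, "rb")
  on.exit(close(con))
  b4 <- readBin(con, "raw", 4L)
  endian <- if (readBin(b4, "integer", 1L, size = 4L,
                        endian = "little") == 348L) "little"
            else if (readBin(b4, "integer", 1L, size = 4L,
                             endian = "big") == 348L) "big"
            else stop(sprintf("read_nifti: %s is not NIfTI-1 (bad sizeof_hdr)",
                              path))
  readBin(con, "raw", 36L)
  dim8 <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  readBin(con, "raw", 12L)                      # intent_p
  readBin(con, "integer", 1L, size = 2L, endian = endian)
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "integer", 2L, size = 2L, endian = endian)  # bitpix, slice_start
  pixdim <- readBin(con, "numeric", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  readBin(con, "raw", 232L)                     # skip to magic at offset 344
  magic <- rawToChar(readBin(con, "raw", 4L)[1:3])
  if (!magic %in% c("n+1", "ni1"))
    stop(sprintf("read_nifti: %s has bad magic '%s'", path, magic))

  ext_text <- NULL
  ext_flag <- readBin(con, "raw", 4L)
  offset_now <- 352
  if (length(ext_flag) == 4L && ext_flag[1] != as.raw(0)) {
    while (offset_now < vox_offset) {
      eh <- readBin(con, "integer", 2L, size = 4L, endian = endian)
      payload <- readBin(con, "raw", eh[1] - 8L)
      if (is.null(ext_text) && eh[2] == 6L) {
        txt <- rawToChar(payload[payload != as.raw(0)])
        ext_text <- txt
      }
      offset_now <- offset_now + eh[1]
    }
  }
  ndim <- dim8[1]
  dims <- dim8[2:(1 + ndim)]
  if (any(dims <= 0)) stop(sprintf("read_nifti: %s has non-positive dim", path))
  spt <- nifti_dt(datatype)
  n <- prod(dims)
  vals <- readBin(con, spt$what, n, size = spt$size, endian = endian,
                  signed = spt$signed)
  if (length(vals) < n)
    stop(sprintf("read_nifti: %s truncated (%d of %d values)",
                 path, length(vals), n))
  spacing <- pixdim[2:4]
  if (any(spacing <= 0))
    stop(sprintf("read_nifti: %s has non-positive spacing", path))
  list(data = array(as.numeric(vals), dims), spacing = spacing,
       extension_text = ext_text)
}

#' Write / read tensor volumes as NIfTI
#'
#' 4D NIfTI with 6 components per voxel in the documented
#' lower-triangular order, tagged by a header extension. The mask is
#' implicit: voxels with all-`NA` tensors are outside it (stored as NaN).
#'
#' @param tv a [tensor_volume()].
#' @param path output `.nii`/`.nii.gz` path.
#' @return `write_tensor_nifti`: `path`, invisibly. `read_tensor_nifti`:
#'   a [tensor_volume()].
#' @export
write_tensor_nifti <- function(tv, path) {
  stopifnot(inherits(tv, "tensor_volume"))
  write_nifti(tv$tensors, path, spacing = tv$spacing,
              extension_text = NIFTI_TENSOR_TAG)
}

#' @rdname write_tensor_nifti
#' @export
read_tensor_nifti <- function(path) {
  nii <- read_nifti(path)
  if (length(dim(nii$data)) != 4L || dim(nii$data)[4] != 6L)
    stop(sprintf("read_tensor_nifti: %s is not a 6-component 4D volume", path))
  if (is.null(nii$extension_text) ||
      !startsWith(nii$extension_text, "cardiotract:tensor:lower_tri"))
    warning(sprintf("read_tensor_nifti: %s lacks the tensor component-order tag; assuming lower-triangular order", path))
  mask <- apply(is.finite(nii$data), c(1, 2, 3), all)
  tensor_volume(nii$data, nii$spacing, mask)
}

#' Read a binary mask NIfTI
#'
#' @param path `.nii`/`.nii.gz` file; nonzero voxels are myocardium.
#' @return List with `mask` (logical 3D array) and `spacing`.
#' @export
read_mask_nifti <- function(path) {
  nii <- read_nifti(path)
  if (length(dim(nii$data)) != 3L)
    stop(sprintf("read_mask_nifti: %s is not a 3D volume", path))
  list(mask = nii$data != 0, spacing = nii$spacing)
}

#' Read a DWI dataset (NIfTI + FSL-style bvals/bvecs)
#'
#' `bvals` is one whitespace-separated row; `bvecs` has three rows
#' (x, y, z). Diffusion-weighted directions within 1% of unit norm are
#' renormalized with a warning; larger deviations are an error.
#'
#' @param nifti_path 4D NIfTI of signal volumes.
#' @param bvals_path,bvecs_path plain-text gradient table paths.
#' @return A [dwi_set()].
#' @export
read_dwi <- function(nifti_path, bvals_path, bvecs_path) {
  nii <- read_nifti(nifti_path)
  if (length(dim(nii$data)) != 4L)
    stop(sprintf("read_dwi: %s is not 4D", nifti_path))
  bvals <- scan(bvals_path, quiet = TRUE)
  bvecs <- unname(as.matrix(read.table(bvecs_path)))
  if (nrow(bvecs) != 3L)
    stop(sprintf("read_dwi: %s must have 3 rows", bvecs_path))
  dw <- bvals > 0
  nrm <- sqrt(colSums(bvecs[, dw, drop = FALSE]^2))
  off <- abs(nrm - 1)
  if (any(off > 0.01))
    stop(sprintf("read_dwi: %s: non-unit gradient direction (max deviation %.3g)",
                 bvecs_path, max(off)))
  if (any(off > 1e-6)) {
    warning(sprintf("read_dwi: renormalizing %d gradient direction(s) within 1%% of unit norm",
                    sum(off > 1e-6)))
    bvecs[, dw] <- sweep(bvecs[, dw, drop = FALSE], 2L, nrm, `/`)
  }
  dwi_set(nii$data, bvals, bvecs, nii$spacing)
}

#' Write FSL-style bvals/bvecs files
#' @param bvals numeric vector; @param bvecs 3 x n matrix.
#' @param bvals_path,bvecs_path output paths.
#' @return `NULL`, invisibly.
#' @export
write_gradients <- function(bvals, bvecs, bvals_path, bvecs_path) {
  writeLines(paste(format(bvals, trim = TRUE), collapse = " "), bvals_path)
  writeLines(apply(format(bvecs, trim = TRUE, digits = 17), 1L, paste,
                   collapse = " "), bvecs_path)
  invisible(NULL)
}

#' Write tracts as VTK legacy ASCII polydata
#'
#' One polyline per streamline; point-data scalar `HA_deg` (discrete HA)
#' and cell-data scalars `HA_min`, `HA_med`, `HA_max`, `HA_mean`,
#' `termination` (forward-branch code) when a classification is supplied.
#'
#' @param tracts a `tract_set`.
#' @param path output `.vtk` path.
#' @param classification optional [classify_tracts()] result.
#' @return `path`, invisibly.
#' @export
write_tracts_vtk <- function(tracts, path, classification = NULL) {
  pts <- do.call(rbind, tracts$points)
  npts <- vapply(tracts$points, nrow, integer(1))
  off <- c(0L, cumsum(npts))
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0", "cardiotract streamlines", "ASCII",
     "DATASET POLYDATA")
  wl(sprintf("POINTS %d float", nrow(pts)))
  wl(apply(format(pts, trim = TRUE, digits = 9), 1L, paste, collapse = " "))
  wl(sprintf("LINES %d %d", length(npts), length(npts) + sum(npts)))
  for (i in seq_along(npts)) {
    wl(paste(c(npts[i], seq.int(off[i], off[i + 1L] - 1L)), collapse = " "))
  }
  if (!is.null(classification)) {
    ha <- unlist(classification$discrete, use.names = FALSE)
    stopifnot(length(ha) == nrow(pts))
    ha[!is.finite(ha)] <- -999
    wl(sprintf("POINT_DATA %d", nrow(pts)))
    wl("SCALARS HA_deg float 1", "LOOKUP_TABLE default")
    wl(format(ha, trim = TRUE, digits = 7))
    st <- classification$stats
    wl(sprintf("CELL_DATA %d", length(npts)))
    for (nm in c("HA_min", "HA_med", "HA_max", "HA_mean")) {
      col <- st[[tolower(sub("HA", "ha", nm))]]
      col[!is.finite(col)] <- -999
      wl(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default")
      wl(format(col, trim = TRUE, digits = 7))
    }
    wl("SCALARS termination int 1", "LOOKUP_TABLE default")
    wl(format(as.integer(tracts$termination$fwd)))
  }
  invisible(path)
}

#' Read VTK legacy ASCII polydata tracts
#'
#' Inverse of [write_tracts_vtk()]; scalar arrays are returned verbatim.
#'
#' @param path `.vtk` file.
#' @return List with `points` (list of n x 3 matrices), `point_scalars`,
#'   `cell_scalars` (named lists of numeric vectors).
#' @export
read_tracts_vtk <- function(path) {
  lines <- readLines(path)
  if (!any(grepl("^DATASET POLYDATA", lines)))
    stop(sprintf("read_tracts_vtk: %s is not polydata", path))
  i_pts <- grep("^POINTS", lines)[1]
  n_pts <- as.integer(strsplit(lines[i_pts], "\\s+")[[1]][2])
  toks <- function(from, n_vals) {
    out <- numeric(0); i <- from
    while (length(out) < n_vals) {
      out <- c(out, as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
      i <- i + 1L
    }
    list(vals = out[seq_len(n_vals)], next_line = i)
  }
  pp <- toks(i_pts + 1L, 3L * n_pts)
  pts <- matrix(pp$vals, ncol = 3L, byrow = TRUE)
  i_lines <- grep("^LINES", lines)[1]
  hdr <- as.integer(strsplit(lines[i_lines], "\\s+")[[1]][2:3])
  conn <- toks(i_lines + 1L, hdr[2])$vals
  polylines <- list(); k <- 1L; j <- 0L
  while (j < length(conn)) {
    m <- conn[j + 1L]
    idx <- conn[(j + 2L):(j + 1L + m)] + 1L
    polylines[[k]] <- pts[idx, , drop = FALSE]
    k <- k + 1L
    j <- j + 1L + m
  }
  read_scalars <- function(section, n_vals) {
    i_sec <- grep(paste0("^", section), lines)
    out <- list()
    if (!length(i_sec)) return(out)
    i <- i_sec[1] + 1L
    while (i <= length(lines) && !grepl("^(POINT_DATA|CELL_DATA)", lines[i])) {
      if (grepl("^SCALARS", lines[i])) {
        nm <- strsplit(lines[i], "\\s+")[[1]][2]
        sc <- toks(i + 2L, n_vals)    # skip LOOKUP_TABLE
        out[[nm]] <- sc$vals
        i <- sc$next_line
      } else i <- i + 1L
    }
    out
  }
  list(points = polylines,
       point_scalars = read_scalars("POINT_DATA", n_pts),
       cell_scalars = read_scalars("CELL_DATA", length(polylines)))
}

#' Write / read plain-text PGM (P2) grayscale images
#'
#' Section images travel as ASCII PGM so fixtures stay text-only.
#' Intensities are scaled to `0..maxval` on write and back to `[0, 1]` on
#' read.
#'
#' @param img numeric matrix.
#' @param path `.pgm` path.
#' @param maxval maximum gray value.
#' @return `write_pgm`: `path` invisibly; `read_pgm`: numeric matrix in
#'   `[0, 1]`.
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  rng <- range(img)
  scaled <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  v <- round(scaled * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(img), nrow(img)),
               sprintf("%d", maxval)), con)
  writeLines(apply(matrix(sprintf("%d", t(v)), nrow(img), byrow = TRUE),
                   1L, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (lines[1] != "P2") stop(sprintf("read_pgm: %s is not ASCII PGM", path))
  dims <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  maxval <- as.numeric(lines[3])
  vals <- as.numeric(unlist(strsplit(trimws(lines[-(1:3)]), "\\s+")))
  matrix(vals / maxval, dims[2], dims[1], byrow = TRUE)
}

#' Write a metrics JSON file with provenance
#'
#' @param metrics named list of scalars/vectors.
#' @param path output `.json` path.
#' @param config optional configuration list recorded (and hashed) into
#'   the provenance block.
#' @param seed seed recorded in provenance.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path, config = NULL, seed = NULL) {
  prov <- list(
    package = "cardiotract",
    version = as.character(utils::packageVersion("cardiotract")),
    seed = seed,
    config_hash = fnv1a(jsonlite::toJSON(config, auto_unbox = TRUE,
                                         digits = NA)))
  jsonlite::write_json(c(metrics, list(provenance = prov, config = config)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
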