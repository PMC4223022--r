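#' @include AllClasses.R
NULL

# ---- NIfTI / NRRD I/O -------------------------------------------------------

nrrdExt <- function(path) grepl("\\.nrrd$|\\.nhdr$", path, ignore.case = TRUE)

#' Read a 3D volume (NIfTI-1/2 or NRRD)
#'
#' Intensities are returned unmodified in the modality's native units;
#' spacing and origin are taken from the header (voxel-center convention).
#'
#' @param path file path ending in .nii, .nii.gz, .nrrd or .nhdr.
#' @param modality optional modality tag stored on the volume.
#' @return an \linkS4class{ImageVolume}.
#' @export
loadVolume <- function(path, modality = "unknown") {
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  if (nrrdExt(path)) {
    v <- readNrrd(path)
    if (length(dim(v$data)) != 3L)
      stop("expected a 3D image, got ", length(dim(v$data)), "D: ", path)
    return(imageVolume(v$data,
                       gridSpec(dim(v$data), v$spacing, v$origin), modality))
  }
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4L] == 1L)
    arr <- array(arr, dim = dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("expected a 3D image, got ", length(dim(arr)), "D: ", path)
  aff <- RNifti::xform(img)
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- aff[1:3, 4L]
  imageVolume(array(as.double(arr), dim = dim(arr)),
              gridSpec(dim(arr), spacing, origin), modality)
}

#' Write a volume or mask to NIfTI or NRRD
#'
#' Masks are stored as uint8. Spacing and origin go into the NIfTI
#' sform/qform (diagonal affine) or the NRRD header.
#'
#' @param x an \linkS4class{ImageVolume} or \linkS4class{GTVMask}.
#' @param path output path (.nii, .nii.gz, .nrrd).
#' @return \code{path}, invisibly.
#' @export
saveVolume <- function(x, path) {
  isMask <- is(x, "GTVMask")
  arr <- if (isMask) array(as.integer(x@data), dim = dim(x@data)) else x@data
  g <- x@grid
  if (nrrdExt(path)) {
    writeNrrd(arr, path, spacing = g@spacing, origin = g@origin)
    return(invisible(path))
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- g@spacing
  aff <- diag(c(g@spacing, 1))
  aff[1:3, 4L] <- g@origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path, datatype = if (isMask) "uint8" else "double")
  invisible(path)
}

#' Read a binary mask
#' @param path NIfTI/NRRD path; voxels are thresholded at 0.5.
#' @return a \linkS4class{GTVMask}.
#' @export
loadMask <- function(path) {
  v <- loadVolume(path, modality = "mask")
  gtvMask(v@data, v@grid)
}

# Minimal NRRD support: 3D scalar, raw or gzip encoding, attached data.
# Covers the subset this pipeline writes; not a general NRRD implementation.
readNrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L || ln == "") break
    if (grepl("^#", ln)) next
    kv <- regmatches(ln, regexpr(":=?", ln), invert = TRUE)[[1L]]
    fields[[tolower(trimws(kv[1L]))]] <- trimws(kv[2L])
  }
  dims <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1L]])
  if (length(dims) != 3L) stop("only 3D NRRD supported")
  type <- fields[["type"]]
  enc <- tolower(fields[["encoding"]])
  n <- prod(dims)
  raw <- readBin(con, "raw", n = 16L * n + 1024L)
  if (enc %in% c("gzip", "gz")) raw <- memDecompress(raw, type = "gzip")
  else if (enc != "raw") stop("unsupported NRRD encoding: ", enc)
  vals <- switch(type,
    "double" = readBin(raw, "double", n = n, size = 8L, endian = "little"),
    "float" = readBin(raw, "double", n = n, size = 4L, endian = "little"),
    "short" = readBin(raw, "integer", n = n, size = 2L, endian = "little"),
    "int" = readBin(raw, "integer", n = n, size = 4L, endian = "little"),
    "uchar" = ,
    "uint8" = as.integer(readBin(raw, "integer", n = n, size = 1L,
                                 signed = FALSE)),
    stop("unsupported NRRD type: ", type))
  spacing <- c(1, 1, 1)
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1L]]
    mat <- vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1L]]), numeric(3))
    spacing <- sqrt(colSums(mat^2))
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1L]])
  }
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       fields[["space origin"]]), ",")[[1L]])
  list(data = array(as.double(vals), dim = dims), spacing = spacing,
       origin = origin)
}

writeNrrd <- function(arr, path, spacing, origin) {
  hdr <- c(
    "NRRD0004",
    "# generated by trifuse",
    "type: double",
    "dimension: 3",
    "space: left-posterior-superior",
    paste0("sizes: ", paste(dim(arr), collapse = " ")),
    paste0("space directions: ",
           sprintf("(%g,0,0) (0,%g,0) (0,0,%g)",
                   spacing[1L], spacing[2L], spacing[3L])),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    paste0("space origin: ", sprintf("(%g,%g,%g)",
                                     origin[1L], origin[2L], origin[3L])),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeBin(as.double(arr), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a rigid transform from a 4x4 plain-text matrix file
#'
#' The file holds a row-major homogeneous matrix (4 lines of 4 numbers,
#' whitespace-separated); the upper-left 3x3 block must be a rotation
#' (orthonormal, determinant +1 within 1e-6).
#'
#' @param path text file path.
#' @return list with \code{rotation} (3x3) and \code{translation} (mm).
#' @export
loadRigidTransform <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (!all(dim(m) == c(4L, 4L))) stop("transform file must be a 4x4 matrix")
  rigidTransform(m[1:3, 1:3], m[1:3, 4L])
}

#' Construct a rigid transform
#' @param rotation 3x3 orthonormal matrix, det +1 within 1e-6.
#' @param translation numeric(3), mm.
#' @return list with \code{rotation} and \code{translation}.
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be orthonormal with determinant +1")
  list(rotation = rotation, translation = as.numeric(translation))
}

# ---- resampling -------------------------------------------------------------

#' Resample a volume onto a reference grid under a rigid transform
#'
#' Pulls intensities of \code{moving} onto each voxel center of
#' \code{reference}: a world point x on the reference grid is looked up at
#' the moving-grid location \code{R^-1 (x - t)} (the transform maps moving
#' world coordinates to reference world coordinates). Out-of-field voxels are
#' filled with \code{background} (CT: -1000 HU; MR/PET: 0).
#'
#' @param moving an \linkS4class{ImageVolume} (or \linkS4class{GTVMask}).
#' @param reference a \linkS4class{GridSpec}.
#' @param transform a rigid transform from \code{rigidTransform()}; identity
#'   by default (inputs already co-registered).
#' @param interpolation "trilinear" or "nearest". Masks require "nearest".
#' @param background fill value outside the moving field of view; default
#'   -1000 for CT, 0 otherwise.
#' @return resampled \linkS4class{ImageVolume} or \linkS4class{GTVMask} on
#'   \code{reference}.
#' @export
resampleToGrid <- function(moving, reference, transform = rigidTransform(),
                           interpolation = c("trilinear", "nearest"),
                           background = NULL) {
  interpolation <- match.arg(interpolation)
  isMask <- is(moving, "GTVMask")
  if (isMask && interpolation != "nearest")
    stop("masks must be resampled with nearest-neighbor interpolation")
  if (is.null(background))
    background <- if (isMask) 0 else if (identical(moving@modality, "CT")) -1000 else 0
  arr <- if (isMask) array(as.double(moving@data), dim = dim(moving@data)) else moving@data
  g <- moving@grid

  sh <- reference@shape
  i <- seq_len(sh[1L]) - 1
  j <- seq_len(sh[2L]) - 1
  k <- seq_len(sh[3L]) - 1
  # world coordinates of every reference voxel center
  W <- cbind(
    rep(reference@origin[1L] + i * reference@spacing[1L], times = sh[2L] * sh[3L]),
    rep(rep(reference@origin[2L] + j * reference@spacing[2L], each = sh[1L]),
        times = sh[3L]),
    rep(reference@origin[3L] + k * reference@spacing[3L], each = sh[1L] * sh[2L])
  )
  # map into moving world, then continuous 0-based moving index
  Rinv <- t(transform$rotation)
  M <- sweep(W, 2L, transform$translation) %*% t(Rinv)
  Fidx <- sweep(sweep(M, 2L, g@origin), 2L, g@spacing, "/")

  out <- interpolateVolume(arr, Fidx, interpolation, background)
  dim(out) <- sh
  if (isMask) gtvMask(array(out >= 0.5, dim = sh), reference)
  else imageVolume(out, reference, moving@modality)
}

# trilinear / nearest sampling at continuous 0-based indices (n x 3)
interpolateVolume <- function(arr, Fidx, interpolation, background) {
  d <- dim(arr)
  if (interpolation == "nearest") {
    ii <- round(Fidx[, 1L]); jj <- round(Fidx[, 2L]); kk <- round(Fidx[, 3L])
    ok <- ii >= 0 & ii <= d[1L] - 1 & jj >= 0 & jj <= d[2L] - 1 &
      kk >= 0 & kk <= d[3L] - 1
    out <- rep(background, nrow(Fidx))
    lin <- 1 + ii[ok] + d[1L] * (jj[ok] + d[2L] * kk[ok])
    out[ok] <- arr[lin]
    return(out)
  }
  # clamp points within a hair of the grid boundary onto it, so exact
  # boundary samples (identity resample) interpolate instead of filling
  clamp <- function(f, n) pmin(pmax(f, 0), n - 1)
  inb <- Fidx[, 1L] >= -1e-9 & Fidx[, 1L] <= d[1L] - 1 + 1e-9 &
    Fidx[, 2L] >= -1e-9 & Fidx[, 2L] <= d[2L] - 1 + 1e-9 &
    Fidx[, 3L] >= -1e-9 & Fidx[, 3L] <= d[3L] - 1 + 1e-9
  cx <- clamp(Fidx[, 1L], d[1L]); cy <- clamp(Fidx[, 2L], d[2L])
  cz <- clamp(Fidx[, 3L], d[3L])
  i0 <- pmin(floor(cx), d[1L] - 2); j0 <- pmin(floor(cy), d[2L] - 2)
  k0 <- pmin(floor(cz), d[3L] - 2)
  fx <- cx - i0; fy <- cy - j0; fz <- cz - k0
  ok <- inb

  out <- rep(background, nrow(Fidx))
  if (!any(ok)) return(out)
  i0 <- i0[ok]; j0 <- j0[ok]; k0 <- k0[ok]
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  base <- 1 + i0 + d[1L] * (j0 + d[2L] * k0)
  sx <- 1; sy <- d[1L]; sz <- d[1L] * d[2L]
  v000 <- arr[base];            v100 <- arr[base + sx]
  v010 <- arr[base + sy];       v110 <- arr[base + sx + sy]
  v001 <- arr[base + sz];       v101 <- arr[base + sx + sz]
  v011 <- arr[base + sy + sz];  v111 <- arr[base + sx + sy + sz]
  out[ok] <-
    v000 * (1 - fx) * (1 - fy) * (1 - fz) + v100 * fx * (1 - fy) * (1 - fz) +
    v010 * (1 - fx) * fy * (1 - fz)       + v110 * fx * fy * (1 - fz) +
    v001 * (1 - fx) * (1 - fy) * fz       + v101 * fx * (1 - fy) * fz +
    v011 * (1 - fx) * fy * fz             + v111 * fx * fy * fz
  out
}

# ---- windowing --------------------------------------------------------------

#' Window specification (level/width)
#'
#' Maps the intensity interval [level - width/2, level + width/2] affinely
#' onto [0, 1], clipping outside. Defaults per modality: CT bone
#' (level 600, width 2800 HU; CT brain 40/80 also common), MR and PET use a
#' robust percentile window (1st-99th percentile of nonzero voxels) since
#' their units are not standardized.
#'
#' @param level window center, modality units.
#' @param width window width, must be > 0.
#' @return list with \code{level} and \code{width}.
#' @export
windowSpec <- function(level, width) {
  if (!is.finite(width) || width <= 0) stop("window width must be > 0")
  list(level = as.numeric(level), width = as.numeric(width))
}

#' Default window for a modality
#' @param vol an \linkS4class{ImageVolume} (used for percentile windows).
#' @param modality "CT" (bone), "CT_brain", "MR" or "PET"; defaults to the
#'   volume's own modality tag.
#' @return a window from \code{windowSpec()}.
#' @export
defaultWindow <- function(vol, modality = vol@modality) {
  switch(modality,
    CT = windowSpec(600, 2800),
    CT_brain = windowSpec(40, 80),
    {
      v <- vol@data[vol@data != 0]
      if (!length(v)) v <- as.vector(vol@data)
      q <- stats::quantile(v, c(0.01, 0.99), names = FALSE)
      if (q[2L] <= q[1L]) q[2L] <- q[1L] + 1
      windowSpec(mean(q), diff(q))
    })
}

#' Window-normalize a volume to [0, 1]
#'
#' @param vol an \linkS4class{ImageVolume}.
#' @param window a \code{windowSpec()}; default chosen per modality via
#'   \code{defaultWindow()}.
#' @return an \linkS4class{ImageVolume} with values in [0, 1].
#' @export
windowNormalize <- function(vol, window = defaultWindow(vol)) {
  if (window$width <= 0) stop("window width must be > 0")
  lo <- window$level - window$width / 2
  out <- (vol@data - lo) / window$width
  out[out < 0] <- 0
  out[out > 1] <- 1
  imageVolume(out, vol@grid, vol@modality)
}

# ---- mask volume ------------------------------------------------------------

#' Volume of a binary mask in cm^3
#'
#' Number of true voxels times the voxel volume (product of spacings, mm^3),
#' converted to cm^3.
#'
#' @param mask a \linkS4class{GTVMask}.
#' @return volume in cm^3.
#' @export
maskVolume <- function(mask) {
  sum(mask@data) * prod(mask@grid@spacing) / 1000
}
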