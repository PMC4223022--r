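#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib trifuse, .registration = TRUE
NULL

#' GridSpec: geometry of an axis-aligned voxel grid
#'
#' Defines a finite, axis-aligned sampling grid by voxel counts, per-axis
#' voxel size (mm) and the world position (mm) of the center of voxel
#' (1,1,1). Two volumes on identical \code{GridSpec}s are voxelwise
#' comparable; the world coordinate of 0-based index \code{i} is
#' \code{origin + i * spacing} (voxel-center convention, right-handed axes).
#'
#' @slot shape integer(3), voxel counts per axis.
#' @slot spacing numeric(3), strictly positive voxel size in mm.
#' @slot origin numeric(3), world coordinate in mm of the first voxel center.
#' @export
setClass("GridSpec",
  representation(shape = "integer", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@shape) != 3L || any(object@shape < 1L))
      msg <- c(msg, "shape must be three positive voxel counts")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be three strictly positive values (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be three finite values (mm)")
    if (is.null(msg)) TRUE else msg
  }
)

#' ImageVolume: a 3D scalar image with grid geometry
#'
#' Holds one modality's 3D scalar data (HU for CT, arbitrary units for MR,
#' activity/SUV for PET, or [0,1] after window normalization) together with
#' its \linkS4class{GridSpec}.
#'
#' @slot data 3D numeric array; dimensions must equal \code{grid@shape}.
#' @slot grid a \linkS4class{GridSpec}.
#' @slot modality character tag ("CT", "MR", "PET", "fused", ...).
#' @export
setClass("ImageVolume",
  representation(data = "array", grid = "GridSpec", modality = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3D array")
    else if (!identical(as.integer(dim(object@data)), object@grid@shape))
      msg <- c(msg, "data dimensions must match grid shape")
    if (length(object@modality) != 1L)
      msg <- c(msg, "modality must be a single string")
    if (is.null(msg)) TRUE else msg
  }
)

#' GTVMask: a binary delineation volume
#'
#' One observer's gross tumor volume (GTV) delineation as a boolean voxel
#' mask on the primary (CT) grid.
#'
#' @slot data 3D logical array; dimensions must equal \code{grid@shape}.
#' @slot grid a \linkS4class{GridSpec}.
#' @export
setClass("GTVMask",
  representation(data = "array", grid = "GridSpec"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@data)) != 3L || !is.logical(object@data))
      msg <- c(msg, "data must be a 3D logical array")
    else if (!identical(as.integer(dim(object@data)), object@grid@shape))
      msg <- c(msg, "data dimensions must match grid shape")
    if (is.null(msg)) TRUE else msg
  }
)

#' MaskSet: an ordered, labelled collection of masks on one grid
#'
#' @slot masks list of \linkS4class{GTVMask}, all sharing one grid.
#' @slot labels unique character labels (observer / scheme identifiers).
#' @export
setClass("MaskSet",
  representation(masks = "list", labels = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@masks) != length(object@labels))
      msg <- c(msg, "one label per mask required")
    if (anyDuplicated(object@labels))
      msg <- c(msg, "labels must be unique")
    if (!all(vapply(object@masks, is, logical(1), "GTVMask")))
      msg <- c(msg, "masks must all be GTVMask objects")
    else if (length(object@masks) > 1L) {
      g <- object@masks[[1L]]@grid
      same <- vapply(object@masks, function(m) sameGrid(m@grid, g), logical(1))
      if (!all(same)) msg <- c(msg, "all masks must share one grid")
    }
    if (is.null(msg)) TRUE else msg
  }
)

#' TriangleMesh: a triangle surface in world coordinates
#'
#' Vertices and outward vertex normals are in world mm; per-vertex scalar
#' attributes (e.g. \code{"sd_local"} in cm) ride along in \code{attributes}.
#'
#' @slot vertices n x 3 numeric matrix, world mm.
#' @slot faces m x 3 integer matrix of 1-based vertex indices.
#' @slot normals n x 3 numeric matrix of outward unit vertex normals.
#' @slot attributes named list of length-n numeric vectors.
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix", normals = "matrix",
                 attributes = "list"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be n x 3")
    if (ncol(object@faces) != 3L) msg <- c(msg, "faces must be m x 3")
    if (nrow(object@faces) > 0L) {
      idx <- range(object@faces)
      if (idx[1L] < 1L || idx[2L] > nrow(object@vertices))
        msg <- c(msg, "faces index out of vertex range")
    }
    if (nrow(object@normals) > 0L &&
        !identical(dim(object@normals), dim(object@vertices)))
      msg <- c(msg, "normals must match vertices in shape")
    bad <- vapply(object@attributes,
                  function(a) length(a) != nrow(object@vertices), logical(1))
    if (any(bad)) msg <- c(msg, "attributes must have one value per vertex")
    if (is.null(msg)) TRUE else msg
  }
)

setMethod("show", "GridSpec", function(object) {
  cat("GridSpec:", paste(object@shape, collapse = " x "),
      "voxels @", paste(signif(object@spacing, 4), collapse = " x "),
      "mm, origin (", paste(signif(object@origin, 4), collapse = ", "), ") mm\n")
})

setMethod("show", "ImageVolume", function(object) {
  cat("ImageVolume [", object@modality, "] ",
      paste(dim(object@data), collapse = " x "),
      ", range [", signif(min(object@data), 4), ", ",
      signif(max(object@data), 4), "]\n", sep = "")
  show(object@grid)
})

setMethod("show", "GTVMask", function(object) {
  cat("GTVMask:", sum(object@data), "of", length(object@data),
      "voxels set (", signif(maskVolume(object), 4), "cm^3 )\n")
  show(object@grid)
})

setMethod("show", "MaskSet", function(object) {
  cat("MaskSet of", length(object@masks), "masks:",
      paste(object@labels, collapse = ", "), "\n")
})

setMethod("show", "TriangleMesh", function(object) {
  cat("TriangleMesh:", nrow(object@vertices), "vertices,",
      nrow(object@faces), "faces")
  if (length(object@attributes))
    cat("; attributes:", paste(names(object@attributes), collapse = ", "))
  cat("\n")
})

#' @describeIn GridSpec-class constructor.
#' @param shape,spacing,origin see slots.
#' @export
gridSpec <- function(shape, spacing, origin = c(0, 0, 0)) {
  new("GridSpec", shape = as.integer(shape), spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' @describeIn ImageVolume-class constructor.
#' @param data,grid,modality see slots.
#' @export
imageVolume <- function(data, grid, modality = "unknown") {
  storage.mode(data) <- "double"
  new("ImageVolume", data = data, grid = grid, modality = modality)
}

#' @describeIn GTVMask-class constructor; numeric input is thresholded at 0.5.
#' @param data,grid see slots.
#' @export
gtvMask <- function(data, grid) {
  if (!is.logical(data)) {
    d <- array(data >= 0.5, dim = dim(data))
    data <- d
  }
  new("GTVMask", data = data, grid = grid)
}

#' @describeIn MaskSet-class constructor.
#' @param masks,labels see slots.
#' @export
maskSet <- function(masks, labels = NULL) {
  if (is.null(labels)) {
    labels <- names(masks)
    if (is.null(labels)) labels <- paste0("obs", seq_along(masks))
  }
  new("MaskSet", masks = unname(masks), labels = labels)
}

#' @describeIn TriangleMesh-class constructor; normals recomputed when absent.
#' @param vertices,faces,normals,attributes see slots.
#' @export
triangleMesh <- function(vertices, faces, normals = NULL, attributes = list()) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  if (is.null(normals)) normals <- vertexNormals(vertices, faces)
  new("TriangleMesh", vertices = vertices, faces = faces, normals = normals,
      attributes = attributes)
}

# grid equality up to tolerance; used for voxelwise-comparability checks
sameGrid <- function(a, b, tol = 1e-6) {
  identical(a@shape, b@shape) &&
    all(abs(a@spacing - b@spacing) < tol) &&
    all(abs(a@origin - b@origin) < tol)
}

#' Test whether two grids are voxelwise comparable
#' @param a,b \linkS4class{GridSpec} objects.
#' @param tol numeric tolerance on spacing/origin (mm).
#' @return logical.
#' @export
gridsIdentical <- function(a, b, tol = 1e-6) sameGrid(a, b, tol)
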