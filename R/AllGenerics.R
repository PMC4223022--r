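#' @include AllClasses.R
NULL

#' Accessors for grid geometry and voxel data
#'
#' @param x an \linkS4class{ImageVolume}, \linkS4class{GTVMask} or
#'   \linkS4class{GridSpec}.
#' @return \code{gridOf}: the \linkS4class{GridSpec}; \code{voxelSpacing},
#'   \code{voxelOrigin}: numeric(3) in mm; \code{gridShape}: integer(3);
#'   \code{voxelData}: the underlying array.
#' @name grid-accessors
NULL

#' @rdname grid-accessors
#' @export
setGeneric("gridOf", function(x) standardGeneric("gridOf"))
#' @rdname grid-accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname grid-accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname grid-accessors
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))
#' @rdname grid-accessors
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

setMethod("gridOf", "ImageVolume", function(x) x@grid)
setMethod("gridOf", "GTVMask", function(x) x@grid)
setMethod("gridOf", "MaskSet", function(x) x@masks[[1L]]@grid)
setMethod("voxelData", "ImageVolume", function(x) x@data)
setMethod("voxelData", "GTVMask", function(x) x@data)
setMethod("voxelSpacing", "GridSpec", function(x) x@spacing)
setMethod("voxelSpacing", "ImageVolume", function(x) x@grid@spacing)
setMethod("voxelSpacing", "GTVMask", function(x) x@grid@spacing)
setMethod("voxelOrigin", "GridSpec", function(x) x@origin)
setMethod("voxelOrigin", "ImageVolume", function(x) x@grid@origin)
setMethod("voxelOrigin", "GTVMask", function(x) x@grid@origin)
setMethod("gridShape", "GridSpec", function(x) x@shape)
setMethod("gridShape", "ImageVolume", function(x) x@grid@shape)
setMethod("gridShape", "GTVMask", function(x) x@grid@shape)

#' Mesh accessors
#'
#' @param x a \linkS4class{TriangleMesh}.
#' @param name attribute name for \code{meshAttribute}.
#' @return vertex/normal matrices in world mm, 1-based face index matrix, or
#'   the named per-vertex attribute vector.
#' @name mesh-accessors
NULL

#' @rdname mesh-accessors
#' @export
meshVertices <- function(x) x@vertices
#' @rdname mesh-accessors
#' @export
meshFaces <- function(x) x@faces
#' @rdname mesh-accessors
#' @export
meshNormals <- function(x) x@normals
#' @rdname mesh-accessors
#' @export
meshAttribute <- function(x, name) x@attributes[[name]]

#' Labels of a MaskSet
#' @param x a \linkS4class{MaskSet}.
#' @return character vector of observer/scheme labels.
#' @export
maskLabels <- function(x) x@labels

#' Extract one mask from a MaskSet
#' @param x a \linkS4class{MaskSet}.
#' @param i index or label.
#' @return a \linkS4class{GTVMask}.
#' @export
getMask <- function(x, i) {
  if (is.character(i)) i <- match(i, x@labels)
  x@masks[[i]]
}

#' Number of masks in a MaskSet
#' @param x a \linkS4class{MaskSet}.
#' @export
setMethod("length", "MaskSet", function(x) length(x@masks))
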