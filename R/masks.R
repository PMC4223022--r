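#' @include AllClasses.R
NULL

checkSameGrid <- function(a, b) {
  if (!sameGrid(a@grid, b@grid))
    stop("masks are on different grids; resample first")
}

#' Boolean algebra on GTV masks
#'
#' Voxelwise set operations implementing the volume-combination steps of the
#' tri-modality delineation protocol: the overlap of the dual-modality GTV
#' and the PET GTV is the common GTV; parts of either exclusive region may
#' then be added back after clinical re-evaluation.
#'
#' @param a,b \linkS4class{GTVMask}s on one grid.
#' @return a \linkS4class{GTVMask}.
#' @name mask-algebra
NULL

#' @rdname mask-algebra
#' @export
maskIntersect <- function(a, b) {
  checkSameGrid(a, b)
  gtvMask(a@data & b@data, a@grid)
}

#' @rdname mask-algebra
#' @export
maskUnion <- function(a, b) {
  checkSameGrid(a, b)
  gtvMask(a@data | b@data, a@grid)
}

#' @rdname mask-algebra
#' @export
maskSubtract <- function(a, b) {
  checkSameGrid(a, b)
  gtvMask(a@data & !b@data, a@grid)
}

#' Compose the final tri-modality GTV
#'
#' Final GTV = (dual-modality GTV intersected with PET GTV) plus the parts of
#' each exclusive region the observer chose to keep. The kept parts are
#' inputs (clinical judgment), constrained to lie inside their respective
#' exclusive regions.
#'
#' @param gtvMrict dual-modality (MRI/CT) GTV mask.
#' @param gtvPet PET GTV mask.
#' @param keepFromMrict kept part of \code{gtvMrict - gtvPet}; empty by
#'   default.
#' @param keepFromPet kept part of \code{gtvPet - gtvMrict}; empty by
#'   default.
#' @return final \linkS4class{GTVMask}; always contains the common GTV and
#'   is contained in the union.
#' @export
composeFinalGtv <- function(gtvMrict, gtvPet,
                            keepFromMrict = NULL, keepFromPet = NULL) {
  checkSameGrid(gtvMrict, gtvPet)
  common <- maskIntersect(gtvMrict, gtvPet)
  out <- common@data
  if (!is.null(keepFromMrict)) {
    checkSameGrid(gtvMrict, keepFromMrict)
    excl <- gtvMrict@data & !gtvPet@data
    if (any(keepFromMrict@data & !excl))
      stop("keepFromMrict must lie inside gtvMrict minus gtvPet")
    out <- out | keepFromMrict@data
  }
  if (!is.null(keepFromPet)) {
    checkSameGrid(gtvPet, keepFromPet)
    excl <- gtvPet@data & !gtvMrict@data
    if (any(keepFromPet@data & !excl))
      stop("keepFromPet must lie inside gtvPet minus gtvMrict")
    out <- out | keepFromPet@data
  }
  gtvMask(out, gtvMrict@grid)
}
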