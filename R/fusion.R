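#' @include AllClasses.R
NULL

#' Transparency pair for PET/MR layers
#'
#' Both factors live in [0, 1]. Following the figure-panel convention of the
#' compositing model, t = 1 fully shows the layer (an opacity-like weight):
#' (0, 0) displays pure CT, (0, 1) pure MR, (1, anything) pure PET.
#'
#' @param tP PET transparency factor in [0, 1].
#' @param tM MR transparency factor in [0, 1].
#' @return list with \code{tP}, \code{tM}.
#' @export
transparencyPair <- function(tP, tM) {
  if (!is.finite(tP) || tP < 0 || tP > 1 || !is.finite(tM) || tM < 0 || tM > 1)
    stop("transparency factors must lie in [0, 1]")
  list(tP = as.numeric(tP), tM = as.numeric(tM))
}

#' Fuse co-registered, normalized CT/MR/PET volumes
#'
#' Back-to-front alpha compositing with CT as the opaque background and MR
#' then PET as semi-transparent foreground layers:
#' \deqn{I_{mix} = t_P I_{PET} + (1 - t_P)[ t_M I_{MR} + (1 - t_M) I_{CT} ]}
#' The three weights \eqn{t_P}, \eqn{(1-t_P)t_M}, \eqn{(1-t_P)(1-t_M)} are
#' nonnegative and sum to 1, so the output is a voxelwise convex combination
#' of the inputs and stays in [0, 1] for inputs in [0, 1].
#'
#' @param ct,mr,pet \linkS4class{ImageVolume}s on one grid with intensities
#'   in [0, 1] (see \code{\link{windowNormalize}}).
#' @param t a \code{\link{transparencyPair}}.
#' @return fused \linkS4class{ImageVolume} (modality "fused").
#' @export
fuseVolumes <- function(ct, mr, pet, t) {
  if (!sameGrid(ct@grid, mr@grid) || !sameGrid(ct@grid, pet@grid))
    stop("fusion requires all three volumes on an identical grid")
  rng <- range(ct@data, mr@data, pet@data)
  if (rng[1L] < -1e-9 || rng[2L] > 1 + 1e-9)
    stop("fusion inputs must be window-normalized to [0, 1]")
  t <- transparencyPair(t$tP, t$tM)
  mix <- t$tP * pet@data +
    (1 - t$tP) * (t$tM * mr@data + (1 - t$tM) * ct@data)
  imageVolume(mix, ct@grid, "fused")
}

#' Fused 2D slice for preview/export
#'
#' Equals the corresponding slice of \code{\link{fuseVolumes}}; computed
#' slicewise so single panels can be exported cheaply.
#'
#' @inheritParams fuseVolumes
#' @param axis slice axis, 1, 2 or 3.
#' @param index 1-based slice index along \code{axis}.
#' @return 2D numeric matrix in [0, 1].
#' @export
fuseSlice <- function(ct, mr, pet, t, axis, index) {
  if (!axis %in% 1:3) stop("axis must be 1, 2 or 3")
  sh <- ct@grid@shape
  if (index < 1L || index > sh[axis]) stop("slice index out of range")
  pick <- function(v) switch(axis,
                             v@data[index, , ], v@data[, index, ],
                             v@data[, , index])
  t <- transparencyPair(t$tP, t$tM)
  t$tP * pick(pet) + (1 - t$tP) * (t$tM * pick(mr) + (1 - t$tM) * pick(ct))
}

#' Convex compositing weights for a transparency pair
#'
#' @param t a \code{\link{transparencyPair}}.
#' @return numeric(3): weights on (PET, MR, CT); nonnegative, sum 1.
#' @export
fusionWeights <- function(t) {
  c(PET = t$tP, MR = (1 - t$tP) * t$tM, CT = (1 - t$tP) * (1 - t$tM))
}
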