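#' @include AllClasses.R
NULL

# run expr with a temporary RNG state so generators are seeded and pure
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specification of a synthetic tri-modality head phantom
#'
#' Describes a head-sized scene: a soft-tissue head sphere with a bony skull
#' shell on CT, a brain with a contrast-enhanced lesion rim on MR, and focal
#' lesion uptake over a uniform brain background on PET, plus an ellipsoidal
#' lesion whose exact digitization is the ground-truth GTV.
#'
#' @param shape voxel counts, default 128^3.
#' @param spacingMm voxel size in mm, default 2 mm isotropic.
#' @param lesionCenterMm lesion center in world mm; default grid center.
#' @param lesionRadiiMm ellipsoid semi-axes in mm, default (20, 16, 18).
#' @param ctHu HU levels: background (air), head soft tissue, skull shell,
#'   lesion.
#' @param skullThicknessMm skull shell thickness, mm.
#' @param mrLevels MR arbitrary units: brain and lesion core; rim intensity
#'   is \code{rimFactor * brain}.
#' @param rimFactor MR lesion-rim enhancement factor (>= 1).
#' @param rimThicknessMm MR rim thickness inside the lesion boundary, mm.
#' @param petUptakeRatio lesion-to-background PET uptake ratio (>= 1).
#' @param noiseSd additive Gaussian noise SD per modality (CT HU, MR a.u.,
#'   PET relative units).
#' @param seed integer seed; all phantom randomness derives from it.
#' @return validated spec list for \code{\link{generatePhantom}}.
#' @export
phantomSpec <- function(shape = c(128L, 128L, 128L), spacingMm = c(2, 2, 2),
                        lesionCenterMm = NULL,
                        lesionRadiiMm = c(20, 16, 18),
                        ctHu = c(background = -1000, tissue = 40,
                                 skull = 1000, lesion = 60),
                        skullThicknessMm = 6,
                        mrLevels = c(brain = 400, lesionCore = 300),
                        rimFactor = 2, rimThicknessMm = 3,
                        petUptakeRatio = 4,
                        noiseSd = c(ct = 5, mr = 10, pet = 0.05),
                        seed = 1L) {
  shape <- as.integer(shape)
  extent <- shape * spacingMm
  if (is.null(lesionCenterMm)) lesionCenterMm <- extent / 2
  if (any(lesionRadiiMm <= 0)) stop("lesion radii must be positive")
  if (petUptakeRatio < 1) stop("PET uptake ratio must be >= 1")
  if (any(lesionCenterMm - lesionRadiiMm < 0) ||
      any(lesionCenterMm + lesionRadiiMm > extent))
    stop("lesion must lie strictly inside the grid")
  list(shape = shape, spacingMm = as.numeric(spacingMm),
       lesionCenterMm = as.numeric(lesionCenterMm),
       lesionRadiiMm = as.numeric(lesionRadiiMm), ctHu = ctHu,
       skullThicknessMm = skullThicknessMm, mrLevels = mrLevels,
       rimFactor = rimFactor, rimThicknessMm = rimThicknessMm,
       petUptakeRatio = petUptakeRatio, noiseSd = noiseSd,
       seed = as.integer(seed))
}

#' Generate a synthetic tri-modality phantom
#'
#' Deterministic given the spec's seed. The truth mask is the exact
#' digitization of the lesion ellipsoid (voxel centers inside); with zero
#' noise the maximum PET value inside the lesion is exactly
#' \code{petUptakeRatio} times the brain background.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return list with \code{ct}, \code{mr}, \code{pet}
#'   (\linkS4class{ImageVolume}s) and \code{truth} (\linkS4class{GTVMask}),
#'   all on one grid whose first voxel center sits at world (0,0,0) mm.
#' @export
generatePhantom <- function(spec) {
  g <- gridSpec(spec$shape, spec$spacingMm, c(0, 0, 0))
  sh <- spec$shape
  x <- (seq_len(sh[1L]) - 1) * spec$spacingMm[1L]
  y <- (seq_len(sh[2L]) - 1) * spec$spacingMm[2L]
  z <- (seq_len(sh[3L]) - 1) * spec$spacingMm[3L]
  extent <- sh * spec$spacingMm
  headC <- extent / 2
  headR <- 0.42 * min(extent)

  X <- array(rep(x, times = sh[2L] * sh[3L]), dim = sh)
  Y <- array(rep(rep(y, each = sh[1L]), times = sh[3L]), dim = sh)
  Z <- array(rep(z, each = sh[1L] * sh[2L]), dim = sh)

  rHead <- sqrt((X - headC[1L])^2 + (Y - headC[2L])^2 + (Z - headC[3L])^2)
  inHead <- rHead <= headR
  inSkull <- inHead & rHead > headR - spec$skullThicknessMm

  # ellipsoid radial coordinate (1 on the lesion boundary)
  rho <- sqrt(((X - spec$lesionCenterMm[1L]) / spec$lesionRadiiMm[1L])^2 +
              ((Y - spec$lesionCenterMm[2L]) / spec$lesionRadiiMm[2L])^2 +
              ((Z - spec$lesionCenterMm[3L]) / spec$lesionRadiiMm[3L])^2)
  inLesion <- rho <= 1
  # rim: inside the boundary within rimThickness (scaled by mean radius)
  rimRho <- 1 - spec$rimThicknessMm / mean(spec$lesionRadiiMm)
  inRim <- inLesion & rho > rimRho

  ct <- array(spec$ctHu[["background"]], dim = sh)
  ct[inHead] <- spec$ctHu[["tissue"]]
  ct[inSkull] <- spec$ctHu[["skull"]]
  ct[inLesion] <- spec$ctHu[["lesion"]]

  mr <- array(0, dim = sh)
  mr[inHead & !inSkull] <- spec$mrLevels[["brain"]]
  mr[inLesion] <- spec$mrLevels[["lesionCore"]]
  mr[inRim] <- spec$rimFactor * spec$mrLevels[["brain"]]

  pet <- array(0, dim = sh)
  pet[inHead & !inSkull] <- 1
  pet[inLesion] <- spec$petUptakeRatio

  withSeed(spec$seed, {
    if (spec$noiseSd[["ct"]] > 0)
      ct <- ct + array(stats::rnorm(length(ct), 0, spec$noiseSd[["ct"]]),
                       dim = sh)
    if (spec$noiseSd[["mr"]] > 0)
      mr <- mr + array(stats::rnorm(length(mr), 0, spec$noiseSd[["mr"]]),
                       dim = sh)
    if (spec$noiseSd[["pet"]] > 0)
      pet <- pet + array(stats::rnorm(length(pet), 0, spec$noiseSd[["pet"]]),
                         dim = sh)
  })

  list(ct = imageVolume(ct, g, "CT"), mr = imageVolume(mr, g, "MR"),
       pet = imageVolume(pet, g, "PET"), truth = gtvMask(inLesion, g))
}

#' Specification of simulated observer delineations
#'
#' Each observer's contour is the truth surface displaced outward/inward by
#' a smooth random radial field plus a per-observer systematic margin, then
#' re-digitized. Radial fields are band-limited real spherical-harmonic
#' expansions with i.i.d. Gaussian coefficients scaled so the pointwise SD
#' of the displacement equals \code{radialSdMm} in expectation. All
#' randomness derives from \code{seed} via per-observer sub-seeds
#' (\code{seed + observer index}).
#'
#' @param nObservers number of observers (>= 1).
#' @param radialSdMm pointwise SD of the random radial displacement, mm.
#' @param lmax spherical-harmonic band limit (smoothness; low = smoother).
#' @param marginMm systematic margin per observer, mm (recycled).
#' @param seed integer seed.
#' @return validated spec list for \code{\link{simulateObservers}}.
#' @export
observerSpec <- function(nObservers = 3L, radialSdMm = 2, lmax = 4L,
                         marginMm = 0, seed = 1L) {
  if (nObservers < 1L) stop("need at least one observer")
  if (radialSdMm < 0) stop("radial SD must be >= 0")
  list(nObservers = as.integer(nObservers), radialSdMm = radialSdMm,
       lmax = as.integer(lmax),
       marginMm = rep_len(marginMm, nObservers), seed = as.integer(seed))
}

#' Simulate multi-observer delineations of a truth mask
#'
#' Computes the signed Euclidean distance to the truth boundary (negative
#' inside; half-voxel digitization correction applied) and keeps each voxel
#' whose signed distance does not exceed the observer's radial displacement
#' field (evaluated in the voxel's direction from the truth centroid) plus
#' the systematic margin. With zero SD and zero margin every observer equals
#' the truth exactly.
#'
#' @param truth a nonempty \linkS4class{GTVMask}.
#' @param spec an \code{\link{observerSpec}}.
#' @return a \linkS4class{MaskSet} labelled obs1..obsN.
#' @export
simulateObservers <- function(truth, spec) {
  if (!any(truth@data)) stop("truth mask is empty")
  g <- truth@grid
  d <- signedDistanceMm(truth)
  cen <- maskCentroid(truth)
  s <- mean(g@spacing)

  maxShift <- 5 * spec$radialSdMm + max(abs(spec$marginMm)) + 2 * s
  band <- which(abs(d) <= maxShift)
  idx <- arrayInd(band, dim(truth@data)) - 1L
  W <- sweep(sweep(idx, 2L, g@spacing, "*"), 2L, g@origin, "+")
  U <- sweep(W, 2L, cen)
  len <- sqrt(rowSums(U^2))
  len[len == 0] <- 1
  U <- U / len

  masks <- vector("list", spec$nObservers)
  for (i in seq_len(spec$nObservers)) {
    f <- withSeed(spec$seed + i, {
      coef <- drawShCoefficients(spec$lmax, spec$radialSdMm)
      evalShField(U, coef, spec$lmax)
    })
    shift <- f + spec$marginMm[i]
    m <- truth@data
    m[band] <- d[band] <= shift
    if (!any(m))
      stop("perturbation emptied an observer mask; reduce radialSdMm")
    masks[[i]] <- gtvMask(m, g)
  }
  maskSet(masks, paste0("obs", seq_len(spec$nObservers)))
}

#' Signed distance to a mask boundary (mm)
#'
#' Exact Euclidean distance transform of voxel centers (Felzenszwalb lower
#' envelope, anisotropic spacing), signed negative inside the mask. A
#' quarter-voxel offset compensates the digitization bias of measuring
#' center-to-center distances against a continuous boundary, so that
#' thresholding the signed distance at a margin m reproduces the analytic
#' dilation/erosion radius without systematic drift in either direction.
#'
#' @param mask a \linkS4class{GTVMask}.
#' @return numeric array of signed distances in mm (negative inside).
#' @export
signedDistanceMm <- function(mask) {
  dimv <- dim(mask@data)
  sp <- mask@grid@spacing
  dOut <- sqrt(.cpp_edt_sq(as.logical(mask@data), as.integer(dimv), sp))
  dIn <- sqrt(.cpp_edt_sq(as.logical(!mask@data), as.integer(dimv), sp))
  h <- mean(sp) / 4
  out <- array(0, dim = dimv)
  inside <- mask@data
  out[inside] <- -(dIn[inside] - h)
  out[!inside] <- dOut[!inside] - h
  out
}

# ---- real spherical harmonics ----------------------------------------------

# coefficients a_lm ~ N(0, c) with c = sigma^2 * 4*pi / sum_l (2l+1):
# by the addition theorem sum_m Y_lm(u)^2 = (2l+1)/(4pi), so the pointwise
# variance of the field is sigma^2 everywhere on the sphere.
drawShCoefficients <- function(lmax, sigma) {
  ncoef <- (lmax + 1L)^2
  cvar <- sigma^2 * 4 * pi / ((lmax + 1L)^2) # sum_l (2l+1) = (lmax+1)^2
  stats::rnorm(ncoef, 0, sqrt(cvar))
}

# evaluate the real spherical-harmonic expansion at unit directions U (n x 3)
evalShField <- function(U, coef, lmax) {
  ct <- pmin(1, pmax(-1, U[, 3L]))
  phi <- atan2(U[, 2L], U[, 1L])
  st <- sqrt(pmax(0, 1 - ct^2))
  n <- nrow(U)
  out <- numeric(n)
  k <- 0L
  for (l in 0:lmax) {
    P <- legendreAssoc(l, ct, st) # list over m = 0..l
    for (m in (-l):l) {
      k <- k + 1L
      am <- abs(m)
      K <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      Yl <- if (m == 0) K * P[[1L]]
      else if (m > 0) sqrt(2) * K * cos(m * phi) * P[[am + 1L]]
      else sqrt(2) * K * sin(am * phi) * P[[am + 1L]]
      out <- out + coef[k] * Yl
    }
  }
  out
}

# associated Legendre P_l^m(cos theta) for m = 0..l (no Condon-Shortley
# phase issues matter here; standard recurrence, stable for small l)
legendreAssoc <- function(l, ct, st) {
  P <- vector("list", l + 1L)
  # P_m^m by upward m recurrence
  pmm <- rep(1, length(ct))
  for (m in 0:l) {
    P[[m + 1L]] <- pmm
    if (m < l) {
      # fill l index upward for this m below; store P_m^m first
    }
    pmm <- pmm * (2 * m + 1) * st
  }
  # P[[m+1]] currently holds P_m^m; raise degree from m to l
  for (m in 0:l) {
    if (l == m) next
    pm1 <- P[[m + 1L]]                  # P_m^m
    pm2 <- ct * (2 * m + 1) * pm1       # P_{m+1}^m
    if (l == m + 1L) {
      P[[m + 1L]] <- pm2
    } else {
      for (ll in (m + 2L):l) {
        pnew <- ((2 * ll - 1) * ct * pm2 - (ll + m - 1) * pm1) / (ll - m)
        pm1 <- pm2
        pm2 <- pnew
      }
      P[[m + 1L]] <- pm2
    }
  }
  P
}
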