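#' @include AllClasses.R
NULL

#' Coefficient of variation (sample-SD convention)
#'
#' COV = sample standard deviation (n-1 denominator) divided by the mean.
#' The n-1 convention is the one that reproduces published per-patient GTV
#' volume COVs after 2-decimal rounding; the population (n) convention does
#' not (see the bundled study tables).
#'
#' @param values numeric vector, length >= 2 (e.g. volumes in cm^3).
#' @return list with \code{values}, \code{mean}, \code{sd}, \code{cov} and
#'   \code{undefined} (TRUE when the mean is zero, in which case \code{cov}
#'   is NA rather than an error).
#' @export
covReport <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("COV needs at least two values")
  m <- mean(values)
  s <- stats::sd(values)
  if (m == 0)
    return(list(values = values, mean = m, sd = s, cov = NA_real_,
                undefined = TRUE))
  list(values = values, mean = m, sd = s, cov = s / m, undefined = FALSE)
}

#' Paired two-tailed t-test
#'
#' Classic paired t on d = a - b with a 95 percent confidence interval.
#' Zero-variance differences are reported as a degenerate result (no t or
#' p), never as spurious significance.
#'
#' @param a,b numeric vectors of equal length n >= 2.
#' @param conf.level confidence level for the interval.
#' @return list with \code{n}, \code{meanDifference}, \code{t}, \code{df},
#'   \code{p}, \code{conf.int}, \code{degenerate}.
#' @export
pairedTTest <- function(a, b, conf.level = 0.95) {
  if (length(a) != length(b)) stop("paired test needs equal-length vectors")
  if (length(a) < 2L) stop("paired test needs at least two pairs")
  d <- as.numeric(a) - as.numeric(b)
  if (stats::sd(d) == 0)
    return(list(n = length(d), meanDifference = mean(d), t = NA_real_,
                df = length(d) - 1L, p = NA_real_,
                conf.int = c(mean(d), mean(d)), degenerate = TRUE))
  tt <- stats::t.test(a, b, paired = TRUE, conf.level = conf.level)
  list(n = length(d), meanDifference = unname(tt$estimate),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, conf.int = as.numeric(tt$conf.int),
       degenerate = FALSE)
}

#' Coverage-probability volume of a mask set
#'
#' A voxel is kept when the fraction of masks containing it is at least
#' \code{threshold} (ties kept: with three observers the 50 percent volume
#' is the majority vote; with four, voxels in exactly two masks stay in).
#' At threshold approaching 0 this is the union, at 1 the intersection.
#'
#' @param masks a \linkS4class{MaskSet} with >= 2 masks on one grid.
#' @param threshold coverage fraction in (0, 1].
#' @return a \linkS4class{GTVMask}.
#' @export
coverageVolume <- function(masks, threshold = 0.5) {
  if (length(masks) < 2L) stop("coverage needs at least two masks")
  g <- gridOf(masks)
  counts <- Reduce(`+`, lapply(masks@masks,
                               function(m) array(as.integer(m@data),
                                                 dim = dim(m@data))))
  gtvMask(counts / length(masks) >= threshold - 1e-12, g)
}

#' Median surface of observer delineations
#'
#' Iso-surface of the 50 percent coverage-probability volume: every point of
#' the median surface is covered by at least half of the observers.
#'
#' @param masks a \linkS4class{MaskSet}.
#' @return a \linkS4class{TriangleMesh} with outward vertex normals.
#' @export
medianSurface <- function(masks) {
  cov50 <- coverageVolume(masks, 0.5)
  if (!any(cov50@data)) stop("median coverage volume is empty")
  extractSurface(cov50)
}

#' Signed perpendicular distances from median-surface vertices to a surface
#'
#' For each vertex of \code{mesh}, the bidirectional ray along the outward
#' unit normal is intersected with \code{target}; the intersection of
#' smallest absolute ray parameter within \code{capMm} gives the signed
#' distance (positive when the target surface lies on the outward side,
#' i.e. the target is locally larger). Vertices whose rays miss within the
#' cap fall back to the unsigned nearest-point distance signed by an
#' inside/outside parity test, and are flagged.
#'
#' @param mesh query \linkS4class{TriangleMesh} (e.g. the median surface).
#' @param target target \linkS4class{TriangleMesh} (one observer's surface).
#' @param capMm maximum normal-ray search distance in mm (default 50).
#' @return list with \code{distanceCm} (signed, cm), \code{fallback}
#'   (logical per vertex) and \code{fallbackRate}.
#' @export
signedNormalDistance <- function(mesh, target, capMm = 50) {
  if (capMm <= 0) stop("distance cap must be positive")
  n <- mesh@normals
  if (any(rowSums(n^2) < 0.5)) stop("mesh has degenerate vertex normals")
  res <- .cpp_signed_normal_dist(mesh@vertices, n, target@vertices,
                                 target@faces, capMm)
  list(distanceCm = res$distance / 10, fallback = res$fallback,
       fallbackRate = mean(res$fallback))
}

#' Per-vertex local standard deviation of surface distances (SD_local)
#'
#' For every vertex of the median surface, the sample SD (n-1) of the signed
#' perpendicular distances to each observer surface. Identical observers
#' give SD_local = 0 everywhere; concentric shells displaced by -d, 0, +d
#' give SD_local = d at every vertex.
#'
#' @param medianMesh the \linkS4class{TriangleMesh} from
#'   \code{\link{medianSurface}}.
#' @param observerMeshes list of >= 2 observer \linkS4class{TriangleMesh}es.
#' @param capMm normal-ray search cap in mm.
#' @param signed use signed distances (default); \code{FALSE} takes absolute
#'   values before the SD.
#' @return list with \code{mesh} (median mesh carrying attribute
#'   \code{"sd_local"} in cm), \code{distancesCm} (vertex x observer
#'   matrix), \code{sdLocalCm}, \code{fallbackRate}.
#' @export
sdLocal <- function(medianMesh, observerMeshes, capMm = 50, signed = TRUE) {
  if (length(observerMeshes) < 2L)
    stop("SD_local needs at least two observer surfaces")
  res <- lapply(observerMeshes, function(om)
    signedNormalDistance(medianMesh, om, capMm))
  D <- vapply(res, `[[`, numeric(nrow(medianMesh@vertices)), "distanceCm")
  if (!signed) D <- abs(D)
  sdv <- apply(D, 1L, stats::sd)
  mesh <- medianMesh
  mesh@attributes[["sd_local"]] <- sdv
  list(mesh = mesh, distancesCm = D, sdLocalCm = sdv,
       fallbackRate = mean(vapply(res, `[[`, numeric(1), "fallbackRate")))
}

#' Octant labels for median-surface vertices
#'
#' Labels each vertex by the octant of a coordinate system whose origin is
#' the mean of the observer-mask centroids and whose axes are the world
#' axes. Declared convention:
#' \code{label = 1 + (x < Ox) + 2*(y < Oy) + 4*(z < Oz)}; coordinates
#' exactly equal to the origin on an axis go to the ">=" side, so a vertex
#' with all coordinates >= the origin gets label 1.
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param masks the \linkS4class{MaskSet} of observer masks.
#' @return integer vector of labels in 1..8, one per vertex.
#' @export
octantLabels <- function(mesh, masks) {
  cents <- vapply(masks@masks, maskCentroid, numeric(3))
  O <- rowMeans(cents)
  V <- mesh@vertices
  1L + (V[, 1L] < O[1L]) + 2L * (V[, 2L] < O[2L]) + 4L * (V[, 3L] < O[3L])
}

#' Aggregate SD_local over octants and overall
#'
#' Unweighted vertex means of SD_local per octant plus the overall mean over
#' all vertices (regardless of octant occupancy; empty octants report NA).
#'
#' @param sdLocalCm per-vertex SD_local, cm.
#' @param labels octant labels from \code{\link{octantLabels}}.
#' @return list with \code{octantMeanCm} (numeric(8), NA for empty octants)
#'   and \code{overallMeanCm}.
#' @export
aggregateSdLocal <- function(sdLocalCm, labels) {
  oct <- vapply(1:8, function(k) {
    v <- sdLocalCm[labels == k]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  list(octantMeanCm = oct, overallMeanCm = mean(sdLocalCm))
}

#' Full inter-observer variation report for one structure
#'
#' Runs the complete shape pipeline for one patient/scheme: observer
#' surfaces, ADSC per observer with mean/SD, median surface, SD_local with
#' octant aggregation, and the volume COV.
#'
#' @param masks a \linkS4class{MaskSet} of observer delineations.
#' @param capMm normal-ray cap in mm for SD_local.
#' @return list with \code{volumesCm3}, \code{volumeCov} (a
#'   \code{\link{covReport}}), \code{adscCm} (per observer),
#'   \code{adscMeanCm}, \code{adscSdCm}, \code{medianMesh} (with
#'   \code{"sd_local"} attribute), \code{sdLocal} (octant + overall means,
#'   cm) and \code{fallbackRate}.
#' @export
structureVariation <- function(masks, capMm = 50) {
  vols <- vapply(masks@masks, maskVolume, numeric(1))
  names(vols) <- masks@labels
  meshes <- lapply(masks@masks, extractSurface)
  adscs <- vapply(seq_along(meshes), function(i)
    adsc(meshes[[i]], maskCentroid(masks@masks[[i]])), numeric(1))
  names(adscs) <- masks@labels
  med <- medianSurface(masks)
  sdl <- sdLocal(med, meshes, capMm = capMm)
  labs <- octantLabels(sdl$mesh, masks)
  agg <- aggregateSdLocal(sdl$sdLocalCm, labs)
  list(volumesCm3 = vols, volumeCov = covReport(vols),
       adscCm = adscs, adscMeanCm = mean(adscs), adscSdCm = stats::sd(adscs),
       medianMesh = sdl$mesh, octantLabels = labs, sdLocal = agg,
       fallbackRate = sdl$fallbackRate)
}

#' Tabulated variation report across patients and schemes
#'
#' Assembles the published-table style outputs from per-observer scalars:
#' per patient and scheme the observer values, mean, SD and COV, plus paired
#' two-tailed t-tests between the two schemes.
#'
#' @param values data.frame with columns \code{patient}, \code{scheme},
#'   \code{observer}, \code{value} (volumes in cm^3 or ADSC in cm).
#' @param statistic "cov" (volume COV per patient/scheme) or "meanSd" (ADSC
#'   style mean and SD per patient/scheme).
#' @return list with \code{table} (data.frame: one row per patient x scheme
#'   with observer values, mean, sd and cov) and \code{pairedTests} (one
#'   paired test per scheme pair on the per-patient summary statistic).
#' @export
variationReport <- function(values, statistic = c("cov", "meanSd")) {
  statistic <- match.arg(statistic)
  need <- c("patient", "scheme", "observer", "value")
  if (!all(need %in% names(values)))
    stop("values needs columns: ", paste(need, collapse = ", "))
  rows <- list()
  for (p in unique(values$patient)) {
    for (s in unique(values$scheme)) {
      v <- values$value[values$patient == p & values$scheme == s]
      obs <- values$observer[values$patient == p & values$scheme == s]
      if (!length(v)) next
      if (length(v) < 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          patient = p, scheme = s, n = length(v), mean = mean(v),
          sd = NA_real_, cov = NA_real_, computable = FALSE)
        next
      }
      cr <- covReport(v)
      rows[[length(rows) + 1L]] <- data.frame(
        patient = p, scheme = s, n = length(v), mean = cr$mean, sd = cr$sd,
        cov = cr$cov, computable = TRUE)
    }
  }
  tab <- do.call(rbind, rows)
  schemes <- unique(values$scheme)
  tests <- list()
  if (length(schemes) == 2L) {
    stat <- if (statistic == "cov") "cov" else "sd"
    a <- tab[[stat]][tab$scheme == schemes[1L]]
    b <- tab[[stat]][tab$scheme == schemes[2L]]
    if (length(a) == length(b) && length(a) >= 2L &&
        !anyNA(a) && !anyNA(b))
      tests[[paste(schemes, collapse = " vs ")]] <- pairedTTest(a, b)
  }
  list(table = tab, pairedTests = tests)
}

#' Write a variation table to CSV
#' @param report result of \code{\link{variationReport}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeVariationCsv <- function(report, path) {
  utils::write.csv(report$table, path, row.names = FALSE)
  invisible(path)
}
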