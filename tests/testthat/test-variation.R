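test_that("COV uses the sample-SD convention and reproduces known values", {
  expect_equal(round(covReport(c(19.91, 22.72, 20.47))$cov, 2), 0.07)
  expect_equal(round(covReport(c(2.96, 2.92, 1.82))$cov, 2), 0.25)
  expect_equal(covReport(c(5, 5, 5))$cov, 0)
  r <- covReport(c(2, 4, 6))
  expect_equal(r$mean, 4)
  expect_equal(r$sd, sd(c(2, 4, 6)))
  expect_error(covReport(3), "two values")
  z <- covReport(c(-1, 1))
  expect_true(z$undefined)
  expect_true(is.na(z$cov))
})

test_that("the population-SD variant fails a known COV (convention check)", {
  v <- c(19.91, 22.72, 20.47)
  covN <- sqrt(mean((v - mean(v))^2)) / mean(v)
  expect_equal(round(covN, 2), 0.06) # not the published 0.07
  expect_equal(round(covReport(v)$cov, 2), 0.07)
})

test_that("paired t matches hand computation and flags degeneracy", {
  # d = (1,2,3): t = 2 / (1/sqrt(3)) = 3.4641, df 2
  r <- pairedTTest(c(1, 2, 3), c(0, 0, 0))
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(r$df, 2)
  expect_equal(r$meanDifference, 2)
  # p and CI against the closed form
  expect_equal(r$p, 2 * pt(-abs(r$t), 2), tolerance = 1e-12)
  se <- sd(c(1, 2, 3)) / sqrt(3)
  expect_equal(r$conf.int, 2 + c(-1, 1) * qt(0.975, 2) * se,
               tolerance = 1e-10)
  expect_equal(mean(r$conf.int), r$meanDifference) # CI symmetric
  deg <- pairedTTest(c(1, 2, 3), c(1, 2, 3))
  expect_true(deg$degenerate)
  expect_equal(deg$meanDifference, 0)
  expect_true(is.na(deg$p))
  expect_error(pairedTTest(1:3, 1:2), "equal-length")
})

test_that("coverage keeps voxels seen by at least the threshold fraction", {
  g <- gridSpec(c(4, 4, 4), c(1, 1, 1))
  mk <- function(idx) {
    a <- array(FALSE, c(4, 4, 4))
    a[idx] <- TRUE
    gtvMask(a, g)
  }
  # voxel 1: all three; voxel 2: two of three; voxel 3: one of three
  ms3 <- maskSet(list(mk(c(1, 2, 3)), mk(c(1, 2)), mk(1)))
  cov50 <- voxelData(coverageVolume(ms3, 0.5))
  expect_true(cov50[1] && cov50[2])
  expect_false(cov50[3])
  # N = 4: a voxel in exactly 2 of 4 masks sits on the 50% tie and stays
  ms4 <- maskSet(list(mk(c(1, 2)), mk(c(1, 2)), mk(1), mk(1)))
  expect_true(voxelData(coverageVolume(ms4, 0.5))[2])
  # identical masks reproduce themselves at any threshold
  m <- randomMask(0.4, seed = 3)
  msI <- maskSet(list(m, m, m))
  expect_identical(voxelData(coverageVolume(msI, 0.5)), voxelData(m))
  expect_error(coverageVolume(maskSet(list(m))), "two masks")
})

test_that("coverage is monotone in threshold with union/intersection limits", {
  ms <- maskSet(lapply(1:3, function(s) randomMask(0.4, seed = s)))
  u <- Reduce(maskUnion, ms@masks)
  i <- Reduce(maskIntersect, ms@masks)
  expect_identical(voxelData(coverageVolume(ms, 1e-9)), voxelData(u))
  expect_identical(voxelData(coverageVolume(ms, 1)), voxelData(i))
  prev <- voxelData(coverageVolume(ms, 1e-9))
  for (th in c(1 / 3, 0.5, 2 / 3, 1)) {
    cur <- voxelData(coverageVolume(ms, th))
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("median surface of concentric spheres is the middle sphere", {
  ms <- maskSet(list(sphereMask(8, 40L), sphereMask(10, 40L),
                     sphereMask(12, 40L)))
  med <- medianSurface(ms)
  mid <- extractSurface(sphereMask(10, 40L))
  expect_equal(meshVertices(med), meshVertices(mid))
  expect_lt(abs(meshVolume(med) / (4 / 3 * pi * 1) - 1), 0.05)
  # identical masks: median mesh is the individual mesh
  msI <- maskSet(list(sphereMask(9, 36L), sphereMask(9, 36L),
                      sphereMask(9, 36L)))
  expect_equal(meshVertices(medianSurface(msI)),
               meshVertices(extractSurface(sphereMask(9, 36L))))
})

test_that("majority vote picks the overlap region of shifted blocks", {
  g <- gridSpec(c(24, 24, 24), c(1, 1, 1))
  mk <- function(off) {
    a <- array(FALSE, c(24, 24, 24))
    a[off + 1:8, 5 + 1:8, 5 + 1:8] <- TRUE
    gtvMask(a, g)
  }
  # blocks at x offsets 4, 8 and 8: majority = voxels in >= 2 masks
  ms <- maskSet(list(mk(4), mk(8), mk(8)))
  cov <- coverageVolume(ms, 0.5)
  expect_equal(sum(voxelData(cov)), 8 * 8 * 8) # the two aligned blocks
  expect_identical(voxelData(cov), voxelData(mk(8)))
})

test_that("signed distances to concentric spheres have the right magnitude and sign", {
  med <- extractSurface(sphereMask(10, 40L))
  outer <- extractSurface(sphereMask(12, 40L))
  inner <- extractSurface(sphereMask(8, 40L))
  dOut <- signedNormalDistance(med, outer)
  dIn <- signedNormalDistance(med, inner)
  expect_equal(mean(dOut$distanceCm), 0.2, tolerance = 0.05)
  expect_equal(mean(dIn$distanceCm), -0.2, tolerance = 0.05)
  expect_true(all(dOut$distanceCm > 0))
  expect_true(all(dIn$distanceCm < 0))
  # self-distance is numerically zero
  dSelf <- signedNormalDistance(med, med)
  expect_lt(max(abs(dSelf$distanceCm)), 1e-7)
})

test_that("SD_local recovers the closed-form SD on concentric shells", {
  ms <- maskSet(list(sphereMask(8, 40L), sphereMask(10, 40L),
                     sphereMask(12, 40L)))
  med <- medianSurface(ms)
  meshes <- lapply(ms@masks, extractSurface)
  sdl <- sdLocal(med, meshes)
  # distances per vertex ~ (-2, 0, +2) mm -> SD = 2 mm = 0.2 cm
  expect_lt(abs(mean(sdl$sdLocalCm) / 0.2 - 1), 0.1)
  expect_true(all(sdl$sdLocalCm >= 0))
  expect_identical(meshAttribute(sdl$mesh, "sd_local"), sdl$sdLocalCm)
})

test_that("identical observers give SD_local identically zero", {
  msI <- maskSet(lapply(1:3, function(i) sphereMask(9, 32L)))
  med <- medianSurface(msI)
  sdl <- sdLocal(med, lapply(msI@masks, extractSurface))
  expect_equal(max(sdl$sdLocalCm), 0)
  expect_error(sdLocal(med, list(extractSurface(sphereMask(9, 32L)))),
               "two observer")
})

test_that("SD_local is invariant under a common rigid motion of all masks", {
  base <- lapply(c(7, 9, 11), function(r) sphereMask(r, 36L))
  ms <- maskSet(base)
  sdl0 <- sdLocal(medianSurface(ms), lapply(base, extractSurface))
  # translate every mask by the same world offset (shift the grid origin)
  shift <- c(14, -6, 3)
  moved <- lapply(base, function(m)
    gtvMask(voxelData(m), gridSpec(gridShape(m), voxelSpacing(m),
                                   voxelOrigin(m) + shift)))
  msM <- maskSet(moved)
  sdlM <- sdLocal(medianSurface(msM), lapply(moved, extractSurface))
  expect_equal(sdlM$sdLocalCm, sdl0$sdLocalCm, tolerance = 1e-10)
})

test_that("octant labels follow the declared convention and partition", {
  ms <- maskSet(list(sphereMask(8, 40L), sphereMask(10, 40L),
                     sphereMask(12, 40L)))
  med <- medianSurface(ms)
  labs <- octantLabels(med, ms)
  expect_true(all(labs %in% 1:8))
  expect_equal(length(labs), nrow(meshVertices(med)))
  # convention anchor: all coordinates >= origin -> label 1
  O <- rowMeans(vapply(ms@masks, maskCentroid, numeric(3)))
  V <- meshVertices(med)
  allGe <- V[, 1] >= O[1] & V[, 2] >= O[2] & V[, 3] >= O[3]
  expect_true(all(labs[allGe] == 1L))
  # near-symmetry: each octant holds about 1/8 of the vertices
  frac <- as.vector(table(factor(labs, levels = 1:8))) / length(labs)
  expect_true(all(abs(frac - 1 / 8) < 0.05))
})

test_that("octant aggregation averages per region and overall", {
  labs <- rep(1:8, each = 10L)
  expect_equal(aggregateSdLocal(rep(0.3, 80), labs)$octantMeanCm, rep(0.3, 8))
  expect_equal(aggregateSdLocal(rep(0.3, 80), labs)$overallMeanCm, 0.3)
  # overall mean equals the vertex-count-weighted mean of octant means
  set.seed(21)
  sdv <- runif(80)
  labs2 <- sample(1:8, 80, replace = TRUE)
  agg <- aggregateSdLocal(sdv, labs2)
  counts <- as.vector(table(factor(labs2, levels = 1:8)))
  expect_equal(agg$overallMeanCm,
               sum(agg$octantMeanCm * counts, na.rm = TRUE) / sum(counts))
  # empty octants flagged NA, overall still over all vertices
  labs3 <- rep(1L, 80)
  agg3 <- aggregateSdLocal(sdv, labs3)
  expect_true(all(is.na(agg3$octantMeanCm[2:8])))
  expect_equal(agg3$overallMeanCm, mean(sdv))
})

test_that("variation reports reproduce published table statistics", {
  vols <- studyTable("volumes")
  names(vols)[names(vols) == "volume_cm3"] <- "value"
  rep <- variationReport(vols, statistic = "cov")
  tab <- rep$table
  dual <- tab[tab$scheme == "dual", ]
  tri <- tab[tab$scheme == "tri", ]
  expect_equal(round(dual$cov[order(dual$patient)], 2), c(0.07, 0.11, 0.25))
  expect_equal(round(tri$cov[order(tri$patient)], 2), c(0.06, 0.06, 0.08))
  adscTab <- studyTable("adsc")
  names(adscTab)[names(adscTab) == "adsc_cm"] <- "value"
  repA <- variationReport(adscTab, statistic = "meanSd")
  t1 <- repA$table[repA$table$patient == 1 & repA$table$scheme == "dual", ]
  expect_equal(round(t1$mean, 2), 1.81)
  expect_equal(round(t1$sd, 2), 0.05)
  # single observer rows are flagged not computable
  solo <- data.frame(patient = 1, scheme = "dual", observer = 1, value = 5)
  repS <- variationReport(solo)
  expect_false(repS$table$computable)
  expect_true(is.na(repS$table$cov))
})

test_that("full structure variation pipeline runs and is coherent", {
  ms <- maskSet(list(sphereMask(8, 36L), sphereMask(10, 36L),
                     sphereMask(12, 36L)))
  res <- structureVariation(ms)
  expect_equal(unname(res$volumesCm3),
               vapply(ms@masks, maskVolume, numeric(1)))
  expect_equal(res$volumeCov$cov,
               sd(res$volumesCm3) / mean(res$volumesCm3))
  expect_equal(res$adscMeanCm, mean(res$adscCm))
  expect_equal(res$sdLocal$overallMeanCm,
               mean(meshAttribute(res$medianMesh, "sd_local")))
  f <- tempfile(fileext = ".csv")
  writeVariationCsv(list(table = data.frame(a = 1)), f)
  expect_true(file.exists(f))
  unlink(f)
})
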