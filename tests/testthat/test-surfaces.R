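test_that("a single voxel meshes to a small closed solid", {
  g <- gridSpec(c(5, 5, 5), c(1, 1, 1))
  a <- array(FALSE, c(5, 5, 5))
  a[3, 3, 3] <- TRUE
  mesh <- extractSurface(gtvMask(a, g))
  expect_true(isWatertight(mesh))
  v <- meshVolume(mesh) * 1000 # mm^3
  expect_gt(v, 0.1)
  expect_lt(v, 1.5) # voxel volume is 1 mm^3; iso-surface trims corners
})

test_that("digitized spheres mesh to within 2% of the analytic volume", {
  m <- sphereMask(20, n = 48L, spacingMm = 1)
  mesh <- extractSurface(m)
  expect_true(isWatertight(mesh))
  expect_lt(abs(meshVolume(mesh) / (4 / 3 * pi * 20^3 / 1000) - 1), 0.02)
})

test_that("mesh volume agrees with voxel-count volume on smooth phantoms", {
  for (r in c(10, 15)) {
    m <- sphereMask(r, n = 40L, spacingMm = 1)
    mesh <- extractSurface(m)
    expect_lt(abs(meshVolume(mesh) / maskVolume(m) - 1), 0.05)
  }
})

test_that("surfaces touching the grid boundary still close", {
  g <- gridSpec(c(6, 6, 6), c(1, 1, 1))
  a <- array(TRUE, c(6, 6, 6)) # fills the whole grid
  mesh <- extractSurface(gtvMask(a, g))
  expect_true(isWatertight(mesh))
  expect_gt(meshVolume(mesh), 0)
  expect_error(extractSurface(gtvMask(array(FALSE, c(6, 6, 6)), g)), "empty")
})

test_that("mask centroids obey symmetry and translation equivariance", {
  # symmetric block centered at the world origin
  g <- gridSpec(c(4, 4, 4), c(1, 1, 1), origin = c(-1.5, -1.5, -1.5))
  m <- gtvMask(array(TRUE, c(4, 4, 4)), g)
  expect_equal(maskCentroid(m), c(0, 0, 0))
  # single voxel -> its own center
  a <- array(FALSE, c(5, 5, 5))
  a[2, 3, 4] <- TRUE
  m1 <- gtvMask(a, gridSpec(c(5, 5, 5), c(2, 2, 2), c(0, 0, 0)))
  expect_equal(maskCentroid(m1), c(2, 4, 6))
  # brute-force mean + translation equivariance on a random mask
  m2 <- randomMask(0.3, n = 10L, seed = 9)
  idx <- which(voxelData(m2), arr.ind = TRUE) - 1
  expect_equal(maskCentroid(m2), colMeans(idx), ignore_attr = TRUE)
  shifted <- gtvMask(voxelData(m2), gridSpec(rep(10L, 3), c(1, 1, 1),
                                             c(5, -2, 7)))
  expect_equal(maskCentroid(shifted), maskCentroid(m2) + c(5, -2, 7))
  expect_error(maskCentroid(gtvMask(array(FALSE, c(3, 3, 3)),
                                    gridSpec(c(3, 3, 3), c(1, 1, 1)))),
               "empty")
})

test_that("ADSC of a 1 cm digitized sphere is 1 cm within 1%", {
  m <- sphereMask(10, n = 32L, spacingMm = 1)
  mesh <- extractSurface(m)
  expect_lt(abs(adsc(mesh, maskCentroid(m)) - 1), 0.01)
})

test_that("ADSC matches brute-force enumeration on a hand-built cube mesh", {
  # unit cube [0,10]^3 mm as 12 triangles, centroid at the center
  V <- as.matrix(expand.grid(x = c(0, 10), y = c(0, 10), z = c(0, 10)))
  F <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 10
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 10
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 10
  mesh <- triangleMesh(V, F)
  centroid <- c(5, 5, 5)
  bary <- (V[F[, 1], ] + V[F[, 2], ] + V[F[, 3], ]) / 3
  oracle <- mean(sqrt(rowSums(sweep(bary, 2, centroid)^2))) / 10
  expect_equal(adsc(mesh, centroid), oracle)
  # area weighting changes nothing for congruent triangles
  expect_equal(adsc(mesh, centroid, areaWeighted = TRUE), oracle)
})

test_that("ADSC is rigid-motion invariant and scales linearly", {
  m <- sphereMask(8, n = 28L)
  mesh <- extractSurface(m)
  cen <- maskCentroid(m)
  a0 <- adsc(mesh, cen)
  # common translation of mesh and centroid
  sh <- c(12, -3, 4)
  mesh2 <- triangleMesh(sweep(meshVertices(mesh), 2, sh, "+"),
                        meshFaces(mesh))
  expect_equal(adsc(mesh2, cen + sh), a0)
  # rotation about the centroid
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  Vr <- sweep(sweep(meshVertices(mesh), 2, cen) %*% t(R), 2, cen, "+")
  expect_equal(adsc(triangleMesh(Vr, meshFaces(mesh)), cen), a0)
  # uniform scaling about the centroid
  Vs <- sweep(sweep(meshVertices(mesh), 2, cen) * 2, 2, cen, "+")
  expect_equal(adsc(triangleMesh(Vs, meshFaces(mesh)), cen), 2 * a0,
               tolerance = 1e-12)
  expect_error(adsc(triangleMesh(matrix(0, 0, 3), matrix(0L, 0, 3)), cen),
               "empty")
})

test_that("vertex normals point outward on a sphere", {
  m <- sphereMask(10, n = 32L)
  mesh <- extractSurface(m)
  cen <- maskCentroid(m)
  radial <- sweep(meshVertices(mesh), 2, cen)
  radial <- radial / sqrt(rowSums(radial^2))
  cosang <- rowSums(radial * meshNormals(mesh))
  expect_true(all(cosang > 0.8))
  expect_equal(sqrt(rowSums(meshNormals(mesh)^2)),
               rep(1, nrow(meshVertices(mesh))))
})

test_that("meshes export to parseable PLY and STL", {
  m <- sphereMask(5, n = 18L)
  mesh <- extractSurface(m)
  mesh@attributes[["sd_local"]] <- rep(0.25, nrow(meshVertices(mesh)))
  fp <- tempfile(fileext = ".ply")
  writePly(mesh, fp)
  lines <- readLines(fp)
  expect_equal(grep("element vertex", lines, value = TRUE),
               paste("element vertex", nrow(meshVertices(mesh))))
  expect_true(any(grepl("property float sd_local", lines)))
  nface <- as.integer(sub("element face ", "",
                          grep("element face", lines, value = TRUE)))
  expect_equal(nface, nrow(meshFaces(mesh)))
  fs <- tempfile(fileext = ".stl")
  writeStl(mesh, fs)
  stl <- readLines(fs)
  expect_equal(sum(grepl("^facet normal", stl)), nrow(meshFaces(mesh)))
  expect_equal(stl[1], "solid trifuse")
  unlink(c(fp, fs))
})
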