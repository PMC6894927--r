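test_that("sampled force directions are unit, reproducible and sphere-uniform", {
  d <- sampleForceDirections(1000, seed = 3)
  expect_equal(nrow(d), 1000L)
  expect_lt(max(abs(sqrt(rowSums(d^2)) - 1)), 1e-12)
  expect_identical(d, sampleForceDirections(1000, seed = 3))
  expect_false(identical(d, sampleForceDirections(1000, seed = 4)))
  expect_error(sampleForceDirections(0), ">= 1")

  big <- sampleForceDirections(100000, seed = 5)
  expect_lt(sqrt(sum(colMeans(big)^2)), 0.02)
  # z component uniform on [-1, 1] for a uniform sphere distribution
  ks <- suppressWarnings(stats::ks.test(big[, 3], "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("shoulder features are the stacked selected displacements", {
  s <- makeC4Structure(nResPerChain = 80, resStart = 401, seed = 2)
  m <- buildANM(s)
  shoulder <- residueSelection(446:465)
  r <- lrtResponse(m, makeC4Perturbation(m, 425, c(0, 0, 1)))
  feat <- shoulderFeatures(r, s, shoulder)
  expect_length(feat, 240L)  # 20 residues x 4 chains x 3 components

  idx <- resolveSelection(s, shoulder)
  expect_equal(feat, as.vector(t(displacements(r)[idx, ])))

  zero <- new("ResponseField", displacements = matrix(0, nBeads(s), 3),
              perturbation = r@perturbation, modelRef = "zero")
  expect_equal(shoulderFeatures(zero, s, shoulder), rep(0, 240))

  # linear in the response
  r2 <- lrtResponse(m, makeC4Perturbation(m, 430, c(1, 0, 0)))
  both <- new("ResponseField",
              displacements = displacements(r) + displacements(r2),
              perturbation = r@perturbation, modelRef = "sum")
  expect_equal(shoulderFeatures(both, s, shoulder),
               feat + shoulderFeatures(r2, s, shoulder))
})

test_that("k-means recovers blobs, keeps duplicates together, scans representatives", {
  b <- makeClusterBlobs(k = 4, dim = 5, separation = 10, spread = 1,
                        nPer = 40, seed = 7)
  cl <- kmeansCluster(b$features, 4, nInit = 10, seed = 7)
  expect_equal(ariOracle(clusterLabels(cl), b$labels), 1)
  expect_equal(mclust::adjustedRandIndex(clusterLabels(cl), b$labels), 1)

  # k = 1: withinss is the total sum of squares about the mean
  c1 <- kmeansCluster(b$features, 1, seed = 1)
  expect_equal(c1@withinss,
               sum(sweep(b$features, 2, colMeans(b$features))^2))

  # duplicated points share a label
  dup <- rbind(b$features, b$features)
  cd <- kmeansCluster(dup, 4, seed = 2)
  n <- nrow(b$features)
  expect_identical(clusterLabels(cd)[1:n], clusterLabels(cd)[n + 1:n])

  # representative = exhaustive nearest-to-centroid scan
  for (j in seq_len(cl@k)) {
    members <- which(clusterLabels(cl) == j)
    d2 <- colSums((t(b$features[members, ]) - cl@centroids[j, ])^2)
    expect_equal(cl@representativeIndex[j], members[which.min(d2)])
  }

  expect_error(kmeansCluster(b$features, 1000), "exceeds")
})

test_that("the elbow criterion finds four blobs, one blob, and degenerate data", {
  for (seed in c(1, 5, 9)) {
    b <- makeClusterBlobs(k = 4, dim = 3, separation = 10, spread = 1,
                          nPer = 50, seed = seed)
    sel <- elbowSelectK(b$features, 1:8, seed = seed)
    expect_equal(sel$k, 4L)
    expect_equal(nrow(sel$table), 8L)
    expect_true(all(diff(sel$table$maxWithinss[1:4]) < 0))
  }

  one <- makeClusterBlobs(k = 1, dim = 3, separation = 0, spread = 1,
                          nPer = 150, seed = 3)
  expect_equal(elbowSelectK(one$features, 1:8, seed = 3)$k, 1L)

  ident <- matrix(2, 60, 4)
  sel0 <- elbowSelectK(ident, 1:5, seed = 1)
  expect_equal(sel0$k, 1L)
  expect_true(all(sel0$table$maxWithinss == 0))
})

test_that("domain motion geometry matches constructed displacements", {
  s <- makeC4Structure(nResPerChain = 20, seed = 8)
  sel <- residueSelection(5:15, chains = "A")
  idx <- resolveSelection(s, sel)

  # rigid +5 degree rotation about z as the displacement field
  th <- 5 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  com <- colMeans(coords(s))
  rel <- sweep(coords(s), 2, com)
  disp <- rel %*% t(R) - rel
  pert <- forcePerturbation(1, c(1, 0, 0))
  r <- new("ResponseField", displacements = disp, perturbation = pert,
           modelRef = "rigid rotation")
  mo <- domainMotion(r, s, sel)
  expect_equal(mo$inPlaneRotation, 5, tolerance = 0.1 / 5)
  # for pure in-plane motion the mean displacement lies in the xy plane
  expect_equal(mo$angleToZ, 90, tolerance = 1e-6)

  up <- new("ResponseField",
            displacements = matrix(rep(c(0, 0, 1), nBeads(s)), ncol = 3,
                                   byrow = TRUE),
            perturbation = pert, modelRef = "up")
  expect_equal(domainMotion(up, s, sel)$angleToZ, 0)

  sideways <- new("ResponseField",
                  displacements = matrix(rep(c(1, 0, 0), nBeads(s)), ncol = 3,
                                         byrow = TRUE),
                  perturbation = pert, modelRef = "x")
  expect_equal(domainMotion(sideways, s, sel)$angleToZ, 90)

  zero <- new("ResponseField", displacements = matrix(0, nBeads(s), 3),
              perturbation = pert, modelRef = "zero")
  expect_true(is.na(domainMotion(zero, s, sel)$angleToZ))
})

test_that("a full experiment is reproducible and respects the C4 symmetry", {
  asm <- makeCoupledAssembly(seed = 3)
  m <- buildANM(asm$structure)
  e <- runPerturbationExperiment(m, asm$sites$linker, asm$shoulder,
                                 asm$domains, nSamples = 200, k = 4,
                                 seed = 21)
  expect_length(e$representatives, 4L)
  expect_s4_class(e$cluster, "ClusterResult")
  expect_equal(dim(e$motionVectors), c(4L, 9L))

  # bit-for-bit reproducibility from (structure, config, seed)
  e2 <- runPerturbationExperiment(m, asm$sites$linker, asm$shoulder,
                                  asm$domains, nSamples = 200, k = 4,
                                  seed = 21)
  expect_identical(e$motionVectors, e2$motionVectors)
  expect_identical(clusterLabels(e$cluster), clusterLabels(e2$cluster))

  # symmetry-equivalent per-chain domains move as C4 images of each other
  repResp <- e$representativeResponses[[1]]
  R <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)
  mA <- domainMotion(repResp, asm$structure,
                     residueSelection(440:455, chains = "A"))
  mB <- domainMotion(repResp, asm$structure,
                     residueSelection(440:455, chains = "B"))
  expect_lt(max(abs(as.vector(R %*% mA$meanDisplacement) -
                    mB$meanDisplacement)) /
            max(abs(mA$meanDisplacement)), 1e-6)

  # representative of a singleton cluster is its only member
  feats <- t(vapply(e$representativeResponses,
                    function(r) shoulderFeatures(r, asm$structure,
                                                 asm$shoulder),
                    numeric(3 * 64)))
  cl1 <- kmeansCluster(feats, 4, seed = 1)
  expect_setequal(cl1@representativeIndex, 1:4)
})

test_that("cluster structure is invariant under a common z rotation of the responses", {
  b <- makeClusterBlobs(k = 3, dim = 6, separation = 8, spread = 1,
                        nPer = 30, seed = 4)
  cl <- kmeansCluster(b$features, 3, seed = 9)
  # rotate every consecutive 3-vector of the feature space about z
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  rotFeat <- b$features
  for (blk in seq_len(ncol(b$features) / 3)) {
    cols <- (3 * blk - 2):(3 * blk)
    rotFeat[, cols] <- b$features[, cols] %*% t(R)
  }
  clR <- kmeansCluster(rotFeat, 3, seed = 9)
  expect_equal(sum(clR@withinss), sum(cl@withinss), tolerance = 1e-8)
  expect_equal(ariOracle(clusterLabels(cl), clusterLabels(clR)), 1)
})
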