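dimer <- function(d = 5) {
  cloudStructure(matrix(c(0, 0, 0, d, 0, 0), ncol = 3, byrow = TRUE))
}

test_that("a single spring gives the closed-form Hessian and spectrum", {
  m <- buildANM(dimer(5), cutoff = 13, springModel = uniformSprings(1))
  H <- hessianMatrix(m)
  expect_equal(H[1:3, 4:6], -diag(c(1, 0, 0)))
  expect_equal(sort(modeEigenvalues(m)), c(0, 0, 0, 0, 0, 2),
               tolerance = 1e-12)
  expect_equal(nRigidModes(m), 5L)  # a dimer has 5 rigid modes, not 6
})

test_that("beads beyond the cutoff are unconnected and flagged", {
  expect_warning(m <- buildANM(dimer(14), cutoff = 13), "disconnected")
  expect_equal(hessianMatrix(m), matrix(0, 6, 6))
  expect_equal(modeEigenvalues(m), rep(0, 6))
  expect_error(buildANM(cloudStructure(matrix(0, 1, 3))), "at least 2")
})

test_that("the Hessian matches a brute-force double-loop oracle on random clouds", {
  for (seed in 1:6) {
    n <- 20 + 5 * seed
    xyz <- randomConnectedCloud(n, cutoff = 6, seed = seed)
    m <- buildANM(cloudStructure(xyz), cutoff = 6)
    H <- hessianMatrix(m)
    expect_lt(max(abs(H - bruteHessian(xyz, cutoff = 6))), 1e-10)
    expect_lt(max(abs(H - t(H))), 1e-10 * max(abs(H)))
    # every 3x3 super-row sums to zero (translation invariance)
    rowSumBlocks <- vapply(seq_len(n), function(i) {
      max(abs(Reduce(`+`, lapply(seq_len(n), function(j) {
        H[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)]
      }))))
    }, numeric(1))
    expect_lt(max(rowSumBlocks), 1e-10)
    expect_equal(nRigidModes(m), 6L)
    V <- modeEigenvectors(m)
    expect_lt(max(abs(crossprod(V) - diag(3 * n))), 1e-8)
  }
})

test_that("a pairwise spring table is honoured with fallback", {
  s <- cloudStructure(matrix(c(0, 0, 0, 5, 0, 0, 0, 5, 0), ncol = 3,
                             byrow = TRUE))
  s@residueNames <- c("ALA", "GLY", "ALA")
  tab <- data.frame(resA = "ALA", resB = "GLY", gamma = 3)
  m <- buildANM(s, cutoff = 6, springModel = pairSprings(tab, fallback = 1))
  # ALA1-GLY2 contact: gamma 3; ALA1-ALA3: fallback 1
  expect_equal(hessianMatrix(m)[1:3, 4:6], -3 * diag(c(1, 0, 0)))
  expect_equal(hessianMatrix(m)[1:3, 7:9], -1 * diag(c(0, 1, 0)))
})

test_that("linear response obeys Hooke's law and scales linearly", {
  m <- buildANM(dimer(5), cutoff = 13)
  pull <- forcePerturbation(c(1, 2),
                            matrix(c(-1, 0, 0, 1, 0, 0), ncol = 3,
                                   byrow = TRUE),
                            magnitude = 2)
  u <- displacements(lrtResponse(m, pull))
  # relative extension f / gamma along the bond, zero transverse
  expect_equal(u[2, 1] - u[1, 1], 2)
  expect_equal(u[, 2:3], matrix(0, 2, 2))

  half <- forcePerturbation(c(1, 2),
                            matrix(c(-1, 0, 0, 1, 0, 0), ncol = 3,
                                   byrow = TRUE),
                            magnitude = 1)
  expect_equal(2 * displacements(lrtResponse(m, half)), u)
})

test_that("mode-sum response equals the dense pseudo-inverse oracle", {
  for (seed in c(3, 7)) {
    xyz <- randomConnectedCloud(30, cutoff = 6, seed = seed)
    m <- buildANM(cloudStructure(xyz), cutoff = 6)
    set.seed(seed + 100)
    bead <- sample(30, 1)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    resp <- lrtResponse(m, forcePerturbation(bead, dir, magnitude = 1600))
    f <- numeric(90); f[(3 * bead - 2):(3 * bead)] <- 1600 * dir
    expect_lt(max(abs(as.vector(t(displacements(resp))) -
                      pinvResponse(hessianMatrix(m), f))), 1e-8)
  }
})

test_that("the response operator is reciprocal and equivariant", {
  xyz <- randomConnectedCloud(25, cutoff = 6, seed = 11)
  s <- cloudStructure(xyz)
  m <- buildANM(s, cutoff = 6)
  set.seed(12)
  fi <- rnorm(3); fi <- fi / sqrt(sum(fi^2))
  fj <- rnorm(3); fj <- fj / sqrt(sum(fj^2))
  ui <- displacements(lrtResponse(m, forcePerturbation(3, fi, magnitude = 1)))
  uj <- displacements(lrtResponse(m, forcePerturbation(17, fj, magnitude = 1)))
  # f_j . u(i applied, at bead j) == f_i . u(j applied, at bead i)
  expect_equal(sum(fj * ui[17, ]), sum(fi * uj[3, ]), tolerance = 1e-10)

  # force-free input gives the zero field
  zero <- lrtResponse(m, forcePerturbation(1, c(1, 0, 0), magnitude = 0))
  expect_equal(displacements(zero), matrix(0, 25, 3))

  # translation invariance of the structure
  sT <- s; sT@coords <- sweep(xyz, 2, c(10, -4, 2), "+")
  mT <- buildANM(sT, cutoff = 6)
  uT <- displacements(lrtResponse(mT, forcePerturbation(3, fi, magnitude = 1)))
  expect_lt(max(abs(uT - ui)), 1e-8)

  # rotating structure and force together rotates the response
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  sR <- s; sR@coords <- xyz %*% t(R)
  mR <- buildANM(sR, cutoff = 6)
  uR <- displacements(lrtResponse(mR, forcePerturbation(3, as.vector(R %*% fi),
                                                        magnitude = 1)))
  expect_lt(max(abs(uR - ui %*% t(R))), 1e-8)

  expect_error(lrtResponse(m, forcePerturbation(99, c(1, 0, 0))),
               "out of range")
})

test_that("C4 perturbations rotate the base direction around the tetramer", {
  s <- makeC4Structure(nResPerChain = 15, seed = 5)
  m <- buildANM(s)
  p <- makeC4Perturbation(m, 7, c(1, 0, 0), magnitude = 1600)
  dirs <- as.matrix(p@targets[, c("dx", "dy", "dz")])
  expect_equal(dirs,
               matrix(c(1, 0, 0, 0, 1, 0, -1, 0, 0, 0, -1, 0), ncol = 3,
                      byrow = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)
  # each per-chain force has the stated norm
  f <- displacements(lrtResponse(m, p))  # just to ensure it runs
  expect_equal(sqrt(rowSums((1600 * dirs)^2)), rep(1600, 4))

  # beads are taken in z-rotation order around the axis
  az <- atan2(coords(s)[p@targets$bead, 2], coords(s)[p@targets$bead, 1]) %%
    (2 * pi)
  expect_false(is.unsorted(az))

  expect_error(makeC4Perturbation(m, 999, c(1, 0, 0)), "not found")
  s2 <- cloudStructure(randomConnectedCloud(10, seed = 1))
  expect_error(makeC4Perturbation(buildANM(s2, cutoff = 6), 1, c(1, 0, 0)),
               "4 chains")
})

test_that("the response to a C4 force pattern is itself C4 symmetric", {
  s <- makeC4Structure(nResPerChain = 15, seed = 6)
  m <- buildANM(s)
  p <- makeC4Perturbation(m, 8, c(0.6, 0.8, 0), magnitude = 1600)
  u <- displacements(lrtResponse(m, p))
  n <- 15
  R <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)  # Rz(90), column-major
  # chain A beads map onto chain B beads under Rz(90)
  uA <- u[1:n, ] %*% t(R)
  uB <- u[n + 1:n, ]
  expect_lt(max(abs(uA - uB)) / max(abs(u)), 1e-6)
})
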