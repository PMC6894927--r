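#' Sample uniformly distributed force directions on the unit sphere
#'
#' Directions are drawn by normalizing standard trivariate Gaussians, which
#' is exactly uniform on the sphere. Deterministic for a fixed seed; the
#' caller's RNG state is left untouched.
#'
#' @param n number of directions (>= 1).
#' @param seed integer RNG seed.
#' @return n x 3 matrix of unit vectors.
#' @export
sampleForceDirections <- function(n, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  withSeed(seed, {
    m <- matrix(stats::rnorm(3 * n), ncol = 3)
    m / sqrt(rowSums(m^2))
  })
}

#' Construct a force ensemble for a perturbation experiment
#'
#' @param nSamples number of force directions (default 1000).
#' @param magnitude force magnitude in arbitrary units (default 1600).
#' @param seed RNG seed for the directions.
#' @return a [ForceEnsemble-class].
#' @export
forceEnsemble <- function(nSamples = 1000L, magnitude = 1600, seed = 1L) {
  new("ForceEnsemble",
      nSamples = as.integer(nSamples), magnitude = magnitude,
      seed = as.integer(seed),
      directions = sampleForceDirections(nSamples, seed))
}

#' Shoulder feature vector of a response field
#'
#' Concatenates the displacement 3-vectors of the selected beads in the
#' structure's stable bead order: the clustering variable for grouping
#' sampled forces is the displacement of the C-linker shoulder (C'/D'
#' helices, residues 446-465 in the channel numbering), not the raw force
#' direction.
#'
#' @param response a [ResponseField-class].
#' @param structure the [CoarseGrainedStructure-class] the response lives on.
#' @param shoulder a [ResidueSelection-class].
#' @return numeric feature vector of length 3 x (number of selected beads).
#' @export
shoulderFeatures <- function(response, structure, shoulder) {
  idx <- resolveSelection(structure, shoulder)
  asVec3N(displacements(response)[idx, , drop = FALSE])
}

# k-means++ initial centres (Arthur & Vassilvitskii seeding).
kmeansPPInit <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  first <- sample.int(n, 1)
  centers[1, ] <- X[first, ]
  if (k > 1) {
    d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
    for (j in 2:k) {
      if (sum(d2) <= 0) {
        pick <- sample.int(n, 1)
      } else {
        pick <- sample.int(n, 1, prob = d2)
      }
      centers[j, ] <- X[pick, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
    }
  }
  centers
}

#' k-means clustering of feature vectors
#'
#' Lloyd's algorithm (via [stats::kmeans()]) with k-means++ seeding, keeping
#' the best of `nInit` restarts by total within-cluster sum of squares.
#' The representative of each cluster is the sample nearest (Euclidean) to
#' its centroid -- an automated stand-in for picking a force "from the
#' cluster center" by hand.
#'
#' @param features numeric matrix, one row per sample.
#' @param k number of clusters (<= number of samples).
#' @param nInit number of k-means++ restarts.
#' @param seed RNG seed.
#' @return a [ClusterResult-class].
#' @export
kmeansCluster <- function(features, k, nInit = 10L, seed = 1L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (k > n) stop("k (", k, ") exceeds number of samples (", n, ")")
  k <- as.integer(k)

  fit <- withSeed(seed, {
    best <- NULL
    for (r in seq_len(nInit)) {
      init <- kmeansPPInit(features, k)
      # duplicated centres (duplicate data points) would abort kmeans
      if (anyDuplicated(init)) {
        init <- init + stats::rnorm(length(init), sd = 1e-9)
      }
      km <- tryCatch(
        suppressWarnings(
          stats::kmeans(features, centers = init, iter.max = 100L,
                        algorithm = "Lloyd")),
        error = function(e) NULL)
      if (is.null(km) || length(unique(km$cluster)) < k) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })
  if (is.null(fit)) {
    stop("k-means failed to produce ", k, " non-empty clusters; ",
         "the data may have fewer than k distinct points")
  }

  rep <- vapply(seq_len(k), function(j) {
    members <- which(fit$cluster == j)
    d2 <- rowSums(sweep(features[members, , drop = FALSE], 2,
                        fit$centers[j, ])^2)
    members[which.min(d2)]
  }, integer(1))

  new("ClusterResult",
      k = k, labels = as.integer(fit$cluster), centroids = fit$centers,
      withinss = fit$withinss,
      maxWithinssByK = data.frame(k = integer(), maxWithinss = numeric(),
                                  logMaxWithinss = numeric()),
      representativeIndex = rep)
}

#' Elbow selection of the number of clusters
#'
#' For each candidate k the maximal per-cluster within-cluster sum of
#' squares (max withinss) is recorded on a natural-log scale, following the
#' practice of judging cluster number from log(max withinss) versus k. The
#' chosen k is the candidate immediately after the largest drop in
#' log(max withinss), provided that drop is pronounced (at least
#' `minLogDrop` natural-log units, i.e. max withinss falls by a factor of
#' about e); without a pronounced drop -- or for degenerate data with zero
#' scatter -- k = 1 is returned.
#'
#' @param features numeric matrix, one row per sample.
#' @param kCandidates candidate cluster numbers (default 1:8).
#' @param nInit restarts per k.
#' @param seed RNG seed.
#' @param minLogDrop pronouncedness threshold for the elbow (natural-log
#'   units, default 1).
#' @return list with `k` (chosen), `table` (data.frame k, maxWithinss,
#'   logMaxWithinss) and `cluster` (the [ClusterResult-class] at the chosen
#'   k, with the table attached).
#' @export
elbowSelectK <- function(features, kCandidates = 1:8, nInit = 10L, seed = 1L,
                         minLogDrop = 1) {
  features <- as.matrix(features)
  if (length(kCandidates) < 1) stop("kCandidates must be nonempty")
  kCandidates <- sort(unique(as.integer(kCandidates)))
  if (any(kCandidates > nrow(features))) {
    stop("candidate k exceeds number of samples")
  }

  totSS <- sum(sweep(features, 2, colMeans(features))^2)
  if (totSS <= 1e-24) {
    tab <- data.frame(k = kCandidates, maxWithinss = 0,
                      logMaxWithinss = -Inf)
    cl <- kmeansCluster(features, 1L, nInit, seed)
    cl@maxWithinssByK <- tab
    return(list(k = 1L, table = tab, cluster = cl))
  }

  fits <- lapply(seq_along(kCandidates), function(i) {
    kmeansCluster(features, kCandidates[i], nInit, seed + i)
  })
  maxW <- vapply(fits, function(f) max(f@withinss), numeric(1))
  logW <- log(pmax(maxW, .Machine$double.xmin))
  tab <- data.frame(k = kCandidates, maxWithinss = maxW,
                    logMaxWithinss = logW)

  chosen <- 1L
  if (length(kCandidates) > 1) {
    drops <- -diff(logW)
    iBest <- which.max(drops)
    if (drops[iBest] >= minLogDrop) chosen <- kCandidates[iBest + 1L]
  }
  cl <- fits[[match(chosen, kCandidates)]]
  cl@maxWithinssByK <- tab
  list(k = chosen, table = tab, cluster = cl)
}

#' Representative force of a cluster
#'
#' Returns the sampled force whose shoulder feature lies nearest its
#' cluster centroid, rebuilt as the four-fold symmetric perturbation it was
#' applied as.
#'
#' @param cluster a [ClusterResult-class].
#' @param ensemble the [ForceEnsemble-class] that was clustered.
#' @param clusterIndex cluster number in 1..k.
#' @param model the [ANMModel-class] of the experiment.
#' @param residueNumber perturbed residue.
#' @return a [ForcePerturbation-class].
#' @export
representativeForce <- function(cluster, ensemble, clusterIndex, model,
                                residueNumber) {
  if (clusterIndex < 1L || clusterIndex > cluster@k) {
    stop("clusterIndex out of range 1..", cluster@k)
  }
  i <- cluster@representativeIndex[clusterIndex]
  makeC4Perturbation(model, residueNumber, ensemble@directions[i, ],
                     ensemble@magnitude)
}

#' Domain motion descriptors of a response field
#'
#' Summarizes the movement of a domain (a residue selection) as its mean
#' displacement vector, the angle of that vector to the z axis, and the
#' mean in-plane (about-z) rotation. The in-plane rotation of a bead is the
#' signed angle between its radial position projected to the xy plane
#' (about the structure's centre of mass) and that position plus its
#' displacement; positive means counter-clockwise viewed from the
#' extracellular side (looking down the +z axis).
#'
#' @param response a [ResponseField-class].
#' @param structure the [CoarseGrainedStructure-class] the response lives on.
#' @param domain a [ResidueSelection-class].
#' @return list with `meanDisplacement` (3-vector), `angleToZ` (degrees in
#'   [0, 180], NA for a zero mean displacement), `inPlaneRotation`
#'   (degrees, signed) and `domainSize` (bead count).
#' @export
domainMotion <- function(response, structure, domain) {
  idx <- resolveSelection(structure, domain)
  disp <- displacements(response)[idx, , drop = FALSE]
  m <- colMeans(disp)
  nm <- sqrt(sum(m^2))
  angleToZ <- if (nm == 0) NA_real_ else acos(m[3] / nm) * 180 / pi

  com <- colMeans(coords(structure))
  rel <- sweep(coords(structure)[idx, , drop = FALSE], 2, com)
  p <- rel[, 1:2, drop = FALSE]
  q <- p + disp[, 1:2, drop = FALSE]
  ang <- atan2(p[, 1] * q[, 2] - p[, 2] * q[, 1],
               rowSums(p * q)) * 180 / pi
  ok <- rowSums(p^2) > 0 & rowSums(q^2) > 0
  list(meanDisplacement = m, angleToZ = angleToZ,
       inPlaneRotation = mean(ang[ok]), domainSize = length(idx))
}

#' Run a full force-perturbation experiment
#'
#' Samples `nSamples` force directions, applies each as a four-fold
#' symmetric perturbation at `residueNumber`, computes all linear-response
#' fields, clusters them by their shoulder displacements, selects the
#' representative force of each cluster and summarizes the motion of each
#' named domain under each representative response. With a `reference`
#' motion table, the cluster whose stacked domain-motion mean displacements
#' have the highest cosine similarity to the reference is reported.
#'
#' Responses are evaluated through the stored mode decomposition in one
#' matrix product over all samples, so the 1000-force protocol runs in
#' seconds on toy structures.
#'
#' @param model an [ANMModel-class] over a 4-chain structure.
#' @param residueNumber residue at which the four-fold force is applied.
#' @param shoulder [ResidueSelection-class] used for the clustering features.
#' @param domains named list of [ResidueSelection-class] domains to track.
#' @param nSamples number of force directions (default 1000).
#' @param magnitude force strength, a.u. (default 1600).
#' @param k number of clusters (default 4, the channel protocol), or
#'   "auto" for elbow selection over `kCandidates`.
#' @param kCandidates candidate k grid for "auto" (default 1:8).
#' @param seed RNG seed; the whole experiment is reproducible from
#'   (structure, configuration, seed).
#' @param reference optional motions to match: either the `motions` matrix
#'   of another experiment cluster (a named list as returned in
#'   `$motions[[i]]`) or a plain numeric vector of stacked mean
#'   displacements.
#' @return list of class `PerturbationExperiment`: `ensemble`, `cluster`,
#'   `representatives` (list of [ForcePerturbation-class]),
#'   `representativeResponses` (list of [ResponseField-class]),
#'   `motions` (per cluster: named list of [domainMotion()] results),
#'   `motionVectors` (k x (3 x n domains) matrix of stacked mean
#'   displacements), and `bestMatch` (cluster index, cosine) if a reference
#'   was given.
#' @export
runPerturbationExperiment <- function(model, residueNumber, shoulder, domains,
                                      nSamples = 1000L, magnitude = 1600,
                                      k = 4L, kCandidates = 1:8, seed = 1L,
                                      reference = NULL) {
  stopifnot(is(model, "ANMModel"), is(shoulder, "ResidueSelection"))
  structure <- model@structure
  ens <- forceEnsemble(nSamples, magnitude, seed)

  # assemble all C4 force vectors: reuse target beads/ordering once
  proto <- makeC4Perturbation(model, residueNumber, c(1, 0, 0), magnitude)
  beads <- proto@targets$bead   # in azimuthal order
  rot <- lapply(0:3, function(kk) rotationZ(90 * kk))

  vals <- model@eigenValues
  keep <- vals >= RIGID_MODE_TOL * max(vals, 0) & vals > 0
  V <- model@eigenVectors[, keep, drop = FALSE]
  lam <- vals[keep]

  fidx <- as.vector(vapply(beads, function(b) (3 * b - 2):(3 * b),
                           numeric(3)))
  # F: 12 x nSamples force components at the target coordinates
  Fmat <- matrix(0, 12, ens@nSamples)
  for (ci in 1:4) {
    dirs <- ens@directions %*% t(rot[[ci]])   # rows: Rz((ci-1)*90) d
    Fmat[(3 * ci - 2):(3 * ci), ] <- t(dirs) * magnitude
  }
  coef <- crossprod(V[fidx, , drop = FALSE], Fmat) / lam  # modes x samples

  shoulderIdx <- resolveSelection(structure, shoulder)
  sidx <- as.vector(vapply(shoulderIdx, function(b) (3 * b - 2):(3 * b),
                           numeric(3)))
  features <- t(V[sidx, , drop = FALSE] %*% coef)  # samples x (3*|shoulder|)

  elbowTab <- NULL
  if (identical(k, "auto")) {
    sel <- elbowSelectK(features, kCandidates, nInit = 10L, seed = seed + 1L)
    cl <- sel$cluster
    elbowTab <- sel$table
  } else {
    cl <- kmeansCluster(features, as.integer(k), nInit = 10L, seed = seed + 1L)
  }

  reps <- lapply(seq_len(cl@k), function(j) {
    representativeForce(cl, ens, j, model, residueNumber)
  })
  repResp <- lapply(reps, function(p) lrtResponse(model, p))
  motions <- lapply(repResp, function(r) {
    lapply(domains, function(dsel) domainMotion(r, structure, dsel))
  })
  motionVectors <- t(vapply(motions, function(ms) {
    unlist(lapply(ms, `[[`, "meanDisplacement"), use.names = FALSE)
  }, numeric(3L * length(domains))))

  out <- list(
    residueNumber = residueNumber, ensemble = ens, cluster = cl,
    elbowTable = elbowTab, representatives = reps,
    representativeResponses = repResp, motions = motions,
    motionVectors = motionVectors, domains = names(domains), seed = seed
  )

  if (!is.null(reference)) {
    refVec <- if (is.numeric(reference)) reference else {
      unlist(lapply(reference, `[[`, "meanDisplacement"), use.names = FALSE)
    }
    cos <- apply(motionVectors, 1, cosineSimilarity, b = refVec)
    out$bestMatch <- list(cluster = which.max(cos), cosine = max(cos),
                          cosines = cos)
  }
  class(out) <- "PerturbationExperiment"
  out
}

#' @export
print.PerturbationExperiment <- function(x, ...) {
  cat("PerturbationExperiment: residue", x$residueNumber, ";",
      x$ensemble@nSamples, "forces at", x$ensemble@magnitude, "a.u.;",
      x$cluster@k, "clusters\n")
  if (!is.null(x$bestMatch)) {
    cat("  best match: cluster", x$bestMatch$cluster, "cosine",
        signif(x$bestMatch$cosine, 3), "\n")
  }
  invisible(x)
}
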