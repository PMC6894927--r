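#' Uniform spring parameterization
#'
#' @param gamma spring constant (arbitrary units) applied to every contact.
#' @return a [SpringModel-class].
#' @export
uniformSprings <- function(gamma = 1) {
  new("SpringModel", kind = "uniform", gamma = gamma,
      pairTable = data.frame(resA = character(), resB = character(),
                             gamma = numeric()))
}

#' Pairwise-table spring parameterization
#'
#' A heterogeneous parameterization keyed by the residue names of the two
#' contacting beads (order-insensitive). Pairs absent from the table fall
#' back to `fallback`.
#'
#' @param pairTable data.frame with columns resA, resB, gamma (all gamma > 0).
#' @param fallback spring constant used for pairs not in the table.
#' @return a [SpringModel-class].
#' @export
pairSprings <- function(pairTable, fallback = 1) {
  new("SpringModel", kind = "pairwise-table", gamma = fallback,
      pairTable = pairTable)
}

# Spring constant for a residue-name pair under a SpringModel.
springConstant <- function(model, resA, resB) {
  if (model@kind == "uniform") return(rep(model@gamma, length(resA)))
  tab <- model@pairTable
  keyTab <- paste(pmin(tab$resA, tab$resB), pmax(tab$resA, tab$resB))
  key <- paste(pmin(resA, resB), pmax(resA, resB))
  g <- tab$gamma[match(key, keyTab)]
  g[is.na(g)] <- model@gamma
  g
}

# Relative eigenvalue threshold below which a mode counts as rigid.
RIGID_MODE_TOL <- 1e-8

#' Build an anisotropic network model
#'
#' Beads closer than `cutoff` are connected by springs. The off-diagonal
#' 3x3 Hessian block for a contacting pair (i, j) is
#' `-gamma_ij / d_ij^2 * r_ij r_ij^T` (r_ij the inter-bead vector); diagonal
#' blocks are minus the sum of the row's off-diagonal blocks, which makes
#' every 3x3 super-row sum to zero (translation invariance). The full
#' symmetric eigendecomposition is stored; a connected network has exactly
#' 6 rigid (near-zero) modes. More rigid modes trigger a warning with the
#' connected-component count.
#'
#' @param structure a [CoarseGrainedStructure-class] with >= 2 beads.
#' @param cutoff contact distance cutoff in Angstrom (default 13).
#' @param springModel a [SpringModel-class]; default uniform gamma = 1.
#' @return an [ANMModel-class].
#' @export
buildANM <- function(structure, cutoff = 13, springModel = uniformSprings()) {
  stopifnot(is(structure, "CoarseGrainedStructure"))
  if (cutoff <= 0) stop("cutoff must be > 0")
  n <- nBeads(structure)
  if (n < 2L) stop("need at least 2 beads to build an ANM")

  xyz <- coords(structure)
  d <- as.matrix(stats::dist(xyz))
  contact <- d <= cutoff
  diag(contact) <- FALSE

  H <- matrix(0, 3L * n, 3L * n)
  pair <- which(contact & upper.tri(contact), arr.ind = TRUE)
  if (nrow(pair) > 0) {
    g <- springConstant(springModel,
                        residueNames(structure)[pair[, 1]],
                        residueNames(structure)[pair[, 2]])
    for (p in seq_len(nrow(pair))) {
      i <- pair[p, 1]; j <- pair[p, 2]
      rij <- xyz[j, ] - xyz[i, ]
      blk <- -(g[p] / sum(rij^2)) * tcrossprod(rij)
      ri <- (3 * i - 2):(3 * i); rj <- (3 * j - 2):(3 * j)
      H[ri, rj] <- blk
      H[rj, ri] <- blk
      H[ri, ri] <- H[ri, ri] - blk
      H[rj, rj] <- H[rj, rj] - blk
    }
  }

  eig <- eigen(H, symmetric = TRUE)
  vals <- rev(eig$values)
  vecs <- eig$vectors[, rev(seq_len(ncol(eig$vectors))), drop = FALSE]

  maxEv <- max(vals, 0)
  nRigid <- if (maxEv == 0) 3L * n else sum(vals < RIGID_MODE_TOL * maxEv)
  g <- igraph::graph_from_adjacency_matrix(contact, mode = "undirected")
  nComp <- igraph::components(g)$no
  if (nComp > 1L) {
    warning("network is disconnected: ", nComp, " component(s), ",
            nRigid, " rigid modes")
  }

  new("ANMModel",
      structure = structure, cutoff = cutoff, springModel = springModel,
      hessian = H, eigenValues = vals, eigenVectors = vecs,
      nRigidModes = as.integer(nRigid))
}

#' Construct a force perturbation
#'
#' @param beads integer bead indices the force acts on.
#' @param directions matrix of direction vectors (one row per bead), each
#'   normalized to unit length.
#' @param magnitude force magnitude per target, arbitrary units.
#' @param symmetryMode "as-given" or "C4-about-z".
#' @return a [ForcePerturbation-class].
#' @export
forcePerturbation <- function(beads, directions, magnitude = 1600,
                              symmetryMode = "as-given") {
  directions <- matrix(directions, ncol = 3)
  directions <- t(apply(directions, 1, unitVector))
  new("ForcePerturbation",
      targets = data.frame(bead = as.integer(beads),
                           dx = directions[, 1], dy = directions[, 2],
                           dz = directions[, 3]),
      magnitude = magnitude, symmetryMode = symmetryMode)
}

#' Four-fold symmetric force perturbation about the z axis
#'
#' Applies the force simultaneously on all four monomers at the same
#' residue position: one target per chain, with the direction on successive
#' chains rotated by 90 degree increments about z. Chains are taken in
#' z-rotation order, i.e. ordered by the azimuth of the target bead around
#' the structure's centre of mass (the channel's four-fold axis is assumed
#' to be the z axis of the input frame).
#'
#' @param model an [ANMModel-class] whose structure has exactly 4 chains.
#' @param residueNumber author residue number, present in all four chains.
#' @param baseDirection 3-vector; normalized internally. Applied as-is to
#'   the first chain in azimuthal order.
#' @param magnitude force magnitude, arbitrary units (default 1600).
#' @return a [ForcePerturbation-class] with symmetryMode "C4-about-z".
#' @export
makeC4Perturbation <- function(model, residueNumber, baseDirection,
                               magnitude = 1600) {
  stopifnot(is(model, "ANMModel"))
  structure <- model@structure
  chains <- unique(chainIds(structure))
  if (length(chains) != 4L) {
    stop("C4 perturbation requires exactly 4 chains, found ", length(chains))
  }
  beads <- vapply(chains, function(ch) {
    i <- which(chainIds(structure) == ch &
               residueNumbers(structure) == residueNumber)
    if (length(i) != 1L) {
      stop("residue ", residueNumber, " not found in chain ", ch)
    }
    i
  }, integer(1))

  com <- colMeans(coords(structure))
  rel <- sweep(coords(structure)[beads, , drop = FALSE], 2, com)
  azimuth <- atan2(rel[, 2], rel[, 1]) %% (2 * pi)
  ord <- order(azimuth)
  beads <- beads[ord]

  base <- unitVector(baseDirection)
  dirs <- t(vapply(0:3, function(k) as.vector(rotationZ(90 * k) %*% base),
                   numeric(3)))
  forcePerturbation(beads, dirs, magnitude, symmetryMode = "C4-about-z")
}

#' Linear-response displacement field for a force perturbation
#'
#' Assembles the 3N force vector from the perturbation targets and computes
#' the static linear response by summation over the non-rigid modes:
#' `u = sum_m (v_m^T f / lambda_m) v_m`. The response is exactly linear in
#' the force magnitude and free of rigid-body content (net translation and
#' net rotation are zero because rigid modes are excluded).
#'
#' @param model an [ANMModel-class].
#' @param perturbation a [ForcePerturbation-class].
#' @return a [ResponseField-class]; displacement units are arbitrary
#'   (linear in force; no thermal scaling is applied).
#' @export
lrtResponse <- function(model, perturbation) {
  stopifnot(is(model, "ANMModel"), is(perturbation, "ForcePerturbation"))
  n <- nBeads(model)
  t <- perturbation@targets
  if (any(t$bead < 1L | t$bead > n)) {
    stop("target bead index out of range 1..", n)
  }

  f <- numeric(3L * n)
  for (p in seq_len(nrow(t))) {
    idx <- (3 * t$bead[p] - 2):(3 * t$bead[p])
    f[idx] <- f[idx] + perturbation@magnitude * c(t$dx[p], t$dy[p], t$dz[p])
  }

  vals <- model@eigenValues
  maxEv <- max(vals, 0)
  keep <- vals >= RIGID_MODE_TOL * maxEv & vals > 0
  if (!any(keep)) stop("model has no non-rigid modes (all-rigid network)")

  V <- model@eigenVectors[, keep, drop = FALSE]
  u <- V %*% ((crossprod(V, f)) / vals[keep])

  new("ResponseField",
      displacements = asMat3(as.vector(u)),
      perturbation = perturbation,
      modelRef = paste0("ANM cutoff ", model@cutoff, " on ",
                        model@structure@source))
}
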