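#' @import methods
NULL

#' CoarseGrainedStructure: a C-alpha bead model of a protein
#'
#' One bead per residue, placed at the C-alpha position, with chain and
#' author residue numbering preserved verbatim from the source file. Beads
#' are stored sorted by chain identifier, then residue number, so that the
#' bead order is stable and reproducible across I/O round trips.
#'
#' @slot coords numeric matrix, N x 3, coordinates in Angstrom.
#' @slot chainIds character vector of per-bead chain labels.
#' @slot residueNumbers integer vector of per-bead author residue numbers.
#' @slot residueNames character vector of per-bead 3-letter residue codes.
#' @slot source free-text provenance of the structure.
#'
#' @exportClass CoarseGrainedStructure
setClass("CoarseGrainedStructure",
  representation(
    coords = "matrix",
    chainIds = "character",
    residueNumbers = "integer",
    residueNames = "character",
    source = "character"
  )
)

setValidity("CoarseGrainedStructure", function(object) {
  n <- nrow(object@coords)
  if (n < 1L) return("structure must contain at least one bead")
  if (ncol(object@coords) != 3L) return("coords must be an N x 3 matrix")
  if (!all(is.finite(object@coords))) return("all coordinates must be finite")
  if (length(object@chainIds) != n || length(object@residueNumbers) != n ||
      length(object@residueNames) != n) {
    return("chainIds, residueNumbers and residueNames must match bead count")
  }
  key <- paste(object@chainIds, object@residueNumbers)
  if (anyDuplicated(key)) {
    return("exactly one bead per (chain, residue number) pair is required")
  }
  ord <- order(object@chainIds, object@residueNumbers)
  if (!identical(ord, seq_len(n))) {
    return("beads must be sorted by chain, then residue number")
  }
  TRUE
})

#' ResidueSelection: a chain- and residue-number based bead selection
#'
#' @slot chains character vector of chain labels; empty means all chains.
#' @slot residues integer vector of author residue numbers (a range is given
#'   as the expanded sequence).
#'
#' @exportClass ResidueSelection
setClass("ResidueSelection",
  representation(chains = "character", residues = "integer")
)

setValidity("ResidueSelection", function(object) {
  if (length(object@residues) < 1L) return("selection needs >= 1 residue number")
  if (anyNA(object@residues)) return("residue numbers must not be NA")
  TRUE
})

#' MorphTrajectory: linear interpolation frames between two bead states
#'
#' @slot frames list of N x 3 coordinate matrices, all sharing the bead
#'   count and ordering of the parent structure.
#' @slot frameLabels numeric interpolation parameter in [0, 1] per frame.
#'
#' @exportClass MorphTrajectory
setClass("MorphTrajectory",
  representation(frames = "list", frameLabels = "numeric")
)

setValidity("MorphTrajectory", function(object) {
  if (length(object@frames) != length(object@frameLabels)) {
    return("one label per frame required")
  }
  if (length(object@frames) < 2L) return("a morph needs >= 2 frames")
  dims <- vapply(object@frames, function(f) nrow(f), integer(1))
  if (length(unique(dims)) != 1L) return("all frames must share bead count")
  if (any(object@frameLabels < 0 | object@frameLabels > 1)) {
    return("frame labels must lie in [0, 1]")
  }
  TRUE
})

#' SpringModel: spring-constant parameterization of an elastic network
#'
#' Either a uniform constant for every contact, or a pairwise table keyed by
#' the two residue names, standing in for heterogeneous parameterizations.
#'
#' @slot kind "uniform" or "pairwise-table".
#' @slot gamma uniform spring constant (arbitrary units), used directly for
#'   kind "uniform" and as the fallback for pairs missing from the table.
#' @slot pairTable data.frame with columns resA, resB, gamma.
#'
#' @exportClass SpringModel
setClass("SpringModel",
  representation(kind = "character", gamma = "numeric", pairTable = "data.frame")
)

setValidity("SpringModel", function(object) {
  if (!object@kind %in% c("uniform", "pairwise-table")) {
    return("kind must be 'uniform' or 'pairwise-table'")
  }
  if (length(object@gamma) != 1L || !is.finite(object@gamma) || object@gamma <= 0) {
    return("gamma must be a single positive number")
  }
  if (object@kind == "pairwise-table") {
    if (!all(c("resA", "resB", "gamma") %in% names(object@pairTable))) {
      return("pairTable needs columns resA, resB, gamma")
    }
    if (any(object@pairTable$gamma <= 0)) return("all spring constants must be > 0")
  }
  TRUE
})

#' ANMModel: anisotropic network model with stored mode decomposition
#'
#' The Hessian couples residues closer than the distance cutoff with springs
#' of the given parameterization; its eigendecomposition (eigenvalues stored
#' ascending) is kept so that linear-response fields can be computed by mode
#' summation over the non-rigid modes.
#'
#' @slot structure the [CoarseGrainedStructure-class] the model was built from.
#' @slot cutoff contact cutoff, Angstrom.
#' @slot springModel the [SpringModel-class] used.
#' @slot hessian 3N x 3N symmetric matrix, a.u. / Angstrom^2.
#' @slot eigenValues ascending eigenvalues.
#' @slot eigenVectors orthonormal eigenvectors, columns matching eigenValues.
#' @slot nRigidModes number of near-zero (rigid body) modes; 6 for a
#'   connected network.
#'
#' @exportClass ANMModel
setClass("ANMModel",
  representation(
    structure = "CoarseGrainedStructure",
    cutoff = "numeric",
    springModel = "SpringModel",
    hessian = "matrix",
    eigenValues = "numeric",
    eigenVectors = "matrix",
    nRigidModes = "integer"
  )
)

setValidity("ANMModel", function(object) {
  n3 <- 3L * nrow(object@structure@coords)
  if (!identical(dim(object@hessian), c(n3, n3))) {
    return("hessian must be 3N x 3N")
  }
  if (length(object@eigenValues) != n3) return("need 3N eigenvalues")
  if (is.unsorted(object@eigenValues)) return("eigenvalues must be ascending")
  TRUE
})

#' ForcePerturbation: an external static force applied to network beads
#'
#' @slot targets data.frame with columns bead (index), dx, dy, dz (unit
#'   direction components).
#' @slot magnitude force magnitude per target, arbitrary units.
#' @slot symmetryMode "as-given" or "C4-about-z".
#'
#' @exportClass ForcePerturbation
setClass("ForcePerturbation",
  representation(targets = "data.frame", magnitude = "numeric",
                 symmetryMode = "character")
)

setValidity("ForcePerturbation", function(object) {
  t <- object@targets
  if (!all(c("bead", "dx", "dy", "dz") %in% names(t))) {
    return("targets needs columns bead, dx, dy, dz")
  }
  nrm <- sqrt(t$dx^2 + t$dy^2 + t$dz^2)
  if (any(abs(nrm - 1) > 1e-12)) return("direction vectors must have unit norm")
  if (object@magnitude < 0) return("magnitude must be >= 0")
  if (!object@symmetryMode %in% c("as-given", "C4-about-z")) {
    return("symmetryMode must be 'as-given' or 'C4-about-z'")
  }
  TRUE
})

#' ResponseField: per-bead linear-response displacements
#'
#' Displacements are in arbitrary length units, exactly linear in the force
#' magnitude; rigid-body content is absent because rigid modes are excluded
#' from the mode sum.
#'
#' @slot displacements numeric matrix, N x 3.
#' @slot perturbation the generating [ForcePerturbation-class].
#' @slot modelRef free-text provenance of the ANM model.
#'
#' @exportClass ResponseField
setClass("ResponseField",
  representation(displacements = "matrix", perturbation = "ForcePerturbation",
                 modelRef = "character")
)

setValidity("ResponseField", function(object) {
  if (ncol(object@displacements) != 3L) return("displacements must be N x 3")
  if (!all(is.finite(object@displacements))) return("displacements must be finite")
  TRUE
})

#' ForceEnsemble: sampled force directions for a perturbation experiment
#'
#' @slot nSamples number of sampled directions.
#' @slot magnitude force magnitude, arbitrary units.
#' @slot seed RNG seed the directions were drawn from.
#' @slot directions nSamples x 3 matrix of unit vectors.
#'
#' @exportClass ForceEnsemble
setClass("ForceEnsemble",
  representation(nSamples = "integer", magnitude = "numeric", seed = "integer",
                 directions = "matrix")
)

setValidity("ForceEnsemble", function(object) {
  if (nrow(object@directions) != object@nSamples) {
    return("directions must have nSamples rows")
  }
  nrm <- sqrt(rowSums(object@directions^2))
  if (any(abs(nrm - 1) > 1e-12)) return("directions must be unit vectors")
  TRUE
})

#' ClusterResult: k-means partition of sampled forces by response features
#'
#' Labels are 1-based cluster indices (R convention). The representative of
#' each cluster is the sample whose feature vector lies nearest (Euclidean)
#' to the cluster centroid.
#'
#' @slot k number of clusters.
#' @slot labels integer vector of per-sample cluster indices in 1..k.
#' @slot centroids k x p matrix of cluster centres in feature space.
#' @slot withinss per-cluster within-cluster sum of squares.
#' @slot maxWithinssByK data.frame (k, maxWithinss, logMaxWithinss) over the
#'   candidate k grid when produced by [elbowSelectK()]; empty otherwise.
#' @slot representativeIndex per-cluster index of the sample nearest its
#'   centroid.
#'
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(
    k = "integer", labels = "integer", centroids = "matrix",
    withinss = "numeric", maxWithinssByK = "data.frame",
    representativeIndex = "integer"
  )
)

setValidity("ClusterResult", function(object) {
  if (any(object@labels < 1L | object@labels > object@k)) {
    return("labels must lie in 1..k")
  }
  if (length(unique(object@labels)) != object@k) {
    return("every cluster must be non-empty")
  }
  if (any(object@withinss < -1e-12)) return("withinss must be >= 0")
  if (length(object@representativeIndex) != object@k) {
    return("one representative per cluster required")
  }
  TRUE
})

#' TrajectoryEnsemble: ordered coordinate frames of labelled atoms
#'
#' @slot frames numeric array, frames x atoms x 3, Angstrom.
#' @slot atomLabels data.frame with columns chain, resno, atom.
#' @slot times per-frame time, strictly increasing (ns).
#' @slot box orthorhombic box lengths (3 values, Angstrom), or numeric(0)
#'   for non-periodic coordinates.
#'
#' @exportClass TrajectoryEnsemble
setClass("TrajectoryEnsemble",
  representation(frames = "array", atomLabels = "data.frame",
                 times = "numeric", box = "numeric")
)

setValidity("TrajectoryEnsemble", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L || d[3] != 3L) return("frames must be F x A x 3")
  if (nrow(object@atomLabels) != d[2]) {
    return("atomLabels must have one row per atom")
  }
  if (!all(c("chain", "resno", "atom") %in% names(object@atomLabels))) {
    return("atomLabels needs columns chain, resno, atom")
  }
  if (length(object@times) != d[1]) return("one time per frame required")
  if (d[1] > 1 && any(diff(object@times) <= 0)) {
    return("times must be strictly increasing")
  }
  if (!length(object@box) %in% c(0L, 3L)) {
    return("box must be empty or 3 lengths")
  }
  TRUE
})
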