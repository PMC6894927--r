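# Accessor generics for the S4 containers. Slot access from user code is
# discouraged; these are the supported surface.

#' Bead coordinates of a structure-like object
#' @param x a CoarseGrainedStructure
#' @return N x 3 numeric matrix (Angstrom)
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Per-bead chain labels
#' @param x a CoarseGrainedStructure
#' @return character vector
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' Per-bead author residue numbers
#' @param x a CoarseGrainedStructure
#' @return integer vector
#' @export
setGeneric("residueNumbers", function(x) standardGeneric("residueNumbers"))

#' Per-bead residue names (3-letter codes)
#' @param x a CoarseGrainedStructure
#' @return character vector
#' @export
setGeneric("residueNames", function(x) standardGeneric("residueNames"))

#' Number of beads
#' @param x a CoarseGrainedStructure or ANMModel
#' @return integer
#' @export
setGeneric("nBeads", function(x) standardGeneric("nBeads"))

#' 3N x 3N Hessian of an elastic network model
#' @param x an ANMModel
#' @return symmetric numeric matrix
#' @export
setGeneric("hessianMatrix", function(x) standardGeneric("hessianMatrix"))

#' Ascending eigenvalues of an ANM Hessian
#' @param x an ANMModel
#' @return numeric vector
#' @export
setGeneric("modeEigenvalues", function(x) standardGeneric("modeEigenvalues"))

#' Orthonormal eigenvectors of an ANM Hessian (columns)
#' @param x an ANMModel
#' @return numeric matrix
#' @export
setGeneric("modeEigenvectors", function(x) standardGeneric("modeEigenvectors"))

#' Number of rigid-body (near-zero) modes
#' @param x an ANMModel
#' @return integer, 6 for a connected network
#' @export
setGeneric("nRigidModes", function(x) standardGeneric("nRigidModes"))

#' Per-bead displacement vectors of a response field
#' @param x a ResponseField
#' @return N x 3 numeric matrix
#' @export
setGeneric("displacements", function(x) standardGeneric("displacements"))

#' Per-sample cluster labels
#' @param x a ClusterResult
#' @return integer vector in 1..k
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' Morph frames as a list of coordinate matrices
#' @param x a MorphTrajectory
#' @return list of N x 3 matrices
#' @export
setGeneric("morphFrames", function(x) standardGeneric("morphFrames"))

setMethod("coords", "CoarseGrainedStructure", function(x) x@coords)
setMethod("chainIds", "CoarseGrainedStructure", function(x) x@chainIds)
setMethod("residueNumbers", "CoarseGrainedStructure", function(x) x@residueNumbers)
setMethod("residueNames", "CoarseGrainedStructure", function(x) x@residueNames)
setMethod("nBeads", "CoarseGrainedStructure", function(x) nrow(x@coords))
setMethod("nBeads", "ANMModel", function(x) nrow(x@structure@coords))
setMethod("hessianMatrix", "ANMModel", function(x) x@hessian)
setMethod("modeEigenvalues", "ANMModel", function(x) x@eigenValues)
setMethod("modeEigenvectors", "ANMModel", function(x) x@eigenVectors)
setMethod("nRigidModes", "ANMModel", function(x) x@nRigidModes)
setMethod("displacements", "ResponseField", function(x) x@displacements)
setMethod("clusterLabels", "ClusterResult", function(x) x@labels)
setMethod("morphFrames", "MorphTrajectory", function(x) x@frames)

setMethod("show", "CoarseGrainedStructure", function(object) {
  ch <- unique(object@chainIds)
  cat("CoarseGrainedStructure:", nrow(object@coords), "beads,",
      length(ch), "chain(s) [", paste(ch, collapse = ","), "]\n")
  cat("  source:", object@source, "\n")
})

setMethod("show", "ANMModel", function(object) {
  cat("ANMModel:", nBeads(object), "beads, cutoff", object@cutoff,
      "A,", object@springModel@kind, "springs\n")
  cat("  rigid modes:", object@nRigidModes, "\n")
})

setMethod("show", "ResponseField", function(object) {
  nrm <- sqrt(rowSums(object@displacements^2))
  cat("ResponseField:", nrow(object@displacements), "beads; |u| max",
      signif(max(nrm), 4), ", mean", signif(mean(nrm), 4), "\n")
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult: k =", object@k, "; sizes:",
      paste(tabulate(object@labels, object@k), collapse = ", "), "\n")
  cat("  withinss:", paste(signif(object@withinss, 4), collapse = ", "), "\n")
})

setMethod("show", "TrajectoryEnsemble", function(object) {
  d <- dim(object@frames)
  cat("TrajectoryEnsemble:", d[1], "frames x", d[2], "atoms;",
      if (length(object@box)) paste("box", paste(object@box, collapse = " x "))
      else "no box", "\n")
})
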