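#' Construct a trajectory ensemble
#'
#' @param frames numeric array frames x atoms x 3 (Angstrom), or a list of
#'   atoms x 3 matrices.
#' @param atomLabels data.frame with columns chain, resno, atom (one row
#'   per atom; constant across frames).
#' @param times per-frame times in ns; defaults to 0, 1, 2, ...
#' @param box optional orthorhombic box lengths (3 values, Angstrom).
#' @return a [TrajectoryEnsemble-class].
#' @export
trajectoryEnsemble <- function(frames, atomLabels, times = NULL, box = NULL) {
  if (is.list(frames)) {
    arr <- array(0, dim = c(length(frames), nrow(frames[[1]]), 3))
    for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
    frames <- arr
  }
  if (is.null(times)) times <- seq_len(dim(frames)[1]) - 1
  new("TrajectoryEnsemble", frames = frames, atomLabels = atomLabels,
      times = as.numeric(times),
      box = if (is.null(box)) numeric(0) else as.numeric(box))
}

#' Read a trajectory from a whitespace-delimited frames table
#'
#' The table must have a header with columns `frame`, `chain`, `resno`,
#' `atom`, `x`, `y`, `z` and optionally `time`; every frame must list the
#' same atoms in the same order. Binary MD formats are not parsed natively;
#' convert them upstream or pass coordinates directly to
#' [trajectoryEnsemble()].
#'
#' @param path path to the table.
#' @param box optional orthorhombic box lengths.
#' @return a [TrajectoryEnsemble-class].
#' @export
readFramesTable <- function(path, box = NULL) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("frame", "chain", "resno", "atom", "x", "y", "z")
  if (!all(need %in% names(tab))) {
    stop("frames table needs columns: ", paste(need, collapse = ", "))
  }
  frames <- sort(unique(tab$frame))
  first <- tab[tab$frame == frames[1], ]
  arr <- array(0, dim = c(length(frames), nrow(first), 3))
  times <- numeric(length(frames))
  for (i in seq_along(frames)) {
    sub <- tab[tab$frame == frames[i], ]
    if (nrow(sub) != nrow(first)) {
      stop("frame ", frames[i], " has a different atom count")
    }
    arr[i, , ] <- as.matrix(sub[, c("x", "y", "z")])
    times[i] <- if ("time" %in% names(sub)) sub$time[1] else i - 1
  }
  trajectoryEnsemble(arr,
                     data.frame(chain = first$chain, resno = first$resno,
                                atom = first$atom,
                                stringsAsFactors = FALSE),
                     times = times, box = box)
}

#' Atom selection for trajectory observables
#'
#' @param resno residue numbers to select (NULL = any).
#' @param atoms atom names to select (NULL = any).
#' @param chains chain labels (NULL = any).
#' @return an object of class `AtomSelection`.
#' @export
atomSelection <- function(resno = NULL, atoms = NULL, chains = NULL) {
  structure(list(resno = resno, atoms = atoms, chains = chains),
            class = "AtomSelection")
}

resolveAtoms <- function(traj, sel, chain = NULL) {
  lab <- traj@atomLabels
  hit <- rep(TRUE, nrow(lab))
  if (!is.null(sel$resno)) hit <- hit & lab$resno %in% sel$resno
  if (!is.null(sel$atoms)) hit <- hit & lab$atom %in% sel$atoms
  if (!is.null(sel$chains)) hit <- hit & lab$chain %in% sel$chains
  if (!is.null(chain)) hit <- hit & lab$chain == chain
  which(hit)
}

# Pairwise distances between two coordinate sets, minimum-image on an
# orthorhombic box when box lengths are present.
pairDistances <- function(a, b, box) {
  na <- nrow(a); nb <- nrow(b)
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  dz <- outer(a[, 3], b[, 3], "-")
  if (length(box) == 3L) {
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
    dz <- dz - box[3] * round(dz / box[3])
  }
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Minimum inter-selection distance time series
#'
#' For every frame and subunit (chain), the minimum over all A x B atom
#' pair distances between the two selections resolved within that chain --
#' the "shortest found distance" between two side chains. The mean over
#' subunits and its dispersion band (SEM by default, SD optionally) are
#' attached, matching the convention of plotting a per-subunit average
#' with translucent error bands.
#'
#' @param traj a [TrajectoryEnsemble-class].
#' @param selA,selB [atomSelection()] objects, resolved per chain.
#' @param chains chains to treat as subunits; default all chains present.
#' @param band "sem" (default) or "sd".
#' @return list of class `DistanceSeries`: `times` (ns), `perSubunit`
#'   (frames x subunits matrix, Angstrom), `mean`, `band`, `bandType`.
#' @export
minDistanceSeries <- function(traj, selA, selB, chains = NULL, band = "sem") {
  stopifnot(is(traj, "TrajectoryEnsemble"))
  if (is.null(chains)) chains <- unique(traj@atomLabels$chain)
  idxA <- lapply(chains, function(ch) resolveAtoms(traj, selA, chain = ch))
  idxB <- lapply(chains, function(ch) resolveAtoms(traj, selB, chain = ch))
  empty <- vapply(idxA, length, integer(1)) == 0 |
           vapply(idxB, length, integer(1)) == 0
  if (any(empty)) {
    stop("empty selection in subunit(s): ",
         paste(chains[empty], collapse = ", "))
  }

  nf <- dim(traj@frames)[1]
  per <- matrix(0, nf, length(chains),
                dimnames = list(NULL, as.character(chains)))
  for (f in seq_len(nf)) {
    co <- matrix(traj@frames[f, , ], ncol = 3)
    for (s in seq_along(chains)) {
      d <- pairDistances(co[idxA[[s]], , drop = FALSE],
                         co[idxB[[s]], , drop = FALSE], traj@box)
      per[f, s] <- min(d)
    }
  }
  mn <- rowMeans(per)
  disp <- apply(per, 1, stats::sd)
  if (identical(band, "sem")) disp <- disp / sqrt(length(chains))
  structure(list(times = traj@times, perSubunit = per, mean = mn,
                 band = disp, bandType = band),
            class = "DistanceSeries")
}

#' Radial distribution function g(r)
#'
#' Histogram of distances from each target atom to the nearest atom of the
#' reference group (the group convention: "distance from the side chain"
#' means distance to its closest atom), normalized per frame by the
#' ideal-gas expectation -- shell volume times the bulk target number
#' density -- and averaged over frames. The bulk density is the target
#' count divided by the box volume, or an explicit `density` override for
#' box-free coordinates.
#'
#' @param traj a [TrajectoryEnsemble-class].
#' @param reference [atomSelection()] for the reference group.
#' @param targets [atomSelection()] for the target atoms (e.g. water
#'   oxygens).
#' @param rMax maximum distance, Angstrom.
#' @param binWidth bin width, Angstrom.
#' @param density optional bulk number density override (atoms/Angstrom^3);
#'   required when the trajectory has no box.
#' @return list of class `RDFProfile`: `rCenters`, `g`, `binWidth`,
#'   `nFramesUsed`, `density`.
#' @export
rdf <- function(traj, reference, targets, rMax, binWidth = 0.1,
                density = NULL) {
  stopifnot(is(traj, "TrajectoryEnsemble"))
  if (binWidth <= 0) stop("binWidth must be > 0")
  if (rMax <= binWidth) stop("rMax must exceed binWidth")

  refIdx <- resolveAtoms(traj, reference)
  tgtIdx <- resolveAtoms(traj, targets)
  if (length(refIdx) == 0) stop("reference selection resolves to no atoms")
  if (length(tgtIdx) == 0) stop("target selection resolves to no atoms")

  if (is.null(density)) {
    if (length(traj@box) != 3L) {
      stop("no box on the trajectory and no density override: ",
           "cannot normalize g(r)")
    }
    density <- length(tgtIdx) / prod(traj@box)
  }

  breaks <- seq(0, rMax, by = binWidth)
  if (breaks[length(breaks)] < rMax) breaks <- c(breaks, rMax)
  nb <- length(breaks) - 1L
  counts <- numeric(nb)
  nf <- dim(traj@frames)[1]
  for (f in seq_len(nf)) {
    co <- matrix(traj@frames[f, , ], ncol = 3)
    d <- pairDistances(co[tgtIdx, , drop = FALSE],
                       co[refIdx, , drop = FALSE], traj@box)
    dmin <- apply(d, 1, min)
    dmin <- dmin[dmin > 0 & dmin <= rMax]  # exclude self-distances
    counts <- counts + tabulate(findInterval(dmin, breaks,
                                             rightmost.closed = TRUE), nb)
  }
  shellVol <- 4 / 3 * pi * (breaks[-1]^3 - breaks[-length(breaks)]^3)
  g <- counts / (nf * shellVol * density)
  structure(list(rCenters = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 g = g, binWidth = binWidth, nFramesUsed = nf,
                 density = density),
            class = "RDFProfile")
}
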