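# Synthetic-data generators. Every generator is a pure function of its
# parameters and an explicit seed (no hidden RNG state), and returns its
# ground truth alongside the data wherever there is one.

#' Synthetic C4-symmetric bead structure
#'
#' Four chains A-D, each a jittered helical bead trace; chains B-D are
#' exact 90/180/270-degree z-rotation images of chain A, so the structure
#' is C4-symmetric about the z axis by construction (the same convention as
#' a channel tetramer whose four-fold axis is z). Defaults give a connected
#' elastic network at the 13 Angstrom cutoff.
#'
#' @param nResPerChain beads per chain (>= 10).
#' @param radius distance of each chain's helical axis from z, Angstrom.
#' @param pitch rise per bead, Angstrom.
#' @param jitter sd of Gaussian positional noise applied to chain A (and
#'   replicated exactly onto B-D), Angstrom.
#' @param resStart first residue number (author numbering).
#' @param seed RNG seed.
#' @return a [CoarseGrainedStructure-class] with 4 x nResPerChain beads.
#' @export
makeC4Structure <- function(nResPerChain = 50L, radius = 10, pitch = 1.5,
                            jitter = 0.3, resStart = 1L, seed = 1L) {
  if (nResPerChain < 10) stop("nResPerChain must be >= 10")
  n <- as.integer(nResPerChain)
  a <- 2.5  # local helix radius
  i <- seq_len(n)
  th <- i * 100 * pi / 180
  base <- cbind(radius + a * cos(th), a * sin(th), pitch * i)
  base <- base + withSeed(seed, matrix(stats::rnorm(3 * n, sd = jitter),
                                       ncol = 3))
  resNames <- rep(c("ALA", "GLY", "LEU", "SER", "VAL"), length.out = n)
  chains <- c("A", "B", "C", "D")
  coords <- do.call(rbind, lapply(0:3, function(k) {
    base %*% t(rotationZ(90 * k))
  }))
  new("CoarseGrainedStructure",
      coords = coords,
      chainIds = rep(chains, each = n),
      residueNumbers = rep(as.integer(seq(resStart, length.out = n)), 4),
      residueNames = rep(resNames, 4),
      source = sprintf("synthetic C4 helix bundle (n=%d, seed=%d)", n,
                       as.integer(seed)))
}

#' Synthetic coupled toy assembly (gating ring + crank arms)
#'
#' A C4 bead assembly emulating the mechanical architecture of an HCN
#' channel at toy scale: a double-layered "linker" gating ring (the
#' clustering shoulder), four slanted zigzag "hcnd" arms whose lower beads
#' contact the ring, and a "vsd" strand stacked on each arm. The ring
#' contacts the hcnd arms of neighbouring chains (within the 13 Angstrom
#' cutoff) and each hcnd contacts the vsd of its own chain, giving a
#' connected mechanical path from ring to sensor. The arms slant
#' azimuthally with height (a sliding-crank geometry), so the assembly's
#' softest four-fold symmetric mode converts planar ring rotation into
#' vertical arm displacement -- the transmission the perturbation
#' experiments probe. With `sever = TRUE` the hcnd beads in contact with
#' the ring are removed, which disconnects the arms from the ring (the
#' network then splits into ring + four arms and the model warns about
#' disconnection).
#'
#' @param seed RNG seed for the positional jitter.
#' @param sever remove the hcnd-linker contact beads.
#' @param jitter sd of positional noise on chain A, Angstrom.
#' @return list: `structure` ([CoarseGrainedStructure-class]), `domains`
#'   (named [residueSelection()] list: linker, hcnd, vsd), `shoulder`
#'   (selection used for clustering), `sites` (per-domain perturbation
#'   residue numbers), `contacts` (data.frame of annotated inter-domain
#'   bead contacts with distances), `severedResidues`.
#' @export
makeCoupledAssembly <- function(seed = 1L, sever = FALSE, jitter = 0.15) {
  nArc <- 8L; nH <- 6L; nV <- 7L
  rRing <- 16; zRing <- c(0, 3); rArm <- 12; azArm <- 60
  armZig <- 4; slant <- 50; zHcnd <- c(6, 20); zVsd <- c(23, 40)
  linkerRes <- seq(440L, length.out = 2L * nArc)
  hcndRes <- seq(104L, length.out = nH)
  vsdRes <- seq(280L, length.out = nV)

  azL <- seq(-40, 40, length.out = nArc) * pi / 180
  linker <- rbind(cbind(rRing * cos(azL), rRing * sin(azL), zRing[1]),
                  cbind(rRing * cos(azL), rRing * sin(azL), zRing[2]))
  zig <- function(zlo, zhi, nn) {
    z <- seq(zlo, zhi, length.out = nn)
    frac <- (z - zHcnd[1]) / (zVsd[2] - zHcnd[1])
    azs <- (azArm + slant * frac +
              armZig * rep(c(-1, 1), length.out = nn)) * pi / 180
    cbind(rArm * cos(azs), rArm * sin(azs), z)
  }
  hcnd <- zig(zHcnd[1], zHcnd[2], nH)
  vsd <- zig(zVsd[1], zVsd[2], nV)
  base <- rbind(linker, hcnd, vsd)
  base <- base + withSeed(seed, matrix(stats::rnorm(length(base), sd = jitter),
                                       ncol = 3))
  nL <- 2L * nArc
  resno <- c(linkerRes, hcndRes, vsdRes)
  resnm <- c(rep("LEU", nL), rep("HIS", nH), rep("VAL", nV))
  nPer <- nL + nH + nV
  coords <- do.call(rbind, lapply(0:3, function(k) base %*% t(rotationZ(90 * k))))
  chainIds <- rep(c("A", "B", "C", "D"), each = nPer)
  resnoAll <- rep(resno, 4)
  resnmAll <- rep(resnm, 4)
  ord <- order(chainIds, resnoAll)
  struct <- new("CoarseGrainedStructure",
                coords = coords[ord, , drop = FALSE],
                chainIds = chainIds[ord],
                residueNumbers = resnoAll[ord],
                residueNames = resnmAll[ord],
                source = sprintf("synthetic coupled assembly (seed=%d%s)",
                                 as.integer(seed),
                                 if (sever) ", severed" else ""))

  isLinker <- residueNumbers(struct) %in% linkerRes
  isHcnd <- residueNumbers(struct) %in% hcndRes
  d <- as.matrix(stats::dist(coords(struct)))
  contactPairs <- which(outer(isLinker, isHcnd) & d <= 13, arr.ind = TRUE)
  contacts <- data.frame(
    linkerBead = contactPairs[, 1], hcndBead = contactPairs[, 2],
    distance = d[contactPairs])
  severed <- sort(unique(residueNumbers(struct)[contacts$hcndBead]))

  if (sever) {
    keep <- !(residueNumbers(struct) %in% severed &
              residueNumbers(struct) %in% hcndRes)
    struct <- new("CoarseGrainedStructure",
                  coords = coords(struct)[keep, , drop = FALSE],
                  chainIds = chainIds(struct)[keep],
                  residueNumbers = residueNumbers(struct)[keep],
                  residueNames = residueNames(struct)[keep],
                  source = struct@source)
  }

  keptHcnd <- setdiff(hcndRes, if (sever) severed else integer())
  if (length(keptHcnd) == 0) stop("severing removed every hcnd bead")
  list(structure = struct,
       domains = list(linker = residueSelection(linkerRes),
                      hcnd = residueSelection(keptHcnd),
                      vsd = residueSelection(vsdRes)),
       shoulder = residueSelection(linkerRes),
       sites = list(linker = linkerRes[nArc %/% 2L],
                    hcnd = max(hcndRes),
                    vsd = vsdRes[ceiling(nV / 2)]),
       contacts = contacts,
       severedResidues = severed)
}

#' Synthetic activation datasets from a known Boltzmann truth
#'
#' Per cell, tail amplitudes `A / (1 + exp((V - vHalf)/k))` at the protocol
#' voltages plus Gaussian noise with sd `noiseFrac * A`.
#'
#' @param vHalf,kSlope,amplitude ground-truth Boltzmann parameters
#'   (mV, mV, pA).
#' @param protocol a [voltageProtocol()].
#' @param noiseFrac noise sd as a fraction of the amplitude (>= 0).
#' @param nCells number of cells to simulate.
#' @param seed RNG seed.
#' @param construct,condition labels carried into the datasets.
#' @return list of per-cell data.frames (cell_id, construct, condition,
#'   voltage_mV, tail_pA) with the truth in attribute "truth".
#' @export
makeActivationDataset <- function(vHalf, kSlope, amplitude = 1000,
                                  protocol = voltageProtocol(),
                                  noiseFrac = 0.02, nCells = 1L, seed = 1L,
                                  construct = "wt", condition = "control") {
  if (noiseFrac < 0) stop("noiseFrac must be >= 0")
  v <- protocol$voltages
  clean <- amplitude / (1 + exp((v - vHalf) / kSlope))
  cells <- withSeed(seed, {
    lapply(seq_len(nCells), function(ci) {
      data.frame(cell_id = sprintf("cell%03d", ci), construct = construct,
                 condition = condition, voltage_mV = v,
                 tail_pA = clean + stats::rnorm(length(v),
                                                sd = noiseFrac * amplitude))
    })
  })
  attr(cells, "truth") <- list(vHalf = vHalf, kSlope = kSlope,
                               amplitude = amplitude)
  cells
}

#' Synthetic mono-exponential current trace
#'
#' `I(t) = I0 exp(-t/tau)` sampled at `rate` kHz over `duration` ms with
#' additive Gaussian noise. The default 5 kHz matches a typical patch-clamp
#' sampling rate.
#'
#' @param I0 amplitude, pA.
#' @param tau time constant, ms.
#' @param duration trace length, ms.
#' @param rate sampling rate, kHz.
#' @param noiseFrac noise sd as fraction of I0.
#' @param seed RNG seed.
#' @return data.frame (time_ms, current_pA) with truth attribute.
#' @export
makeCurrentTrace <- function(I0 = 500, tau = 500, duration = 5000, rate = 5,
                             noiseFrac = 0, seed = 1L) {
  if (rate <= 0) stop("rate must be > 0")
  t <- seq(0, duration, by = 1 / rate)
  i <- I0 * exp(-t / tau)
  if (noiseFrac > 0) {
    i <- i + withSeed(seed, stats::rnorm(length(t), sd = noiseFrac * I0))
  }
  out <- data.frame(time_ms = t, current_pA = i)
  attr(out, "truth") <- list(I0 = I0, tau = tau)
  out
}

#' Labelled isotropic Gaussian blobs
#'
#' Blob centres are drawn at random and rescaled so the minimum pairwise
#' centre distance equals `separation`; points are centre + N(0, spread^2)
#' per coordinate. Ground-truth labels ride along for use as a clustering
#' oracle.
#'
#' @param k number of blobs.
#' @param dim feature dimension.
#' @param separation minimum pairwise centre distance.
#' @param spread per-coordinate sd within a blob.
#' @param nPer points per blob.
#' @param seed RNG seed.
#' @return list: `features` (matrix), `labels` (integer), `centers`.
#' @export
makeClusterBlobs <- function(k = 4L, dim = 3L, separation = 10, spread = 1,
                             nPer = 50L, seed = 1L) {
  if (k < 1) stop("k must be >= 1")
  withSeed(seed, {
    centers <- matrix(stats::rnorm(k * dim), k, dim)
    if (k > 1 && separation > 0) {
      dmin <- min(stats::dist(centers))
      if (dmin == 0) stop("degenerate random centers; change seed")
      centers <- centers * (separation / dmin)
    } else if (separation == 0) {
      centers <- matrix(0, k, dim)
    }
    features <- do.call(rbind, lapply(seq_len(k), function(j) {
      sweep(matrix(stats::rnorm(nPer * dim, sd = spread), nPer, dim), 2,
            centers[j, ], "+")
    }))
    list(features = features, labels = rep(seq_len(k), each = nPer),
         centers = centers)
  })
}

#' Four-construct energy table with a known coupling
#'
#' Builds wild type, two single mutants and the double mutant as
#' [constructEnergetics()] objects such that
#' `dG(double) = dG(s1) + dG(s2) - dG(wt) + coupling`, back-solving each
#' dG_app into a half-activation voltage at a fixed inverse slope factor.
#' A cycle with `coupling = 0` is perfectly additive (ddG = 0); any
#' injected coupling is recovered exactly as the cycle's ddG.
#'
#' @param dGWt,dGS1,dGS2 apparent gating free energies, kcal/mol. The
#'   defaults place all four half-activation voltages inside the standard
#'   HCN2 step-protocol range so that every construct's activation curve is
#'   resolvable by per-cell fitting.
#' @param coupling injected non-additivity, kcal/mol.
#' @param kSlope fixed inverse slope factor, mV.
#' @param temperature Kelvin.
#' @param labels construct names (wt, single1, single2, double).
#' @return named list of four [constructEnergetics()] with attribute
#'   "coupling".
#' @export
makeEnergyTable <- function(dGWt = -7.2, dGS1 = -6.6, dGS2 = -7.0,
                            coupling = 0, kSlope = 8, temperature = 298,
                            labels = c("wt", "single1", "single2", "double")) {
  dG <- c(dGWt, dGS1, dGS2, dGS1 + dGS2 - dGWt + coupling)
  vHalf <- dG * kSlope / (R_KCAL * temperature)
  out <- Map(function(lab, vh) constructEnergetics(lab, vh, kSlope,
                                                   temperature),
             labels, vHalf)
  names(out) <- c("wt", "single1", "single2", "double")
  attr(out, "coupling") <- coupling
  out
}

#' Ideal-gas (uniform random) trajectory for g(r) validation
#'
#' Uniform random target atoms in an orthorhombic box, positions
#' independent across frames, with one fixed reference atom at the box
#' centre. The target count is Poisson-distributed with mean
#' `density * volume` (drawn once, so the atom count is constant across
#' frames as a trajectory requires).
#'
#' @param density target number density, atoms/Angstrom^3.
#' @param box box lengths (3 values or scalar), Angstrom.
#' @param nFrames number of frames.
#' @param seed RNG seed.
#' @return a [TrajectoryEnsemble-class]; reference atom is chain "R",
#'   atom "REF"; targets are chain "W", atom "O".
#' @export
makeIdealGasTraj <- function(density = 0.02, box = 30, nFrames = 100L,
                             seed = 1L) {
  if (density <= 0 || any(box <= 0)) stop("density and box must be > 0")
  box <- rep(as.numeric(box), length.out = 3)
  withSeed(seed, {
    n <- max(1L, stats::rpois(1, density * prod(box)))
    frames <- array(0, dim = c(nFrames, n + 1L, 3))
    for (f in seq_len(nFrames)) {
      frames[f, 1, ] <- box / 2
      frames[f, -1, ] <- cbind(stats::runif(n, 0, box[1]),
                               stats::runif(n, 0, box[2]),
                               stats::runif(n, 0, box[3]))
    }
    trajectoryEnsemble(
      frames,
      data.frame(chain = c("R", rep("W", n)),
                 resno = c(1L, seq_len(n)),
                 atom = c("REF", rep("O", n)),
                 stringsAsFactors = FALSE),
      box = box)
  })
}

#' Hydration-shell toy trajectory for g(r) validation
#'
#' Target atoms placed exactly on a sphere of the given radius around a
#' central reference atom, in random directions per frame: g(r) must show
#' a single occupied bin at the shell radius and zero elsewhere.
#'
#' @param radius shell radius, Angstrom.
#' @param nTargets targets per frame.
#' @param nFrames frames.
#' @param seed RNG seed.
#' @return a [TrajectoryEnsemble-class] (no box; pass a density override
#'   to [rdf()]).
#' @export
makeShellTraj <- function(radius = 3, nTargets = 50L, nFrames = 20L,
                          seed = 1L) {
  withSeed(seed, {
    frames <- array(0, dim = c(nFrames, nTargets + 1L, 3))
    for (f in seq_len(nFrames)) {
      dirs <- matrix(stats::rnorm(3 * nTargets), ncol = 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      frames[f, -1, ] <- radius * dirs
    }
    trajectoryEnsemble(
      frames,
      data.frame(chain = c("R", rep("W", nTargets)),
                 resno = c(1L, seq_len(nTargets)),
                 atom = c("REF", rep("O", nTargets)),
                 stringsAsFactors = FALSE))
  })
}
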