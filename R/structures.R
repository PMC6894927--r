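#' Read an atomic structure and reduce it to a C-alpha bead model
#'
#' Parses a PDB or mmCIF file (dispatching on the file extension, falling
#' back to PDB), takes the requested model, and keeps one bead per residue
#' at its C-alpha position. Residues without a C-alpha atom are dropped with
#' a warning. Author chain labels and residue numbers are preserved
#' verbatim; beads are ordered by chain then residue number. Alternate
#' locations resolve to the first listed atom.
#'
#' @param path path to a PDB (`.pdb`, `.ent`) or mmCIF (`.cif`, `.mmcif`)
#'   file.
#' @param modelIndex 1-based model index for multi-model files.
#' @return a [CoarseGrainedStructure-class].
#' @examples
#' s <- makeC4Structure(nResPerChain = 12, seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' writeStructurePDB(s, f)
#' readStructure(f)
#' @export
readStructure <- function(path, modelIndex = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  parsed <- tryCatch({
    # bio3d warns about secondary-structure records we never use
    withCallingHandlers({
      if (ext %in% c("cif", "mmcif")) {
        bio3d::read.cif(path, multi = TRUE)
      } else {
        bio3d::read.pdb(path, multi = TRUE)
      }
    }, warning = function(w) {
      if (grepl("helix/sheet|beta version", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  }, error = function(e) {
    stop("could not parse '", path, "' as ",
         if (ext %in% c("cif", "mmcif")) "mmCIF" else "PDB",
         ": ", conditionMessage(e), call. = FALSE)
  })

  nModels <- max(1L, nrow(parsed$xyz))
  if (modelIndex < 1L || modelIndex > nModels) {
    stop("model index ", modelIndex, " out of range (file has ",
         nModels, " model(s))")
  }

  atoms <- parsed$atom
  xyz <- matrix(parsed$xyz[modelIndex, ], ncol = 3, byrow = TRUE)

  # altloc: keep the first listed atom per (chain, resno, atom name)
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  keep <- !duplicated(key)

  isCA <- atoms$elety == "CA" & keep
  if (!any(isCA)) stop("no CA atoms found in '", path, "': empty structure")
  resKey <- paste(atoms$chain, atoms$resno)
  missing <- setdiff(unique(resKey), unique(resKey[isCA]))
  if (length(missing) > 0) {
    warning(length(missing), " residue(s) without a CA atom dropped: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ..." else "")
  }

  idx <- which(isCA)
  chain <- as.character(atoms$chain[idx])
  chain[is.na(chain)] <- " "
  resno <- as.integer(atoms$resno[idx])
  resid <- as.character(atoms$resid[idx])
  co <- xyz[idx, , drop = FALSE]

  ord <- order(chain, resno)
  new("CoarseGrainedStructure",
      coords = co[ord, , drop = FALSE],
      chainIds = chain[ord],
      residueNumbers = resno[ord],
      residueNames = resid[ord],
      source = paste0(basename(path), " model ", modelIndex))
}

#' Construct a residue selection
#'
#' @param residues integer vector of author residue numbers (e.g.
#'   `446:465`).
#' @param chains chain labels to restrict to; empty (default) selects every
#'   chain.
#' @return a [ResidueSelection-class].
#' @export
residueSelection <- function(residues, chains = character()) {
  new("ResidueSelection", chains = as.character(chains),
      residues = as.integer(residues))
}

#' Resolve a residue selection to bead indices
#'
#' Resolution is deterministic: the returned indices are ascending and
#' duplicate-free, in the structure's stable bead order.
#'
#' @param structure a [CoarseGrainedStructure-class].
#' @param sel a [ResidueSelection-class].
#' @return integer vector of bead indices.
#' @export
resolveSelection <- function(structure, sel) {
  stopifnot(is(structure, "CoarseGrainedStructure"), is(sel, "ResidueSelection"))
  hit <- residueNumbers(structure) %in% sel@residues
  if (length(sel@chains) > 0) {
    hit <- hit & chainIds(structure) %in% sel@chains
  }
  idx <- which(hit)
  if (length(idx) == 0) {
    stop("selection resolves to no beads (residues ",
         min(sel@residues), "..", max(sel@residues), ", chains: ",
         if (length(sel@chains)) paste(sel@chains, collapse = ",") else "all",
         ")")
  }
  sort(unique(idx))
}

#' Write a bead structure as a PDB file
#'
#' Each bead is emitted as a CA atom with its chain, residue number and
#' residue name. Used both for synthetic structures and morph frames so
#' that all coordinate output flows through one writer.
#'
#' @param structure a [CoarseGrainedStructure-class].
#' @param path output file path.
#' @param xyzFrames optional matrix of frames (rows are flattened 3N
#'   coordinate vectors); when given, a multi-model PDB is written.
#' @return invisibly, the path written.
#' @export
writeStructurePDB <- function(structure, path, xyzFrames = NULL) {
  n <- nBeads(structure)
  xyz <- if (is.null(xyzFrames)) {
    matrix(asVec3N(coords(structure)), nrow = 1)
  } else xyzFrames
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    resno = residueNumbers(structure),
    resid = residueNames(structure),
    chain = chainIds(structure),
    eleno = seq_len(n),
    elety = rep("CA", n)
  )
  invisible(path)
}

#' Write a morph trajectory interpolating a linear-response displacement
#'
#' Frame 0 is the unperturbed structure; the last frame is the structure
#' displaced by `scale` times the response field; intermediate frames are
#' linear interpolations. The result is written as a multi-model PDB
#' (MODEL/ENDMDL) viewable in any molecular graphics program. The morph is
#' qualitative: it illustrates relative directional movement, not physical
#' amplitudes.
#'
#' @param structure a [CoarseGrainedStructure-class].
#' @param response a [ResponseField-class] with matching bead count.
#' @param scale multiplier applied to the displacement field.
#' @param nFrames number of frames (>= 2).
#' @param path output PDB path, or NULL to skip writing.
#' @return a [MorphTrajectory-class], invisibly when a path is written.
#' @export
writeMorph <- function(structure, response, scale = 1, nFrames = 11L, path = NULL) {
  stopifnot(is(structure, "CoarseGrainedStructure"), is(response, "ResponseField"))
  if (nFrames < 2L) stop("nFrames must be >= 2")
  disp <- displacements(response)
  if (nrow(disp) != nBeads(structure)) {
    stop("bead-count mismatch: structure has ", nBeads(structure),
         " beads, response has ", nrow(disp))
  }
  labels <- seq(0, 1, length.out = nFrames)
  ref <- coords(structure)
  frames <- lapply(labels, function(t) ref + t * scale * disp)
  morph <- new("MorphTrajectory", frames = frames, frameLabels = labels)
  if (!is.null(path)) {
    xyz <- do.call(rbind, lapply(frames, asVec3N))
    writeStructurePDB(structure, path, xyzFrames = xyz)
    return(invisible(morph))
  }
  morph
}
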