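#' Run a configured analysis pipeline
#'
#' Executes the stages named in a configuration (a YAML file or an
#' equivalent named list) in order and writes a reproducibility manifest
#' (inputs, parameters, seed, package version, and MD5 hashes of every
#' output file) into the output directory. Deterministic stages re-run
#' bit-identically from the same configuration and seed.
#'
#' Supported stages and their parameters (defaults in parentheses match
#' the standard channel protocol):
#' \describe{
#'   \item{simulate_c4}{`n_res_per_chain` (50), `radius`, `pitch`,
#'     `res_start`; writes `c4_structure.pdb`.}
#'   \item{simulate_assembly}{`sever` (false); writes `assembly.pdb`.}
#'   \item{anm}{`structure` (path; defaults to the last simulated
#'     structure), `cutoff` (13), `gamma` (1); writes `anm_modes.tsv`
#'     (eigenvalue spectrum).}
#'   \item{lrt_respond}{`residue`, `direction` ("x", "y", "z" or a
#'     3-vector), `magnitude` (1600); writes `response_<residue>.tsv`
#'     (chain, residue, dx, dy, dz) and a morph PDB.}
#'   \item{experiment}{`residue`, `n` (1000), `magnitude` (1600),
#'     `shoulder` (residue range string "446-465"), `k` (4 or "auto"),
#'     `domains` (named residue range strings); writes
#'     `experiment_<residue>_motions.tsv` and per-cluster morphs.}
#' }
#'
#' @param config path to a YAML configuration file, or a named list with
#'   entries `seed` (integer), `output_dir`, and `stages` (list of stages,
#'   each with a `kind` and its parameters).
#' @param outputDir overrides the configuration's output directory.
#' @return the manifest, invisibly, after writing `manifest.json`.
#' @export
runPipeline <- function(config, outputDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a YAML path or a named list")
  seed <- as.integer(config$seed %||% 1L)
  outDir <- outputDir %||% config$output_dir %||% "."
  stages <- config$stages %||% list()
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  validateStage <- function(st, i) {
    kind <- st$kind %||% stop("stage ", i, " has no 'kind'")
    if (kind == "anm" && !is.null(st$cutoff) && st$cutoff <= 0) {
      stop("invalid value for 'anm.cutoff': must be > 0, got ", st$cutoff)
    }
    if (kind %in% c("lrt_respond", "experiment") && is.null(st$residue)) {
      stop("missing required key '", kind, ".residue'")
    }
    kind
  }

  state <- new.env(parent = emptyenv())
  outputs <- character()
  parseRange <- function(s) {
    if (is.numeric(s)) return(residueSelection(s))
    p <- as.integer(strsplit(s, "-", fixed = TRUE)[[1]])
    residueSelection(p[1]:p[2])
  }
  dirVec <- function(d) {
    if (is.numeric(d)) return(d)
    switch(d, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1),
           stop("unknown direction: ", d))
  }

  for (i in seq_along(stages)) {
    st <- stages[[i]]
    kind <- validateStage(st, i)
    if (kind == "simulate_c4") {
      s <- makeC4Structure(nResPerChain = st$n_res_per_chain %||% 50L,
                           radius = st$radius %||% 10,
                           pitch = st$pitch %||% 1.5,
                           resStart = st$res_start %||% 1L, seed = seed)
      f <- file.path(outDir, "c4_structure.pdb")
      writeStructurePDB(s, f)
      state$structure <- s; state$structurePath <- f
      outputs <- c(outputs, f)
    } else if (kind == "simulate_assembly") {
      asm <- makeCoupledAssembly(seed = seed, sever = isTRUE(st$sever))
      f <- file.path(outDir, "assembly.pdb")
      writeStructurePDB(asm$structure, f)
      state$structure <- asm$structure; state$assembly <- asm
      state$structurePath <- f
      outputs <- c(outputs, f)
    } else if (kind == "anm") {
      s <- if (!is.null(st$structure)) readStructure(st$structure)
           else state$structure %||% stop("anm stage: no structure available")
      state$model <- buildANM(s, cutoff = st$cutoff %||% 13,
                              springModel = uniformSprings(st$gamma %||% 1))
      f <- file.path(outDir, "anm_modes.tsv")
      utils::write.table(
        data.frame(mode = seq_along(modeEigenvalues(state$model)),
                   eigenvalue = modeEigenvalues(state$model)),
        f, sep = "\t", row.names = FALSE, quote = FALSE)
      outputs <- c(outputs, f)
    } else if (kind == "lrt_respond") {
      model <- state$model %||% stop("lrt_respond: run an 'anm' stage first")
      pert <- makeC4Perturbation(model, st$residue, dirVec(st$direction %||% "x"),
                                 magnitude = st$magnitude %||% 1600)
      resp <- lrtResponse(model, pert)
      s <- model@structure
      f <- file.path(outDir, sprintf("response_%s.tsv", st$residue))
      u <- displacements(resp)
      utils::write.table(
        data.frame(chain = chainIds(s), residue = residueNumbers(s),
                   dx = u[, 1], dy = u[, 2], dz = u[, 3]),
        f, sep = "\t", row.names = FALSE, quote = FALSE)
      fm <- file.path(outDir, sprintf("morph_%s.pdb", st$residue))
      nrm <- max(sqrt(rowSums(u^2)))
      writeMorph(s, resp, scale = if (nrm > 0) 5 / nrm else 1,
                 nFrames = st$n_frames %||% 11L, path = fm)
      outputs <- c(outputs, f, fm)
    } else if (kind == "experiment") {
      model <- state$model %||% stop("experiment: run an 'anm' stage first")
      shoulder <- parseRange(st$shoulder %||% "446-465")
      domains <- if (!is.null(st$domains)) lapply(st$domains, parseRange)
                 else list(shoulder = shoulder)
      exp <- runPerturbationExperiment(
        model, st$residue, shoulder, domains,
        nSamples = st$n %||% 1000L, magnitude = st$magnitude %||% 1600,
        k = st$k %||% 4L, seed = seed)
      f <- file.path(outDir, sprintf("experiment_%s_motions.tsv", st$residue))
      rows <- do.call(rbind, lapply(seq_len(exp$cluster@k), function(j) {
        do.call(rbind, lapply(names(exp$motions[[j]]), function(dn) {
          m <- exp$motions[[j]][[dn]]
          data.frame(cluster = j, domain = dn,
                     mx = m$meanDisplacement[1], my = m$meanDisplacement[2],
                     mz = m$meanDisplacement[3], angle_to_z = m$angleToZ,
                     in_plane_rotation = m$inPlaneRotation)
        }))
      }))
      utils::write.table(rows, f, sep = "\t", row.names = FALSE, quote = FALSE)
      outputs <- c(outputs, f)
    } else {
      stop("unknown stage kind: '", kind, "'")
    }
  }

  manifest <- list(
    package = "hcnmech",
    version = as.character(utils::packageVersion("hcnmech")),
    seed = seed,
    stages = stages,
    outputs = lapply(outputs, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
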