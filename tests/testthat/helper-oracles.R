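# Independent oracles and fixture builders used across the test files.
# Everything here is deliberately written the slow, obvious way, separate
# from the package's implementation paths.

# Brute-force ANM Hessian: explicit double loop over all bead pairs.
bruteHessian <- function(xyz, cutoff, gamma = 1) {
  n <- nrow(xyz)
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      rij <- xyz[j, ] - xyz[i, ]
      dij <- sqrt(sum(rij^2))
      if (dij > cutoff) next
      blk <- -(gamma / dij^2) * (rij %o% rij)
      ri <- (3 * i - 2):(3 * i); rj <- (3 * j - 2):(3 * j)
      H[ri, rj] <- blk
      H[ri, ri] <- H[ri, ri] - blk
    }
  }
  H
}

# Dense pseudo-inverse linear-response oracle.
pinvResponse <- function(H, f, tol = 1e-8) {
  e <- eigen(H, symmetric = TRUE)
  keep <- e$values > tol * max(e$values)
  e$vectors[, keep, drop = FALSE] %*%
    ((t(e$vectors[, keep, drop = FALSE]) %*% f) / e$values[keep])
}

# Random connected bead cloud: uniform points in a ball packed densely
# enough (~20 mean contacts at the cutoff, protein-like) that the network
# is connected and mechanically rigid. Regenerates until breadth-first
# search confirms one component and the brute-force Hessian has exactly 6
# zero modes, so downstream tests exercise generic rigid networks.
randomConnectedCloud <- function(n, cutoff = 6, seed = 1) {
  attempt <- 0
  repeat {
    set.seed(seed + 1000 * attempt)
    R <- cutoff * (n / 20)^(1 / 3)  # ball radius for ~20 mean neighbours
    xyz <- matrix(0, n, 3)
    i <- 0
    while (i < n) {
      p <- runif(3, -R, R)
      if (sum(p^2) <= R^2) {
        i <- i + 1
        xyz[i, ] <- p
      }
    }
    if (isConnectedCloud(xyz, cutoff)) {
      ev <- eigen(bruteHessian(xyz, cutoff), symmetric = TRUE,
                  only.values = TRUE)$values
      if (sum(ev < 1e-8 * max(ev)) == 6) return(xyz)
    }
    attempt <- attempt + 1
    if (attempt > 50) stop("could not build a rigid connected cloud")
  }
}

isConnectedCloud <- function(xyz, cutoff) {
  n <- nrow(xyz)
  adj <- as.matrix(dist(xyz)) <= cutoff
  seen <- rep(FALSE, n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(adj[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# Wrap a coordinate matrix as a single-chain bead structure.
cloudStructure <- function(xyz, chain = "A") {
  new("CoarseGrainedStructure",
      coords = xyz,
      chainIds = rep(chain, nrow(xyz)),
      residueNumbers = seq_len(nrow(xyz)),
      residueNames = rep("ALA", nrow(xyz)),
      source = "test cloud")
}

# Textbook one-way ANOVA F statistic.
anovaFOracle <- function(values, groups) {
  groups <- factor(groups)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  dfb <- nlevels(groups) - 1
  dfw <- length(values) - nlevels(groups)
  (ssb / dfb) / (ssw / dfw)
}

# Adjusted Rand index (independent of mclust, used as a cross-check).
ariOracle <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sumIJ <- sum(comb2(tab))
  sumI <- sum(comb2(rowSums(tab)))
  sumJ <- sum(comb2(colSums(tab)))
  nAll <- comb2(sum(tab))
  expected <- sumI * sumJ / nAll
  (sumIJ - expected) / ((sumI + sumJ) / 2 - expected)
}

# Minimal hand-written PDB fixture text.
miniPDBLines <- function() {
  c(paste0("ATOM      1  N   ALA A   1       0.000   0.000   0.000",
           "  1.00  0.00           N"),
    paste0("ATOM      2  CA  ALA A   1       1.500   2.250   3.125",
           "  1.00  0.00           C"),
    paste0("ATOM      3  CA  GLY A   2      -4.750   5.000   6.500",
           "  1.00  0.00           C"),
    "END")
}

# Minimal mmCIF fixture: 4 chains x nRes residues of CA atoms on a grid.
writeSyntheticCIF <- function(path, nRes = 50) {
  hdr <- c("data_synthetic",
           "#",
           "loop_",
           "_atom_site.group_PDB",
           "_atom_site.id",
           "_atom_site.type_symbol",
           "_atom_site.label_atom_id",
           "_atom_site.label_alt_id",
           "_atom_site.label_comp_id",
           "_atom_site.label_asym_id",
           "_atom_site.label_entity_id",
           "_atom_site.label_seq_id",
           "_atom_site.pdbx_PDB_ins_code",
           "_atom_site.Cartn_x",
           "_atom_site.Cartn_y",
           "_atom_site.Cartn_z",
           "_atom_site.occupancy",
           "_atom_site.B_iso_or_equiv",
           "_atom_site.pdbx_formal_charge",
           "_atom_site.auth_seq_id",
           "_atom_site.auth_comp_id",
           "_atom_site.auth_asym_id",
           "_atom_site.auth_atom_id",
           "_atom_site.pdbx_PDB_model_num")
  rows <- character(0)
  id <- 0
  for (ch in c("A", "B", "C", "D")) {
    for (r in seq_len(nRes)) {
      id <- id + 1
      rows <- c(rows, sprintf(
        "ATOM %d C CA . ALA %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d ALA %s CA 1",
        id, ch, r, r * 1.1, match(ch, LETTERS) * 2.0, r * 0.5, r, ch))
    }
  }
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}
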