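test_that("noiseless Boltzmann data invert exactly and degenerate data are flagged", {
  ds <- makeActivationDataset(vHalf = -96.7, kSlope = 8, amplitude = 800,
                              noiseFrac = 0, nCells = 1, seed = 1)[[1]]
  f <- fitBoltzmann(ds)
  expect_equal(f$vHalf, -96.7, tolerance = 1e-6)
  expect_equal(f$kSlope, 8, tolerance = 1e-6)
  expect_equal(f$amplitude, 800, tolerance = 1e-6)
  expect_true(f$converged)

  flat <- data.frame(voltage_mV = seq(-40, -130, by = -10),
                     tail_pA = rep(500, 10))
  expect_warning(fs <- fitBoltzmann(flat), "saturated")
  expect_true(fs$saturated)
  expect_true(is.na(fs$vHalf))

  expect_error(fitBoltzmann(data.frame(voltage_mV = c(-40, -50, -60),
                                       tail_pA = c(1, 2, 3))), ">= 4")
  expect_error(fitBoltzmann(data.frame(voltage_mV = c(-40, -40, -50, -60),
                                       tail_pA = c(1, 1, 2, 3))),
               "one amplitude per voltage")
})

test_that("the fitted optimum has a numerically zero residual gradient", {
  ds <- makeActivationDataset(vHalf = -95, kSlope = 8, amplitude = 900,
                              noiseFrac = 0.02, nCells = 1, seed = 6)[[1]]
  f <- fitBoltzmann(ds)
  rssAt <- function(vh, k, A) {
    sum((ds$tail_pA - A / (1 + exp((ds$voltage_mV - vh) / k)))^2)
  }
  theta <- c(f$vHalf, f$kSlope, f$amplitude)
  model <- function(th) {
    th[3] / (1 + exp((ds$voltage_mV - th[1]) / th[2]))
  }
  r <- ds$tail_pA - model(theta)
  # numerical Jacobian and the scale-free first-order condition: at the
  # optimum the residual vector is orthogonal to every Jacobian column
  for (i in 1:3) {
    h <- 1e-6 * abs(theta[i])
    up <- theta; up[i] <- up[i] + h
    dn <- theta; dn[i] <- dn[i] - h
    Ji <- (model(up) - model(dn)) / (2 * h)
    cosine <- abs(sum(Ji * r)) / (sqrt(sum(Ji^2)) * sqrt(sum(r^2)))
    expect_lt(cosine, 1e-6)
  }
})

test_that("parameter recovery is unbiased across the physiological grid", {
  # 2% amplitude noise; bias of both parameters below 0.5 mV
  for (vh in c(-80, -95, -110)) {
    for (k in c(6, 8, 10)) {
      cells <- makeActivationDataset(vh, k, 1000, noiseFrac = 0.02,
                                     nCells = 25,
                                     seed = 1000 + vh + k)
      fits <- lapply(cells, fitBoltzmann)
      s <- meanActivation(fits)
      expect_lt(abs(s$vHalf["mean"] - vh), 0.5)
      expect_lt(abs(s$kSlope["mean"] - k), 0.5)
    }
  }
})

test_that("activation summaries average per-cell fits", {
  mk <- function(vh) {
    f <- fitBoltzmann(makeActivationDataset(vh, 8, 800, noiseFrac = 0,
                                            seed = 1)[[1]])
    f
  }
  one <- meanActivation(list(mk(-90)))
  expect_equal(unname(one$vHalf["mean"]), -90, tolerance = 1e-6)
  expect_true(is.na(one$vHalf["sem"]))

  two <- meanActivation(list(mk(-90), mk(-100)))
  expect_equal(unname(two$vHalf["mean"]), -95, tolerance = 1e-6)
  expect_equal(unname(two$vHalf["sem"]), 5, tolerance = 1e-6)
})

test_that("exponential kinetics fit recovers tau exactly and under noise", {
  tr <- makeCurrentTrace(I0 = 500, tau = 500, duration = 2500, rate = 5,
                         noiseFrac = 0)
  f <- fitExponential(tr$time_ms, tr$current_pA)
  expect_equal(f$tau, 500, tolerance = 1e-9)
  expect_equal(f$I0, 500, tolerance = 1e-9)
  # value at t = tau is I0 / e
  expect_equal(tr$current_pA[tr$time_ms == 500], 500 / exp(1))

  # deactivation-style tail window with 1% noise: tau within 2%
  tail <- makeCurrentTrace(I0 = 400, tau = 180, duration = 1500, rate = 5,
                           noiseFrac = 0.01, seed = 4)
  fw <- fitExponential(tail$time_ms, tail$current_pA, window = c(0, 900))
  expect_lt(abs(fw$tau - 180) / 180, 0.02)

  expect_error(fitExponential(tr$time_ms, tr$current_pA,
                              window = c(0, 0.8)), ">= 10")
})

test_that("apparent gating free energy follows the worked arithmetic", {
  expect_equal(deltaGApp(0, 8), 0)
  # -96.7 mV at k = 8 mV and 298 K: direct arithmetic oracle
  expect_equal(deltaGApp(-96.7, 8, 298), 1.987e-3 * 298 * (-96.7 / 8),
               tolerance = 1e-12)
  expect_equal(deltaGApp(-96.7, 8, 298), -7.158, tolerance = 1e-3)
  # invariance to a common rescaling of voltage units
  expect_equal(deltaGApp(-967, 80), deltaGApp(-96.7, 8))
  expect_error(deltaGApp(-90, 0), "nonzero")
})

test_that("mutant cycles are additive, recover injected coupling, and are symmetric", {
  et0 <- makeEnergyTable(coupling = 0)
  mc0 <- mutantCycle(et0$wt, et0$single1, et0$single2, et0$double)
  expect_equal(mc0$ddG, 0)
  expect_false(mc0$coupled)

  et <- makeEnergyTable(coupling = -2.0)
  mc <- mutantCycle(et$wt, et$single1, et$single2, et$double)
  expect_equal(mc$ddG, -2.0)
  expect_true(mc$coupled)
  # flipping the injected coupling flips ddG
  etp <- makeEnergyTable(coupling = 2.0)
  expect_equal(mutantCycle(etp$wt, etp$single1, etp$single2,
                           etp$double)$ddG, 2.0)

  # swapping the single mutants leaves ddG unchanged
  mcSwap <- mutantCycle(et$wt, et$single2, et$single1, et$double)
  expect_equal(mcSwap$ddG, mc$ddG)

  # the two routes around the cycle differ by exactly +/- ddG
  path1 <- mc$dGp$dGp[mc$dGp$from == "wt" & mc$dGp$to == "single1"] +
    mc$dGp$dGp[mc$dGp$from == "single1"]
  path2 <- mc$dGp$dGp[mc$dGp$from == "wt" & mc$dGp$to == "single2"] +
    mc$dGp$dGp[mc$dGp$from == "single2"]
  expect_equal(path1, path2, tolerance = 1e-12)
  expect_equal(mc$dGp$dGp[3] - mc$dGp$dGp[2], mc$ddG, tolerance = 1e-12)

  # invariant to adding a constant to every dG_app
  shift <- function(ce, c0) {
    constructEnergetics(ce$label, (ce$dGApp + c0) * ce$kSlope /
                          (1.987e-3 * ce$temperature), ce$kSlope,
                        ce$temperature)
  }
  mcS <- mutantCycle(shift(et$wt, 3), shift(et$single1, 3),
                     shift(et$single2, 3), shift(et$double, 3))
  expect_equal(mcS$ddG, mc$ddG, tolerance = 1e-9)

  bad <- constructEnergetics("cold", -90, 8, temperature = 278)
  expect_error(mutantCycle(et$wt, et$single1, et$single2, bad),
               "temperature")
})

test_that("group comparisons match a textbook F statistic and detect real shifts", {
  # two identical groups (with internal scatter): no significance
  same <- compareGroups(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_gt(same$p.value, 0.05)
  expect_false(same$significant)

  # power: clearly separated normals are significant for every seed tried
  for (seed in 1:10) {
    set.seed(seed)
    v <- c(rnorm(20, 0, 1), rnorm(20, 5, 1))
    cmp <- compareGroups(v, rep(c("g1", "g2"), each = 20))
    expect_lt(cmp$p.value, 0.05)
  }

  # three balanced groups: F equals the independently coded formula
  set.seed(77)
  v3 <- c(rnorm(15, 0), rnorm(15, 1), rnorm(15, 3))
  g3 <- rep(c("x", "y", "z"), each = 15)
  cmp3 <- compareGroups(v3, g3)
  expect_equal(cmp3$statistic, anovaFOracle(v3, g3), tolerance = 1e-10)
  expect_true(!is.null(cmp3$pairwise))
  expect_equal(nrow(cmp3$pairwise), 3L)

  # degenerate variance is flagged rather than crashing
  dg <- compareGroups(c(1, 1, 2, 2), rep(c("a", "b"), each = 2))
  expect_true(dg$degenerate)
  expect_error(compareGroups(1:5, c("a", "a", "a", "a", "b")), "n >= 2")
})

test_that("cAMP shifts difference mean V1/2 with quadrature errors", {
  mkSummary <- function(vh, sem) {
    structure(list(n = 10, vHalf = c(mean = vh, sem = sem),
                   kSlope = c(mean = 8, sem = 0.2)),
              class = "ActivationSummary")
  }
  expect_equal(campShift(mkSummary(-96.7, 1), mkSummary(-96.7, 1))$shift_mV, 0)
  sh <- campShift(mkSummary(-96.7, 1), mkSummary(-81.0, 1))
  expect_equal(sh$shift_mV, 15.7)
  expect_equal(sh$sem_mV, sqrt(2))
})
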