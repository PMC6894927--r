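# Gas constant in kcal/(mol K)
R_KCAL <- 1.987e-3

#' Voltage-step protocol description
#'
#' Defaults describe the HCN2 whole-cell protocol: holding -30 mV (1 s),
#' steps -40 to -130 mV in 10 mV intervals (5 s), tails at -40 mV (5 s).
#' Presets for the three isoforms are available via `isoform`.
#'
#' @param holding_mV holding potential.
#' @param stepStart_mV,stepEnd_mV first and last step potential.
#' @param stepInterval_mV signed step increment.
#' @param stepDuration_s step duration.
#' @param tail_mV tail potential.
#' @param tailDuration_s tail duration.
#' @param isoform optional "HCN1", "HCN2" or "HCN4" preset overriding the
#'   other arguments.
#' @return list of class `VoltageProtocol` with a `voltages` element
#'   enumerating the step sequence.
#' @export
voltageProtocol <- function(holding_mV = -30, stepStart_mV = -40,
                            stepEnd_mV = -130, stepInterval_mV = -10,
                            stepDuration_s = 5, tail_mV = -40,
                            tailDuration_s = 5, isoform = NULL) {
  if (!is.null(isoform)) {
    p <- switch(isoform,
      HCN1 = list(-30, -20, -120, -10, 3.5, -40, 3),
      HCN2 = list(-30, -40, -130, -10, 5, -40, 5),
      HCN4 = list(-30, -30, -165, -15, 5, -40, 5),
      stop("unknown isoform: ", isoform))
    holding_mV <- p[[1]]; stepStart_mV <- p[[2]]; stepEnd_mV <- p[[3]]
    stepInterval_mV <- p[[4]]; stepDuration_s <- p[[5]]
    tail_mV <- p[[6]]; tailDuration_s <- p[[7]]
  }
  if (stepDuration_s <= 0 || tailDuration_s <= 0) stop("durations must be > 0")
  if (stepInterval_mV == 0) stop("step interval must be nonzero")
  voltages <- seq(stepStart_mV, stepEnd_mV, by = stepInterval_mV)
  structure(list(holding_mV = holding_mV, stepStart_mV = stepStart_mV,
                 stepEnd_mV = stepEnd_mV, stepInterval_mV = stepInterval_mV,
                 stepDuration_s = stepDuration_s, tail_mV = tail_mV,
                 tailDuration_s = tailDuration_s, voltages = voltages),
            class = "VoltageProtocol")
}

#' Fit a Boltzmann activation curve to tail-current amplitudes
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `I(V) = A / (1 + exp((V - Vhalf) / k))` to maximal tail current
#' amplitude against step voltage, on the raw amplitudes with free A.
#' Starting values: Vhalf from the voltage of half-maximal observed
#' amplitude, k from the 25-75% amplitude voltage span divided by 2.2, A
#' from the maximum; |k| is bounded to (0.5, 50) mV. V_half is stored
#' signed (negative for hyperpolarization-activated channels); the
#' literature often prints magnitudes.
#'
#' @param dataset data.frame with columns `voltage_mV` and `tail_pA` (one
#'   amplitude per voltage for one cell); extra columns such as `cell_id`,
#'   `construct`, `condition` are carried through.
#' @return list of class `BoltzmannFit`: `vHalf`, `kSlope`, `amplitude`
#'   (all with standard errors in `se`), `rss`, `sigma`, `converged`,
#'   `saturated`, `fitted` (function of voltage), plus any carried labels.
#' @export
fitBoltzmann <- function(dataset) {
  need <- c("voltage_mV", "tail_pA")
  if (!all(need %in% names(dataset))) {
    stop("dataset needs columns voltage_mV and tail_pA")
  }
  v <- dataset$voltage_mV; i <- dataset$tail_pA
  if (anyDuplicated(v)) stop("one amplitude per voltage required")
  if (length(v) < 4) stop("need >= 4 distinct voltages to fit")
  if (!all(is.finite(i))) stop("amplitudes must be finite")

  out <- list(vHalf = NA_real_, kSlope = NA_real_, amplitude = NA_real_,
              se = c(vHalf = NA_real_, kSlope = NA_real_,
                     amplitude = NA_real_),
              rss = NA_real_, sigma = NA_real_, converged = FALSE,
              saturated = FALSE)
  for (lab in intersect(c("cell_id", "construct", "condition"),
                        names(dataset))) {
    out[[lab]] <- dataset[[lab]][1]
  }

  span <- max(i) - min(i)
  if (span < 0.05 * max(abs(i), .Machine$double.eps)) {
    out$saturated <- TRUE
    warning("saturated data: amplitudes show no inflection in the ",
            "voltage range; Boltzmann fit not attempted")
    class(out) <- "BoltzmannFit"
    return(out)
  }

  A0 <- max(i)
  y <- (i - min(i)) / span
  ord <- order(v)
  vq <- function(level) {
    stats::approx(y[ord], v[ord], xout = level, ties = mean)$y
  }
  vh0 <- vq(0.5)
  k0 <- (vq(0.25) - vq(0.75)) / 2.2
  if (!is.finite(vh0)) vh0 <- stats::median(v)
  if (!is.finite(k0) || abs(k0) < 0.5) k0 <- sign(k0 + 1e-9) * 6
  lower <- if (k0 >= 0) c(-Inf, 0.5, 0) else c(-Inf, -50, 0)
  upper <- if (k0 >= 0) c(Inf, 50, Inf) else c(Inf, -0.5, Inf)

  df <- data.frame(V = v, I = i)
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ A / (1 + exp((V - vh) / k)), data = df,
                      start = list(vh = vh0, k = k0, A = A0),
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-14, ptol = 1e-14,
                        gtol = 1e-14)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    stop("Boltzmann fit did not converge: ", conditionMessage(fit),
         " (starting values vh=", signif(vh0, 4), ", k=", signif(k0, 3), ")")
  }

  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  out$vHalf <- unname(cf["vh"]); out$kSlope <- unname(cf["k"])
  out$amplitude <- unname(cf["A"])
  out$se <- c(vHalf = unname(se["vh"]), kSlope = unname(se["k"]),
              amplitude = unname(se["A"]))
  out$rss <- sum(stats::resid(fit)^2)
  out$sigma <- summary(fit)$sigma
  out$converged <- TRUE
  if (out$vHalf < min(v) || out$vHalf > max(v)) out$saturated <- TRUE
  out$fitted <- function(V) {
    out$amplitude / (1 + exp((V - out$vHalf) / out$kSlope))
  }
  class(out) <- "BoltzmannFit"
  out
}

#' @export
print.BoltzmannFit <- function(x, ...) {
  cat("BoltzmannFit: V1/2 =", signif(x$vHalf, 5), "mV, k =",
      signif(x$kSlope, 4), "mV, A =", signif(x$amplitude, 5), "pA",
      if (isTRUE(x$saturated)) "(saturated)" else "", "\n")
  invisible(x)
}

#' Average Boltzmann parameters across cells
#'
#' Mean activation parameters are obtained by fitting each cell
#' individually and then averaging the fitted values, not by fitting the
#' mean curve.
#'
#' @param fits list of [fitBoltzmann()] results.
#' @return list of class `ActivationSummary`: `n`, `vHalf` and `kSlope`
#'   (each mean + SEM; SEM is NA for a single cell).
#' @export
meanActivation <- function(fits) {
  if (length(fits) < 1) stop("need >= 1 fit")
  vh <- vapply(fits, `[[`, numeric(1), "vHalf")
  k <- vapply(fits, `[[`, numeric(1), "kSlope")
  n <- length(fits)
  semf <- function(x) if (n > 1) stats::sd(x) / sqrt(n) else NA_real_
  structure(list(n = n,
                 vHalf = c(mean = mean(vh), sem = semf(vh)),
                 kSlope = c(mean = mean(k), sem = semf(k))),
            class = "ActivationSummary")
}

#' Fit a mono-exponential to a current trace
#'
#' Least-squares fit of `I(t) = I0 exp(-t / tau)` on the chosen window;
#' time is taken relative to the window start, so I0 is the amplitude at
#' the start of the window (e.g. at the beginning of a tail for
#' deactivation).
#'
#' @param time,current numeric vectors (time in ms).
#' @param window `c(tStart, tEnd)` in the units of `time`; default full
#'   trace.
#' @return list of class `KineticsFit`: `tau` (ms), `I0`, `window`, `rss`,
#'   `sigma`, `converged`.
#' @export
fitExponential <- function(time, current, window = range(time)) {
  keep <- time >= window[1] & time <= window[2]
  if (sum(keep) < 10) {
    stop("fit window contains ", sum(keep), " samples; >= 10 required")
  }
  t <- time[keep] - window[1]
  i <- current[keep]

  i0 <- i[1]
  tl <- i[length(i)]
  tau0 <- if (is.finite(log(abs(i0 / tl))) && abs(i0) > abs(tl) && tl * i0 > 0) {
    (t[length(t)] - t[1]) / log(abs(i0 / tl))
  } else {
    (t[length(t)] - t[1]) / 3
  }
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- (t[length(t)] - t[1]) / 3

  df <- data.frame(t = t, I = i)
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ I0 * exp(-t / tau), data = df,
                      start = list(I0 = i0, tau = tau0),
                      lower = c(-Inf, .Machine$double.eps),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-14, ptol = 1e-14,
                        gtol = 1e-14)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    stop("exponential fit did not converge: ", conditionMessage(fit))
  }
  cf <- stats::coef(fit)
  structure(list(tau = unname(cf["tau"]), I0 = unname(cf["I0"]),
                 window = window, rss = sum(stats::resid(fit)^2),
                 sigma = summary(fit)$sigma, converged = TRUE),
            class = "KineticsFit")
}

#' Apparent gating free energy from Boltzmann parameters
#'
#' `dG_app = (R T / k) * V_half` with R = 1.987e-3 kcal/(mol K); V_half and
#' k must be in the same voltage units so their ratio is dimensionless, and
#' the result is in kcal/mol. Signed V_half must be used (negative for
#' hyperpolarization-activated channels).
#'
#' @param vHalf half-activation voltage, mV (signed).
#' @param kSlope inverse slope factor, mV (nonzero).
#' @param temperature Kelvin; default 298 (room temperature).
#' @return apparent free energy of activation, kcal/mol.
#' @export
deltaGApp <- function(vHalf, kSlope, temperature = 298) {
  if (any(kSlope == 0)) stop("inverse slope factor k must be nonzero")
  (R_KCAL * temperature / kSlope) * vHalf
}

#' Per-construct gating energetics
#'
#' @param label construct name.
#' @param vHalf half-activation voltage, mV (signed).
#' @param kSlope inverse slope factor, mV.
#' @param temperature Kelvin.
#' @return list of class `ConstructEnergetics` with `dGApp` (kcal/mol).
#' @export
constructEnergetics <- function(label, vHalf, kSlope, temperature = 298) {
  structure(list(label = label, vHalf = vHalf, kSlope = kSlope,
                 temperature = temperature,
                 dGApp = deltaGApp(vHalf, kSlope, temperature)),
            class = "ConstructEnergetics")
}

#' Thermodynamic double-mutant cycle
#'
#' Perturbation free energies `dGp = delta (RT/k) V_half` along each edge of
#' the wt / single1 / single2 / double cycle, and the non-additivity
#' (coupling) energy
#' `ddG = dG_app(wt) + dG_app(double) - dG_app(single1) - dG_app(single2)`.
#' Equal perturbation energies along parallel edges (ddG = 0) mean the two
#' sites do not interact; `|ddG|` above `couplingThreshold` flags the pair
#' as coupled.
#'
#' @param wt,single1,single2,double [constructEnergetics()] objects at a
#'   common temperature.
#' @param couplingThreshold kcal/mol (default 1).
#' @return list of class `MutantCycle`: `ddG`, `dGp` (per-edge
#'   data.frame), `coupled`, `constructs`.
#' @export
mutantCycle <- function(wt, single1, single2, double, couplingThreshold = 1) {
  cons <- list(wt = wt, single1 = single1, single2 = single2, double = double)
  temps <- vapply(cons, `[[`, numeric(1), "temperature")
  if (length(unique(temps)) != 1) {
    stop("all four constructs must share one temperature; got ",
         paste(unique(temps), collapse = ", "))
  }
  g <- vapply(cons, `[[`, numeric(1), "dGApp")
  dGp <- data.frame(
    from = c("wt", "wt", "single1", "single2"),
    to = c("single1", "single2", "double", "double"),
    dGp = c(g["single1"] - g["wt"], g["single2"] - g["wt"],
            g["double"] - g["single1"], g["double"] - g["single2"])
  )
  ddG <- unname(g["wt"] + g["double"] - g["single1"] - g["single2"])
  structure(list(ddG = ddG, dGp = dGp,
                 coupled = abs(ddG) > couplingThreshold,
                 couplingThreshold = couplingThreshold, constructs = cons),
            class = "MutantCycle")
}

#' @export
print.MutantCycle <- function(x, ...) {
  cat("MutantCycle: ddG =", signif(x$ddG, 4), "kcal/mol ->",
      if (x$coupled) "coupled" else "not coupled",
      "(threshold", x$couplingThreshold, "kcal/mol)\n")
  print(x$dGp, row.names = FALSE)
  invisible(x)
}

#' Compare groups of values (one-way ANOVA + Fisher's LSD, or t-test)
#'
#' Two groups are compared with Student's t-test; three or more with
#' one-way ANOVA followed, when the ANOVA is significant at alpha, by
#' Fisher's least-significant-difference pairwise tests on the pooled
#' residual variance (no additional multiple-testing correction, matching
#' common electrophysiology practice; a documented limitation).
#'
#' @param values numeric vector.
#' @param groups factor or character vector of group labels.
#' @param alpha significance level (default 0.05).
#' @return list of class `GroupComparison`: `method`, `statistic`,
#'   `p.value`, `pairwise` (data.frame, NULL unless LSD ran), `alpha`,
#'   `significant`, `degenerate`.
#' @export
compareGroups <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  ns <- table(groups)
  if (any(ns < 2)) stop("each group needs n >= 2")

  degenerate <- all(tapply(values, groups, stats::var) == 0)
  if (degenerate) {
    means <- tapply(values, groups, mean)
    identicalMeans <- length(unique(means)) == 1
    return(structure(list(method = "degenerate", statistic = NA_real_,
                          p.value = if (identicalMeans) 1 else 0,
                          pairwise = NULL, alpha = alpha,
                          significant = !identicalMeans, degenerate = TRUE),
                     class = "GroupComparison"))
  }

  if (nlevels(groups) == 2) {
    tt <- stats::t.test(values ~ groups, var.equal = TRUE)
    return(structure(list(method = "Student t-test",
                          statistic = unname(tt$statistic),
                          p.value = tt$p.value, pairwise = NULL,
                          alpha = alpha,
                          significant = tt$p.value < alpha,
                          degenerate = FALSE),
                     class = "GroupComparison"))
  }

  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  Fval <- an[["F value"]][1]
  p <- an[["Pr(>F)"]][1]
  pairwise <- NULL
  if (p < alpha) {
    mse <- an[["Mean Sq"]][2]
    dfres <- an[["Df"]][2]
    lv <- levels(groups)
    comb <- utils::combn(lv, 2)
    means <- tapply(values, groups, mean)
    pairwise <- data.frame(groupA = comb[1, ], groupB = comb[2, ],
                           diff = NA_real_, t = NA_real_, p = NA_real_)
    for (r in seq_len(ncol(comb))) {
      a <- comb[1, r]; b <- comb[2, r]
      d <- means[a] - means[b]
      se <- sqrt(mse * (1 / ns[a] + 1 / ns[b]))
      tval <- d / se
      pairwise$diff[r] <- d
      pairwise$t[r] <- tval
      pairwise$p[r] <- 2 * stats::pt(-abs(tval), dfres)
    }
  }
  structure(list(method = "one-way ANOVA + Fisher LSD", statistic = Fval,
                 p.value = p, pairwise = pairwise, alpha = alpha,
                 significant = p < alpha, degenerate = FALSE),
            class = "GroupComparison")
}

#' cAMP-induced shift of the half-activation voltage
#'
#' Difference of mean V_half between a cAMP and a control summary
#' (cAMP minus control; positive = depolarizing shift), with the SEM
#' propagated in quadrature.
#'
#' @param summaryControl,summaryCAMP [meanActivation()] summaries.
#' @return list with `shift_mV` and `sem_mV`.
#' @export
campShift <- function(summaryControl, summaryCAMP) {
  shift <- unname(summaryCAMP$vHalf["mean"] - summaryControl$vHalf["mean"])
  sem <- sqrt(sum(c(summaryCAMP$vHalf["sem"],
                    summaryControl$vHalf["sem"])^2))
  list(shift_mV = shift, sem_mV = unname(sem))
}
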