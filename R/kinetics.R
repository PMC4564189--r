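# Pre-steady-state kinetic analysis: gel-product quantitation, burst fits,
# hyperbolic kobs-[dNTP] fits, catalytic efficiencies and their comparisons.

#' Product concentration from gel band signals
#'
#' The fraction of extended primer, corrected for substrate running as
#' product in the no-polymerase control (zero point), scaled by the
#' primer/template concentration and floored at 0.
#'
#' @param extended_signal,unextended_signal band intensities (>= 0, not both
#'   zero).
#' @param zero_point_fraction extended fraction in the absence of polymerase.
#' @param template_conc primer/template concentration, nM.
#' @return product, nM.
#' @export
product_from_gel <- function(extended_signal, unextended_signal,
                             zero_point_fraction = 0, template_conc) {
  if (any(extended_signal < 0) || any(unextended_signal < 0))
    stop("product_from_gel: signals must be >= 0")
  tot <- extended_signal + unextended_signal
  if (any(tot == 0)) stop("product_from_gel: both signals zero")
  pmax(0, (extended_signal / tot - zero_point_fraction) * template_conc)
}

#' Fit the single-exponential burst equation
#'
#' Nonlinear least squares for `y(t) = A (1 - exp(-kobs t)) + C` with
#' `A, kobs >= 0`.  Initialization: `A0 = max(y) - min(y)`, `C0` = earliest
#' point, `kobs0` from log-linearizing the early approach to the plateau.
#' Non-convergence (or a kobs collapsed onto the 0 boundary, as for constant
#' data) is flagged; parameters are still returned.
#'
#' @param timecourse data frame with columns `time_s` and `product_nM`
#'   (e.g. from [simulate_timecourse()]), or a numeric time vector.
#' @param product product concentrations (nM) when `timecourse` is a vector.
#' @param weights optional least-squares weights (default unweighted).
#' @return `burst_fit`: `A`, `kobs`, `C`, `sse`, `converged`, `flagged`.
#' @export
fit_burst <- function(timecourse, product = NULL, weights = NULL) {
  if (is.data.frame(timecourse)) {
    t <- timecourse$time_s; y <- timecourse$product_nM
  } else {
    t <- timecourse; y <- product
  }
  if (length(t) < 4) stop("fit_burst: need at least 4 time points")
  if (length(unique(t)) < 2) stop("fit_burst: need at least 2 distinct times")
  if (is.null(weights)) weights <- rep(1, length(t))

  C0 <- y[which.min(t)]
  A0 <- max(y) - min(y)
  k0 <- {
    plateau <- C0 + A0
    frac <- 1 - (y - C0) / max(A0, .Machine$double.eps)
    ok <- which(frac > 0.05 & frac < 1 & t > min(t))
    if (length(ok) >= 2) {
      sl <- .ols_slope(t[ok], log(frac[ok]))
      if (is.finite(sl) && sl < 0) -sl else 1 / max(stats::median(t[t > 0]), 1e-6)
    } else 1 / max(stats::median(t[t > 0]), 1e-6)
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * (1 - exp(-kobs * t)) + C,
      start = list(A = max(A0, 1e-8), kobs = max(k0, 1e-8), C = C0),
      lower = c(A = 0, kobs = 0, C = -Inf),
      weights = weights,
      control = minpack.lm::nls.lm.control(maxiter = 500,
                                           ftol = 1e-12, ptol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(A = 0, kobs = 0, C = mean(y),
                          sse = sum(weights * (y - mean(y))^2),
                          converged = FALSE, flagged = TRUE),
                     class = "burst_fit"))
  }
  p <- stats::coef(fit)
  conv <- fit$convInfo$isConv %||% TRUE
  flagged <- !conv || p[["kobs"]] < 1e-8
  structure(list(A = unname(p["A"]), kobs = unname(p["kobs"]),
                 C = unname(p["C"]),
                 sse = sum(weights * stats::resid(fit)^2),
                 converged = conv, flagged = flagged),
            class = "burst_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.burst_fit <- function(x, ...) {
  cat(sprintf("burst fit: A = %.4g nM, kobs = %.4g 1/s, C = %.4g nM (SSE %.3g)%s\n",
              x$A, x$kobs, x$C, x$sse, if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Fit the hyperbolic kobs-[dNTP] relation
#'
#' Nonlinear least squares for `kobs = kpol [dNTP] / (Kd + [dNTP])`.
#' Initialization: `kpol0 = max(kobs)`, `Kd0` = concentration nearest the
#' half-maximal kobs.  Standard errors come from the covariance of the fit.
#' A Kd exceeding 10x the largest concentration is flagged as poorly
#' constrained (the regime reported as lower bounds such as ">300").
#'
#' @param conc dNTP concentrations, uM (>= 3 distinct values).
#' @param kobs observed rate constants, 1/s.
#' @return `mm_fit`: `kpol`, `Kd`, `kpol_se`, `Kd_se`, `sse`,
#'   `poorly_constrained`, `converged`.
#' @export
fit_mm <- function(conc, kobs) {
  if (length(unique(conc)) < 3)
    stop("fit_mm: need at least 3 distinct concentrations")
  kpol0 <- max(kobs)
  Kd0 <- conc[which.min(abs(kobs - kpol0 / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      kobs ~ kpol * conc / (Kd + conc),
      start = list(kpol = max(kpol0, 1e-8), Kd = max(Kd0, 1e-6)),
      lower = c(kpol = 0, Kd = 0),
      control = minpack.lm::nls.lm.control(maxiter = 500,
                                           ftol = 1e-12, ptol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(kpol = NA_real_, Kd = NA_real_, kpol_se = NA_real_,
                          Kd_se = NA_real_, sse = NA_real_,
                          poorly_constrained = TRUE, converged = FALSE),
                     class = "mm_fit"))
  p <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(kpol = NA_real_, Kd = NA_real_))
  structure(list(kpol = unname(p["kpol"]), Kd = unname(p["Kd"]),
                 kpol_se = unname(se["kpol"]), Kd_se = unname(se["Kd"]),
                 sse = sum(stats::resid(fit)^2),
                 poorly_constrained = unname(p["Kd"]) > 10 * max(conc),
                 converged = fit$convInfo$isConv %||% TRUE),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("hyperbolic fit: kpol = %.4g +/- %.2g 1/s, Kd = %.4g +/- %.2g uM%s\n",
              x$kpol, x$kpol_se, x$Kd, x$Kd_se,
              if (x$poorly_constrained) " [poorly constrained]" else ""))
  invisible(x)
}

# significant figures used for reporting efficiencies: 3 at >= 1000, else 2
.report_sf <- function(x) ifelse(abs(x) >= 1000, 3L, 2L)

#' Catalytic efficiency kpol/Kd
#'
#' `kpol / (Kd * 1e-6)` in 1/(M s), with Kd in uM.  The unrounded value is
#' retained alongside the value rounded for reporting (3 significant figures
#' at or above 1,000, otherwise 2, matching the usual table precision).
#'
#' @param kpol maximal polymerization rate constant, 1/s (or an `mm_fit`).
#' @param Kd apparent dNTP dissociation constant, uM.
#' @param sig_figs override the reporting precision.
#' @return list: `value` (unrounded), `reported`, `sig_figs`.
#' @export
efficiency <- function(kpol, Kd = NULL, sig_figs = NULL) {
  if (inherits(kpol, "mm_fit")) { Kd <- kpol$Kd; kpol <- kpol$kpol }
  if (is.null(Kd) || Kd <= 0) stop("efficiency: Kd must be > 0")
  if (kpol < 0) stop("efficiency: kpol must be >= 0")
  value <- kpol / (Kd * 1e-6)
  sf <- if (is.null(sig_figs)) .report_sf(value) else as.integer(sig_figs)
  list(value = value, reported = signif(value, sf), sig_figs = sf)
}

#' Fold change between two catalytic efficiencies
#'
#' @param eff_a,eff_b efficiencies (numbers or [efficiency()] results);
#'   `eff_b` must be > 0.
#' @param sig_figs significant figures for the reported fold change.
#' @return rounded fold change `eff_a / eff_b`.
#' @export
efficiency_ratio <- function(eff_a, eff_b, sig_figs = 2) {
  if (is.list(eff_a)) eff_a <- eff_a$value
  if (is.list(eff_b)) eff_b <- eff_b$value
  if (eff_b <= 0) stop("efficiency_ratio: zero denominator")
  signif(eff_a / eff_b, sig_figs)
}

#' Published nucleotide-incorporation kinetic constants bundled with the
#' package
#'
#' Kd (uM), kpol (1/s) and the reported catalytic efficiency (1/(M s)) for
#' wild-type Pol IV and Pol IV-T120P across undamaged and lesion-containing
#' primer/templates (O6-methyl-dG, the stable N3-methyl-dA mimic 3d-medA,
#' and an abasic site).  `kd_qualifier` marks lower-bound (">") or
#' approximate ("~") entries; rows with unmeasurable kinetics are NA.
#'
#' @return data frame with columns `enzyme`, `template`, `lesion`, `dntp`,
#'   `kd_um`, `kd_qualifier`, `kpol_s`, `kpol_qualifier`, `reported_eff`,
#'   `eff_sig_figs`.
#' @export
kinetic_constants <- function() {
  path <- system.file("extdata", "pol4_kinetic_constants_published.csv",
                      package = "flowstretch", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Consistency report for a table of kinetic constants
#'
#' Recomputes each catalytic efficiency from its Kd and kpol, rounds it to
#' the precision at which the tabulated efficiency is reported, and flags
#' rows where the two disagree by more than one unit in the last reported
#' significant digit.  Rows with missing constants are skipped
#' (`consistent = NA`).
#'
#' @param tbl data frame in the [kinetic_constants()] schema.
#' @return the table with added columns `recomputed_eff`,
#'   `recomputed_rounded`, `consistent`.
#' @export
efficiency_report <- function(tbl = kinetic_constants()) {
  need <- c("kd_um", "kpol_s", "reported_eff", "eff_sig_figs")
  if (!all(need %in% names(tbl)))
    stop("efficiency_report: missing columns: ",
         paste(setdiff(need, names(tbl)), collapse = ", "))
  tbl$recomputed_eff <- NA_real_
  tbl$recomputed_rounded <- NA_real_
  tbl$consistent <- NA
  for (k in seq_len(nrow(tbl))) {
    kd <- tbl$kd_um[k]; kp <- tbl$kpol_s[k]
    rep_eff <- tbl$reported_eff[k]; sf <- tbl$eff_sig_figs[k]
    if (any(is.na(c(kd, kp, rep_eff, sf)))) next
    val <- kp / (kd * 1e-6)
    rounded <- signif(val, sf)
    ulp <- 10^(floor(log10(abs(rep_eff))) - (sf - 1))
    tbl$recomputed_eff[k] <- val
    tbl$recomputed_rounded[k] <- rounded
    tbl$consistent[k] <- abs(rounded - rep_eff) <= ulp + 1e-9
  }
  tbl
}

#' Screen efficiencies for misincorporation
#'
#' Incorporation whose catalytic efficiency is below 10% of the
#' correct-pair efficiency on the same template is labeled misincorporation.
#'
#' @param eff efficiencies to screen (1/(M s)).
#' @param eff_correct efficiency of the correct incorporation.
#' @param threshold fraction of the correct efficiency (default 0.10).
#' @return logical vector, TRUE where misincorporation.
#' @export
misincorporation_flags <- function(eff, eff_correct, threshold = 0.10) {
  if (eff_correct <= 0) stop("misincorporation_flags: eff_correct must be > 0")
  eff < threshold * eff_correct
}
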