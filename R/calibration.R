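# Polymer calibration: convert bead displacement (nm) at constant force into
# nucleotides converted from coiled ssDNA to extended dsDNA.  At ~3 pN the
# extension per base pair of dsDNA (worm-like chain) exceeds the extension per
# nucleotide of ssDNA (freely-jointed chain), so synthesis moves the bead
# downstream; the gain per nucleotide is the calibration constant.

# Boltzmann constant in pN nm / K
.kB <- 1.380649e-2

#' Force-extension parameters for the tether
#'
#' Bundles the working force and the standard polymer constants used to map
#' bead displacement to nucleotides synthesized.  The polymer constants are
#' ordinary literature values for dsDNA (worm-like chain, persistence length
#' 50 nm, 0.34 nm contour per bp) and ssDNA (freely-jointed chain, Kuhn
#' length 1.5 nm, 0.56 nm contour per nt); a user-supplied scalar calibration
#' via [calibration()] bypasses the polymer physics entirely.
#'
#' @param force applied stretching force in pN (default 3, the constant
#'   laminar-flow force of the assay).
#' @param temperature temperature in K.
#' @param ds_contour_per_bp dsDNA contour length per base pair, nm.
#' @param ds_persistence dsDNA persistence length, nm.
#' @param ss_contour_per_nt ssDNA contour length per nucleotide, nm.
#' @param ss_kuhn ssDNA Kuhn length, nm.
#' @return object of class `fe_params`.
#' @export
fe_params <- function(force = 3.0, temperature = 298,
                      ds_contour_per_bp = 0.34, ds_persistence = 50,
                      ss_contour_per_nt = 0.56, ss_kuhn = 1.5) {
  p <- list(force = force, temperature = temperature,
            ds_contour_per_bp = ds_contour_per_bp,
            ds_persistence = ds_persistence,
            ss_contour_per_nt = ss_contour_per_nt,
            ss_kuhn = ss_kuhn)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("fe_params: '", nm, "' must be a single finite number")
  }
  if (p$force < 0) stop("fe_params: force must be >= 0")
  if (p$temperature <= 0) stop("fe_params: temperature must be > 0")
  lens <- c("ds_contour_per_bp", "ds_persistence", "ss_contour_per_nt", "ss_kuhn")
  if (any(unlist(p[lens]) <= 0)) stop("fe_params: lengths must be > 0")
  structure(p, class = "fe_params")
}

#' Relative extension of dsDNA under force (Marko-Siggia worm-like chain)
#'
#' Solves the interpolation formula
#' \deqn{F = (k_B T / P) [ 1/(4(1-z)^2) - 1/4 + z ]}
#' for the fractional extension z in (0, 1) at the given force.  The root is
#' bracketed on (0, 1) and refined until the force residual is below
#' 1e-9 pN.
#'
#' @param params an [fe_params()] object.
#' @return fractional extension z in \[0, 1).
#' @export
ds_extension_fraction <- function(params) {
  stopifnot(inherits(params, "fe_params"))
  F <- params$force
  if (F == 0) return(0)
  kT <- .kB * params$temperature
  P <- params$ds_persistence
  f_of_z <- function(z) (kT / P) * (1 / (4 * (1 - z)^2) - 0.25 + z) - F
  hi <- 1 - 1e-12
  z <- stats::uniroot(f_of_z, lower = 1e-14, upper = hi,
                      tol = .Machine$double.eps^0.75)$root
  # polish by bisection until |dF| < 1e-9 pN
  lo <- max(z - 1e-6, 0); up <- min(z + 1e-6, hi)
  if (f_of_z(lo) > 0 || f_of_z(up) < 0) { lo <- 0; up <- hi }
  while (abs(f_of_z(z)) > 1e-9 && (up - lo) > .Machine$double.eps) {
    if (f_of_z(z) > 0) up <- z else lo <- z
    z <- (lo + up) / 2
  }
  z
}

#' Extension per nucleotide of ssDNA under force (freely-jointed chain)
#'
#' Langevin-function extension of an FJC with Kuhn length b:
#' `ss_contour_per_nt * (coth(Fb/kT) - kT/(Fb))`, with the `F -> 0` limit 0.
#'
#' @param params an [fe_params()] object.
#' @return extension per nucleotide in nm.
#' @export
ss_extension_per_nt <- function(params) {
  stopifnot(inherits(params, "fe_params"))
  F <- params$force
  if (F == 0) return(0)
  kT <- .kB * params$temperature
  x <- F * params$ss_kuhn / kT
  L <- if (x < 1e-4) x / 3 - x^3 / 45 else 1 / tanh(x) - 1 / x
  params$ss_contour_per_nt * L
}

#' Calibration: extension gain per nucleotide synthesized
#'
#' Difference between the dsDNA extension per base pair and the ssDNA
#' extension per nucleotide at the working force.  Positive means the bead
#' moves downstream as ssDNA is converted to dsDNA (true below the ~6 pN
#' ss/ds extension crossover, so at the assay's 3 pN the gain is positive).
#'
#' @param params an [fe_params()] object.
#' @return object of class `calibration` with element `nm_per_nt`.
#' @export
nm_per_nt <- function(params) {
  stopifnot(inherits(params, "fe_params"))
  val <- ds_extension_fraction(params) * params$ds_contour_per_bp -
    ss_extension_per_nt(params)
  calibration(val)
}

#' User-supplied calibration constant
#'
#' @param nm_per_nt signed extension gain in nm per nucleotide synthesized.
#' @return object of class `calibration`.
#' @export
calibration <- function(nm_per_nt) {
  if (!is.numeric(nm_per_nt) || length(nm_per_nt) != 1L || !is.finite(nm_per_nt))
    stop("calibration: nm_per_nt must be a single finite number")
  structure(list(nm_per_nt = nm_per_nt), class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("calibration: %.6g nm per nt synthesized\n", x$nm_per_nt))
  invisible(x)
}

#' Convert bead displacement to bases synthesized, and back
#'
#' Exact linear maps through the calibration constant; mutual inverses.
#'
#' @param displacement_nm bead displacement along the flow axis, nm.
#' @param bp nucleotides synthesized.
#' @param cal a [calibration()] object (or [nm_per_nt()] result).
#' @return numeric vector (bp or nm).
#' @export
displacement_to_bases <- function(displacement_nm, cal) {
  stopifnot(inherits(cal, "calibration"))
  if (cal$nm_per_nt == 0) stop("displacement_to_bases: zero calibration")
  displacement_nm / cal$nm_per_nt
}

#' @rdname displacement_to_bases
#' @export
bases_to_displacement <- function(bp, cal) {
  stopifnot(inherits(cal, "calibration"))
  if (cal$nm_per_nt == 0) stop("bases_to_displacement: zero calibration")
  bp * cal$nm_per_nt
}
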