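## S4 class definitions and validity methods.

#' Spectrum: an absorption curve on an energy grid
#'
#' Energies are in eV relative to the absorption edge (edge = 0); values are
#' normalized absorption (dimensionless).  The grid must be strictly
#' increasing and all values finite.
#'
#' @slot energies Numeric, strictly increasing, eV relative to the edge.
#' @slot values Numeric, normalized absorption, same length as `energies`.
#' @slot meta List of free-form provenance tags.
#' @export
setClass("Spectrum",
  slots = c(energies = "numeric", values = "numeric", meta = "list"),
  prototype = prototype(energies = numeric(0), values = numeric(0),
                        meta = list()))

setValidity("Spectrum", function(object) {
  e <- object@energies; v <- object@values
  if (length(e) != length(v))
    return("energies and values must have equal length")
  if (length(e) && any(!is.finite(e)))
    return("energies must all be finite")
  if (length(v) && any(!is.finite(v)))
    return("values must all be finite")
  if (length(e) > 1L && any(diff(e) <= 0))
    return("energies must be strictly increasing")
  TRUE
})

#' ExperimentalSpectrum: a measured curve with constant error and weights
#'
#' Extends [Spectrum-class] with the experimental error epsilon (one positive
#' scalar applied to every point, the convention for normalized XANES data)
#' and per-point statistical weights (default 1).
#'
#' @slot epsilon Positive scalar error applied to all points.
#' @slot weights Non-negative per-point weights, at least one positive.
#' @export
setClass("ExperimentalSpectrum", contains = "Spectrum",
  slots = c(epsilon = "numeric", weights = "numeric"))

setValidity("ExperimentalSpectrum", function(object) {
  if (length(object@epsilon) != 1L || !is.finite(object@epsilon) ||
      object@epsilon <= 0)
    return("epsilon must be a single positive finite scalar")
  w <- object@weights
  if (length(w) != length(object@energies))
    return("weights must match the number of points")
  if (length(w)) {
    if (any(!is.finite(w)) || any(w < 0))
      return("weights must be finite and non-negative")
    if (!any(w > 0))
      return("at least one weight must be positive")
  }
  TRUE
})

#' Snapshot: one frame of an atomic trajectory
#'
#' Sites are stored as a data.frame with columns `element`, `Z`, `label`,
#' `x`, `y`, `z` (coordinates in Angstrom).  Exactly one site carries the
#' label `"FE"`, the absorber.
#'
#' @slot sites data.frame of atomic sites.
#' @slot index Frame ordinal (1-based).
#' @slot time Frame time in ps.
#' @export
setClass("Snapshot",
  slots = c(sites = "data.frame", index = "integer", time = "numeric"))

setValidity("Snapshot", function(object) {
  s <- object@sites
  need <- c("element", "Z", "label", "x", "y", "z")
  if (!all(need %in% names(s)))
    return(paste("sites must have columns", paste(need, collapse = ", ")))
  if (nrow(s)) {
    if (any(s$Z < 1)) return("atomic numbers must be >= 1")
    if (any(!is.finite(as.matrix(s[, c("x", "y", "z")]))))
      return("coordinates must be finite")
    if (sum(s$label == "FE") != 1L)
      return("exactly one site must be labeled FE")
  }
  TRUE
})

#' SnapshotEnsemble: a compact multi-frame trajectory
#'
#' Stores a template site table plus, per frame, the Cartesian coordinates of
#' the movable atoms (a frames x 3*n_movable matrix; columns x,y,z per
#' movable site in order).  Atoms not listed in `movable` keep their template
#' coordinates in every frame.  Frame times are in ps and non-decreasing.
#'
#' @slot template data.frame of sites as in [Snapshot-class].
#' @slot movable Integer indices (rows of `template`) that vary by frame.
#' @slot coords Numeric matrix, frames x (3 * length(movable)).
#' @slot times Numeric frame times, ps, non-decreasing.
#' @slot meta List of provenance (force field, seed, sampler settings).
#' @export
setClass("SnapshotEnsemble",
  slots = c(template = "data.frame", movable = "integer",
            coords = "matrix", times = "numeric", meta = "list"))

setValidity("SnapshotEnsemble", function(object) {
  if (ncol(object@coords) != 3L * length(object@movable))
    return("coords must have 3 columns per movable atom")
  if (nrow(object@coords) != length(object@times))
    return("one time per frame required")
  if (length(object@times) > 1L && any(diff(object@times) < 0))
    return("frame times must be non-decreasing")
  if (length(object@movable) &&
      (min(object@movable) < 1L || max(object@movable) > nrow(object@template)))
    return("movable indices out of range")
  TRUE
})

#' Cluster: absorber-centered neighborhood fed to the forward model
#'
#' @slot absorber One-row data.frame (the FE site).
#' @slot neighbors data.frame of neighbor sites with a `dist` column,
#'   sorted by non-decreasing distance to the absorber.
#' @slot maxSize Requested maximum neighbor count.
#' @export
setClass("Cluster",
  slots = c(absorber = "data.frame", neighbors = "data.frame",
            maxSize = "integer"))

setValidity("Cluster", function(object) {
  nb <- object@neighbors
  if (nrow(object@absorber) != 1L) return("absorber must be a single site")
  if (nrow(nb)) {
    if (!"dist" %in% names(nb)) return("neighbors need a dist column")
    if (any(diff(nb$dist) < 0))
      return("neighbor distances must be non-decreasing")
  }
  if (nrow(nb) > object@maxSize) return("more neighbors than maxSize")
  TRUE
})

#' RdFResult: radial distribution histogram with coordination number
#'
#' The density is the raw per-frame distance histogram (counts per frame per
#' bin); the coordination curve is the running mean neighbor count within r,
#' evaluated at the upper edge of each bin.
#'
#' @slot binCenters Bin centers, Angstrom.
#' @slot density Mean counts per frame in each bin.
#' @slot coordination Running mean count within the bin's upper edge.
#' @slot binWidth Bin width, Angstrom.
#' @slot nFrames Number of frames averaged.
#' @slot group Character vector of the selected labels.
#' @export
setClass("RdFResult",
  slots = c(binCenters = "numeric", density = "numeric",
            coordination = "numeric", binWidth = "numeric",
            nFrames = "integer", group = "character"))

setValidity("RdFResult", function(object) {
  if (length(object@binCenters) != length(object@density) ||
      length(object@density) != length(object@coordination))
    return("binCenters, density and coordination must align")
  if (length(object@coordination) > 1L && any(diff(object@coordination) < 0))
    return("coordination must be non-decreasing in r")
  TRUE
})

#' ForceFieldParams: harmonic bonded parameters and charges
#'
#' Bonds use U = 1/2 k_b (r - r0)^2 (kcal/mol/A^2) and angles
#' U = 1/2 k_theta (theta - theta0)^2 (kcal/mol/rad^2) under the default
#' half-k convention; set `halfK = FALSE` for the CHARMM-style K(x-x0)^2
#' convention (the sampler then uses 2K internally).
#'
#' @slot bonds data.frame with columns a, b (labels), r0 (A), kb.
#' @slot angles data.frame with columns a, b, c (labels), theta0 (degrees,
#'   in (0, 180]), ktheta.
#' @slot charges Named numeric, elementary charges per label.
#' @slot totalCharge Declared total charge the charges must sum to.
#' @slot halfK Logical; TRUE for the 1/2 k convention (default).
#' @export
setClass("ForceFieldParams",
  slots = c(bonds = "data.frame", angles = "data.frame",
            charges = "numeric", totalCharge = "numeric", halfK = "logical"))

setValidity("ForceFieldParams", function(object) {
  b <- object@bonds; a <- object@angles
  if (!all(c("a", "b", "r0", "kb") %in% names(b)))
    return("bonds need columns a, b, r0, kb")
  if (!all(c("a", "b", "c", "theta0", "ktheta") %in% names(a)))
    return("angles need columns a, b, c, theta0, ktheta")
  if (nrow(b) && (any(b$r0 <= 0) || any(b$kb <= 0)))
    return("bond r0 and kb must be positive")
  if (nrow(a)) {
    if (any(a$ktheta <= 0)) return("angle ktheta must be positive")
    if (any(a$theta0 <= 0) || any(a$theta0 > 180))
      return("angle theta0 must lie in (0, 180] degrees")
  }
  if (length(object@charges) &&
      abs(sum(object@charges) - object@totalCharge) > 1e-6)
    return(sprintf("charges sum to %.6f, declared total is %.6f",
                   sum(object@charges), object@totalCharge))
  TRUE
})

#' BroadeningParams: the four inelastic-loss parameters
#'
#' Experimental broadening, core-hole lifetime width, and the energy onset
#' and amplitude of the plasmon contribution; all in eV and non-negative.
#' Note that gammaExp and gammaCore enter the width model only through their
#' sum (see [gammaOfE()]).
#'
#' @slot gammaExp Experimental broadening, eV.
#' @slot gammaCore Core-hole lifetime width, eV (about 1.25 eV at the Fe
#'   K-edge).
#' @slot eOnset Plasmon energy onset E_s, eV.
#' @slot amp Plasmon amplitude A_s, eV.
#' @export
setClass("BroadeningParams",
  slots = c(gammaExp = "numeric", gammaCore = "numeric",
            eOnset = "numeric", amp = "numeric"))

setValidity("BroadeningParams", function(object) {
  v <- c(object@gammaExp, object@gammaCore, object@eOnset, object@amp)
  if (length(v) != 4L || any(!is.finite(v)) || any(v < 0))
    return("all broadening parameters must be finite and >= 0")
  TRUE
})

#' FitResult: outcome of a non-structural (inelastic-loss) fit
#'
#' @slot rSq The square residual statistic at the optimum.
#' @slot broadening Fitted [BroadeningParams-class].
#' @slot energies Energy grid of the comparison (experimental grid).
#' @slot theory Fitted theoretical curve on that grid.
#' @slot fCurve Pointwise squared error f(E).
#' @slot fIntegral Cumulative trapezoidal integral of f(E).
#' @slot nUsed Number of free parameters n entering R_sq.
#' @slot mUsed Number of data points m.
#' @slot iterations Objective evaluations spent by the optimizer.
#' @slot converged Logical convergence flag.
#' @export
setClass("FitResult",
  slots = c(rSq = "numeric", broadening = "BroadeningParams",
            energies = "numeric", theory = "numeric",
            fCurve = "numeric", fIntegral = "numeric",
            nUsed = "integer", mUsed = "integer",
            iterations = "integer", converged = "logical"))

setValidity("FitResult", function(object) {
  if (object@rSq < 0) return("rSq must be >= 0")
  if (length(object@fCurve) && any(object@fCurve < -1e-300))
    return("fCurve must be non-negative")
  if (length(object@fIntegral) > 1L && any(diff(object@fIntegral) < -1e-12))
    return("fIntegral must be non-decreasing")
  TRUE
})

#' EnsembleAverage: running configurational average with convergence trace
#'
#' Holds the averaged cross section sigma^N over N frames and the residual
#' history R_f(N) = ||sigma^N - sigma^(N-1)||_2 for N = 2..N_total.
#'
#' @slot sigma [Spectrum-class], the ensemble-averaged spectrum.
#' @slot nFrames Number of frames averaged.
#' @slot rfHistory R_f(N) for N = 2..nFrames (length nFrames - 1).
#' @export
setClass("EnsembleAverage",
  slots = c(sigma = "Spectrum", nFrames = "integer", rfHistory = "numeric"))

setValidity("EnsembleAverage", function(object) {
  if (object@nFrames >= 2L &&
      length(object@rfHistory) != object@nFrames - 1L)
    return("rfHistory must have nFrames - 1 entries")
  if (length(object@rfHistory) && any(object@rfHistory < 0))
    return("rfHistory entries must be >= 0")
  TRUE
})

#' RefinementTrace: audit of the greedy force-field refinement
#'
#' @slot steps data.frame with one row per evaluated candidate: round,
#'   parameter, proposed value, rSqBefore, rSqAfter, accepted, seed.
#' @slot final [ForceFieldParams-class] after refinement.
#' @slot initialRSq R_sq of the starting parameters.
#' @slot finalRSq R_sq of the final parameters.
#' @export
setClass("RefinementTrace",
  slots = c(steps = "data.frame", final = "ForceFieldParams",
            initialRSq = "numeric", finalRSq = "numeric"))

setValidity("RefinementTrace", function(object) {
  st <- object@steps
  if (nrow(st) && any(st$accepted & !(st$rSqAfter < st$rSqBefore)))
    return("accepted steps must strictly lower rSq")
  TRUE
})
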