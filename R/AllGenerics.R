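## Generics, constructors, accessors and show methods.

#' Construct a Spectrum
#'
#' @param energies Strictly increasing energies, eV relative to the edge.
#' @param values Normalized absorption values.
#' @param meta Optional list of provenance tags.
#' @return A [Spectrum-class] object.
#' @export
#' @examples
#' Spectrum(0:3, c(0.1, 0.4, 0.8, 1.0))
Spectrum <- function(energies, values, meta = list()) {
  new("Spectrum", energies = as.numeric(energies),
      values = as.numeric(values), meta = meta)
}

#' Construct an ExperimentalSpectrum
#'
#' @inheritParams Spectrum
#' @param epsilon Constant per-point experimental error (positive scalar).
#' @param weights Per-point statistical weights, default 1.
#' @return An [ExperimentalSpectrum-class] object.
#' @export
ExperimentalSpectrum <- function(energies, values, epsilon,
                                 weights = rep(1, length(energies)),
                                 meta = list()) {
  new("ExperimentalSpectrum", energies = as.numeric(energies),
      values = as.numeric(values), meta = meta,
      epsilon = as.numeric(epsilon), weights = as.numeric(weights))
}

#' Construct broadening parameters
#'
#' @param gammaExp Experimental broadening, eV.
#' @param gammaCore Core-hole lifetime width, eV.
#' @param eOnset Plasmon onset energy E_s, eV.
#' @param amp Plasmon amplitude A_s, eV.
#' @return A [BroadeningParams-class] object.
#' @export
#' @examples
#' BroadeningParams(gammaExp = 1.5, gammaCore = 1.25, eOnset = 30, amp = 4)
BroadeningParams <- function(gammaExp = 1.5, gammaCore = 1.25,
                             eOnset = 30, amp = 4) {
  new("BroadeningParams", gammaExp = gammaExp, gammaCore = gammaCore,
      eOnset = eOnset, amp = amp)
}

#' @rdname energies
#' @export
setGeneric("energies", function(x) standardGeneric("energies"))

#' Accessors for spectral objects
#'
#' `energies()` returns the energy grid (eV relative to the edge),
#' `absorption()` the normalized absorption values, `epsilonError()` the
#' constant experimental error, `pointWeights()` the statistical weights.
#'
#' @param x A [Spectrum-class] or [ExperimentalSpectrum-class].
#' @return Numeric vector (scalar for `epsilonError`).
#' @name energies
#' @export
setMethod("energies", "Spectrum", function(x) x@energies)

#' @rdname energies
#' @export
setGeneric("absorption", function(x) standardGeneric("absorption"))

#' @rdname energies
#' @export
setMethod("absorption", "Spectrum", function(x) x@values)

#' @rdname energies
#' @export
setGeneric("epsilonError", function(x) standardGeneric("epsilonError"))

#' @rdname energies
#' @export
setMethod("epsilonError", "ExperimentalSpectrum", function(x) x@epsilon)

#' @rdname energies
#' @export
setGeneric("pointWeights", function(x) standardGeneric("pointWeights"))

#' @rdname energies
#' @export
setMethod("pointWeights", "ExperimentalSpectrum", function(x) x@weights)

#' @rdname nFrames
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Ensemble accessors
#'
#' `nFrames()` counts frames; `frameTimes()` returns times in ps;
#' `getSnapshot()` materializes one frame as a [Snapshot-class];
#' `rfHistory()` returns the R_f(N) convergence trace of an
#' [EnsembleAverage-class]; `averageSpectrum()` its sigma^N.
#'
#' @param x A [SnapshotEnsemble-class] or [EnsembleAverage-class].
#' @param i Frame index (1-based).
#' @name nFrames
#' @export
setMethod("nFrames", "SnapshotEnsemble", function(x) nrow(x@coords))

#' @rdname nFrames
#' @export
setMethod("nFrames", "EnsembleAverage", function(x) x@nFrames)

#' @rdname nFrames
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname nFrames
#' @export
setMethod("frameTimes", "SnapshotEnsemble", function(x) x@times)

#' @rdname nFrames
#' @export
setGeneric("getSnapshot", function(x, i) standardGeneric("getSnapshot"))

#' @rdname nFrames
#' @export
setMethod("getSnapshot", "SnapshotEnsemble", function(x, i) {
  i <- as.integer(i)
  stopifnot(i >= 1L, i <= nrow(x@coords))
  sites <- x@template
  if (length(x@movable)) {
    xyz <- matrix(x@coords[i, ], ncol = 3L, byrow = TRUE)
    sites[x@movable, c("x", "y", "z")] <- xyz
  }
  new("Snapshot", sites = sites, index = i, time = x@times[i])
})

#' @rdname nFrames
#' @export
setGeneric("rfHistory", function(x) standardGeneric("rfHistory"))

#' @rdname nFrames
#' @export
setMethod("rfHistory", "EnsembleAverage", function(x) x@rfHistory)

#' @rdname nFrames
#' @export
setGeneric("averageSpectrum", function(x) standardGeneric("averageSpectrum"))

#' @rdname nFrames
#' @export
setMethod("averageSpectrum", "EnsembleAverage", function(x) x@sigma)

#' @rdname rSqValue
#' @export
setGeneric("rSqValue", function(x) standardGeneric("rSqValue"))

#' Fit-result accessors
#'
#' `rSqValue()` extracts the square-residual statistic, `broadening()` the
#' fitted [BroadeningParams-class], `fIntegral()` the cumulative integral of
#' the pointwise squared error f(E).
#'
#' @param x A [FitResult-class] (or [RefinementTrace-class] for `rSqValue`).
#' @name rSqValue
#' @export
setMethod("rSqValue", "FitResult", function(x) x@rSq)

#' @rdname rSqValue
#' @export
setMethod("rSqValue", "RefinementTrace", function(x) x@finalRSq)

#' @rdname rSqValue
#' @export
setGeneric("broadening", function(x) standardGeneric("broadening"))

#' @rdname rSqValue
#' @export
setMethod("broadening", "FitResult", function(x) x@broadening)

#' @rdname rSqValue
#' @export
setGeneric("fIntegral", function(x) standardGeneric("fIntegral"))

#' @rdname rSqValue
#' @export
setMethod("fIntegral", "FitResult", function(x) x@fIntegral)

#' @rdname rSqValue
#' @export
setGeneric("finalParams", function(x) standardGeneric("finalParams"))

#' @rdname rSqValue
#' @export
setMethod("finalParams", "RefinementTrace", function(x) x@final)

#' Broadening parameter vector
#'
#' @param x A [BroadeningParams-class].
#' @return Named numeric of length 4 (gammaExp, gammaCore, eOnset, amp), eV.
#' @export
setGeneric("asVector", function(x) standardGeneric("asVector"))

#' @rdname asVector
#' @export
setMethod("asVector", "BroadeningParams", function(x) {
  c(gammaExp = x@gammaExp, gammaCore = x@gammaCore,
    eOnset = x@eOnset, amp = x@amp)
})

## show methods -------------------------------------------------------------

setMethod("show", "Spectrum", function(object) {
  m <- length(object@energies)
  cat(sprintf("%s with %d points", class(object), m))
  if (m) cat(sprintf(" over [%g, %g] eV", min(object@energies),
                     max(object@energies)))
  cat("\n")
  if (is(object, "ExperimentalSpectrum"))
    cat(sprintf("  constant error epsilon = %g\n", object@epsilon))
})

setMethod("show", "SnapshotEnsemble", function(object) {
  cat(sprintf("SnapshotEnsemble: %d frames, %d sites (%d movable)\n",
              nrow(object@coords), nrow(object@template),
              length(object@movable)))
  if (length(object@times))
    cat(sprintf("  times %g..%g ps\n", object@times[1],
                object@times[length(object@times)]))
})

setMethod("show", "Cluster", function(object) {
  cat(sprintf("Cluster: absorber %s with %d neighbors (max %d)\n",
              object@absorber$label[1], nrow(object@neighbors),
              object@maxSize))
})

setMethod("show", "ForceFieldParams", function(object) {
  cat(sprintf("ForceFieldParams: %d bonds, %d angles, %d charges (total %g e), %s-k convention\n",
              nrow(object@bonds), nrow(object@angles),
              length(object@charges), object@totalCharge,
              if (object@halfK) "half" else "full"))
})

setMethod("show", "BroadeningParams", function(object) {
  v <- asVector(object)
  cat("BroadeningParams (eV):",
      paste(names(v), signif(v, 4), sep = "=", collapse = ", "), "\n")
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: R_sq = %.4g (n = %d, m = %d, %d evaluations%s)\n",
              object@rSq, object@nUsed, object@mUsed, object@iterations,
              if (object@converged) "" else ", NOT converged"))
  show(object@broadening)
})

setMethod("show", "EnsembleAverage", function(object) {
  cat(sprintf("EnsembleAverage over %d frames", object@nFrames))
  if (length(object@rfHistory))
    cat(sprintf("; final R_f = %.3g", tail(object@rfHistory, 1L)))
  cat("\n")
})

setMethod("show", "RefinementTrace", function(object) {
  acc <- sum(object@steps$accepted)
  cat(sprintf("RefinementTrace: %d evaluations, %d accepted moves, R_sq %.4g -> %.4g\n",
              nrow(object@steps), acc, object@initialRSq, object@finalRSq))
})
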