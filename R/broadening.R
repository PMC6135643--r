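## Energy-dependent Lorentzian broadening and the non-structural fit.

#' Energy-dependent total Lorentzian width
#'
#' Gamma(E) = gammaCore + gammaExp + amp * (1/2 + (1/pi) arctan((E -
#' eOnset)/delta)): constant core-hole plus experimental width below the
#' plasmon onset, rising smoothly by `amp` above it.  The smooth-step width
#' `delta` is fixed (default 5 eV).
#'
#' @param E Energies, eV.
#' @param p A [BroadeningParams-class].
#' @param delta Smooth-step width, eV.
#' @return Gamma(E) in eV, same length as `E`.
#' @export
#' @examples
#' gammaOfE(c(-1e6, 30, 1e6), BroadeningParams(1.5, 1.25, 30, 4))
gammaOfE <- function(E, p, delta = 5) {
  p@gammaCore + p@gammaExp +
    p@amp * (0.5 + atan((E - p@eOnset) / delta) / pi)
}

#' Convolve a spectrum with the energy-dependent Lorentzian
#'
#' Models inelastic losses: each source point E' is spread by a unit-area
#' Lorentzian of FWHM Gamma(E'),
#' out(E) = sum_E' raw(E') L(E - E'; Gamma(E')) dE'.  The input must sit on
#' a uniform grid (resample first otherwise) and is treated as zero outside
#' it.  Columns with Gamma below 1e-9 eV degenerate to identity (delta
#' kernel), so the all-zero parameter limit returns the input unchanged.
#'
#' @param raw A [Spectrum-class] on a uniform grid.
#' @param p A [BroadeningParams-class].
#' @param delta Smooth-step width passed to [gammaOfE()].
#' @return A [Spectrum-class] on the same grid.
#' @export
convolveSpectrum <- function(raw, p, delta = 5) {
  e <- raw@energies
  if (length(e) < 2L) stop("need at least two grid points")
  h <- diff(e)
  if (max(h) - min(h) > 1e-9 * mean(h))
    stop("non-uniform grid: resample the spectrum onto a uniform grid first")
  h <- mean(h)
  gam <- gammaOfE(e, p, delta)
  # kernel column j spreads raw[j]; delta column when the width vanishes
  out <- numeric(length(e))
  for (j in seq_along(e)) {
    if (gam[j] < 1e-9) {
      out[j] <- out[j] + raw@values[j]
    } else {
      hw <- gam[j] / 2
      L <- (hw / pi) / ((e - e[j])^2 + hw^2)
      out <- out + raw@values[j] * L * h
    }
  }
  Spectrum(e, out, meta = raw@meta)
}

#' Fit the non-structural (inelastic-loss) parameters
#'
#' The only fit performed in a dynamic-average analysis: Nelder-Mead search
#' of the broadening parameters minimizing R_sq between the convolved
#' ensemble-average spectrum and the experimental curve, with n = `nFree`
#' (default 4, the four inelastic-loss parameters).  Non-negativity is
#' enforced by reflection (the objective sees |p|).
#'
#' Because `gammaExp` and `gammaCore` enter [gammaOfE()] only through their
#' sum, the optimizer works on the three identifiable quantities (base width
#' gammaExp + gammaCore, onset, amplitude) and apportions the fitted base
#' width between the two components in the ratio of the initial guess; the
#' split itself is not determined by the data.
#'
#' @param avg A [Spectrum-class] (or [EnsembleAverage-class]), the
#'   unbroadened ensemble average on a uniform grid.
#' @param exp_ An [ExperimentalSpectrum-class] whose grid lies within the
#'   average's grid.
#' @param init Initial [BroadeningParams-class].
#' @param nFree Parameter count n entering R_sq (default 4).
#' @param maxit Maximum simplex iterations per start (default 500).
#' @param restarts Additional polishing restarts from the incumbent
#'   (default 1).
#' @param delta Smooth-step width passed to [gammaOfE()].
#' @return A [FitResult-class].
#' @export
fitNonstructural <- function(avg, exp_, init = BroadeningParams(),
                             nFree = 4, maxit = 500, restarts = 1,
                             delta = 5) {
  if (is(avg, "EnsembleAverage")) avg <- avg@sigma
  eExp <- exp_@energies
  objective <- function(q) {
    q <- abs(q)
    p <- new("BroadeningParams", gammaExp = init@gammaExp /
               max(init@gammaExp + init@gammaCore, 1e-12) * q[1L],
             gammaCore = init@gammaCore /
               max(init@gammaExp + init@gammaCore, 1e-12) * q[1L],
             eOnset = q[2L], amp = q[3L])
    conv <- convolveSpectrum(avg, p, delta)
    yth <- resampleSpectrum(conv, eExp)@values
    val <- rSq(yth, exp_, n = nFree)
    if (!is.finite(val))
      stop("non-finite objective at parameters (",
           paste(signif(q, 6), collapse = ", "), ")")
    val
  }
  q0 <- c(init@gammaExp + init@gammaCore, init@eOnset, init@amp)
  best <- list(par = q0, value = objective(q0), counts = c(1L, 0L),
               convergence = 0L)
  for (s in seq_len(1L + max(0L, restarts))) {
    fit <- optim(best$par, objective, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-6))
    if (fit$value < best$value) {
      fit$counts <- fit$counts + best$counts
      best <- fit
    } else {
      best$counts <- best$counts + fit$counts
      break
    }
  }
  q <- abs(best$par)
  base <- max(init@gammaExp + init@gammaCore, 1e-12)
  pOpt <- new("BroadeningParams",
              gammaExp = init@gammaExp / base * q[1L],
              gammaCore = init@gammaCore / base * q[1L],
              eOnset = q[2L], amp = q[3L])
  conv <- convolveSpectrum(avg, pOpt, delta)
  yth <- resampleSpectrum(conv, eExp)@values
  fe <- fError(yth, exp_@values, energies = eExp)
  new("FitResult", rSq = rSq(yth, exp_, n = nFree), broadening = pOpt,
      energies = eExp, theory = yth, fCurve = fe$curve,
      fIntegral = fe$integral, nUsed = as.integer(nFree),
      mUsed = length(eExp),
      iterations = as.integer(best$counts[[1L]]),
      converged = best$convergence == 0L)
}
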