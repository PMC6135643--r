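## The three residual statistics and ensemble averaging.

#' Square residual statistic R_sq
#'
#' R_sq = n * sum_i w_i ((y_i_th - y_i_exp)/eps_i)^2 / sum_i w_i, the
#' goodness-of-fit statistic of XANES fitting, with n the number of free
#' parameters, eps the constant experimental error and w the statistical
#' weights (usually 1).
#'
#' @param yTh Theoretical values on the experimental grid.
#' @param exp_ An [ExperimentalSpectrum-class] (or a numeric vector of
#'   experimental values if `epsilon` and `weights` are given explicitly).
#' @param n Number of free parameters (>= 1).
#' @param epsilon,weights Used only when `exp_` is a bare numeric vector.
#' @return R_sq, dimensionless.
#' @export
#' @examples
#' e <- ExperimentalSpectrum(1:3, c(0, 0, 0), epsilon = 0.01)
#' rSq(c(0.01, 0.02, 0.03), e, n = 4)  # 4*(1+4+9)/3
rSq <- function(yTh, exp_, n, epsilon = NULL, weights = NULL) {
  if (is(exp_, "ExperimentalSpectrum")) {
    yExp <- exp_@values
    epsilon <- exp_@epsilon
    weights <- exp_@weights
  } else {
    yExp <- exp_
    if (is.null(weights)) weights <- rep(1, length(yExp))
  }
  m <- length(yExp)
  if (m == 0L) stop("empty spectra: m = 0")
  if (length(yTh) != m) stop("theory and experiment lengths differ")
  if (n < 1) stop("n must be >= 1")
  eps <- rep(epsilon, length.out = m)
  if (any(eps == 0)) stop("epsilon must be nonzero at every point")
  n * sum(weights * ((yTh - yExp) / eps)^2) / sum(weights)
}

#' Pointwise squared fit error f(E) and its cumulative integral
#'
#' f(E_i) = (y_th(E_i) - y_exp(E_i))^2, the curve that localizes misfit in
#' energy; its cumulative trapezoidal integral is the standard comparison
#' plot when two fits differ by less than ~10 percent in R_sq.
#'
#' @param yTh,yExp Aligned theoretical and experimental values.
#' @param energies Energy grid for the integral (defaults to point index).
#' @return List with `curve` (f at each point) and `integral` (cumulative
#'   trapezoidal integral of f over energy).
#' @export
fError <- function(yTh, yExp, energies = seq_along(yTh)) {
  if (length(yTh) != length(yExp)) stop("lengths differ")
  curve <- (yTh - yExp)^2
  list(curve = curve, integral = .cumtrapz(energies, curve))
}

#' Configurational average of a spectrum stream
#'
#' Streaming arithmetic mean sigma^N of instantaneous spectra, recording at
#' each step the convergence residual
#' R_f(N) = [sum_i (sigma^N(E_i) - sigma^(N-1)(E_i))^2]^(1/2).  The final
#' mean is recomputed with an order-invariant (per-energy sorted) summation
#' so that frame order cannot leak into the average through floating-point
#' non-associativity; R_f remains order-dependent by definition.
#'
#' @param spectra List of [Spectrum-class] objects on one common grid, or a
#'   numeric matrix (frames in rows).
#' @param energies Grid when `spectra` is a matrix.
#' @return An [EnsembleAverage-class].
#' @export
ensembleAverage <- function(spectra, energies = NULL) {
  if (is.list(spectra)) {
    stopifnot(length(spectra) >= 1L)
    grid <- spectra[[1L]]@energies
    mat <- matrix(0, length(spectra), length(grid))
    for (i in seq_along(spectra)) {
      if (!isTRUE(all.equal(spectra[[i]]@energies, grid)))
        stop("grid mismatch at frame ", i)
      mat[i, ] <- spectra[[i]]@values
    }
  } else {
    mat <- spectra
    grid <- if (is.null(energies)) seq_len(ncol(mat)) else energies
  }
  n <- nrow(mat)
  rf <- numeric(max(0L, n - 1L))
  sigma <- mat[1L, ]
  if (n >= 2L) for (N in 2:n) {
    prev <- sigma
    sigma <- prev + (mat[N, ] - prev) / N
    rf[N - 1L] <- sqrt(sum((sigma - prev)^2))
  }
  # order-invariant final mean (exchangeability of frames)
  sigmaFinal <- apply(mat, 2L, function(col) sum(sort(col))) / n
  new("EnsembleAverage", sigma = Spectrum(grid, sigmaFinal),
      nFrames = as.integer(n), rfHistory = rf)
}

#' Average per-snapshot spectra over an ensemble
#'
#' Runs the forward model on every frame's absorber-centered cluster and
#' feeds the resulting spectrum stream to [ensembleAverage()].
#'
#' @param ens A [SnapshotEnsemble-class].
#' @param grid Energy grid for the calculation.
#' @param calculator Registered calculator name (see
#'   [registerCalculator()]).
#' @param cfg Forward-model configuration.
#' @param clusterSize Cluster size k (default 100).
#' @return An [EnsembleAverage-class].
#' @export
ensembleSpectra <- function(ens, grid = analysisGrid(), calculator = "toy",
                            cfg = toyModelConfig(), clusterSize = 100) {
  calc <- getCalculator(calculator)
  n <- nFrames(ens)
  stopifnot(n >= 1L)
  mat <- matrix(0, n, length(grid))
  for (i in seq_len(n)) {
    cl <- selectCluster(getSnapshot(ens, i), k = clusterSize, quiet = TRUE)
    mat[i, ] <- calc(cl, grid, cfg)@values
  }
  ensembleAverage(mat, energies = grid)
}

#' Check convergence of the running average
#'
#' Converged means R_f(N) stays below `threshold` for every N >= `after`.
#' Also reports the first N after which R_f never again exceeds the
#' threshold.
#'
#' @param avg An [EnsembleAverage-class].
#' @param threshold R_f threshold (units of the cross section; scale
#'   depends on normalization, hence a run-time input).
#' @param after Frame count from which the criterion applies (default 2).
#' @return List with `converged` (logical) and `firstPass` (smallest N such
#'   that R_f < threshold from N on; NA if never).
#' @export
checkConvergence <- function(avg, threshold, after = 2L) {
  rf <- avg@rfHistory
  if (length(rf) < max(0L, after - 1L)) stop("rfHistory shorter than 'after'")
  Ns <- seq.int(2L, length.out = length(rf))
  bad <- Ns[rf >= threshold]
  firstPass <- if (!length(bad)) 2L
    else if (max(bad) == max(Ns)) NA_integer_ else max(bad) + 1L
  list(converged = !any(bad >= after), firstPass = firstPass)
}

#' Time-windowed R_sq series
#'
#' Partitions the trajectory into contiguous non-overlapping left-aligned
#' windows of `window` ps, runs the full average-plus-nonstructural-fit
#' pipeline in each, and returns the per-window R_sq series.  Exposes the
#' variability of the fit statistic along the trajectory and separates
#' conformational regimes.
#'
#' @param ens A [SnapshotEnsemble-class].
#' @param exp_ An [ExperimentalSpectrum-class].
#' @param window Window length, ps.
#' @param grid Energy grid for the forward model.
#' @param calculator,cfg,clusterSize Forward-model settings as in
#'   [ensembleSpectra()].
#' @param init Broadening initialization for each window's fit.
#' @param discardFirst Drop the first window (equilibration), default FALSE.
#' @return List with `series` (data.frame: start/end ps, nFrames, rSq and
#'   fitted broadening), `best` and `worst` (row indices of the extreme
#'   windows) and `fits` (the per-window [FitResult-class] objects).
#' @export
windowedRsq <- function(ens, exp_, window, grid = analysisGrid(),
                        calculator = "toy", cfg = toyModelConfig(),
                        clusterSize = 100, init = BroadeningParams(),
                        discardFirst = FALSE) {
  t <- ens@times
  span <- diff(range(t))
  if (window <= 0) stop("window must be positive")
  if (length(t) >= 2L && window < min(diff(t)[diff(t) > 0]))
    stop("window smaller than the frame spacing")
  if (span < window) stop("total duration shorter than one window")
  ratio <- span / window
  # a frame landing exactly on the final boundary joins the last window
  nWin <- if (abs(ratio - round(ratio)) < 1e-9) max(1L, round(ratio))
          else ceiling(ratio)
  idx <- pmin(floor((t - t[1L]) / window + 1e-12), nWin - 1L)
  windows <- sort(unique(idx))
  if (discardFirst) windows <- windows[-1L]
  rows <- list(); fits <- list()
  for (wi in seq_along(windows)) {
    w <- windows[wi]
    keep <- which(idx == w)
    sub <- new("SnapshotEnsemble", template = ens@template,
               movable = ens@movable,
               coords = ens@coords[keep, , drop = FALSE],
               times = t[keep], meta = ens@meta)
    avg <- ensembleSpectra(sub, grid, calculator, cfg, clusterSize)
    fit <- fitNonstructural(avg, exp_, init = init)
    fits[[wi]] <- fit
    bp <- asVector(fit@broadening)
    rows[[wi]] <- data.frame(start_ps = t[1L] + w * window,
                             end_ps = t[1L] + (w + 1) * window,
                             nFrames = length(keep), rSq = fit@rSq,
                             gammaExp = bp[["gammaExp"]],
                             gammaCore = bp[["gammaCore"]],
                             eOnset = bp[["eOnset"]], amp = bp[["amp"]])
  }
  series <- do.call(rbind, rows)
  rownames(series) <- NULL
  list(series = series, best = which.min(series$rSq),
       worst = which.max(series$rSq), fits = fits)
}
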