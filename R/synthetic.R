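## Harmonic heme-site model, Metropolis sampler, synthetic experiments.
##
## These routines stand in for the unavailable raw inputs of a full
## analysis: long explicit-solvent MD of the protein and a measured Fe
## K-edge spectrum.  They emulate the features the pipeline actually
## consumes -- a 300 K Boltzmann ensemble of the first coordination shell
## and a noisy broadened "experimental" curve with known ground truth.

.requiredBonds <- list(c("FE", "N_HIS"), c("FE", "C_CO"), c("C_CO", "O_CO"))
.requiredAngles <- list(c("N_HIS", "FE", "C_CO"), c("FE", "C_CO", "O_CO"))

#' Construct force-field parameters
#'
#' @param bonds data.frame with columns a, b (labels), r0 (Angstrom),
#'   kb (kcal/mol/A^2).
#' @param angles data.frame with columns a, b, c (labels), theta0 (degrees),
#'   ktheta (kcal/mol/rad^2).
#' @param charges Named numeric vector of partial charges (label -> e).
#' @param totalCharge Declared charge total the charges must sum to.
#' @param halfK TRUE for the U = 1/2 k (x-x0)^2 convention (default); FALSE
#'   for the CHARMM-style K (x-x0)^2 convention.
#' @return A [ForceFieldParams-class].
#' @export
forceFieldParams <- function(bonds, angles, charges = defaultCharges(),
                             totalCharge = -2, halfK = TRUE) {
  new("ForceFieldParams", bonds = bonds, angles = angles,
      charges = charges, totalCharge = totalCharge, halfK = halfK)
}

#' Default partial charges for the reduced heme-CO site
#'
#' A plausible set summing to the declared total charge of -2 carried by
#' heme + proximal histidine + CO.  Published refined charge tables for
#' this system are not reproduced here; these values are scenery for the
#' topology export, not refined quantities.
#'
#' @return Named numeric vector summing to -2.
#' @export
defaultCharges <- function() {
  c(FE = 0.24, N_PYR1 = -0.50, N_PYR2 = -0.50, N_PYR3 = -0.50,
    N_PYR4 = -0.50, N_HIS = -0.29, C_CO = 0.35, O_CO = -0.30)
}

.bondRow <- function(a, b, r0, kb) data.frame(a = a, b = b, r0 = r0, kb = kb,
                                              stringsAsFactors = FALSE)
.angleRow <- function(a, b, c, theta0, ktheta)
  data.frame(a = a, b = b, c = c, theta0 = theta0, ktheta = ktheta,
             stringsAsFactors = FALSE)

#' Canned force-field parameter sets
#'
#' `ffOptimized()` carries the spectroscopy-refined bonded values for the
#' covalently bound heme-CO site (Fe-C 1.80 A, Fe-N_His 2.04 A, C-O 1.25 A,
#' Fe-C-O bending constant 67.4 kcal/mol/rad^2); `ffCharmm()` the
#' CHARMM36-style starting values (1.90, 2.20, 1.128 A, 70.0), which model a
#' photodissociated CO.  Bond force constants and the N_His-Fe-C angle are
#' CHARMM-typical defaults, not refined quantities.
#'
#' @return A [ForceFieldParams-class].
#' @export
ffOptimized <- function() {
  forceFieldParams(
    bonds = rbind(.bondRow("FE", "N_HIS", 2.04, 270),
                  .bondRow("FE", "C_CO", 1.80, 300),
                  .bondRow("C_CO", "O_CO", 1.25, 1115)),
    angles = rbind(.angleRow("N_HIS", "FE", "C_CO", 180, 50),
                   .angleRow("FE", "C_CO", "O_CO", 180, 67.4)))
}

#' @rdname ffOptimized
#' @export
ffCharmm <- function() {
  forceFieldParams(
    bonds = rbind(.bondRow("FE", "N_HIS", 2.20, 270),
                  .bondRow("FE", "C_CO", 1.90, 300),
                  .bondRow("C_CO", "O_CO", 1.128, 1115)),
    angles = rbind(.angleRow("N_HIS", "FE", "C_CO", 180, 50),
                   .angleRow("FE", "C_CO", "O_CO", 180, 70.0)))
}

.findBond <- function(ff, a, b) {
  bd <- ff@bonds
  hit <- which((bd$a == a & bd$b == b) | (bd$a == b & bd$b == a))
  if (!length(hit)) stop("missing required bond ", a, "-", b)
  hit[1L]
}

.findAngle <- function(ff, a, b, c) {
  an <- ff@angles
  hit <- which((an$a == a & an$b == b & an$c == c) |
               (an$a == c & an$b == b & an$c == a))
  if (!length(hit)) stop("missing required angle ", a, "-", b, "-", c)
  hit[1L]
}

#' Bond equilibrium length lookup
#'
#' @param ff A [ForceFieldParams-class].
#' @param a,b Site labels of the bond (order-free).
#' @return r0 in Angstrom.
#' @export
bondR0 <- function(ff, a, b) ff@bonds$r0[.findBond(ff, a, b)]

#' Build the template heme-site geometry
#'
#' Fe at the origin with four fixed pyrrole nitrogens in the xy-plane at
#' 2.00 Angstrom (typical heme value, scenery for the forward model); the
#' proximal histidine nitrogen below Fe at its equilibrium bond length, the
#' CO carbon above at r0(Fe-C) and the oxygen collinear beyond it at
#' r0(C-O).
#'
#' @param ff A [ForceFieldParams-class] containing the Fe-N_His, Fe-C_CO and
#'   C_CO-O_CO bonds and the N_HIS-FE-C_CO and FE-C_CO-O_CO angles.
#' @return A [Snapshot-class] template (index 1, time 0).
#' @export
buildSiteModel <- function(ff) {
  for (b in .requiredBonds) .findBond(ff, b[1L], b[2L])
  for (a in .requiredAngles) .findAngle(ff, a[1L], a[2L], a[3L])
  rFeN <- bondR0(ff, "FE", "N_HIS")
  rFeC <- bondR0(ff, "FE", "C_CO")
  rCO <- bondR0(ff, "C_CO", "O_CO")
  lab <- c("FE", "N_PYR1", "N_PYR2", "N_PYR3", "N_PYR4",
           "N_HIS", "C_CO", "O_CO")
  elem <- c("FE", "N", "N", "N", "N", "N", "C", "O")
  xyz <- rbind(c(0, 0, 0),
               c(2, 0, 0), c(0, 2, 0), c(-2, 0, 0), c(0, -2, 0),
               c(0, 0, -rFeN),
               c(0, 0, rFeC),
               c(0, 0, rFeC + rCO))
  sites <- data.frame(element = elem, Z = .elementZ(elem), label = lab,
                      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                      stringsAsFactors = FALSE)
  new("Snapshot", sites = sites, index = 1L, time = 0)
}

#' Sampler configuration
#'
#' @param temperature Kelvin (default 300).
#' @param nSteps Production Monte Carlo steps.
#' @param burnIn Equilibration steps (discarded; max-step auto-tuning
#'   happens here).
#' @param stride Emit one frame every `stride` steps (accepted or rejected).
#' @param maxStep Initial maximum single-atom displacement, Angstrom.
#' @param seed RNG seed (required for reproducibility).
#' @param frameDt Nominal time between emitted frames, ps (default 5, the
#'   usual snapshot collection interval).
#' @param autotune Tune maxStep toward ~40 percent acceptance during
#'   burn-in, then freeze (default TRUE).
#' @return A list of class `SamplerConfig`.
#' @export
samplerConfig <- function(temperature = 300, nSteps = 50000, burnIn = 5000,
                          stride = 50, maxStep = 0.12, seed = 1,
                          frameDt = 5, autotune = TRUE) {
  stopifnot(temperature > 0, stride >= 1, nSteps >= stride, burnIn >= 0,
            maxStep > 0)
  structure(list(temperature = temperature, nSteps = as.integer(nSteps),
                 burnIn = as.integer(burnIn), stride = as.integer(stride),
                 maxStep = maxStep, seed = as.integer(seed),
                 frameDt = frameDt, autotune = isTRUE(autotune)),
            class = "SamplerConfig")
}

#' Sample a Boltzmann ensemble of the heme site
#'
#' Metropolis Monte Carlo in the Cartesian coordinates of the movable atoms
#' (N_HIS, C_CO, O_CO; Fe and the pyrrole nitrogens stay fixed so that only
#' the refinable parameters act).  The energy is the harmonic bonded model
#' U = sum 1/2 kb (r-r0)^2 + sum 1/2 ktheta (theta-theta0)^2 and moves are
#' accepted with probability exp(-dU/kT) (kT = 0.5962 kcal/mol at 300 K).
#' Sampling in Cartesian space automatically carries the r^2 and sin(theta)
#' Jacobian weights of the bond and angle marginals.  Runs are bitwise
#' reproducible given the seed.
#'
#' @param template A [Snapshot-class] from [buildSiteModel()].
#' @param ff A [ForceFieldParams-class].
#' @param cfg A [samplerConfig()].
#' @return A [SnapshotEnsemble-class] with `floor(nSteps/stride)` frames;
#'   acceptance statistics are stored in `meta`.  A warning is raised when
#'   the post-tuning acceptance rate leaves [0.2, 0.7].
#' @export
sampleEnsemble <- function(template, ff, cfg = samplerConfig()) {
  sites <- template@sites
  lab <- sites$label
  idxOf <- function(l) {
    i <- which(lab == l)
    if (!length(i)) stop("template lacks site ", l)
    i[1L]
  }
  kScale <- if (ff@halfK) 1 else 2  # full-k convention folds into half-k
  bd <- ff@bonds
  bonds <- cbind(vapply(bd$a, idxOf, 1L), vapply(bd$b, idxOf, 1L)) - 1L
  an <- ff@angles
  angles <- cbind(vapply(an$a, idxOf, 1L), vapply(an$b, idxOf, 1L),
                  vapply(an$c, idxOf, 1L)) - 1L
  movable <- vapply(c("N_HIS", "C_CO", "O_CO"), idxOf, 1L)
  coords0 <- as.numeric(t(as.matrix(sites[, c("x", "y", "z")])))
  set.seed(cfg$seed)
  res <- .mcSample(coords0, as.integer(movable - 1L),
                   bonds, bd$r0, kScale * bd$kb,
                   angles, an$theta0 * pi / 180, kScale * an$ktheta,
                   kBT(cfg$temperature), cfg$nSteps, cfg$burnIn,
                   cfg$stride, cfg$maxStep, cfg$autotune)
  if (is.finite(res$acceptance) &&
      (res$acceptance < 0.2 || res$acceptance > 0.7))
    warning(sprintf(
      "acceptance rate %.2f outside [0.2, 0.7] (tuned maxStep %.3g A)",
      res$acceptance, res$maxStep))
  nfr <- nrow(res$frames)
  new("SnapshotEnsemble", template = sites,
      movable = as.integer(unname(movable)), coords = res$frames,
      times = (seq_len(nfr) - 1) * cfg$frameDt,
      meta = list(seed = cfg$seed, temperature = cfg$temperature,
                  acceptance = res$acceptance, maxStep = res$maxStep,
                  stride = cfg$stride, burnIn = cfg$burnIn))
}

#' Per-frame internal coordinate series
#'
#' `distanceSeries()` returns the instantaneous distance between two labeled
#' sites; `angleSeries()` the instantaneous a-b-c angle in degrees.
#'
#' @param ens A [SnapshotEnsemble-class].
#' @param a,b,c Site labels.
#' @return Numeric vector, one value per frame.
#' @export
distanceSeries <- function(ens, a, b) {
  pa <- .siteCoords(ens, a); pb <- .siteCoords(ens, b)
  sqrt(rowSums((pa - pb)^2))
}

#' @rdname distanceSeries
#' @export
angleSeries <- function(ens, a, b, c) {
  pa <- .siteCoords(ens, a); pb <- .siteCoords(ens, b)
  pc <- .siteCoords(ens, c)
  v1 <- pa - pb; v2 <- pc - pb
  cth <- rowSums(v1 * v2) / sqrt(rowSums(v1^2) * rowSums(v2^2))
  acos(pmax(-1, pmin(1, cth))) * 180 / pi
}

#' Mean and standard deviation of an instantaneous angle
#'
#' For a harmonic bending potential 1/2 k (theta-theta0)^2 with theta0 =
#' 180 degrees sampled in Cartesian coordinates, the sin(theta) Jacobian
#' makes the deviation from linearity Rayleigh-distributed, so the sampled
#' mean sits below 180 even though the potential minimum is at 180 (for the
#' heme carbonyl at 300 K: about 173 +/- 3.5 degrees).
#'
#' @param ens A [SnapshotEnsemble-class] with at least 2 frames.
#' @param triple Character vector of three labels (a, b, c).
#' @return List with `mean` and `sd`, degrees.
#' @export
angleStatistics <- function(ens, triple = c("FE", "C_CO", "O_CO")) {
  stopifnot(length(triple) == 3L)
  if (nFrames(ens) < 2L) stop("need at least 2 frames")
  th <- angleSeries(ens, triple[1L], triple[2L], triple[3L])
  list(mean = mean(th), sd = sd(th))
}

#' Generate a synthetic experimental spectrum with known ground truth
#'
#' Samples an ensemble under `truthFf`, averages the toy spectra, convolves
#' with `truthBroadening`, and adds iid Gaussian noise of standard deviation
#' `noiseSd`.  The ground truth is returned alongside so recovery tests can
#' close the loop.
#'
#' @param truthFf Generating [ForceFieldParams-class].
#' @param truthBroadening Generating [BroadeningParams-class].
#' @param noiseSd Gaussian noise amplitude (>= 0); also the default for the
#'   experimental error epsilon when positive.
#' @param nFrames Frames in the generating ensemble (>= 1).
#' @param seed Master seed (sampler and noise seeds derive from it).
#' @param grid Energy grid.
#' @param cfg Forward-model configuration.
#' @param samplerCfg Base [samplerConfig()]; its nSteps/seed are overridden
#'   to produce `nFrames` frames from `seed`.
#' @param epsilon Experimental error; defaults to `noiseSd` when positive,
#'   else 0.01.
#' @return List with `experiment` ([ExperimentalSpectrum-class]), `truth`
#'   (ff, broadening, noiseSd, seed), `ensemble` and `average`.
#' @export
makeSyntheticExperiment <- function(truthFf,
                                    truthBroadening = BroadeningParams(),
                                    noiseSd = 0, nFrames = 200, seed = 1,
                                    grid = analysisGrid(),
                                    cfg = toyModelConfig(),
                                    samplerCfg = samplerConfig(),
                                    epsilon = NULL) {
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  stopifnot(nFrames >= 1)
  scfg <- samplerCfg
  scfg$nSteps <- as.integer(nFrames * scfg$stride)
  scfg$seed <- as.integer(seed)
  ens <- sampleEnsemble(buildSiteModel(truthFf), truthFf, scfg)
  avg <- ensembleSpectra(ens, grid, cfg = cfg)
  conv <- convolveSpectrum(avg@sigma, truthBroadening)
  y <- conv@values
  if (noiseSd > 0) {
    set.seed(seed + 104729L)  # distinct stream from the sampler
    y <- y + rnorm(length(y), 0, noiseSd)
  }
  if (is.null(epsilon)) epsilon <- if (noiseSd > 0) noiseSd else 0.01
  list(experiment = ExperimentalSpectrum(grid, y, epsilon = epsilon,
         meta = list(synthetic = TRUE, seed = seed)),
       truth = list(ff = truthFf, broadening = truthBroadening,
                    noiseSd = noiseSd, seed = seed, nFrames = nFrames),
       ensemble = ens, average = avg)
}
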