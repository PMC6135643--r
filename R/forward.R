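## Pluggable forward spectral model with a deterministic toy implementation.
##
## The toy model is explicitly a stand-in for a full multiple-scattering
## XANES engine: an EXAFS-like single-scattering oscillation per neighbor
## plus a collinear-focusing correction, chosen so that the Fe-C and
## Fe-N_His distances, the C-O bond length and the Fe-C-O angle all imprint
## on the spectrum.  It depends only on interatomic distances and internal
## angles, hence is invariant under rigid motion of the cluster.

#' Toy forward-model configuration
#'
#' @param gamma0 Edge arctan width Gamma_0, eV (> 0).
#' @param lambda Photoelectron mean free path, Angstrom (> 0).
#' @param phaseA Constant scattering phase, rad.
#' @param phaseB Linear-in-k phase, rad*Angstrom.
#' @param amplitude Overall oscillation amplitude A (dimensionless).
#' @param focusGain Forward-focusing gain g (>= 0).
#' @param focusWidth Angular width w of the focusing lobe, rad (> 0).
#' @param firstShellCutoff Distance separating first-shell scatterers from
#'   the atoms they can shadow, Angstrom.
#' @return A list of class `ToyModelConfig`.
#' @export
#' @examples
#' toyModelConfig()
toyModelConfig <- function(gamma0 = 2, lambda = 8, phaseA = 0,
                           phaseB = -0.35, amplitude = 0.4,
                           focusGain = 2, focusWidth = 0.3,
                           firstShellCutoff = 2.5) {
  stopifnot(gamma0 > 0, lambda > 0, focusWidth > 0, focusGain >= 0)
  structure(list(gamma0 = gamma0, lambda = lambda, phaseA = phaseA,
                 phaseB = phaseB, amplitude = amplitude,
                 focusGain = focusGain, focusWidth = focusWidth,
                 firstShellCutoff = firstShellCutoff),
            class = "ToyModelConfig")
}

# k(E) in 1/Angstrom from energy above the edge in eV
.kOfE <- function(E) 0.5123 * sqrt(pmax(E, 0))

#' Compute an unbroadened per-snapshot spectrum
#'
#' Deterministic toy scattering model: the smooth edge is
#' mu0(E) = 1/2 + (1/pi) arctan(E/Gamma_0); each neighbor j contributes
#' chi_j(E) = A (Z_j/Z_Fe) F_j sin(2 k r_j + a + b k) exp(-2 r_j/lambda) /
#' (k r_j^2) with k(E) = 0.5123 sqrt(E) (chi = 0 at k = 0).  The focusing
#' factor F_j = 1 + g exp(-(pi - beta_j)^2 / (2 w^2)) applies to atoms
#' beyond the first shell shadowed by a first-shell atom; beta_j is the
#' absorber-bridge-atom angle (e.g. Fe-C-O), taken over the most collinear
#' bridge.  Output is mu0(E) (1 + sum_j chi_j(E)).
#'
#' @param cluster A [Cluster-class].
#' @param grid Energies >= 0, eV relative to the edge.
#' @param cfg A [toyModelConfig()] list.
#' @return A [Spectrum-class].  An empty cluster returns pure mu0 with a
#'   warning.
#' @export
computeRawSpectrum <- function(cluster, grid, cfg = toyModelConfig()) {
  if (any(grid < 0)) stop("grid energies must be >= 0")
  mu0 <- 0.5 + atan(grid / cfg$gamma0) / pi
  nb <- cluster@neighbors
  if (!nrow(nb)) {
    warning("empty cluster: returning the bare edge cross section")
    return(Spectrum(grid, mu0, meta = list(model = "toy")))
  }
  k <- .kOfE(grid)
  pos <- as.matrix(nb[, c("x", "y", "z")])
  abspos <- as.numeric(cluster@absorber[1L, c("x", "y", "z")])
  rel <- sweep(pos, 2L, abspos)
  r <- nb$dist
  zAbs <- .elementZ(cluster@absorber$element[1L])
  first <- which(r <= cfg$firstShellCutoff)
  chiSum <- numeric(length(grid))
  posK <- k > 0
  for (j in seq_len(nrow(nb))) {
    fj <- 1
    if (!(j %in% first) && length(first)) {
      # most collinear first-shell bridge: largest absorber-bridge-atom angle
      beta <- vapply(first, function(b) {
        v1 <- -rel[b, ]              # bridge -> absorber
        v2 <- rel[j, ] - rel[b, ]    # bridge -> atom
        cosb <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        acos(max(-1, min(1, cosb)))
      }, 1)
      betaMax <- max(beta)
      fj <- 1 + cfg$focusGain *
        exp(-(pi - betaMax)^2 / (2 * cfg$focusWidth^2))
    }
    chi <- numeric(length(grid))
    chi[posK] <- cfg$amplitude * (nb$Z[j] / zAbs) * fj *
      sin(2 * k[posK] * r[j] + cfg$phaseA + cfg$phaseB * k[posK]) *
      exp(-2 * r[j] / cfg$lambda) / (k[posK] * r[j]^2)
    chiSum <- chiSum + chi
  }
  Spectrum(grid, mu0 * (1 + chiSum), meta = list(model = "toy", cfg = cfg))
}

## calculator registry ------------------------------------------------------

.calculators <- new.env(parent = emptyenv())

#' Register or fetch a forward-model calculator
#'
#' A calculator is any `function(cluster, grid, cfg)` returning a
#' [Spectrum-class]; registering one under a config key lets a full
#' multiple-scattering engine replace the toy model without touching the
#' pipeline.  `"toy"` is registered at load time.
#'
#' @param name Calculator identifier (must be unused for registration).
#' @param fn The calculator function.
#' @return `registerCalculator` returns `name` invisibly;
#'   `getCalculator` returns the function; `listCalculators` the known names.
#' @export
registerCalculator <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  if (exists(name, envir = .calculators, inherits = FALSE))
    stop("calculator '", name, "' is already registered")
  assign(name, fn, envir = .calculators)
  invisible(name)
}

#' @rdname registerCalculator
#' @export
getCalculator <- function(name) {
  if (!exists(name, envir = .calculators, inherits = FALSE))
    stop("no calculator registered under '", name,
         "'; known: ", paste(listCalculators(), collapse = ", "))
  get(name, envir = .calculators, inherits = FALSE)
}

#' @rdname registerCalculator
#' @export
listCalculators <- function() ls(.calculators)

.onLoad <- function(libname, pkgname) {
  if (!exists("toy", envir = .calculators, inherits = FALSE))
    assign("toy", function(cluster, grid, cfg = toyModelConfig())
      computeRawSpectrum(cluster, grid, cfg), envir = .calculators)
}
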