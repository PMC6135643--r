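clusterFromXYZ <- function(xyz, labels = NULL) {
  selectCluster(snapshotFromXYZ(xyz, labels), k = nrow(xyz) - 1L,
                quiet = TRUE)
}

test_that("an empty cluster yields the bare arctan edge", {
  snap <- snapshotFromXYZ(matrix(c(0, 0, 0), 1))
  cl <- new("Cluster", absorber = snap@sites, neighbors =
              cbind(snap@sites[0, ], data.frame(dist = numeric(0))),
            maxSize = 100L)
  grid <- analysisGrid()
  expect_warning(s <- computeRawSpectrum(cl, grid), "empty cluster")
  expect_equal(absorption(s), 0.5 + atan(grid / 2) / pi)
  expect_error(computeRawSpectrum(cl, c(-1, 0, 1)), ">= 0")
})

test_that("single-scatterer oscillation nodes follow 2kr = n*pi and scale as r^-2", {
  cfg <- toyModelConfig(phaseA = 0, phaseB = 0)
  grid <- seq(0, 200, by = 0.05)
  crossings <- function(r) {
    cl <- clusterFromXYZ(rbind(c(0, 0, 0), c(0, 0, r)))
    s <- computeRawSpectrum(cl, grid, cfg)
    mu0 <- 0.5 + atan(grid / cfg$gamma0) / pi
    chi <- absorption(s) / mu0 - 1
    sgn <- sign(chi)
    idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    # linear root refinement between grid points
    grid[idx] - chi[idx] * 0.05 / (chi[idx + 1] - chi[idx])
  }
  # closed-form root oracle: chi = 0 where 2 k r = n pi, k = 0.5123 sqrt(E)
  r <- 1.80
  want <- (seq(1, 20) * pi / (2 * r) / 0.5123)^2
  want <- want[want > 1 & want < 199]
  got <- crossings(r)
  got <- got[got > 1]
  expect_equal(length(got), length(want))
  expect_lt(max(abs(got - want) / want), 1e-3)
  # crossing energies scale as r^-2
  got2 <- crossings(1.90); got2 <- got2[got2 > 1]
  m <- min(length(got2), length(got))
  expect_lt(max(abs(got2[1:m] * 1.90^2 - got[1:m] * 1.80^2) /
                (got[1:m] * 1.80^2)), 2e-3)
})

test_that("forward focusing amplifies the shadowed atom by the documented factor", {
  geom <- function(betaDeg) {
    b <- betaDeg * pi / 180
    o <- c(0, 0, 1.8) + 1.25 * c(sin(pi - b), 0, cos(pi - b))
    rbind(c(0, 0, 0), c(0, 0, 1.8), o)
  }
  grid <- analysisGrid()
  chiO <- function(betaDeg, g) {
    cfg <- toyModelConfig(focusGain = g, focusWidth = 0.3)
    full <- computeRawSpectrum(clusterFromXYZ(geom(betaDeg),
      c("FE", "C_CO", "O_CO")), grid, cfg)
    noO <- computeRawSpectrum(clusterFromXYZ(geom(betaDeg)[1:2, ],
      c("FE", "C_CO")), grid, cfg)
    absorption(full) - absorption(noO)
  }
  # F = chi_O(g)/chi_O(g=0) isolates the focusing factor at any beta
  # (median across energies is robust to the oscillation's zero crossings)
  f180 <- median(chiO(180, 2)[-1] / chiO(180, 0)[-1], na.rm = TRUE)
  f160 <- median(chiO(160, 2)[-1] / chiO(160, 0)[-1], na.rm = TRUE)
  expect_equal(f180, 3, tolerance = 1e-6)  # 1 + g at perfect collinearity
  want160 <- 1 + 2 * exp(-(20 * pi / 180)^2 / (2 * 0.09))
  expect_equal(f160, want160, tolerance = 1e-6)
  # O-shell amplitude ratio between collinear and bent geometries
  expect_equal(f180 / f160, 3 / want160, tolerance = 1e-5)
})

test_that("the spectrum is invariant under rigid rotation and translation", {
  ff <- ffOptimized()
  snap <- buildSiteModel(ff)
  grid <- analysisGrid()
  base <- absorption(computeRawSpectrum(selectCluster(snap, 7, quiet = TRUE),
                                        grid))
  set.seed(13)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Rz <- rbind(c(cos(th[2]), -sin(th[2]), 0),
              c(sin(th[2]), cos(th[2]), 0), c(0, 0, 1))
  R <- Rx %*% Rz
  shift <- runif(3, -5, 5)
  xyz <- as.matrix(snap@sites[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, -shift)
  moved <- snap
  moved@sites[, c("x", "y", "z")] <- xyz
  got <- absorption(computeRawSpectrum(selectCluster(moved, 7, quiet = TRUE),
                                       grid))
  expect_equal(got, base, tolerance = 1e-10)
})

test_that("the spectrum responds to 0.01 A changes in any distance", {
  ff <- ffOptimized()
  grid <- analysisGrid()
  base <- absorption(computeRawSpectrum(
    selectCluster(buildSiteModel(ff), 7, quiet = TRUE), grid))
  for (bond in list(c("FE", "C_CO"), c("FE", "N_HIS"), c("C_CO", "O_CO"))) {
    ff2 <- setFFParam(ff, paste0("bond:", bond[1], "-", bond[2], ":r0"),
                      bondR0(ff, bond[1], bond[2]) + 0.01)
    pert <- absorption(computeRawSpectrum(
      selectCluster(buildSiteModel(ff2), 7, quiet = TRUE), grid))
    expect_gt(sqrt(sum((pert - base)^2)), 1e-4)
  }
})

test_that("the calculator registry selects, rejects duplicates and unknowns", {
  nm <- paste0("const-", format(Sys.time(), "%H%M%OS3"))
  registerCalculator(nm, function(cluster, grid, cfg)
    Spectrum(grid, rep(0.7, length(grid))))
  expect_true(nm %in% listCalculators())
  expect_error(registerCalculator(nm, identity), "already registered")
  expect_error(getCalculator("no-such-engine"), "no calculator")
  # constant calculator propagates through the ensemble average
  ens <- makeTestEnsemble(nFrames = 4, seed = 2)
  avg <- ensembleSpectra(ens, analysisGrid(0, 10, 1), calculator = nm)
  expect_equal(absorption(averageSpectrum(avg)), rep(0.7, 11))
  expect_equal(rfHistory(avg), rep(0, 3))
})
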