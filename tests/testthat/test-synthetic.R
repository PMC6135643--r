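test_that("the template geometry follows the collinear construction", {
  ff <- ffOptimized()  # Fe-C 1.80, C-O 1.25
  snap <- buildSiteModel(ff)
  d <- function(a, b) {
    s <- snap@sites
    i <- which(s$label == a); j <- which(s$label == b)
    sqrt(sum((s[i, c("x", "y", "z")] - s[j, c("x", "y", "z")])^2))
  }
  expect_equal(d("FE", "O_CO"), 3.05)   # collinear sum 1.80 + 1.25
  expect_equal(d("FE", "N_HIS"), 2.04)
  expect_equal(d("FE", "N_PYR1"), 2.00)

  ffC <- ffCharmm()  # 1.90 + 1.128
  expect_equal({
    s <- buildSiteModel(ffC)@sites
    abs(s$z[s$label == "O_CO"])
  }, 3.028)

  # degenerate equilibrium angle is rejected
  bad <- ff
  bad@angles$theta0[2] <- 0
  expect_error(validObject(bad), "\\(0, 180\\]")
  # missing required bond named in the error
  expect_error(buildSiteModel(forceFieldParams(
    bonds = ff@bonds[-2, ], angles = ff@angles)), "FE-C_CO")
})

test_that("sampled bond fluctuations match the harmonic closed form", {
  ff <- ffOptimized()
  ens <- sampleEnsemble(buildSiteModel(ff), ff,
                        samplerConfig(nSteps = 1e6, burnIn = 1e4,
                                      stride = 2, seed = 101))
  v <- var(distanceSeries(ens, "FE", "C_CO"))
  expect_lt(abs(v - kBT(300) / 300) / (kBT(300) / 300), 0.05)  # kT/kb
})

test_that("the bending-angle ensemble matches the Jacobian-weighted closed form", {
  ff <- ffOptimized()  # Fe-C-O ktheta = 67.4, theta0 = 180
  ens <- sampleEnsemble(buildSiteModel(ff), ff,
                        samplerConfig(nSteps = 1e6, burnIn = 1e4,
                                      stride = 2, seed = 103))
  a <- angleStatistics(ens, c("FE", "C_CO", "O_CO"))
  s <- sqrt(kBT(300) / 67.4) * 180 / pi
  expect_equal(a$mean, 180 - s * sqrt(pi / 2), tolerance = 0.005)
  expect_equal(a$sd, s * sqrt(2 - pi / 2), tolerance = 0.05)
  # streaming values equal brute-force per-frame recomputation
  idx <- seq(1, nFrames(ens), by = 50000)
  brute <- vapply(idx, function(i) {
    st <- getSnapshot(ens, i)@sites
    p <- function(l) as.numeric(st[st$label == l, c("x", "y", "z")])
    v1 <- p("FE") - p("C_CO"); v2 <- p("O_CO") - p("C_CO")
    acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  }, 1)
  expect_equal(angleSeries(ens, "FE", "C_CO", "O_CO")[idx], brute,
               tolerance = 1e-12)
})

test_that("bond-length marginals pass a KS test against the Boltzmann density", {
  ff <- ffOptimized()
  ens <- sampleEnsemble(buildSiteModel(ff), ff,
                        samplerConfig(nSteps = 1e6, burnIn = 2e4,
                                      stride = 100, seed = 107))
  d <- distanceSeries(ens, "FE", "C_CO")
  # r^2-weighted Gaussian radial density for the Fe-C bond
  r0 <- 1.80; s2 <- kBT(300) / 300
  rr <- seq(r0 - 6 * sqrt(s2), r0 + 6 * sqrt(s2), length.out = 4001)
  dens <- rr^2 * exp(-(rr - r0)^2 / (2 * s2))
  cdf <- cumsum(dens); cdf <- cdf / cdf[length(cdf)]
  pfun <- function(q) approx(rr, cdf, xout = q, rule = 2)$y
  ks <- suppressWarnings(ks.test(d, pfun))
  expect_gt(ks$p.value, 0.01)
})

test_that("sampling is reproducible and robust to the step size", {
  ff <- ffOptimized()
  cfg <- samplerConfig(nSteps = 5000, stride = 10, seed = 11)
  e1 <- sampleEnsemble(buildSiteModel(ff), ff, cfg)
  e2 <- sampleEnsemble(buildSiteModel(ff), ff, cfg)
  expect_identical(e1@coords, e2@coords)  # bitwise determinism

  # detailed-balance smoke test: doubling the step leaves means within 2 SE
  big <- samplerConfig(nSteps = 2e5, stride = 20, seed = 13, maxStep = 0.08)
  bigger <- samplerConfig(nSteps = 2e5, stride = 20, seed = 15,
                          maxStep = 0.16, autotune = FALSE)
  d1 <- distanceSeries(sampleEnsemble(buildSiteModel(ff), ff, big),
                       "FE", "C_CO")
  d2 <- distanceSeries(sampleEnsemble(buildSiteModel(ff), ff, bigger),
                       "FE", "C_CO")
  se <- sqrt(var(d1) / length(d1) + var(d2) / length(d2))
  # correlated samples: allow a generous multiple of the naive SE
  expect_lt(abs(mean(d1) - mean(d2)), 10 * se)
})

test_that("synthetic experiments close the loop at zero noise", {
  ff <- ffOptimized()
  syn <- makeSyntheticExperiment(ff, noiseSd = 0, nFrames = 80, seed = 109)
  fit <- fitNonstructural(syn$average, syn$experiment,
                          init = syn$truth$broadening)
  expect_lt(rSqValue(fit), 1e-3)
  expect_error(makeSyntheticExperiment(ff, noiseSd = -1), ">= 0")
})

test_that("with noise the per-point residuals are unit-normal on average", {
  ff <- ffOptimized()
  eps <- 0.02
  syn <- makeSyntheticExperiment(ff, noiseSd = eps, nFrames = 80,
                                 seed = 113)
  # same generating ensemble: residuals against the noiseless curve are
  # exactly the injected noise, so R_sq/n ~ chi^2_m / m ~ 1
  clean <- convolveSpectrum(averageSpectrum(syn$average),
                            syn$truth$broadening)
  r <- rSq(absorption(clean), syn$experiment, n = 4) / 4
  expect_gt(r, 0.75)
  expect_lt(r, 1.25)
})

test_that("independent seeds give replicate ensembles within noise bands", {
  ff <- ffOptimized()
  a <- makeSyntheticExperiment(ff, nFrames = 120, seed = 127)
  b <- makeSyntheticExperiment(ff, nFrames = 120, seed = 131)
  ya <- absorption(a$experiment); yb <- absorption(b$experiment)
  expect_gt(cor(ya, yb), 0.999)
  expect_lt(max(abs(ya - yb)), 0.02)
})
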