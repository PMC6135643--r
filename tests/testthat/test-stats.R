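test_that("rSq reproduces hand-evaluated values and scaling laws", {
  e <- ExperimentalSpectrum(1:3, c(0, 0, 0), epsilon = 0.01)
  # perfect fit
  expect_equal(rSq(c(0, 0, 0), e, n = 4), 0)
  # residuals (0.01, 0.02, 0.03), eps 0.01, w 1, n 4 -> 4*(1+4+9)/3
  expect_equal(rSq(c(0.01, 0.02, 0.03), e, n = 4), 56 / 3)
  # doubling epsilon quarters the statistic
  e2 <- ExperimentalSpectrum(1:3, c(0, 0, 0), epsilon = 0.02)
  expect_equal(rSq(c(0.01, 0.02, 0.03), e2, n = 4), 56 / 12)
  expect_error(rSq(numeric(0), ExperimentalSpectrum(numeric(0), numeric(0),
                                                    epsilon = 1), n = 1),
               "m = 0|equal|weights")
  expect_error(rSq(c(1, 2), c(1, 2), n = 1, epsilon = 0), "nonzero")
})

test_that("rSq matches an independent brute-force implementation", {
  set.seed(19)
  for (rep in 1:20) {
    m <- sample(5:60, 1)
    yTh <- rnorm(m); yExp <- rnorm(m)
    eps <- runif(1, 0.001, 0.1)
    w <- runif(m, 0.1, 2)
    n <- sample(1:6, 1)
    e <- ExperimentalSpectrum(seq_len(m), yExp, epsilon = eps, weights = w)
    want <- bruteRsq(yTh, yExp, rep(eps, m), w, n)
    expect_lt(abs(rSq(yTh, e, n = n) - want) / want, 1e-12)
  }
})

test_that("fError computes the squared misfit and its running integral", {
  expect_equal(fError(c(1, 2, 3), c(1, 2, 3))$curve, c(0, 0, 0))
  # constant offset d: curve d^2, integral linear in E
  E <- seq(0, 10, by = 0.5)
  fe <- fError(rep(0.3, length(E)), rep(0.1, length(E)), energies = E)
  expect_equal(fe$curve, rep(0.04, length(E)))
  expect_equal(fe$integral, 0.04 * (E - E[1]), tolerance = 1e-12)
  set.seed(23)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(fError(a, b)$curve, (a - b)^2)  # elementwise oracle
})

test_that("ensembleAverage handles identical and paired spectra exactly", {
  grid <- 0:10
  s <- Spectrum(grid, sin(grid) + 2)
  avg <- ensembleAverage(rep(list(s), 6))
  expect_equal(absorption(averageSpectrum(avg)), absorption(s))
  expect_equal(rfHistory(avg), rep(0, 5))

  s1 <- Spectrum(grid, rep(0, 11)); s2 <- Spectrum(grid, seq(0, 1, 0.1))
  avg2 <- ensembleAverage(list(s1, s2))
  expect_equal(absorption(averageSpectrum(avg2)), seq(0, 0.5, 0.05))
  # hand algebra: R_f(2) = ||s2 - s1||_2 / 2
  expect_equal(rfHistory(avg2), sqrt(sum(seq(0, 1, 0.1)^2)) / 2)
  expect_error(ensembleAverage(list(s1, Spectrum(0:9, rep(1, 10)))),
               "frame 2")
})

test_that("streaming mean equals the batch mean and R_f obeys its identity", {
  set.seed(29)
  n <- 10000; m <- 30
  mat <- matrix(rnorm(n * m, mean = 1), n, m)
  avg <- ensembleAverage(mat)
  expect_lt(max(abs(absorption(averageSpectrum(avg)) - colMeans(mat))),
            1e-12)
  # R_f(N) = ||s_N - sigma^(N-1)||/N, checked against the direct definition
  run <- mat[1, ]
  for (N in 2:500) {
    idcheck <- sqrt(sum((mat[N, ] - run)^2)) / N
    run <- run + (mat[N, ] - run) / N
    expect_lt(abs(rfHistory(avg)[N - 1] - idcheck), 1e-12)
  }
})

test_that("shuffling frame order leaves the final average bit-identical", {
  set.seed(31)
  mat <- matrix(rnorm(500 * 40), 500, 40)
  a <- absorption(averageSpectrum(ensembleAverage(mat)))
  b <- absorption(averageSpectrum(ensembleAverage(mat[sample(500), ])))
  expect_identical(a, b)
})

test_that("R_f of iid noisy frames decays as 1/N", {
  set.seed(37)
  mat <- matrix(rnorm(1000 * 201), 1000, 201)
  rf <- rfHistory(ensembleAverage(mat))
  N <- 2:1000
  keep <- N >= 10
  slope <- coef(lm(log(rf[keep]) ~ log(N[keep])))[[2]]
  expect_lt(abs(slope + 1), 0.1)
})

test_that("convergence checking follows the alternating-stream closed form", {
  grid <- 0:20
  s1 <- rep(0, 21); s2 <- rep(1, 21)
  n <- 400
  mat <- t(vapply(seq_len(n), function(i) if (i %% 2 == 1) s1 else s2,
                  numeric(21)))
  avg <- ensembleAverage(mat)
  D <- sqrt(sum((s2 - s1)^2))
  # closed form: R_f(N) = D/(2(N-1)) for even N, D/(2N) for odd N
  want <- vapply(2:n, function(N)
    if (N %% 2 == 0) D / (2 * (N - 1)) else D / (2 * N), 1)
  expect_equal(rfHistory(avg), want, tolerance = 1e-12)
  tau <- 0.05
  res <- checkConvergence(avg, threshold = tau, after = 2)
  expect_false(res$converged)
  badMax <- max((2:n)[want >= tau])
  expect_equal(res$firstPass, badMax + 1L)
  expect_true(checkConvergence(avg, threshold = tau,
                               after = badMax + 1L)$converged)
  # identical frames converge immediately; threshold 0 never does
  same <- ensembleAverage(matrix(1, 50, 5))
  expect_true(checkConvergence(same, threshold = 1e-6, after = 2)$converged)
  expect_false(checkConvergence(avg, threshold = 0, after = 2)$converged)
})

test_that("a single full-length window reproduces the global fit", {
  ff <- ffOptimized()
  syn <- makeSyntheticExperiment(ff, nFrames = 60, seed = 41)
  ens <- syn$ensemble
  span <- diff(range(frameTimes(ens)))
  w <- windowedRsq(ens, syn$experiment, window = span)
  expect_equal(nrow(w$series), 1L)
  glob <- fitNonstructural(syn$average, syn$experiment)
  expect_equal(w$series$rSq, rSqValue(glob), tolerance = 1e-9)
  expect_error(windowedRsq(ens, syn$experiment, window = 1), "frame spacing")
})

test_that("windowed R_sq is stable across windows of a stationary ensemble", {
  ff <- ffOptimized()
  syn <- makeSyntheticExperiment(ff, nFrames = 400, seed = 43)
  # 200 frames per window
  w <- windowedRsq(syn$ensemble, syn$experiment, window = 1000)
  expect_equal(nrow(w$series), 2L)
  expect_lt((max(w$series$rSq) - min(w$series$rSq)) / mean(w$series$rSq),
            0.2)
  expect_equal(w$best, which.min(w$series$rSq))
})
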