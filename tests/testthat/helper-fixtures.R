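# Shared fixtures: all inputs are generated in code at test time.

# A short sampled ensemble of the heme-CO site.
makeTestEnsemble <- function(ff = ffOptimized(), nFrames = 100, seed = 1,
                             stride = 25) {
  cfg <- samplerConfig(nSteps = nFrames * stride, burnIn = 2000,
                       stride = stride, seed = seed)
  sampleEnsemble(buildSiteModel(ff), ff, cfg)
}

# Concatenate two ensembles that share a template/movable layout; times of
# the second continue after the first.
concatEnsembles <- function(a, b, dt = 5) {
  stopifnot(identical(a@movable, b@movable))
  new("SnapshotEnsemble", template = a@template, movable = a@movable,
      coords = rbind(a@coords, b@coords),
      times = c(a@times, b@times + max(a@times) + dt),
      meta = list())
}

# A bare snapshot with FE at the origin plus arbitrary neighbor positions.
snapshotFromXYZ <- function(xyz, labels = NULL, time = 0, index = 1L) {
  n <- nrow(xyz)
  if (is.null(labels))
    labels <- c("FE", paste0("X", seq_len(n - 1L), recycle0 = TRUE))
  sites <- data.frame(element = c("FE", rep("C", n - 1L)),
                      Z = c(26, rep(6, n - 1L)), label = labels,
                      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                      stringsAsFactors = FALSE)
  new("Snapshot", sites = sites, index = as.integer(index), time = time)
}

# Independent brute-force R_sq used as the formula oracle.
bruteRsq <- function(yTh, yExp, eps, w, n) {
  acc <- 0; wsum <- 0
  for (i in seq_along(yTh)) {
    acc <- acc + w[i] * ((yTh[i] - yExp[i]) / eps[i])^2
    wsum <- wsum + w[i]
  }
  n * acc / wsum
}
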