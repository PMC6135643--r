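writePdbFixture <- function(path, models) {
  # models: list of matrices (atoms x 3); atom names FE, X2, X3...
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(models)) {
    xyz <- models[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    nm <- c("FE", paste0("C", seq_len(nrow(xyz) - 1L)))
    el <- c("FE", rep(" C", nrow(xyz) - 1L))
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(xyz)), nm, "HEM", 1L, xyz[, 1], xyz[, 2], xyz[, 3],
      1, 0, el), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

test_that("multi-model PDB reads into one snapshot per model", {
  f <- withr::local_tempfile(fileext = ".pdb")
  set.seed(5)
  m1 <- cbind(0, 0, 0:4); m2 <- m1 + 0.1
  writePdbFixture(f, list(m1, m2))
  ens <- readFrames(f)
  expect_equal(nFrames(ens), 2L)
  expect_equal(nrow(ens@template), 5L)
  expect_equal(frameTimes(ens), c(0, 5))
  s2 <- getSnapshot(ens, 2L)
  expect_equal(s2@sites$z, m2[, 3], tolerance = 1e-9)
})

test_that("PDB frames with differing atom counts are rejected with indices", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writePdbFixture(f, list(cbind(0, 0, 0:3), cbind(0, 0, 0:4)))
  expect_error(readFrames(f), "differing atom counts.*2")
})

test_that("sampler-written PDB round-trips coordinates to PDB precision", {
  ens <- makeTestEnsemble(nFrames = 5, seed = 3)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeFramesPDB(ens, f)
  back <- readFrames(f)
  expect_equal(nFrames(back), 5L)
  expect_identical(back@template$label, ens@template$label)
  for (i in 1:5) {
    a <- as.matrix(getSnapshot(ens, i)@sites[, c("x", "y", "z")])
    b <- as.matrix(getSnapshot(back, i)@sites[, c("x", "y", "z")])
    expect_lt(max(abs(a - b)), 1e-3 + 1e-12)
  }
})

test_that("multi-frame XYZ parses and flags malformed count lines", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "frame 1", "FE 0 0 0", "C 0 0 1.8", "O 0 0 3.05",
               "3", "frame 2", "FE 0 0 0", "C 0 0 1.9", "O 0 0 3.0"), f)
  ens <- readFrames(f)
  expect_equal(nFrames(ens), 2L)
  expect_equal(ens@template$label, c("FE", "C_CO", "O_CO"))
  expect_equal(getSnapshot(ens, 2L)@sites$z[2], 1.9)

  writeLines(c("3", "frame", "FE 0 0 0", "C 0 0 1.8", "O 0 0 3.05",
               "nonsense", "x"), f)
  expect_error(readFrames(f), "line 6")
})

test_that("subsampling keeps frames at integer multiples of the interval", {
  ens <- makeTestEnsemble(nFrames = 101, seed = 2)
  ens@times <- seq(0, 100, by = 1)  # 0..100 ps at 1 ps
  sub <- subsampleFrames(ens, every = 5)
  expect_equal(nFrames(sub), 21L)
  expect_equal(frameTimes(sub), seq(0, 100, by = 5))
  # native spacing is the identity
  expect_equal(nFrames(subsampleFrames(ens, every = 1)), 101L)
  expect_error(subsampleFrames(ens, every = 0), "positive")
})

test_that("subsampling irregular times matches a brute-force filter", {
  ens <- makeTestEnsemble(nFrames = 60, seed = 9)
  set.seed(7)
  t <- sort(round(runif(60, 0, 40), 3))
  t <- t + seq_along(t) * 1e-9  # strictly ordered
  ens@times <- t
  sub <- subsampleFrames(ens, every = 2.5)
  keep <- vapply(t, function(x) abs(x - 2.5 * round(x / 2.5)) <= 1e-6,
                 TRUE)
  expect_equal(frameTimes(sub), t[keep])
})

test_that("selectCluster keeps the k nearest atoms sorted by distance", {
  set.seed(21)
  xyz <- rbind(c(0, 0, 0), matrix(rnorm(149 * 3, sd = 4), ncol = 3))
  snap <- snapshotFromXYZ(xyz)
  cl <- selectCluster(snap, k = 100)
  expect_equal(nrow(cl@neighbors), 100L)
  expect_true(all(diff(cl@neighbors$dist) >= 0))
  d <- sort(sqrt(rowSums(xyz[-1, ]^2)))
  expect_equal(cl@neighbors$dist, d[1:100])
})

test_that("selectCluster exhausts small snapshots with a warning", {
  snap <- snapshotFromXYZ(rbind(c(0, 0, 0), cbind(0, 0, 1:4)))
  expect_warning(cl <- selectCluster(snap, k = 100), "4 atoms")
  expect_equal(nrow(cl@neighbors), 4L)
})

test_that("distance ties at the cluster boundary break by input order", {
  # two atoms at exactly 2.0 A straddling a k=2 cutoff behind a 1.0 A atom
  xyz <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 2, 0), c(2, 0, 0))
  snap <- snapshotFromXYZ(xyz)
  cl <- selectCluster(snap, k = 2, quiet = TRUE)
  expect_equal(cl@neighbors$label, c("X1", "X2"))  # earlier index kept
})

test_that("rdf concentrates a fixed neighbor in one bin and counts coordination", {
  ff <- ffOptimized()
  snaps <- lapply(1:10, function(i)
    snapshotFromXYZ(rbind(c(0, 0, 0), c(0, 0, 2.00)), time = i - 1))
  ens <- ensembleFromSnapshots(snaps)
  r <- rdf(ens, group = "X1", binWidth = 0.02, rMax = 5)
  expect_equal(sum(r@density > 0), 1L)
  expect_equal(sum(r@density), 1)  # one neighbor per frame
  peak <- r@binCenters[which.max(r@density)]
  expect_lt(abs(peak - 2.00), 0.02)
  expect_equal(r@coordination[max(which(r@binCenters < 2.5))], 1.0)
})

test_that("rdf coordination steps at each shell", {
  snaps <- lapply(1:4, function(i)
    snapshotFromXYZ(rbind(c(0, 0, 0), c(0, 0, 1.8), c(0, 3.0, 0)),
                    labels = c("FE", "A", "B"), time = i - 1))
  ens <- ensembleFromSnapshots(snaps)
  r <- rdf(ens, group = c("A", "B"), binWidth = 0.02, rMax = 5)
  coordAt <- function(x) r@coordination[max(which(r@binCenters < x))]
  expect_equal(coordAt(2.5), 1)
  expect_equal(coordAt(3.5), 2)
})

test_that("rdf histogram matches brute-force shell counting on random data", {
  set.seed(77)
  n <- 1000
  pos <- matrix(runif(n * 3, -3, 3), ncol = 3)
  snaps <- lapply(seq_len(n), function(i)
    snapshotFromXYZ(rbind(c(0, 0, 0), pos[i, , drop = FALSE]),
                    time = i - 1))
  ens <- ensembleFromSnapshots(snaps)
  bw <- 0.1; rmax <- 6
  r <- rdf(ens, group = "X1", binWidth = bw, rMax = rmax)
  d <- sqrt(rowSums(pos^2))
  breaks <- seq(0, rmax, by = bw)
  brute <- vapply(seq_len(length(breaks) - 1L), function(b)
    sum(d > breaks[b] & d <= breaks[b + 1L]), 1L)
  expect_equal(r@density * n, as.numeric(brute))
  expect_true(all(diff(r@coordination) >= 0))
  # terminal coordination equals mean selected-group size
  expect_equal(r@coordination[length(r@coordination)],
               sum(d <= rmax) / n)
  expect_error(rdf(ens, group = "NOPE"), "empty group")
})

test_that("cluster selection is invariant to atom input order up to tie-breaks", {
  set.seed(31)
  xyz <- rbind(c(0, 0, 0), matrix(rnorm(30, sd = 3), ncol = 3))
  snap <- snapshotFromXYZ(xyz)
  perm <- c(1L, sample(2:11))
  snapP <- snapshotFromXYZ(xyz[perm, ],
                           labels = c("FE", paste0("X", perm[-1] - 1L)))
  a <- selectCluster(snap, k = 5, quiet = TRUE)
  b <- selectCluster(snapP, k = 5, quiet = TRUE)
  expect_equal(sort(a@neighbors$label), sort(b@neighbors$label))
  expect_equal(a@neighbors$dist, b@neighbors$dist, tolerance = 1e-12)
})
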