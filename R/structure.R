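## Trajectory ingestion, cluster extraction, radial distribution analysis.

# Z lookup for the elements this package meets in practice.
.zTable <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16, FE = 26)

.elementZ <- function(element) {
  z <- .zTable[toupper(element)]
  z[is.na(z)] <- 6  # unknown elements scatter like carbon
  as.numeric(z)
}

#' Default atom-name to role-label mapping
#'
#' Maps PDB/XYZ atom names onto the role labels used throughout the package
#' (FE, N_PYR1..4 pyrrole nitrogens, N_HIS proximal histidine nitrogen,
#' C_CO / O_CO the carbonyl ligand).  Users may supply their own named
#' vector to [readFrames()]; unmapped names pass through unchanged.
#'
#' @return Named character vector (atom name -> label).
#' @export
defaultLabelMap <- function() {
  c(FE = "FE", N1 = "N_PYR1", N2 = "N_PYR2", N3 = "N_PYR3", N4 = "N_PYR4",
    NHIS = "N_HIS", C = "C_CO", O = "O_CO")
}

.labelToAtomName <- function(label) {
  map <- defaultLabelMap()
  rev <- setNames(names(map), map)
  nm <- rev[label]
  nm[is.na(nm)] <- substr(gsub("_", "", label[is.na(nm)]), 1L, 4L)
  unname(nm)
}

#' Build a compact ensemble from a list of snapshots
#'
#' All frames must share the same atom count and ordering; every atom is
#' treated as movable.
#'
#' @param snapshots List of [Snapshot-class] objects.
#' @return A [SnapshotEnsemble-class].
#' @export
ensembleFromSnapshots <- function(snapshots) {
  stopifnot(length(snapshots) >= 1L)
  n <- vapply(snapshots, function(s) nrow(s@sites), 1L)
  if (length(unique(n)) != 1L)
    stop("frames with differing atom counts: ",
         paste(which(n != n[1L]), collapse = ", "))
  template <- snapshots[[1L]]@sites
  coords <- t(vapply(snapshots, function(s)
    as.numeric(t(as.matrix(s@sites[, c("x", "y", "z")]))),
    numeric(3L * n[1L])))
  new("SnapshotEnsemble", template = template,
      movable = seq_len(n[1L]), coords = coords,
      times = vapply(snapshots, function(s) s@time, 1),
      meta = list())
}

#' Read a multi-frame trajectory
#'
#' Supports multi-model PDB (MODEL/ENDMDL records, read through bio3d) and
#' multi-frame XYZ.  Role labels are assigned from atom names via
#' `labelMap`; unmapped names keep their atom name as label.  Neither format
#' carries times, so frames are stamped `0, frameDt, 2*frameDt, ...` ps.
#'
#' @param path File path.
#' @param fmt `"pdb"` or `"xyz"`; guessed from the extension by default.
#' @param labelMap Named character vector, atom name -> label.
#' @param frameDt Time between frames, ps (default 5, the usual snapshot
#'   collection interval).
#' @return A [SnapshotEnsemble-class].
#' @export
readFrames <- function(path, fmt = c("auto", "pdb", "xyz"),
                       labelMap = defaultLabelMap(), frameDt = 5) {
  fmt <- match.arg(fmt)
  if (fmt == "auto")
    fmt <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  if (fmt == "pdb") .readFramesPDB(path, labelMap, frameDt)
  else .readFramesXYZ(path, labelMap, frameDt)
}

.checkModelAtomCounts <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) && length(starts) == length(ends)) {
    counts <- mapply(function(s, e)
      sum(grepl("^(ATOM|HETATM)", lines[s:e])), starts, ends)
    if (length(unique(counts)) > 1L)
      stop("frames with differing atom counts: models ",
           paste(which(counts != counts[1L]), collapse = ", "))
  }
  invisible(NULL)
}

.readFramesPDB <- function(path, labelMap, frameDt) {
  .checkModelAtomCounts(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  names0 <- trimws(pdb$atom$elety)
  labels <- unname(ifelse(names0 %in% names(labelMap),
                          labelMap[names0], names0))
  elem <- trimws(pdb$atom$elesy)
  if (all(is.na(elem)) || all(elem == ""))
    elem <- substr(names0, 1L, 1L)
  elem[labels == "FE"] <- "FE"
  template <- data.frame(element = elem, Z = .elementZ(elem),
                         label = labels,
                         x = xyz[1L, c(TRUE, FALSE, FALSE)],
                         y = xyz[1L, c(FALSE, TRUE, FALSE)],
                         z = xyz[1L, c(FALSE, FALSE, TRUE)],
                         stringsAsFactors = FALSE)
  nfr <- nrow(xyz)
  # bio3d row layout (x1 y1 z1 x2 ...) matches the ensemble layout
  new("SnapshotEnsemble", template = template,
      movable = seq_len(nrow(template)), coords = unclass(xyz)[, , drop = FALSE],
      times = (seq_len(nfr) - 1) * frameDt, meta = list(source = path))
}

.readFramesXYZ <- function(path, labelMap, frameDt) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat <= 0)
      stop(sprintf("malformed atom-count line %d in %s: '%s'",
                   i, path, lines[i]))
    if (i + 1L + nat > length(lines))
      stop(sprintf("truncated frame starting at line %d in %s", i, path))
    block <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    bad <- which(vapply(parts, length, 1L) < 4L)
    if (length(bad))
      stop(sprintf("malformed atom line %d in %s", i + 1L + bad[1L], path))
    nm <- vapply(parts, `[[`, "", 1L)
    xyz <- vapply(parts, function(p) as.numeric(p[2:4]), numeric(3L))
    if (any(is.na(xyz)))
      stop(sprintf("non-numeric coordinates in frame starting at line %d in %s",
                   i, path))
    frames[[length(frames) + 1L]] <- list(names = nm, xyz = t(xyz))
    i <- i + 2L + nat
  }
  if (!length(frames)) stop("no frames in ", path)
  nat <- vapply(frames, function(f) nrow(f$xyz), 1L)
  if (length(unique(nat)) != 1L)
    stop("frames with differing atom counts: ",
         paste(which(nat != nat[1L]), collapse = ", "))
  nm <- frames[[1L]]$names
  labels <- unname(ifelse(nm %in% names(labelMap), labelMap[nm], nm))
  elem <- ifelse(toupper(nm) %in% names(.zTable), toupper(nm),
                 substr(nm, 1L, 1L))
  elem[labels == "FE"] <- "FE"
  template <- data.frame(element = elem, Z = .elementZ(elem), label = labels,
                         x = frames[[1L]]$xyz[, 1L],
                         y = frames[[1L]]$xyz[, 2L],
                         z = frames[[1L]]$xyz[, 3L],
                         stringsAsFactors = FALSE)
  coords <- t(vapply(frames, function(f) as.numeric(t(f$xyz)),
                     numeric(3L * nat[1L])))
  new("SnapshotEnsemble", template = template,
      movable = seq_len(nat[1L]), coords = coords,
      times = (seq_along(frames) - 1) * frameDt,
      meta = list(source = path))
}

#' Write an ensemble as a multi-model PDB
#'
#' One MODEL/ENDMDL block per frame; atom names encode role labels through
#' the reverse of [defaultLabelMap()].  Coordinates carry the standard PDB
#' precision of 1e-3 Angstrom.
#'
#' @param ens A [SnapshotEnsemble-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFramesPDB <- function(ens, path) {
  template <- ens@template
  names <- .labelToAtomName(template$label)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nFrames(ens))) {
    snap <- getSnapshot(ens, i)
    s <- snap@sites
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(s)), names, "HEM", 1L, s$x, s$y, s$z, 1, 0,
      toupper(substr(s$element, 1L, 2L))), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Subsample frames at a fixed time interval
#'
#' Keeps frames whose time stamp is an integer multiple of `every` (within
#' 1e-6 ps), emulating snapshot collection at a fixed interval.
#'
#' @param ens A [SnapshotEnsemble-class].
#' @param every Interval in ps, > 0.
#' @return The subsampled [SnapshotEnsemble-class].
#' @export
subsampleFrames <- function(ens, every) {
  if (!is.numeric(every) || length(every) != 1L || every <= 0)
    stop("'every' must be a positive interval in ps")
  t <- ens@times
  keep <- abs(t - every * round(t / every)) <= 1e-6
  new("SnapshotEnsemble", template = ens@template, movable = ens@movable,
      coords = ens@coords[keep, , drop = FALSE], times = t[keep],
      meta = ens@meta)
}

# n x 3 matrix of one labeled site's coordinates across frames.
.siteCoords <- function(ens, label) {
  idx <- which(ens@template$label == label)
  if (!length(idx)) stop("no site labeled '", label, "' in ensemble")
  idx <- idx[1L]
  n <- nFrames(ens)
  j <- match(idx, ens@movable)
  if (is.na(j)) {
    matrix(rep(as.numeric(ens@template[idx, c("x", "y", "z")]), each = n),
           nrow = n)
  } else {
    ens@coords[, (3L * j - 2L):(3L * j), drop = FALSE]
  }
}

#' Extract the absorber-centered cluster from a snapshot
#'
#' Selects the `k` nearest non-absorber sites by Euclidean distance to the
#' FE absorber (the forward model's input; 100 atoms is the conventional
#' cluster size).  Ties are broken by input atom order.  When fewer than `k`
#' atoms exist, all are kept and a warning is raised.
#'
#' @param snapshot A [Snapshot-class].
#' @param k Maximum neighbor count (default 100).
#' @param quiet Suppress the exhaustion warning.
#' @return A [Cluster-class].
#' @export
selectCluster <- function(snapshot, k = 100, quiet = FALSE) {
  s <- snapshot@sites
  fe <- which(s$label == "FE")[1L]
  others <- setdiff(seq_len(nrow(s)), fe)
  d <- sqrt((s$x[others] - s$x[fe])^2 + (s$y[others] - s$y[fe])^2 +
            (s$z[others] - s$z[fe])^2)
  ord <- order(d, seq_along(d))  # stable: ties keep input order
  kk <- min(k, length(others))
  if (kk < k && !quiet)
    warning(sprintf("only %d atoms available for a %d-atom cluster", kk, k))
  pick <- others[ord[seq_len(kk)]]
  nb <- s[pick, , drop = FALSE]
  nb$dist <- d[ord[seq_len(kk)]]
  rownames(nb) <- NULL
  new("Cluster", absorber = s[fe, , drop = FALSE], neighbors = nb,
      maxSize = as.integer(k))
}

#' Radial distribution function with running coordination number
#'
#' Histograms absorber-group distances over all frames (raw counts per frame
#' per bin, the convention under which peak positions read directly as bond
#' lengths) and accumulates the running mean neighbor count within r.
#'
#' @param ens A [SnapshotEnsemble-class].
#' @param group Character vector of site labels to include.
#' @param binWidth Bin width in Angstrom (default 0.02).
#' @param rMax Histogram range in Angstrom (default 10).
#' @return An [RdFResult-class].
#' @export
rdf <- function(ens, group, binWidth = 0.02, rMax = 10) {
  if (binWidth <= 0) stop("binWidth must be > 0")
  if (rMax <= binWidth) stop("rMax must exceed binWidth")
  sel <- which(ens@template$label %in% group)
  sel <- setdiff(sel, which(ens@template$label == "FE"))
  if (!length(sel)) stop("empty group selection: ",
                         paste(group, collapse = ", "))
  fe <- .siteCoords(ens, "FE")
  breaks <- seq(0, rMax, by = binWidth)
  nb <- length(breaks) - 1L
  counts <- numeric(nb)
  n <- nFrames(ens)
  for (idx in sel) {
    lab <- ens@template$label[idx]
    # index-addressed to survive duplicate labels
    j <- match(idx, ens@movable)
    xyz <- if (is.na(j))
      matrix(rep(as.numeric(ens@template[idx, c("x", "y", "z")]), each = n),
             nrow = n)
    else ens@coords[, (3L * j - 2L):(3L * j), drop = FALSE]
    d <- sqrt(rowSums((xyz - fe)^2))
    bin <- findInterval(d, breaks, rightmost.closed = TRUE,
                        left.open = TRUE)
    bin <- bin[bin >= 1L & bin <= nb]
    counts <- counts + tabulate(bin, nbins = nb)
  }
  new("RdFResult",
      binCenters = breaks[-length(breaks)] + binWidth / 2,
      density = counts / n,
      coordination = cumsum(counts) / n,
      binWidth = binWidth, nFrames = as.integer(n),
      group = as.character(group))
}

#' Export an RdF result as CSV
#'
#' @param x An [RdFResult-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeRdFCSV <- function(x, path) {
  df <- data.frame(r_angstrom = x@binCenters,
                   counts_per_frame = x@density,
                   coordination_number = x@coordination)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
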