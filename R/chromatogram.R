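# Chromatogram container, file readers, extracted ion traces and apex
# detection.
#
# A chromatogram is a per-sample scan grid: a strictly increasing vector of
# retention times (minutes) plus one intensity vector per nominal m/z,
# stored as a scans x m/z matrix.  Fragment readings are binned to nominal
# mass (round half-up) and summed within a scan; scans are the time
# resolution throughout — intensities are never interpolated.

#' Construct a chromatogram
#'
#' @param rts strictly increasing scan retention times, minutes.
#' @param traces numeric matrix, `length(rts)` rows, one column per nominal
#'   m/z; column names are the integer m/z values. Intensities must be
#'   non-negative.
#' @param sample_id sample identifier string.
#' @return object of class `chromatogram`.
#' @export
chromatogram <- function(rts, traces, sample_id = "sample") {
  rts <- as.numeric(rts)
  traces <- as.matrix(traces)
  if (length(rts) == 0L) stop("no scans", call. = FALSE)
  if (is.unsorted(rts, strictly = TRUE)) {
    stop("scan retention times must be strictly increasing", call. = FALSE)
  }
  if (nrow(traces) != length(rts)) {
    stop("traces must have one row per scan", call. = FALSE)
  }
  if (is.null(colnames(traces))) {
    stop("trace columns must be named by nominal m/z", call. = FALSE)
  }
  if (any(traces < 0)) stop("intensities must be non-negative", call. = FALSE)
  storage.mode(traces) <- "double"
  structure(list(sample_id = as.character(sample_id),
                 rts = rts, traces = traces),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf(
    "Chromatogram '%s': %d scans, %.2f-%.2f min, %d ion trace(s)\n",
    x$sample_id, length(x$rts), min(x$rts), max(x$rts), ncol(x$traces)))
  invisible(x)
}

#' Read a GC-MS sample file
#'
#' Reads a sample into the scan-grid representation.  Supported formats:
#'
#' * `"delimited"`: long format with header `rt_minutes,mz,intensity`
#'   (comma- or tab-separated);
#' * `"mzml"`: mzML 1.1, MS1 scans only (requires the `mzR` package);
#' * `"cdf"`: ANDI-MS/netCDF (requires `mzR`).
#'
#' Scans are sorted by retention time, m/z readings are binned to nominal
#' (integer) mass by rounding half-up and summing within a scan, and
#' retention times are converted to minutes (mzML and netCDF store
#' seconds).
#'
#' @param path path to the sample file.
#' @param format `"auto"` (from the file extension), `"delimited"`,
#'   `"mzml"` or `"cdf"`.
#' @param sample_id sample identifier; defaults to the file name without
#'   extension.
#' @return a [chromatogram()].
#' @export
read_chromatogram <- function(path,
                              format = c("auto", "delimited", "mzml", "cdf"),
                              sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("sample file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     mzml = "mzml",
                     cdf = "cdf",
                     nc = "cdf",
                     "delimited")
  }
  if (is.null(sample_id)) {
    sample_id <- tools::file_path_sans_ext(basename(path))
  }
  scans <- switch(format,
                  delimited = read_scans_delimited(path),
                  mzml = read_scans_mzr(path, backend = "pwiz"),
                  cdf = read_scans_mzr(path, backend = "netCDF"))
  build_chromatogram(scans$rt, scans$mz, scans$intensity, sample_id)
}

read_scans_delimited <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("no scans", call. = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  d <- utils::read.table(path, sep = sep, header = TRUE,
                         stringsAsFactors = FALSE, strip.white = TRUE)
  names(d) <- tolower(names(d))
  rt_col <- intersect(c("rt_minutes", "rt"), names(d))[1]
  if (is.na(rt_col) || !all(c("mz", "intensity") %in% names(d))) {
    stop("delimited sample needs columns rt_minutes, mz, intensity",
         call. = FALSE)
  }
  if (nrow(d) == 0L) stop("no scans", call. = FALSE)
  bad <- !is.finite(d[[rt_col]]) | !is.finite(d$mz) | !is.finite(d$intensity)
  if (any(bad)) {
    stop("non-numeric value at data row ", which(bad)[1], call. = FALSE)
  }
  list(rt = d[[rt_col]], mz = d$mz, intensity = d$intensity)
}

read_scans_mzr <- function(path, backend) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading this format requires the 'mzR' package", call. = FALSE)
  }
  ms <- mzR::openMSfile(path, backend = backend)
  on.exit(mzR::close(ms))
  hdr <- mzR::header(ms)
  keep <- if ("msLevel" %in% names(hdr)) {
    which(is.na(hdr$msLevel) | hdr$msLevel == 1L)
  } else seq_len(nrow(hdr))
  if (length(keep) == 0L) stop("no scans", call. = FALSE)
  pk <- mzR::peaks(ms, keep)
  if (is.matrix(pk)) pk <- list(pk)
  n <- vapply(pk, nrow, integer(1))
  rt_min <- hdr$retentionTime[keep] / 60
  list(rt = rep.int(rt_min, n),
       mz = unlist(lapply(pk, function(m) m[, 1L]), use.names = FALSE),
       intensity = unlist(lapply(pk, function(m) m[, 2L]), use.names = FALSE))
}

build_chromatogram <- function(rt, mz, intensity, sample_id) {
  if (length(rt) == 0L) stop("no scans", call. = FALSE)
  mz_bin <- round_half_up(mz)
  rts <- sort(unique(rt))
  mzs <- sort(unique(mz_bin))
  traces <- matrix(0, nrow = length(rts), ncol = length(mzs),
                   dimnames = list(NULL, as.character(mzs)))
  i <- match(rt, rts)
  j <- match(mz_bin, mzs)
  # sum readings binned to the same (scan, nominal mass) cell
  for (k in seq_along(i)) {
    traces[i[k], j[k]] <- traces[i[k], j[k]] + intensity[k]
  }
  chromatogram(rts, traces, sample_id)
}

#' Extracted ion chromatogram
#'
#' Returns the intensity-vs-RT trace of a single nominal m/z.  An m/z not
#' recorded in the sample yields an all-zero trace of matching length, so
#' downstream scoring treats "fragment never detected" and "fragment at
#' zero intensity" identically.
#'
#' @param chrom a [chromatogram()].
#' @param mz nominal (integer) m/z.
#' @return an `ion_trace`: list with `mz`, `rts`, `intensities`.
#' @export
eic <- function(chrom, mz) {
  stopifnot(inherits(chrom, "chromatogram"))
  key <- as.character(round_half_up(mz))
  ints <- if (key %in% colnames(chrom$traces)) {
    chrom$traces[, key]
  } else {
    rep.int(0, length(chrom$rts))
  }
  structure(list(mz = round_half_up(mz), rts = chrom$rts,
                 intensities = as.numeric(ints)),
            class = "ion_trace")
}

# Indices of local maxima of an intensity series.  A plateau (run of equal
# values) strictly greater than both flanking values is an apex reported at
# its first scan; series endpoints qualify against their single inner
# neighbour (a single-scan series is its own apex).  Zero-intensity apices
# are discarded by the callers.
apex_indices <- function(y) {
  n <- length(y)
  if (n == 0L) return(integer())
  r <- rle(y)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  left <- c(-Inf, r$values[-k])
  right <- c(r$values[-1L], -Inf)
  starts[r$values > left & r$values > right]
}

#' Candidate peak apices of an ion trace
#'
#' Local maxima of the trace restricted to a closed RT window: scans whose
#' intensity is strictly greater than both neighbours (plateaus report
#' their first scan; a series endpoint is compared against its single
#' neighbour), with positive intensity.  Apices are located on the full
#' series and then filtered to the window, so a window boundary cannot
#' suppress an apex lying exactly on it.
#'
#' @param trace an `ion_trace` from [eic()].
#' @param window closed RT interval `c(lo, hi)`, minutes.
#' @return ascending numeric vector of apex RTs (possibly empty).
#' @export
find_apices <- function(trace, window = range(trace$rts)) {
  stopifnot(inherits(trace, "ion_trace"), length(window) == 2L)
  idx <- apex_indices(trace$intensities)
  idx <- idx[trace$intensities[idx] > 0]
  rts <- trace$rts[idx]
  sort(rts[rts >= window[1] & rts <= window[2]])
}

# First and last scan index inside the closed RT window, or NULL when the
# window holds no scan.  Binary search (findInterval) — hot path for the
# scoring engine.
window_bounds <- function(rts, window) {
  start <- findInterval(window[1], rts)
  if (start == 0L || rts[start] < window[1]) start <- start + 1L
  end <- findInterval(window[2], rts)
  if (start > end) return(NULL)
  c(start, end)
}

#' Maximum trace intensity over an RT window
#'
#' @param trace an `ion_trace`.
#' @param window closed RT interval `c(lo, hi)`, minutes.
#' @return the maximum intensity among scans with RT in the window, or 0
#'   when no scan falls inside it.
#' @export
window_max <- function(trace, window) {
  stopifnot(inherits(trace, "ion_trace"), length(window) == 2L)
  b <- window_bounds(trace$rts, window)
  if (is.null(b)) return(0)
  max(trace$intensities[b[1]:b[2]])
}

#' Write a chromatogram
#'
#' Writes a chromatogram in the delimited long format
#' (`rt_minutes,mz,intensity`; zero cells omitted, but every scan appears
#' at least once so the scan grid survives a round trip) or as mzML via
#' `mzR`.
#'
#' @param chrom a [chromatogram()].
#' @param path output path.
#' @param format `"delimited"` or `"mzml"`.
#' @return `path`, invisibly.
#' @export
write_chromatogram <- function(chrom, path, format = c("delimited", "mzml")) {
  stopifnot(inherits(chrom, "chromatogram"))
  format <- match.arg(format)
  if (format == "delimited") {
    rows <- chromatogram_long(chrom)
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("writing mzML requires the 'mzR' package", call. = FALSE)
  }
  mzs <- as.numeric(colnames(chrom$traces))
  spectra <- lapply(seq_along(chrom$rts), function(i) {
    ints <- chrom$traces[i, ]
    nz <- which(ints > 0)
    if (length(nz) == 0L) nz <- 1L  # placeholder keeps the scan on the grid
    cbind(mz = mzs[nz], intensity = as.numeric(ints[nz]))
  })
  n <- length(spectra)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L, peaksCount = vapply(spectra, nrow, integer(1)),
    totIonCurrent = vapply(spectra, function(s) sum(s[, 2L]), numeric(1)),
    retentionTime = chrom$rts * 60,
    basePeakMZ = vapply(spectra, function(s) s[which.max(s[, 2L]), 1L], numeric(1)),
    basePeakIntensity = vapply(spectra, function(s) max(s[, 2L]), numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = min(mzs), highMZ = max(mzs),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE)
  mzR::writeMSData(spectra, path, header = hdr)
  invisible(path)
}

chromatogram_long <- function(chrom) {
  mzs <- as.integer(colnames(chrom$traces))
  out <- vector("list", length(chrom$rts))
  for (i in seq_along(chrom$rts)) {
    ints <- chrom$traces[i, ]
    nz <- which(ints > 0)
    if (length(nz) == 0L) {
      out[[i]] <- data.frame(rt_minutes = chrom$rts[i], mz = mzs[1L],
                             intensity = 0)
    } else {
      out[[i]] <- data.frame(rt_minutes = chrom$rts[i], mz = mzs[nz],
                             intensity = as.numeric(ints[nz]))
    }
  }
  do.call(rbind, out)
}

#' Total ion current
#'
#' Sum of all ion traces at each scan.
#'
#' @param chrom a [chromatogram()].
#' @return numeric vector aligned with `chrom$rts`.
#' @export
total_ion_current <- function(chrom) {
  stopifnot(inherits(chrom, "chromatogram"))
  as.numeric(rowSums(chrom$traces))
}
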