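# Fixture builders shared across the suite.  All fixtures are generated in
# code; nothing is read from disk except the bundled standard library.

# Build a spectral_library through the public reader (exercises parsing).
make_library <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  read_spectral_library(path)
}

two_compound_library <- function() {
  make_library(data.frame(
    compound = c("CompA", "CompB"),
    expected_rt = c(5.0, 6.0),
    m1 = c(50, 80), m2 = c(60, 90), m3 = c(70, 100), m4 = c(75, 110),
    r2 = c(0.8, 0.5), r3 = c(0.5, 0.25), r4 = c(0.2, 0.1)))
}

# Chromatogram with Gaussian fragment peaks placed directly (no synth
# module), for engine tests that want full manual control.
# peaks: data.frame(mz, center, height, sigma)
gaussian_chromatogram <- function(peaks, rts = seq(4, 7, by = 0.005),
                                  sample_id = "fixture") {
  mzs <- sort(unique(peaks$mz))
  traces <- matrix(0, nrow = length(rts), ncol = length(mzs),
                   dimnames = list(NULL, as.character(mzs)))
  for (k in seq_len(nrow(peaks))) {
    center <- rts[which.min(abs(rts - peaks$center[k]))]
    col <- as.character(peaks$mz[k])
    traces[, col] <- traces[, col] +
      peaks$height[k] * exp(-((rts - center)^2) / (2 * peaks$sigma[k]^2))
  }
  chromatogram(rts, traces, sample_id)
}

# One clean compound-A signal at its expected RT with exact library ratios.
clean_compA_chromatogram <- function(height = 1000, center = 5.0,
                                     sigma = 0.02) {
  gaussian_chromatogram(data.frame(
    mz = c(50, 60, 70, 75), center = center,
    height = height * c(1, 0.8, 0.5, 0.2), sigma = sigma))
}

first_group <- function(chrom, entry, params = pscore_params()) {
  groups <- candidate_groups(chrom, entry, params)
  stopifnot(length(groups) >= 1L)
  groups[[1]]
}

entry_trace_list <- function(chrom, entry) {
  lapply(as.integer(unlist(entry[c("m1", "m2", "m3", "m4")])),
         function(m) eic(chrom, m))
}

search_window <- function(entry, params) {
  entry$expected_rt + c(-1, 1) * params$w
}
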