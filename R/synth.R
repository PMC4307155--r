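# Synthetic GC-MS chromatograms with known ground truth.
#
# Each present compound contributes one Gaussian peak per expected
# fragment, centred at its (offset) expected RT and scaled by the library
# ratio, sampled on a regular scan grid.  Peak centres are snapped to the
# nearest scan so that, noise-free, the generated M1 apex height equals
# the specified height exactly and the fragment ratios at the apex equal
# the library ratios exactly.

#' Specify a synthetic GC-MS sample
#'
#' @param library a `spectral_library` providing expected RTs, fragment
#'   m/z and ratios.
#' @param present compound names to simulate (default: all library
#'   compounds).
#' @param heights M1 apex heights (detector units), recycled over
#'   `present`; `NULL` draws heights log-uniformly from `1e4` to `1e6`
#'   under `seed`.
#' @param rt_offsets true RT minus expected RT, minutes, recycled over
#'   `present` (default 0).
#' @param peak_sigma Gaussian peak width (sd), minutes. Default 0.02.
#' @param scan_interval scan spacing, minutes. Default 0.005.
#' @param rt_range scan range `c(start, end)`, minutes; `NULL` extends
#'   0.5 min beyond the outermost simulated peaks.
#' @param noise_sd additive Gaussian noise sd (detector units), clipped at
#'   zero. Default 0 (noise-free).
#' @param interferents optional data frame with columns `mz`, `rt`,
#'   `height`, `sigma`: extra peaks not tied to any library compound.
#' @param seed RNG seed controlling heights and noise.
#' @return object of class `synthetic_spec`.
#' @examples
#' spec <- synthetic_spec(standard_library(), seed = 7)
#' @export
synthetic_spec <- function(library, present = library$compound,
                           heights = NULL, rt_offsets = 0,
                           peak_sigma = 0.02, scan_interval = 0.005,
                           rt_range = NULL, noise_sd = 0,
                           interferents = NULL, seed = 1L) {
  stopifnot(inherits(library, "spectral_library"))
  present <- as.character(present)
  if (!all(present %in% library$compound)) {
    stop("present compound(s) not in library: ",
         paste(setdiff(present, library$compound), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(is_number(peak_sigma), peak_sigma > 0,
            is_number(scan_interval), scan_interval > 0,
            is_number(noise_sd), noise_sd >= 0,
            is_number(seed))
  if (is.null(heights)) {
    heights <- with_seed(seed, 10^stats::runif(max(length(present), 1L), 4, 6))
  }
  if (length(present)) {
    heights <- rep_len(as.numeric(heights), length(present))
    rt_offsets <- rep_len(as.numeric(rt_offsets), length(present))
    if (any(!is.finite(heights) | heights <= 0)) {
      stop("heights must be positive", call. = FALSE)
    }
  } else {
    heights <- numeric()
    rt_offsets <- numeric()
  }
  if (!is.null(interferents)) {
    stopifnot(is.data.frame(interferents),
              all(c("mz", "rt", "height", "sigma") %in% names(interferents)))
  }
  centers <- library$expected_rt[match(present, library$compound)] + rt_offsets
  all_rts <- c(centers, interferents$rt)
  if (is.null(rt_range)) {
    rt_range <- if (length(all_rts)) {
      c(max(scan_interval, min(all_rts) - 0.5), max(all_rts) + 0.5)
    } else {
      c(scan_interval, 1)
    }
  }
  stopifnot(length(rt_range) == 2L, rt_range[1] < rt_range[2])
  if (length(all_rts) &&
      (min(all_rts) < rt_range[1] || max(all_rts) > rt_range[2])) {
    stop("rt_range must cover all simulated peak RTs", call. = FALSE)
  }
  structure(list(library = library, present = present, heights = heights,
                 rt_offsets = rt_offsets, peak_sigma = peak_sigma,
                 scan_interval = scan_interval, rt_range = rt_range,
                 noise_sd = noise_sd, interferents = interferents,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic sample spec: %d compound(s), %.2f-%.2f min @ %g min/scan, noise sd %g, seed %d\n",
    length(x$present), x$rt_range[1], x$rt_range[2], x$scan_interval,
    x$noise_sd, x$seed))
  invisible(x)
}

# Shared worker: builds the chromatogram for given per-compound heights and
# a given seed (cohort generation re-uses it with modified heights).
generate_sample_impl <- function(spec, heights, seed, sample_id) {
  lib <- spec$library
  rts <- seq(spec$rt_range[1], spec$rt_range[2], by = spec$scan_interval)
  idx <- match(spec$present, lib$compound)
  frag_mz <- lapply(idx, function(i) entry_mz(lib[i, ]))
  int_mz <- if (is.null(spec$interferents)) integer() else
    round_half_up(spec$interferents$mz)
  mzs <- sort(unique(c(unlist(frag_mz), int_mz)))
  if (length(mzs) == 0L) mzs <- 0L  # empty spec still yields a valid grid
  traces <- matrix(0, nrow = length(rts), ncol = length(mzs),
                   dimnames = list(NULL, as.character(mzs)))
  centers <- numeric(length(spec$present))
  for (p in seq_along(spec$present)) {
    e <- lib[idx[p], ]
    center <- e$expected_rt + spec$rt_offsets[p]
    center <- rts[which.min(abs(rts - center))]  # snap to the scan grid
    centers[p] <- center
    shape <- exp(-((rts - center)^2) / (2 * spec$peak_sigma^2))
    ratios <- c(1, entry_ratios(e))
    mz <- frag_mz[[p]]
    # a recycled fragment contributes its trace once, at its first
    # (most abundant) ratio, so the M1 apex height stays exact
    seen <- !duplicated(mz)
    for (i in which(seen)) {
      col <- as.character(mz[i])
      traces[, col] <- traces[, col] + heights[p] * ratios[i] * shape
    }
  }
  if (!is.null(spec$interferents)) {
    for (q in seq_len(nrow(spec$interferents))) {
      it <- spec$interferents[q, ]
      col <- as.character(round_half_up(it$mz))
      traces[, col] <- traces[, col] +
        it$height * exp(-((rts - it$rt)^2) / (2 * it$sigma^2))
    }
  }
  if (spec$noise_sd > 0) {
    noise <- with_seed(seed, matrix(stats::rnorm(length(traces), 0,
                                                 spec$noise_sd),
                                    nrow = nrow(traces)))
    traces <- pmax(traces + noise, 0)
  }
  list(chromatogram = chromatogram(rts, traces, sample_id),
       truth = data.frame(compound = spec$present, rt = centers,
                          height = heights, stringsAsFactors = FALSE))
}

#' Generate one synthetic sample
#'
#' Builds the chromatogram described by a [synthetic_spec()] together with
#' its ground truth.  Deterministic given the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @param sample_id sample identifier (default `"synthetic"`).
#' @return list with components `chromatogram` (a [chromatogram()]) and
#'   `truth` (data frame `compound`, `rt`, `height`; the true, grid-snapped
#'   peak RT and the exact M1 apex height).
#' @examples
#' lib <- standard_library()
#' smp <- generate_sample(synthetic_spec(lib, present = "Ethanol",
#'                                       heights = 2e5, seed = 3))
#' smp$truth
#' @export
generate_sample <- function(spec, sample_id = "synthetic") {
  stopifnot(inherits(spec, "synthetic_spec"))
  generate_sample_impl(spec, spec$heights, spec$seed, sample_id)
}

#' Generate a two-condition synthetic cohort
#'
#' Simulates `n_per_group` samples per condition ("A" and "B") from a
#' common [synthetic_spec()].  Compounds named in `effect` have their
#' apex heights multiplied by the given fold-change in condition B;
#' every sample additionally receives independent multiplicative
#' log-normal between-sample variation (sd `sample_sdlog` on the log
#' scale) on each compound's height.  Deterministic given the spec's
#' seed.
#'
#' @param spec a [synthetic_spec()].
#' @param n_per_group samples per condition, at least 2. Default 5.
#' @param effect named numeric vector of fold-changes (> 0) applied in
#'   condition B; `NULL` for a null cohort.
#' @param sample_sdlog sd of the per-sample log-normal height variation
#'   (log scale). Default 0.2.
#' @return list with components `samples` (list of
#'   `list(chromatogram, condition)`), `groups` (named condition vector
#'   keyed by sample id), and `truth` (data frame `compound`,
#'   `differential`, `fold`).
#' @export
generate_cohort <- function(spec, n_per_group = 5L, effect = NULL,
                            sample_sdlog = 0.2) {
  stopifnot(inherits(spec, "synthetic_spec"),
            is_number(n_per_group), n_per_group >= 2,
            is_number(sample_sdlog), sample_sdlog >= 0)
  if (!is.null(effect)) {
    stopifnot(is.numeric(effect), !is.null(names(effect)))
    if (any(effect <= 0)) stop("fold-change must be positive", call. = FALSE)
    missing <- setdiff(names(effect), spec$present)
    if (length(missing)) {
      stop("effect compound(s) not simulated: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  n_per_group <- as.integer(n_per_group)
  conditions <- rep(c("A", "B"), each = n_per_group)
  sample_ids <- paste0(conditions, rep(seq_len(n_per_group), times = 2))
  n_samples <- length(sample_ids)
  np <- length(spec$present)
  draws <- with_seed(spec$seed, list(
    jitter = matrix(stats::rnorm(n_samples * np, 0, sample_sdlog),
                    nrow = n_samples),
    seeds = sample.int(.Machine$integer.max - 1L, n_samples)))
  fold <- rep(1, np)
  names(fold) <- spec$present
  if (!is.null(effect)) fold[names(effect)] <- effect
  samples <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    h <- spec$heights * exp(draws$jitter[s, ])
    if (conditions[s] == "B") h <- h * fold
    gen <- generate_sample_impl(spec, h, draws$seeds[s], sample_ids[s])
    samples[[s]] <- list(chromatogram = gen$chromatogram,
                         condition = conditions[s])
  }
  groups <- conditions
  names(groups) <- sample_ids
  list(samples = samples, groups = groups,
       truth = data.frame(compound = spec$present,
                          differential = fold != 1,
                          fold = as.numeric(fold),
                          stringsAsFactors = FALSE))
}

#' Write the ground truth of a synthetic sample or cohort
#'
#' @param truth a truth data frame from [generate_sample()] or
#'   [generate_cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}
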