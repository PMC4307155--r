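# The four-stage peak-scoring engine.
#
# For each library compound the RT window [E_RT - w, E_RT + w] of the M1
# trace is searched for apices; each apex t_j defines a candidate peak
# group carrying the four observed fragment intensities.  Three stage
# scores are computed per group:
#
#   Stage 1 (0-12): three binary conditions per fragment — detected at t_j,
#     apexing within one scan of t_j, and reaching the fragment's maximum
#     intensity over the window.
#   Stage 2 (0-3): each observed ratio R^_i = I^_i / I^_1 scores 1 when it
#     lies in the closed match-factor interval [f R_i, (2 - f) R_i].
#   Stage 3 (0-3): each fragment trace scores 1 when its Pearson
#     correlation with the M1 trace over t_j +/- delta reaches ct.
#
# The compound is assigned the candidate with the highest total (ties:
# closest to E_RT, then earliest), and candidates of different compounds
# claiming the same scan are resolved in favour of the highest score.

#' Scoring parameters
#'
#' Bundles and validates the tunable parameters of the scoring engine.
#'
#' @param w RT window half-width around the expected retention time,
#'   minutes (> 0). Default 0.5.
#' @param f match factor in (0, 1); each library ratio `R` is accepted
#'   within the closed interval `[f*R, (2-f)*R]`, so larger `f` means a
#'   narrower interval. Values above 1 (e.g. 70) are interpreted as
#'   percentages and divided by 100. Default 0.70.
#' @param ct correlation threshold in (0, 1) for the fragment co-elution
#'   stage. Default 0.95.
#' @param delta half-width, minutes, of the RT neighbourhood over which
#'   fragment/M1 Pearson correlations are computed. Default 0.07.
#' @param s_t total-score threshold in \[8, 18\] used when building the
#'   thresholded abundance table. Default 13.
#' @return object of class `pscore_params`.
#' @examples
#' pscore_params()
#' pscore_params(f = 70)  # percentage form, normalised to 0.70
#' @export
pscore_params <- function(w = 0.5, f = 0.70, ct = 0.95, delta = 0.07,
                          s_t = 13L) {
  if (is_number(f) && f > 1) f <- f / 100
  stopifnot(is_number(w), w > 0,
            is_number(f), f > 0, f < 1,
            is_number(ct), ct > 0, ct < 1,
            is_number(delta), delta > 0,
            is_number(s_t), s_t >= 8, s_t <= 18)
  structure(list(w = w, f = f, ct = ct, delta = delta,
                 s_t = as.integer(s_t)),
            class = "pscore_params")
}

#' @export
print.pscore_params <- function(x, ...) {
  cat(sprintf(
    "Scoring parameters: w = %g min, f = %g, ct = %g, delta = %g min, s_t = %d\n",
    x$w, x$f, x$ct, x$delta, x$s_t))
  invisible(x)
}

entry_mz <- function(entry) {
  as.integer(unlist(entry[c("m1", "m2", "m3", "m4")], use.names = FALSE))
}
entry_ratios <- function(entry) {
  as.numeric(unlist(entry[c("r2", "r3", "r4")], use.names = FALSE))
}

# Extract the four fragment traces of an entry, caching each trace's
# positive apex indices (scoring revisits them once per candidate group).
entry_traces <- function(chrom, entry) {
  lapply(entry_mz(entry), function(m) {
    tr <- eic(chrom, m)
    ai <- apex_indices(tr$intensities)
    attr(tr, "apex_idx") <- ai[tr$intensities[ai] > 0]
    tr
  })
}

positive_apices <- function(trace) {
  ap <- attr(trace, "apex_idx")
  if (is.null(ap)) {
    ap <- apex_indices(trace$intensities)
    ap <- ap[trace$intensities[ap] > 0]
  }
  ap
}

#' Candidate peak groups for one library compound
#'
#' Each apex of the M1 ion trace inside the closed window
#' `[E_RT - w, E_RT + w]` defines one candidate group: the candidate RT
#' `t_j`, the intensities of the four expected fragments at that scan, and
#' the observed ratios of fragments 2..4 to fragment 1 (`NA` when the M1
#' intensity is zero).
#'
#' @param chrom a [chromatogram()].
#' @param entry one row of a `spectral_library`.
#' @param params a [pscore_params()].
#' @return list of `peak_group` objects (fields `compound`, `t_j`,
#'   `index`, `mz`, `intensities`, `ratios`), ascending in `t_j`; empty
#'   when M1 shows no apex in the window.
#' @export
candidate_groups <- function(chrom, entry, params = pscore_params()) {
  stopifnot(inherits(chrom, "chromatogram"), inherits(params, "pscore_params"))
  mz <- entry_mz(entry)
  window <- entry$expected_rt + c(-1, 1) * params$w
  traces <- entry_traces(chrom, entry)
  ap <- positive_apices(traces[[1]])
  b <- window_bounds(chrom$rts, window)
  ap <- if (is.null(b)) integer() else ap[ap >= b[1] & ap <= b[2]]
  lapply(ap, function(idx) {
    ints <- vapply(traces, function(tr) tr$intensities[idx], numeric(1))
    ratios <- if (ints[1] > 0) ints[2:4] / ints[1] else rep(NA_real_, 3)
    structure(list(compound = entry$compound, t_j = chrom$rts[idx],
                   index = idx, mz = mz, intensities = ints,
                   ratios = ratios),
              class = "peak_group")
  })
}

#' Stage 1: fragment peak co-occurrence score
#'
#' Each of the four expected fragments contributes up to 3 points at the
#' candidate RT `t_j`: 1 if its intensity at `t_j` is positive, 1 if one
#' of its apices lies within one scan step of `t_j`, and 1 if its
#' intensity at `t_j` is the highest that fragment shows in the peak's
#' own neighbourhood — the closed interval `t_j ± delta` intersected with
#' the search window.  Maximum 12.
#'
#' Assessing fragment dominance over the peak neighbourhood rather than
#' the whole search window means a clean, well-separated peak always earns
#' the point even when another compound elutes elsewhere in the window
#' with a stronger shared fragment, while genuinely coeluting signals
#' (within `delta`) still compete.
#'
#' @param group a `peak_group` from [candidate_groups()].
#' @param traces list of four `ion_trace`s aligned with the group's
#'   fragments M1..M4 (same scan grid as the group's chromatogram).
#' @param window closed RT search window `c(lo, hi)`, minutes.
#' @param delta half-width, minutes, of the dominance neighbourhood
#'   around `t_j` (same parameter as the correlation stage). Default
#'   0.07.
#' @return integer in 0..12.
#' @export
stage1_score <- function(group, traces, window, delta = 0.07) {
  stopifnot(inherits(group, "peak_group"), length(traces) == 4L, delta > 0)
  idx <- group$index
  hood <- c(max(window[1], group$t_j - delta),
            min(window[2], group$t_j + delta))
  hb <- window_bounds(traces[[1]]$rts, hood)
  score <- 0L
  for (i in 1:4) {
    y <- traces[[i]]$intensities
    v <- y[idx]
    if (v > 0) score <- score + 1L
    ap <- positive_apices(traces[[i]])
    # ap is sorted: binary-search for an apex within one scan of idx
    j <- findInterval(idx + 1L, ap)
    if (j >= 1L && ap[j] >= idx - 1L) score <- score + 1L
    hood_max <- if (is.null(hb)) 0 else max(y[hb[1]:hb[2]])
    if (v > 0 && v >= hood_max) score <- score + 1L
  }
  score
}

#' Stage 2: spectral similarity score
#'
#' Each observed ratio scores 1 when it lies in the closed match-factor
#' interval `[f*R, (2-f)*R]` around the library ratio `R`.  Undefined
#' observed ratios (zero M1 intensity) score 0.  Maximum 3.
#'
#' @param group a `peak_group`.
#' @param entry the library row the group was built from.
#' @param f match factor in (0, 1); values above 1 are divided by 100.
#' @return integer in 0..3.
#' @export
stage2_score <- function(group, entry, f = 0.70) {
  stopifnot(inherits(group, "peak_group"))
  if (f > 1) f <- f / 100
  stopifnot(f > 0, f < 1)
  r_lib <- entry_ratios(entry)
  r_obs <- group$ratios
  ok <- !is.na(r_obs) & r_obs >= f * r_lib & r_obs <= (2 - f) * r_lib
  sum(ok)
}

#' Stage 3: fragment co-elution correlation score
#'
#' For each fragment 2..4, the Pearson correlation between its intensities
#' and M1's over all scans with RT in the closed neighbourhood
#' `[t_j - delta, t_j + delta]` scores 1 when it reaches `ct`.  A
#' correlation is treated as undefined — and scores 0 — when fewer than 3
#' scans fall in the neighbourhood or either series has zero variance
#' there.  Maximum 3.
#'
#' @param traces list of four `ion_trace`s aligned with fragments M1..M4.
#' @param t_j candidate RT, minutes.
#' @param delta neighbourhood half-width, minutes.
#' @param ct correlation threshold in (0, 1).
#' @return integer in 0..3.
#' @export
stage3_score <- function(traces, t_j, delta = 0.07, ct = 0.95) {
  stopifnot(length(traces) == 4L, delta > 0, ct > 0, ct < 1)
  rts <- traces[[1]]$rts
  b <- window_bounds(rts, c(t_j - delta, t_j + delta))
  if (is.null(b) || b[2] - b[1] < 2L) return(0L)
  sel <- b[1]:b[2]
  x <- traces[[1]]$intensities[sel]
  if (max(x) == min(x)) return(0L)  # zero variance: correlation undefined
  score <- 0L
  for (i in 2:4) {
    y <- traces[[i]]$intensities[sel]
    if (max(y) == min(y)) next
    if (stats::cor(x, y) >= ct) score <- score + 1L
  }
  score
}


#' Score one library compound against a sample
#'
#' Evaluates all candidate peak groups of the compound and returns the
#' winning identification: the candidate with the highest total score,
#' ties broken by the smallest distance to the expected RT, then by the
#' earliest RT.  The reported abundance is the M1 intensity at the winning
#' RT.
#'
#' @param chrom a [chromatogram()].
#' @param entry one row of a `spectral_library`.
#' @param params a [pscore_params()].
#' @return one-row data frame with columns `compound`, `rt`, `s1`, `s2`,
#'   `s3`, `score`, `abundance`, `delta_rt`, or `NULL` when M1 shows no
#'   apex in the search window.
#' @export
score_metabolite <- function(chrom, entry, params = pscore_params()) {
  groups <- candidate_groups(chrom, entry, params)
  if (length(groups) == 0L) return(NULL)
  traces <- entry_traces(chrom, entry)
  entry <- as.list(entry)  # plain-list field access in the scoring loop
  window <- entry$expected_rt + c(-1, 1) * params$w
  n <- length(groups)
  s1 <- s2 <- s3 <- integer(n)
  tj <- ab <- numeric(n)
  for (k in seq_len(n)) {
    g <- groups[[k]]
    s1[k] <- stage1_score(g, traces, window, params$delta)
    s2[k] <- stage2_score(g, entry, params$f)
    s3[k] <- stage3_score(traces, g$t_j, params$delta, params$ct)
    tj[k] <- g$t_j
    ab[k] <- g$intensities[1]
  }
  total <- s1 + s2 + s3
  delta_rt <- abs(tj - entry$expected_rt)
  best <- order(-total, delta_rt, tj)[1]
  data.frame(compound = entry$compound, rt = tj[best],
             s1 = s1[best], s2 = s2[best], s3 = s3[best],
             score = total[best], abundance = ab[best],
             delta_rt = delta_rt[best], stringsAsFactors = FALSE)
}

#' Resolve cross-compound RT conflicts
#'
#' When several compounds are assigned the same scan, only the one with
#' the highest total score survives; ties are broken by the smallest
#' distance to the expected RT, then by compound name.  Losing compounds
#' are dropped (reported absent), not reassigned to another RT.
#'
#' @param idents data frame of identifications as returned by
#'   [score_metabolite()] rows bound together.
#' @return the surviving rows, ordered by `rt`; surviving RTs are
#'   distinct.
#' @export
resolve_conflicts <- function(idents) {
  if (is.null(idents) || nrow(idents) == 0L) return(empty_identifications())
  keep <- unlist(lapply(split(seq_len(nrow(idents)), idents$rt), function(ix) {
    sub <- idents[ix, ]
    ix[order(-sub$score, sub$delta_rt, sub$compound)[1]]
  }), use.names = FALSE)
  out <- idents[sort(keep), , drop = FALSE]
  out <- out[order(out$rt, out$compound), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_identifications <- function() {
  data.frame(compound = character(), rt = numeric(),
             s1 = integer(), s2 = integer(), s3 = integer(),
             score = integer(), abundance = numeric(),
             delta_rt = numeric(), stringsAsFactors = FALSE)
}

#' Analyse one GC-MS sample against a spectral library
#'
#' Runs the full per-sample pipeline: every library compound is scored
#' ([score_metabolite()]) and compounds claiming the same scan are
#' resolved ([resolve_conflicts()]).  The result is deterministic for
#' fixed inputs.
#'
#' @param chrom a [chromatogram()].
#' @param lib a `spectral_library`.
#' @param params a [pscore_params()].
#' @param verbose log per-compound outcomes to stderr.
#' @return data frame of identifications (class `pscore_ids`) with columns
#'   `compound`, `rt`, `s1`, `s2`, `s3`, `score`, `abundance`,
#'   `delta_rt`, ordered by `rt`; attribute `sample_id`.
#' @examples
#' lib <- standard_library()
#' spec <- synthetic_spec(lib, present = "Ethanol", heights = 1e5, seed = 1)
#' smp <- generate_sample(spec)
#' analyse_sample(smp$chromatogram, lib)
#' @export
analyse_sample <- function(chrom, lib, params = pscore_params(),
                           verbose = FALSE) {
  stopifnot(inherits(chrom, "chromatogram"), inherits(lib, "spectral_library"))
  rows <- vector("list", nrow(lib))
  for (r in seq_len(nrow(lib))) {
    id <- score_metabolite(chrom, lib[r, ], params)
    if (verbose) {
      if (is.null(id)) {
        message(sprintf("[%s] %s: no candidate RT", chrom$sample_id,
                        lib$compound[r]))
      } else {
        message(sprintf("[%s] %s: rt %.3f score %d (%d+%d+%d)",
                        chrom$sample_id, lib$compound[r], id$rt, id$score,
                        id$s1, id$s2, id$s3))
      }
    }
    rows[[r]] <- id
  }
  out <- resolve_conflicts(do.call(rbind, rows))
  structure(out, sample_id = chrom$sample_id,
            class = c("pscore_ids", "data.frame"))
}

#' @export
print.pscore_ids <- function(x, ...) {
  cat(sprintf("Identifications for sample '%s': %d compound(s)\n",
              attr(x, "sample_id"), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}
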