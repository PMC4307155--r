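# Cross-sample result tables, score thresholding, prevalence filtering,
# the Welch-t biomarker screen and the FP/FN evaluation metrics.
#
# Missing cells are NA throughout and mean "not identified in this sample
# (or removed by the score cut)"; an abundance of 0 means "identified with
# M1 measured at zero".  Downstream metabolomics tools expect that
# distinction.

#' Merge per-sample identifications into the Total table
#'
#' Merges the identification lists of several samples into a single
#' cross-sample table keyed by compound name.  Compounds appear in order
#' of first appearance across the samples (in input order); sample columns
#' keep the input order.  Cells of samples where a compound was not
#' identified are `NA`.
#'
#' @param results list of identification data frames from
#'   [analyse_sample()], one per sample.
#' @param sample_ids unique sample identifiers; defaults to the names of
#'   `results`, else the `sample_id` attributes.
#' @return object of class `pscore_total`: list of three
#'   compounds-by-samples matrices `abundance`, `rt`, `score`.
#' @export
build_total <- function(results, sample_ids = NULL) {
  stopifnot(is.list(results))
  if (is.null(sample_ids)) {
    sample_ids <- names(results)
    if (is.null(sample_ids)) {
      sample_ids <- vapply(results, function(r) {
        s <- attr(r, "sample_id")
        if (is.null(s)) NA_character_ else s
      }, character(1))
    }
  }
  if (length(sample_ids) != length(results) || anyNA(sample_ids)) {
    stop("each result needs a sample id", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  compounds <- unique(unlist(lapply(results, function(r) r$compound),
                             use.names = FALSE))
  mk <- function() matrix(NA_real_, nrow = length(compounds),
                          ncol = length(results),
                          dimnames = list(compounds, sample_ids))
  ab <- mk(); rt <- mk(); sc <- mk()
  for (s in seq_along(results)) {
    r <- results[[s]]
    if (is.null(r) || nrow(r) == 0L) next
    i <- match(r$compound, compounds)
    ab[i, s] <- r$abundance
    rt[i, s] <- r$rt
    sc[i, s] <- r$score
  }
  structure(list(abundance = ab, rt = rt, score = sc,
                 compounds = compounds, samples = sample_ids),
            class = "pscore_total")
}

#' @export
print.pscore_total <- function(x, ...) {
  cat(sprintf("Total table: %d compound(s) x %d sample(s)\n",
              length(x$compounds), length(x$samples)))
  print(x$abundance, ...)
  invisible(x)
}

#' @describeIn build_total flatten a Total table to a wide data frame with
#'   per-sample abundance, RT and score columns.
#' @param x a `pscore_total`.
#' @param row.names,optional,... passed on conventions of
#'   [base::as.data.frame()]; ignored.
#' @export
as.data.frame.pscore_total <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  out <- data.frame(compound = x$compounds, stringsAsFactors = FALSE)
  for (s in x$samples) {
    out[[paste0(s, "_abundance")]] <- x$abundance[, s]
    out[[paste0(s, "_rt")]] <- x$rt[, s]
    out[[paste0(s, "_score")]] <- x$score[, s]
  }
  rownames(out) <- NULL
  out
}

#' Apply the score threshold: the cutOff table
#'
#' Keeps, cell by cell, the abundances whose total score reaches the score
#' threshold `s_t`; cells below the threshold (or never identified) become
#' `NA`.  Compounds whose cells are all removed are dropped.
#'
#' @param total a `pscore_total` from [build_total()].
#' @param s_t integer score threshold in \[8, 18\].
#' @return object of class `pscore_cutoff`: a data frame with a `compound`
#'   column and one abundance column per sample.
#' @export
apply_score_cut <- function(total, s_t = 13L) {
  stopifnot(inherits(total, "pscore_total"))
  if (!is_number(s_t) || s_t < 8 || s_t > 18) {
    stop("score threshold s_t must lie in [8, 18]", call. = FALSE)
  }
  ab <- total$abundance
  ab[is.na(total$score) | total$score < s_t] <- NA_real_
  keep <- rowSums(!is.na(ab)) > 0L
  ab <- ab[keep, , drop = FALSE]
  out <- data.frame(compound = rownames(ab), ab, check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("pscore_cutoff", "data.frame"))
}

cutoff_samples <- function(cutoff) setdiff(names(cutoff), "compound")

#' Prevalence filter
#'
#' Keeps compounds detected (non-missing) in at least `min_per_group`
#' samples of every experimental condition, removing sporadic
#' identifications that are likely false positives.
#'
#' @param cutoff a `pscore_cutoff` (or any data frame with a `compound`
#'   column and per-sample abundance columns).
#' @param groups named character vector mapping every sample column to its
#'   condition.
#' @param min_per_group minimum number of detections required per
#'   condition; 0 disables the filter.
#' @return the filtered table, same class as the input.
#' @export
prevalence_filter <- function(cutoff, groups, min_per_group = 2L) {
  samples <- cutoff_samples(cutoff)
  unmapped <- setdiff(samples, names(groups))
  if (length(unmapped)) {
    stop("sample(s) not mapped to a condition: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  stopifnot(is_number(min_per_group), min_per_group >= 0)
  conditions <- unique(groups[samples])
  keep <- vapply(seq_len(nrow(cutoff)), function(r) {
    all(vapply(conditions, function(g) {
      cols <- samples[groups[samples] == g]
      sum(!is.na(unlist(cutoff[r, cols]))) >= min_per_group
    }, logical(1)))
  }, logical(1))
  out <- cutoff[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Welch two-sample t-test p-value
#'
#' Two-sided unequal-variance (Welch) t-test on two abundance vectors;
#' missing values are dropped per group.  Returns `NA` when either group
#' retains fewer than two values.  When both groups are constant the test
#' statistic is undefined; equal constants return `p = 1`, unequal
#' constants return `NA`.
#'
#' @param values_a,values_b numeric abundance vectors (may contain `NA`).
#' @return p-value in \[0, 1\], or `NA_real_`.
#' @export
welch_t <- function(values_a, values_b) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) < 2L || length(b) < 2L) return(NA_real_)
  tryCatch(
    stats::t.test(a, b, var.equal = FALSE)$p.value,
    error = function(e) {
      if (isTRUE(all.equal(mean(a), mean(b)))) 1 else NA_real_
    })
}

#' Welch-t biomarker screen
#'
#' Applies the prevalence filter and then a per-compound two-sided Welch
#' t-test between the two conditions.  No multiple-testing correction is
#' applied by default (raw p < `alpha` flags a biomarker); set
#' `adjust = "BH"` for Benjamini-Hochberg adjusted p-values.
#'
#' @param cutoff a `pscore_cutoff`.
#' @param groups named character vector mapping each sample column to one
#'   of exactly two conditions.
#' @param min_per_group prevalence filter threshold (default 2).
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data frame with columns `compound`, `n_a`, `n_b`, `mean_a`,
#'   `mean_b`, `p_value`, `p_adjusted`, `significant`, ordered by p-value.
#' @export
biomarker_screen <- function(cutoff, groups, min_per_group = 2L,
                             alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  filtered <- prevalence_filter(cutoff, groups, min_per_group)
  samples <- cutoff_samples(filtered)
  conditions <- unique(groups[samples])
  if (length(conditions) != 2L) {
    stop("biomarker screen needs exactly 2 conditions, got ",
         length(conditions), call. = FALSE)
  }
  cols_a <- samples[groups[samples] == conditions[1]]
  cols_b <- samples[groups[samples] == conditions[2]]
  rows <- lapply(seq_len(nrow(filtered)), function(r) {
    a <- as.numeric(unlist(filtered[r, cols_a]))
    b <- as.numeric(unlist(filtered[r, cols_b]))
    data.frame(compound = filtered$compound[r],
               n_a = sum(!is.na(a)), n_b = sum(!is.na(b)),
               mean_a = mean(a, na.rm = TRUE),
               mean_b = mean(b, na.rm = TRUE),
               p_value = welch_t(a, b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(compound = character(), n_a = integer(),
                      n_b = integer(), mean_a = numeric(),
                      mean_b = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  }
  out$p_adjusted <- if (adjust == "BH") {
    stats::p.adjust(out$p_value, method = "BH")
  } else {
    out$p_value
  }
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' False-positive and false-negative percentages
#'
#' Evaluates a reported compound list against a known truth: the
#' false-positive percentage is 100 times the proportion of reported
#' compounds not in the truth (relative to the number reported; 0 when
#' nothing is reported), and the false-negative percentage is 100 times
#' the proportion of true compounds not reported.
#'
#' @param reported character vector of reported compound names (treated as
#'   a set).
#' @param truth non-empty character vector of true compound names.
#' @return named numeric vector `c(fp_percent, fn_percent)`, full
#'   precision (round for presentation).
#' @examples
#' truth <- paste0("true", 1:13)
#' reported <- c(truth[1:10], paste0("bogus", 1:90))
#' evaluate_fp_fn(reported, truth)  # 90% FP, 23.1% FN
#' @export
evaluate_fp_fn <- function(reported, truth) {
  truth <- unique(as.character(truth))
  if (length(truth) == 0L) stop("truth set is empty", call. = FALSE)
  reported <- unique(as.character(reported))
  fp <- if (length(reported) == 0L) 0 else {
    100 * length(setdiff(reported, truth)) / length(reported)
  }
  fn <- 100 * length(setdiff(truth, reported)) / length(truth)
  c(fp_percent = fp, fn_percent = fn)
}

#' Export a result table to CSV
#'
#' Writes RFC-4180 CSV with missing cells empty and compound names in the
#' first column.  A Total table is flattened to per-sample abundance, RT
#' and score columns; a cutOff table is written as compound plus one
#' abundance column per sample.
#'
#' @param table a `pscore_total` or `pscore_cutoff`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_csv <- function(table, path) {
  df <- if (inherits(table, "pscore_total")) {
    as.data.frame(table)
  } else if (inherits(table, "pscore_cutoff") || is.data.frame(table)) {
    as.data.frame(table)
  } else {
    stop("cannot export object of class ", class(table)[1], call. = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cutOff table back from CSV
#'
#' @param path CSV written by [export_csv()] for a cutOff table.
#' @return a `pscore_cutoff`.
#' @export
read_cutoff_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"compound" %in% names(d)) {
    stop("cutOff csv needs a 'compound' column", call. = FALSE)
  }
  structure(d, class = c("pscore_cutoff", "data.frame"))
}
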