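# Spectral library input, validation and fragment recycling.
#
# A spectral library holds, per compound: the expected retention time E_RT
# (minutes), the nominal m/z of its four most abundant ion mass fragments
# (IMFs) M1..M4, and the intensity of M2..M4 relative to M1 (ratios R2..R4,
# fractions in (0, 1]).

LIB_COLUMNS <- c("compound", "expected_rt", "m1", "m2", "m3", "m4",
                 "r2", "r3", "r4")

#' Read a spectral library
#'
#' Reads a spectral library from either the canonical delimited format
#' (comma- or tab-separated, header
#' `compound,expected_rt,m1,m2,m3,m4,r2,r3,r4`) or an AMDIS `.msl` text
#' library.  Compounds listing fewer than four fragments have the existing
#' fragments recycled (see [recycle_fragments()]), so every returned entry
#' carries exactly four m/z values and three ratios.
#'
#' For the delimited dialect, fragments must occupy a prefix of the
#' `m1..m4` columns and their ratios the matching prefix of `r2..r4`;
#' trailing columns may be empty for partial compounds.  m/z values are
#' rounded half-up to nominal (integer) mass.  For `.msl` records only the
#' compound name, retention time, and the four most intense peaks are used;
#' relative intensities are computed from the listed peak intensities, with
#' abundance ties broken by ascending m/z.
#'
#' @param path path to the library file.
#' @param dialect `"auto"` (default; `.msl` extension selects the AMDIS
#'   dialect), `"delimited"`, or `"msl"`.
#' @return a `spectral_library`: a data frame with columns `compound`,
#'   `expected_rt`, `m1..m4` (integer), `r2..r4` (fractions), one row per
#'   compound, with attribute `source_path`.
#' @examples
#' lib <- standard_library()
#' lib[lib$compound == "Ethanol", ]
#' @seealso [validate_library()], [write_spectral_library()],
#'   [standard_library()]
#' @export
read_spectral_library <- function(path, dialect = c("auto", "delimited", "msl")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("library file not found: ", path, call. = FALSE)
  }
  if (dialect == "auto") {
    dialect <- if (grepl("\\.msl$", path, ignore.case = TRUE)) "msl" else "delimited"
  }
  entries <- if (dialect == "msl") {
    parse_msl(path)
  } else {
    parse_delimited_library(path)
  }
  if (nrow(entries) == 0L) {
    stop("library contains no entries", call. = FALSE)
  }
  dup <- unique(entries$compound[duplicated(entries$compound)])
  if (length(dup)) {
    stop("duplicate compound name(s) in library: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  new_spectral_library(entries, source_path = path)
}

new_spectral_library <- function(entries, source_path = NA_character_) {
  stopifnot(all(LIB_COLUMNS %in% names(entries)))
  entries <- entries[LIB_COLUMNS]
  rownames(entries) <- NULL
  structure(entries,
            source_path = source_path,
            class = c("spectral_library", "data.frame"))
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("Spectral library: %d compound(s)\n", nrow(x)))
  src <- attr(x, "source_path")
  if (!is.na(src)) cat("  source:", src, "\n")
  print.data.frame(x, ...)
  invisible(x)
}

# Delimited dialect ---------------------------------------------------------

parse_delimited_library <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("library contains no entries", call. = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           strip.white = TRUE, blank.lines.skip = TRUE)
  names(raw) <- tolower(trimws(names(raw)))
  missing_cols <- setdiff(LIB_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("library file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) stop("library contains no entries", call. = FALSE)

  num <- function(col, row, what) {
    v <- raw[[col]][row]
    if (is.na(v) || !nzchar(v)) return(NA_real_)
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x)) {
      stop(sprintf("row %d: non-numeric %s value '%s' in column '%s'",
                   row, what, v, col), call. = FALSE)
    }
    x
  }

  out <- vector("list", nrow(raw))
  for (r in seq_len(nrow(raw))) {
    compound <- trimws(raw$compound[r])
    if (!nzchar(compound)) {
      stop(sprintf("row %d: empty compound name", r), call. = FALSE)
    }
    ert <- num("expected_rt", r, "retention time")
    if (is.na(ert)) {
      stop(sprintf("row %d: missing retention time", r), call. = FALSE)
    }
    mz <- vapply(c("m1", "m2", "m3", "m4"), num, numeric(1),
                 row = r, what = "m/z")
    ratios <- vapply(c("r2", "r3", "r4"), num, numeric(1),
                     row = r, what = "ratio")
    k <- sum(!is.na(mz))
    if (k == 0L) {
      stop(sprintf("row %d (%s): compound has no fragments", r, compound),
           call. = FALSE)
    }
    if (any(is.na(mz[seq_len(k)]))) {
      stop(sprintf("row %d (%s): fragments must fill columns m1..m%d without gaps",
                   r, compound, k), call. = FALSE)
    }
    kr <- sum(!is.na(ratios))
    if (kr != k - 1L || (k > 1L && any(is.na(ratios[seq_len(k - 1L)])))) {
      stop(sprintf(
        "row %d (%s): a compound with %d fragment(s) needs %d ratio(s) in r2..r%d",
        r, compound, k, k - 1L, k), call. = FALSE)
    }
    rec <- recycle_fragments(round_half_up(mz[seq_len(k)]),
                             if (k > 1L) ratios[seq_len(k - 1L)] else numeric())
    out[[r]] <- data.frame(compound = compound, expected_rt = ert,
                           m1 = rec$mz[1], m2 = rec$mz[2],
                           m3 = rec$mz[3], m4 = rec$mz[4],
                           r2 = rec$ratios[1], r3 = rec$ratios[2],
                           r4 = rec$ratios[3],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# AMDIS .msl dialect --------------------------------------------------------
#
# Text records of the form
#   NAME: Ethanol
#   RT: 6.64
#   NUM PEAKS: 6
#   (31 999) (45 777) ...
# Only the name, RT and the 4 most intense peaks are retained; AMDIS
# libraries typically list many more near-noise ions.

parse_msl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  name_idx <- grep("^\\s*NAME\\s*:", lines, ignore.case = TRUE)
  if (length(name_idx) == 0L) stop("library contains no entries", call. = FALSE)
  bounds <- c(name_idx, length(lines) + 1L)
  out <- vector("list", length(name_idx))
  for (e in seq_along(name_idx)) {
    block <- lines[bounds[e]:(bounds[e + 1L] - 1L)]
    compound <- trimws(sub("^\\s*NAME\\s*:", "", block[1L], ignore.case = TRUE))
    rt_line <- grep("^\\s*RT\\s*:", block, ignore.case = TRUE, value = TRUE)
    if (length(rt_line) == 0L) {
      stop("msl record '", compound, "' has no RT: field", call. = FALSE)
    }
    ert <- suppressWarnings(as.numeric(trimws(sub("^\\s*RT\\s*:", "",
                                                  rt_line[1L],
                                                  ignore.case = TRUE))))
    if (is.na(ert)) {
      stop("msl record '", compound, "' has a non-numeric RT", call. = FALSE)
    }
    np_idx <- grep("^\\s*NUM\\s+PEAKS\\s*:", block, ignore.case = TRUE)
    peak_lines <- if (length(np_idx)) {
      block[seq.int(np_idx[1L] + 1L, length.out = length(block) - np_idx[1L])]
    } else character()
    pairs <- regmatches(peak_lines,
                        gregexpr("\\(\\s*[0-9.]+[ ,;]+[0-9.]+\\s*\\)", peak_lines))
    pairs <- unlist(pairs)
    if (length(pairs) == 0L) {
      stop("msl record '", compound, "' has no peaks", call. = FALSE)
    }
    nums <- lapply(regmatches(pairs, gregexpr("[0-9.]+", pairs)), as.numeric)
    mz <- round_half_up(vapply(nums, `[`, numeric(1), 1L))
    int <- vapply(nums, `[`, numeric(1), 2L)
    o <- order(-int, mz)  # abundance order, ties by ascending m/z
    mz <- mz[o]; int <- int[o]
    o <- !duplicated(mz)
    mz <- mz[o]; int <- int[o]
    k <- min(4L, length(mz))
    mz <- mz[seq_len(k)]; int <- int[seq_len(k)]
    ratios <- if (k > 1L) int[-1L] / int[1L] else numeric()
    rec <- recycle_fragments(mz, ratios)
    out[[e]] <- data.frame(compound = compound, expected_rt = ert,
                           m1 = rec$mz[1], m2 = rec$mz[2],
                           m3 = rec$mz[3], m4 = rec$mz[4],
                           r2 = rec$ratios[1], r3 = rec$ratios[2],
                           r4 = rec$ratios[3],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Recycle fragments of a partial spectrum
#'
#' Compounds whose spectra contain fewer than four usable fragments have the
#' existing fragments reused cyclically, in abundance order, until all four
#' fragment slots are filled; such fragments are simply scored more than
#' once.  A recycled copy of the most abundant fragment (M1) carries ratio
#' 1, a recycled copy of fragment i carries that fragment's ratio R_i.  For
#' example a two-fragment compound with fragments 58 and 106 is analysed as
#' `mz = (58, 106, 58, 106)`.
#'
#' Already-complete four-fragment entries are returned unchanged
#' (the operation is idempotent).
#'
#' @param mz integer vector of 1--4 fragment m/z values, ordered by
#'   decreasing expected intensity.
#' @param ratios numeric vector of `length(mz) - 1` relative intensities
#'   (fragment 2..k vs fragment 1).
#' @return list with components `mz` (length 4) and `ratios` (length 3).
#' @examples
#' recycle_fragments(c(58, 106), 0.5)
#' @export
recycle_fragments <- function(mz, ratios = numeric()) {
  k <- length(mz)
  if (k == 0L) stop("compound has no fragments", call. = FALSE)
  if (k > 4L) stop("at most 4 fragments are used", call. = FALSE)
  if (length(ratios) != k - 1L) {
    stop("expected ", k - 1L, " ratio(s) for ", k, " fragment(s)",
         call. = FALSE)
  }
  # slot s (1..4) holds fragment ((s-1) mod k) + 1
  slots <- ((seq_len(4L) - 1L) %% k) + 1L
  full_ratios <- c(1, ratios)     # fragment index -> ratio vs M1
  list(mz = as.integer(mz[slots]),
       ratios = as.numeric(full_ratios[slots][-1L]))
}

#' Validate a spectral library
#'
#' Checks every entry against the library invariants and collects issues
#' rather than raising: positive retention time, m/z at least 1, ratios in
#' (0, 1], exactly four fragments and three ratios.  Additionally flags, as
#' warnings, pairs of compounds that share the same most abundant fragment
#' (M1) and elute within 0.1 min of each other: such pairs risk coelution,
#' which degrades the fragment-correlation score.
#'
#' @param lib a `spectral_library`.
#' @return data frame with columns `compound`, `field`, `issue`,
#'   `severity` (`"error"` or `"warning"`); zero rows when the library is
#'   clean.
#' @export
validate_library <- function(lib) {
  stopifnot(inherits(lib, "spectral_library"))
  issues <- list()
  add <- function(compound, field, issue, severity = "error") {
    issues[[length(issues) + 1L]] <<- data.frame(
      compound = compound, field = field, issue = issue,
      severity = severity, stringsAsFactors = FALSE)
  }
  for (r in seq_len(nrow(lib))) {
    cp <- lib$compound[r]
    if (!is.finite(lib$expected_rt[r]) || lib$expected_rt[r] <= 0) {
      add(cp, "expected_rt", "expected retention time must be positive")
    }
    mz <- as.numeric(lib[r, c("m1", "m2", "m3", "m4")])
    rat <- as.numeric(lib[r, c("r2", "r3", "r4")])
    if (any(is.na(mz))) add(cp, "mz", "entry must carry 4 fragments")
    if (any(!is.na(mz) & mz < 1)) add(cp, "mz", "m/z below 1")
    if (any(is.na(rat))) add(cp, "ratios", "entry must carry 3 ratios")
    if (any(!is.na(rat) & rat <= 0)) add(cp, "ratios", "ratio must be positive")
    if (any(!is.na(rat) & rat > 1)) add(cp, "ratios", "ratio exceeds 1")
  }
  dup <- unique(lib$compound[duplicated(lib$compound)])
  for (d in dup) add(d, "compound", "duplicate compound name")
  # coelution risk: shared M1 within 0.1 min
  if (nrow(lib) > 1L) {
    for (a in seq_len(nrow(lib) - 1L)) {
      for (b in seq.int(a + 1L, nrow(lib))) {
        if (!is.na(lib$m1[a]) && !is.na(lib$m1[b]) &&
            lib$m1[a] == lib$m1[b] &&
            abs(lib$expected_rt[a] - lib$expected_rt[b]) <= 0.1) {
          add(paste(lib$compound[a], "/", lib$compound[b]), "m1",
              "compounds share M1 and elute within 0.1 min (coelution risk)",
              severity = "warning")
        }
      }
    }
  }
  if (length(issues) == 0L) {
    return(data.frame(compound = character(), field = character(),
                      issue = character(), severity = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

#' Write a spectral library in the canonical delimited format
#'
#' @param lib a `spectral_library`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectral_library <- function(lib, path) {
  stopifnot(inherits(lib, "spectral_library"))
  utils::write.csv(as.data.frame(lib)[LIB_COLUMNS], path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' Bundled standard-mixture spectral library
#'
#' The 13-compound volatile-organic-compound library shipped with the
#' package (ethanol through indole): expected retention times, the four
#' most abundant fragments of each compound, and their relative
#' intensities.  It covers the standard mixture used throughout the
#' package's examples and simulations.
#'
#' @return a `spectral_library` of 13 compounds.
#' @examples
#' standard_library()
#' @export
standard_library <- function() {
  read_spectral_library(system.file("extdata", "standard_mix_library.csv",
                                    package = "pscore", mustWork = TRUE))
}
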