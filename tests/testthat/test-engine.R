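params_default <- pscore_params()

test_that("parameter validation and match-factor normalisation", {
  p <- pscore_params(f = 70)
  expect_equal(p$f, 0.70)
  expect_error(pscore_params(w = 0), "w")
  expect_error(pscore_params(s_t = 7))
  expect_error(pscore_params(s_t = 19))
  expect_error(pscore_params(ct = 1.2))
})

test_that("candidate groups are the M1 apices inside the search window", {
  lib <- two_compound_library()
  entry <- lib[1, ]

  chrom <- clean_compA_chromatogram(height = 1000)
  groups <- candidate_groups(chrom, entry, params_default)
  expect_length(groups, 1L)
  expect_lt(abs(groups[[1]]$t_j - 5.0), 0.005 + 1e-9)
  expect_equal(groups[[1]]$intensities,
               1000 * c(1, 0.8, 0.5, 0.2))
  expect_equal(groups[[1]]$ratios, c(0.8, 0.5, 0.2))

  # no M1 signal in the window -> no candidates
  silent <- gaussian_chromatogram(data.frame(mz = 60, center = 5,
                                             height = 100, sigma = 0.02))
  expect_length(candidate_groups(silent, entry, params_default), 0L)

  # two M1 apices -> two groups in ascending order
  double <- gaussian_chromatogram(data.frame(
    mz = 50, center = c(4.8, 5.2), height = c(900, 700), sigma = 0.02))
  groups <- candidate_groups(double, entry, params_default)
  expect_length(groups, 2L)
  expect_lt(groups[[1]]$t_j, groups[[2]]$t_j)
})

test_that("stage 1 awards three points per co-occurring fragment", {
  lib <- two_compound_library()
  entry <- lib[1, ]
  win <- search_window(entry, params_default)

  perfect <- clean_compA_chromatogram()
  g <- first_group(perfect, entry)
  expect_equal(stage1_score(g, entry_trace_list(perfect, entry), win), 12L)

  # all fragments zero at t_j except M1 (needed for a candidate) ->
  # M1 alone scores 3
  m1_only <- gaussian_chromatogram(data.frame(mz = 50, center = 5,
                                              height = 1000, sigma = 0.02))
  g <- first_group(m1_only, entry)
  expect_equal(stage1_score(g, entry_trace_list(m1_only, entry), win), 3L)

  # M4 present but apexed 0.2 min away and rising past t_j: presence
  # point only -> 10
  shifted <- gaussian_chromatogram(data.frame(
    mz = c(50, 60, 70, 75), center = c(5, 5, 5, 5.2),
    height = c(1000, 800, 500, 200), sigma = 0.02))
  g <- first_group(shifted, entry)
  expect_equal(stage1_score(g, entry_trace_list(shifted, entry), win), 10L)
})

test_that("stage 2 scores ratios inside the closed match-factor interval", {
  lib <- standard_library()
  ethanol <- lib[lib$compound == "Ethanol", ]

  # interval endpoints from the match-factor formulas: [f R, (2-f) R]
  f <- 0.70
  expect_equal(f * 0.777, 0.5439)
  expect_equal((2 - f) * 0.777, 1.0101)

  mk_group <- function(ratios, i1 = 1000) {
    structure(list(compound = "Ethanol", t_j = 6.64, index = 1L,
                   mz = c(31L, 45L, 46L, 29L),
                   intensities = c(i1, i1 * ratios),
                   ratios = if (i1 > 0) ratios else rep(NA_real_, 3)),
              class = "peak_group")
  }

  exact <- mk_group(c(0.777, 0.343, 0.249))
  expect_equal(stage2_score(exact, ethanol, f), 3L)

  # one ratio at twice its library value falls above (2-f) R
  doubled <- mk_group(c(2 * 0.777, 0.343, 0.249))
  expect_equal(stage2_score(doubled, ethanol, f), 2L)

  # undefined ratios (no M1 intensity) score zero
  undef <- mk_group(c(0.777, 0.343, 0.249), i1 = 0)
  expect_equal(stage2_score(undef, ethanol, f), 0L)

  # closed interval: exactly on the boundary counts
  boundary <- mk_group(c(f * 0.777, (2 - f) * 0.343, 0.249))
  expect_equal(stage2_score(boundary, ethanol, f), 3L)

  # percentage-style match factor is normalised
  expect_equal(stage2_score(exact, ethanol, 70), 3L)
})

test_that("stage 2 is non-increasing in the match factor", {
  lib <- two_compound_library()
  entry <- lib[1, ]
  set.seed(23)
  for (rep in 1:50) {
    ratios <- as.numeric(unlist(entry[c("r2", "r3", "r4")])) *
      exp(rnorm(3, 0, 0.4))
    g <- structure(list(compound = "CompA", t_j = 5, index = 1L,
                        mz = c(50L, 60L, 70L, 75L),
                        intensities = c(1000, 1000 * ratios),
                        ratios = ratios),
                   class = "peak_group")
    fs <- sort(runif(4, 0.05, 0.95))
    scores <- vapply(fs, function(f) stage2_score(g, entry, f), integer(1))
    expect_true(all(diff(scores) <= 0))
  }
})

test_that("stage 3 scores fragment/M1 correlations over t_j +/- delta", {
  rts <- seq(4.5, 5.5, by = 0.005)
  shape <- 1000 * exp(-((rts - 5)^2) / (2 * 0.02^2))
  mk_trace <- function(mz, y) {
    structure(list(mz = mz, rts = rts, intensities = y),
              class = "ion_trace")
  }

  # exact scalar multiples: all three correlations are 1
  traces <- list(mk_trace(50L, shape), mk_trace(60L, 0.8 * shape),
                 mk_trace(70L, 0.5 * shape), mk_trace(75L, 0.2 * shape))
  expect_equal(stage3_score(traces, 5, 0.07, 0.95), 3L)

  # one fragment replaced by independent noise: that pair fails
  set.seed(41)
  traces_noise <- traces
  traces_noise[[4]] <- mk_trace(75L, runif(length(rts), 0, 100))
  expect_equal(stage3_score(traces_noise, 5, 0.07, 0.95), 2L)
  # and the engine agrees with a textbook Pearson computation
  sel <- rts >= 5 - 0.07 & rts <= 5 + 0.07
  rho <- oracle_pearson(shape[sel], traces_noise[[4]]$intensities[sel])
  expect_lt(rho, 0.95)

  # fewer than three scans in the neighbourhood: undefined, scores 0
  short <- lapply(traces, function(tr) {
    structure(list(mz = tr$mz, rts = c(4.9, 5.1),
                   intensities = c(10, 20)), class = "ion_trace")
  })
  expect_equal(stage3_score(short, 5, 0.07, 0.95), 0L)

  # zero variance in a fragment series: that pair scores 0
  traces_flat <- traces
  traces_flat[[2]] <- mk_trace(60L, rep(5, length(rts)))
  expect_equal(stage3_score(traces_flat, 5, 0.07, 0.95), 2L)
})

test_that("stage 3 is non-increasing in the correlation threshold", {
  rts <- seq(4.5, 5.5, by = 0.005)
  shape <- 1000 * exp(-((rts - 5)^2) / (2 * 0.02^2))
  set.seed(47)
  for (rep in 1:30) {
    traces <- lapply(c(50L, 60L, 70L, 75L), function(mz) {
      noise <- rnorm(length(rts), 0, runif(1, 0, 400))
      structure(list(mz = mz, rts = rts,
                     intensities = pmax(shape * runif(1, 0.2, 1) + noise, 0)),
                class = "ion_trace")
    })
    cts <- sort(runif(4, 0.05, 0.99))
    scores <- vapply(cts, function(ct) stage3_score(traces, 5, 0.07, ct),
                     integer(1))
    expect_true(all(diff(scores) <= 0))
  }
})

test_that("score_metabolite picks the best candidate with RT tie-breaking", {
  lib <- two_compound_library()
  entry <- lib[1, ]

  perfect <- clean_compA_chromatogram(height = 1234)
  id <- score_metabolite(perfect, entry, params_default)
  expect_equal(id$score, 18L)
  expect_equal(id$abundance, 1234)

  expect_null(score_metabolite(
    gaussian_chromatogram(data.frame(mz = 60, center = 5, height = 10,
                                     sigma = 0.02)),
    entry, params_default))

  # two identical peak groups at E_RT +/- 0.1 and E_RT + 0.3: the closer
  # wins on the delta_rt tie-break
  tie <- gaussian_chromatogram(data.frame(
    mz = rep(c(50, 60, 70, 75), 2),
    center = rep(c(5.1, 5.3), each = 4),
    height = rep(1000 * c(1, 0.8, 0.5, 0.2), 2),
    sigma = 0.02))
  id <- score_metabolite(tie, entry, params_default)
  expect_lt(abs(id$rt - 5.1), 0.005 + 1e-9)
})

test_that("conflict resolution keeps one compound per scan", {
  idents <- data.frame(
    compound = c("A", "B"),
    rt = c(13.95, 13.95),
    s1 = c(12L, 9L), s2 = c(3L, 3L), s3 = c(3L, 2L),
    score = c(18L, 14L),
    abundance = c(100, 50), delta_rt = c(0.01, 0.02),
    stringsAsFactors = FALSE)
  out <- resolve_conflicts(idents)
  expect_equal(out$compound, "A")

  # distinct RTs pass through unchanged
  idents$rt <- c(13.95, 14.10)
  out <- resolve_conflicts(idents)
  expect_equal(nrow(out), 2L)

  # equal scores: smaller delta_rt survives
  tie <- data.frame(compound = c("A", "B"), rt = 10, s1 = 10L, s2 = 3L,
                    s3 = 3L, score = 16L, abundance = 1,
                    delta_rt = c(0.30, 0.02), stringsAsFactors = FALSE)
  expect_equal(resolve_conflicts(tie)$compound, "B")

  # full tie: lexicographic compound name, deterministic
  full_tie <- data.frame(compound = c("B", "A"), rt = 10, s1 = 10L,
                         s2 = 3L, s3 = 3L, score = 16L, abundance = 1,
                         delta_rt = 0.1, stringsAsFactors = FALSE)
  expect_equal(resolve_conflicts(full_tie)$compound, "A")
})

test_that("analyse_sample identifies exactly what the sample contains", {
  lib <- standard_library()

  empty_spec <- synthetic_spec(lib, present = character(),
                               rt_range = c(5, 40), seed = 1)
  empty_chrom <- generate_sample(empty_spec)$chromatogram
  expect_equal(nrow(analyse_sample(empty_chrom, lib)), 0L)

  ethanol_only <- generate_sample(
    synthetic_spec(lib, present = "Ethanol", heights = 5e4,
                   rt_range = c(5, 40), seed = 2))
  ids <- analyse_sample(ethanol_only$chromatogram, lib)
  expect_equal(ids$compound, "Ethanol")
  expect_equal(ids$score, 18L)

  # surviving RTs are distinct after conflict resolution
  all13 <- generate_sample(synthetic_spec(lib, seed = 3))
  ids <- analyse_sample(all13$chromatogram, lib)
  expect_equal(anyDuplicated(ids$rt), 0L)
  expect_equal(nrow(ids), 13L)
})

test_that("stage scores are scale invariant and abundances scale", {
  lib <- standard_library()
  spec <- synthetic_spec(lib, present = c("Ethanol", "2-pentanone"),
                         heights = c(3e4, 8e5), noise_sd = 40, seed = 13)
  smp <- generate_sample(spec)
  ids <- analyse_sample(smp$chromatogram, lib)

  scaled <- chromatogram(smp$chromatogram$rts,
                         smp$chromatogram$traces * 37.5,
                         "scaled")
  ids_scaled <- analyse_sample(scaled, lib)
  expect_equal(ids_scaled$compound, ids$compound)
  expect_equal(ids_scaled[c("s1", "s2", "s3", "score")],
               ids[c("s1", "s2", "s3", "score")],
               ignore_attr = TRUE)
  expect_equal(ids_scaled$abundance, ids$abundance * 37.5)
})

test_that("engine stage scores match the brute-force oracle", {
  lib <- standard_library()
  by_rt <- lib[order(lib$expected_rt), ]
  close_pairs <- which(diff(by_rt$expected_rt) <= 1.2)
  set.seed(71)
  mismatches <- 0L
  out_of_bounds <- 0L
  checked <- 0L
  for (rep in 1:10) {
    k <- sample(close_pairs, 1)
    present <- by_rt$compound[c(k, k + 1L)]
    ert <- by_rt$expected_rt[c(k, k + 1L)]
    spec <- synthetic_spec(lib, present = present,
                           heights = 10^runif(2, 4, 6),
                           rt_offsets = runif(2, -0.2, 0.2),
                           noise_sd = runif(1, 0, 150),
                           rt_range = c(min(ert) - 0.9, max(ert) + 0.9),
                           seed = 1000 + rep)
    chrom <- generate_sample(spec)$chromatogram
    params <- pscore_params()
    for (cp in present) {
      entry <- lib[lib$compound == cp, ]
      traces <- entry_trace_list(chrom, entry)
      win <- search_window(entry, params)
      for (g in candidate_groups(chrom, entry, params)) {
        s1 <- stage1_score(g, traces, win, params$delta)
        s2 <- stage2_score(g, entry, params$f)
        s3 <- stage3_score(traces, g$t_j, params$delta, params$ct)
        if (s1 != oracle_stage1(chrom, entry, g$t_j, params) ||
            s2 != oracle_stage2(chrom, entry, g$t_j, params) ||
            s3 != oracle_stage3(chrom, entry, g$t_j, params)) {
          mismatches <- mismatches + 1L
        }
        if (s1 < 0 || s1 > 12 || s2 < 0 || s2 > 3 || s3 < 0 || s3 > 3) {
          out_of_bounds <- out_of_bounds + 1L
        }
        checked <- checked + 1L
      }
    }
  }
  expect_equal(mismatches, 0L)
  expect_equal(out_of_bounds, 0L)
  expect_gt(checked, 20L)
})
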