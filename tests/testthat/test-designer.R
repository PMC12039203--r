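make_features <- function(asym, mfe, gc914, a10, region = "UTR") {
  n <- length(asym)
  data.frame(thermo_asymmetry = asym, self_fold_mfe = mfe,
             accessibility = NA_real_, gc_full = 50, gc_9_14 = gc914,
             a10 = a10, binding_energy = -20,
             region = rep_len(region, n), stringsAsFactors = FALSE)
}

test_that("efficacy scores hit the bounds and honor degenerate weights", {
  er <- rnaidesign:::tetramer_energy_range()
  amax <- er[2] - er[1]
  # all four normalized features at 100 vs all at 0 (self-fold bounds are
  # empirical over the candidate set, so provide a spanning set)
  f <- make_features(asym = c(amax, -amax), mfe = c(0, -12),
                     gc914 = c(100, 0), a10 = c(TRUE, FALSE))
  expect_equal(efficacy_scores(f), c(100, 0))
  # degenerate weights: only asymmetry counts
  f2 <- make_features(asym = c(0, amax / 2, amax), mfe = c(-1, -3, -2),
                      gc914 = c(10, 80, 40), a10 = c(TRUE, FALSE, TRUE))
  got <- efficacy_scores(f2, weights = c(thermo_asymmetry = 1))
  expect_equal(got, 100 * (f2$thermo_asymmetry + amax) / (2 * amax))
  expect_error(efficacy_scores(f2, weights = c(thermo_asymmetry = 0)),
               "positive")
  # all candidates equal on a feature -> that feature contributes 100
  f3 <- make_features(asym = c(0, 0), mfe = c(-2, -2), gc914 = c(50, 50),
                      a10 = c(TRUE, TRUE))
  got3 <- efficacy_scores(f3, weights = c(self_fold = 1))
  expect_equal(got3, c(100, 100))
})

test_that("efficacy scores stay in [0, 100] on real feature tables", {
  t <- gen_transcriptome(1, 300, seed = 51)[[1]]
  ft <- compute_feature_table(t, accessibility = FALSE)
  e <- efficacy_scores(ft)
  expect_true(all(e >= 0 & e <= 100))
})

test_that("combined_scores implements the priority slider", {
  expect_equal(combined_scores(80, 40, 50), 60)
  expect_equal(combined_scores(80, 40, 80), 72)  # 4:1 weighting
  E <- c(10, 50, 90); S <- c(90, 50, 10)
  expect_equal(combined_scores(E, S, 100), E)
  expect_equal(combined_scores(E, S, 0), S)
  expect_error(combined_scores(c(1, 2), 1, 50), "length")
  # monotone in priority when E > S elementwise
  E2 <- c(70, 80); S2 <- c(10, 20)
  vals <- sapply(seq(0, 100, 10), function(p) combined_scores(E2, S2, p))
  expect_true(all(diff(t(vals)) > 0))
})

test_that("select_window matches exhaustive search and breaks ties leftmost", {
  # uniform scores: leftmost window, mean equals the constant
  w <- select_window(rep(42, 480), 500, k = 21, W = 300)
  expect_equal(w$window, interval(0, 300))
  expect_equal(w$mean_score, 42)
  expect_false(w$truncated)

  # planted high-score block
  set.seed(52)
  L <- 2000
  scores <- runif(L - 20, 10, 30)
  scores[800:1079] <- runif(280, 80, 100)  # sites of a high 300-bp region
  w <- select_window(scores, L, k = 21, W = 300)
  o <- oracle_select_window(scores, L, 21, 300)
  expect_equal(w$window$start, o$start)
  expect_equal(w$mean_score, o$mean)
  expect_gte(w$window$start + 300, 1079)
  expect_lte(w$window$start, 800)

  # min objective mirrors the low-score control design
  wmin <- select_window(scores, L, k = 21, W = 300, objective = "min")
  omin <- oracle_select_window(scores, L, 21, 300, "min")
  expect_equal(wmin$window$start, omin$start)
  expect_equal(wmin$mean_score, omin$mean)
})

test_that("select_window handles ORF restriction and short regions", {
  scores <- c(rep(0, 100), rep(100, 160), rep(0, 220))
  # ORF [100, 280): only windows inside it are allowed
  w <- select_window(scores, 500, k = 21, W = 100, restrict_to_orf = TRUE,
                     orf = interval(100, 280))
  expect_gte(w$window$start, 100)
  expect_lte(w$window$end, 280)
  expect_equal(w$mean_score, 100)

  expect_warning(
    ws <- select_window(scores, 500, k = 21, W = 300, restrict_to_orf = TRUE,
                        orf = interval(100, 280)),
    "shorter")
  expect_true(ws$truncated)
  expect_equal(ws$window, interval(100, 280))
  expect_error(suppressWarnings(
    select_window(scores, 500, k = 21, W = 300,
                  restrict_to_orf = TRUE, orf = interval(0, 10))))
  expect_error(select_window(rep(1, 10), 500), "expected")
})

test_that("insertion constructs place the site mid-backbone reversibly", {
  backbone <- gen_transcriptome(1, 210, seed = 53)[[1]]
  site <- random_dna(1, 21)
  cons <- build_insertion_construct(backbone, site)
  expect_equal(nchar(cons$template), 231)
  expect_equal(cons$insertion_offset, 105)
  expect_equal(substr(cons$template, 106, 126), site)
  excised <- paste0(substr(cons$template, 1, 105),
                    substr(cons$template, 127, 231))
  expect_equal(excised, backbone$seq)
  expect_error(build_insertion_construct(backbone, "ACGTN"), "ambiguous")
})

test_that("design_dsrna ties the pipeline together", {
  t <- gen_transcriptome(1, 400, seed = 54)[[1]]
  db <- gen_transcriptome(5, 300, seed = 55)
  res <- design_dsrna(t, W = 120, offtarget_dbs = list(db), m = 0,
                      priority = 80)
  expect_equal(nchar(res$sequence), 120)
  expect_true(all(c("efficacy", "safety", "combined") %in%
                    names(res$features)))
  expect_equal(res$features$combined,
               combined_scores(res$features$efficacy, res$features$safety,
                               80))
  # window mean recomputable from the combined scores
  o <- oracle_select_window(res$features$combined, 400, 21, 120)
  expect_equal(res$window$mean_score, o$mean)
})
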