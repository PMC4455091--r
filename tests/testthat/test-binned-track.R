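# Binned tracks, input subtraction, top-bin selection and Spearman-based
# location validation.

sl <- c(chrA = 10000, chrB = 5500)   # chrB has a partial final bin

test_that("binning conserves mass and apportions by fractional overlap", {
  # one read fully inside bin 3 of chrA ([3000, 4000))
  tr <- bin_coverage(reads_gr("chrA", 3201, width = 100), sl)
  expect_equal(sum(tr$counts), 1)
  expect_equal(tr$counts[4], 1)
  expect_equal(sum(tr$counts != 0), 1)

  # interval [2400, 3000) + [3000, 3400): 60%/40% across bins 2/3
  gr <- GenomicRanges::GRanges("chrA", IRanges::IRanges(2401, 3400))
  tr2 <- bin_coverage(gr, sl)
  expect_equal(tr2$counts[3], 0.6)
  expect_equal(tr2$counts[4], 0.4)

  # empty input: all-zero track on the full grid (10 + 6 bins)
  tr0 <- bin_coverage(GenomicRanges::GRanges(), sl)
  expect_equal(length(tr0$counts), 16)
  expect_true(all(tr0$counts == 0))

  # conservation on random weighted intervals, incl. multi-bin spans
  set.seed(31)
  n <- 200
  start <- sample(1:3000, n, replace = TRUE)
  gr3 <- GenomicRanges::GRanges(
    sample(names(sl), n, replace = TRUE, prob = c(2, 1)),
    IRanges::IRanges(start, width = sample(1:2500, n, TRUE)))
  gr3$score <- runif(n, 0.1, 5)
  tr3 <- bin_coverage(gr3, sl)
  expect_equal(sum(tr3$counts), sum(gr3$score), tolerance = 1e-9)

  expect_error(
    bin_coverage(reads_gr("chrB", 5490, width = 50), sl), "beyond")
  expect_error(
    bin_coverage(reads_gr("chrZ", 10, width = 5), sl), "absent")
})

test_that("five-prime mode assigns whole reads to the 5' bin", {
  gr <- GenomicRanges::GRanges("chrA", IRanges::IRanges(2950, 3049),
                               strand = c("+"))
  plus <- bin_coverage(gr, sl, mode = "five_prime")
  expect_equal(plus$counts[3], 1)         # 5' end at 2950 -> bin 2
  GenomicRanges::strand(gr) <- "-"
  minus <- bin_coverage(gr, sl, mode = "five_prime")
  expect_equal(minus$counts[4], 1)        # 5' end at 3049 -> bin 3
})

test_that("input subtraction is RPM arithmetic with negatives retained", {
  tr <- BinnedTrack(c(5, 0, 1, rep(0, 13)), sl, total_reads = 1e6)
  inp <- BinnedTrack(c(2, 0, 3, rep(0, 13)), sl, total_reads = 1e6)
  out <- subtract_input(tr, inp)
  expect_equal(out$values[1], 3)
  expect_equal(out$values[3], -2)        # input exceeds track: retained
  expect_equal(out$values[2], 0)

  zero <- BinnedTrack(rep(0, 16), sl, total_reads = 1e6)
  expect_equal(subtract_input(tr, zero)$values, tr$values)

  other <- BinnedTrack(rep(1, 8), c(chrA = 8000), total_reads = 1e6)
  expect_error(subtract_input(tr, other), "grid")
})

test_that("top bins select by value with coordinate tie-breaking", {
  tr <- BinnedTrack(c(5, 3, 9, 1, rep(0, 12)), sl)
  sel2 <- top_bins(tr, 2)                       # bins holding 9 and 5,
  expect_equal(sel2$flat, c(1, 3))              # returned in coordinate order
  expect_equal(sel2$value, c(5, 9) * 1e6 / 18)  # RPM scale

  tie <- BinnedTrack(c(4, 4, 4, rep(0, 13)), sl)
  expect_equal(top_bins(tie, 2)$flat, c(1, 2))   # lowest coordinates win

  expect_warning(sel <- top_bins(tr, 10), "nonzero")
  expect_equal(nrow(sel), 4)
  expect_error(top_bins(tr, 0), "k")
  expect_error(top_bins(BinnedTrack(rep(0, 16), sl, total_reads = 1)),
               "nonzero")
})

test_that("unified bin lists equal brute-force set union", {
  mk <- function(hot) {
    counts <- rep(0, 16); counts[hot] <- seq_along(hot) + 1
    top_bins(BinnedTrack(counts, sl), length(hot))
  }
  a <- mk(c(1, 5, 9)); b <- mk(c(2, 6, 10)); c3 <- mk(c(5, 6, 7))
  expect_equal(unified_bins(a, b)$flat, sort(c(1, 5, 9, 2, 6, 10)))
  expect_equal(unified_bins(a, a)$flat, a$flat)       # idempotent
  expect_equal(unified_bins(a, b, c3)$flat,
               sort(unique(c(a$flat, b$flat, c3$flat))))
  n <- nrow(unified_bins(a, b, c3))
  expect_gte(n, max(nrow(a), nrow(b), nrow(c3)))
  expect_lte(n, nrow(a) + nrow(b) + nrow(c3))
})

test_that("Spearman matches hand and brute-force rank computations", {
  mkt <- function(v) BinnedTrack(abs(v), sl, total_reads = 1)
  all_bins <- data.frame(flat = 1:16)
  v <- c(runif(16))
  ta <- mkt(v)
  expect_equal(spearman_correlation(ta, ta, all_bins), 1)
  desc <- BinnedTrack(rev(sort(v)), sl, total_reads = 1)
  asc <- BinnedTrack(sort(v), sl, total_reads = 1)
  expect_equal(spearman_correlation(asc, desc, all_bins), -1)

  # 5-bin toy, no ties: 1 - 6 * sum(d^2) / (n(n^2-1)) with sum(d^2) = 4
  a5 <- BinnedTrack(c(1, 2, 3, 4, 5, rep(0, 11)), sl, total_reads = 1)
  b5 <- BinnedTrack(c(2, 1, 4, 3, 5, rep(0, 11)), sl, total_reads = 1)
  expect_equal(spearman_correlation(a5, b5, data.frame(flat = 1:5)),
               1 - 24 / 120)

  # brute-force oracle at 1e-12 on 100 random 100-bin tracks (with ties)
  set.seed(88)
  big_sl <- c(chr1 = 100000)
  for (i in 1:100) {
    x <- sample(0:30, 100, replace = TRUE)
    y <- 0.4 * x + sample(0:30, 100, replace = TRUE)
    tx <- BinnedTrack(x, big_sl, total_reads = 1)
    ty <- BinnedTrack(y, big_sl, total_reads = 1)
    got <- spearman_correlation(tx, ty, data.frame(flat = 1:100))
    expect_equal(got, brute_spearman(x, y), tolerance = 1e-12)
  }

  # invariance under strictly monotone transforms
  tx <- BinnedTrack(runif(16), sl, total_reads = 1e6)   # values in [0, 1]
  ty <- BinnedTrack(runif(16), sl, total_reads = 1e6)
  r0 <- spearman_correlation(tx, ty, all_bins)
  tx2 <- tx; tx2$values <- exp(3 * tx$values) + 2
  ty2 <- ty; ty2$values <- log(ty$values + 1)
  expect_equal(spearman_correlation(tx2, ty2, all_bins), r0)

  # degenerate selections are flagged, not errors
  flat1 <- data.frame(flat = 1)
  expect_warning(r <- spearman_correlation(tx, ty, flat1), "undefined")
  expect_true(is.na(r))
  const <- BinnedTrack(rep(2, 16), sl, total_reads = 1)
  expect_warning(r2 <- spearman_correlation(const, ty, all_bins))
  expect_true(is.na(r2))
})

test_that("correlation argmax maps marks to locations with no-calls", {
  expect_equal(predict_by_correlation(
    c(H3K4me3 = 0.6, H3K4me1 = 0.4, H3K9me3 = -0.2)), "promoter")
  expect_equal(predict_by_correlation(
    c(H3K4me3 = 0.30, H3K4me1 = 0.31, H3K9me3 = 0)), "enhancer")
  # H3K27ac never wins the argmax even when largest
  expect_equal(predict_by_correlation(
    c(H3K4me3 = 0.3, H3K4me1 = 0.2, H3K27ac = 0.9, H3K9me3 = 0.1)),
    "promoter")
  expect_true(is.na(predict_by_correlation(
    c(H3K4me3 = NA, H3K4me1 = 0.2, H3K9me3 = 0.1))))
  expect_warning(r <- predict_by_correlation(c(H3K4me3 = 0.2)), "missing")
  expect_true(is.na(r))
})

test_that("concordance table counts per-location agreement", {
  ms <- data.frame(
    protein_id = sprintf("F%02d", 1:20),
    location = c(rep("promoter", 17), rep("enhancer", 3)),
    stringsAsFactors = FALSE)
  corr <- c(rep("promoter", 14), rep("enhancer", 3),
            rep("enhancer", 2), "promoter")
  names(corr) <- ms$protein_id
  tab <- concordance_table(ms, corr)
  expect_equal(tab$n[tab$location == "promoter"], 17)
  expect_equal(tab$n_agree[tab$location == "promoter"], 14)
  expect_equal(tab$pct_agree[tab$location == "promoter"], 82)
  expect_equal(tab$pct_agree[tab$location == "enhancer"], round(100 * 2 / 3))
  empty <- concordance_table(ms, c(ZZ = "promoter"))
  expect_equal(nrow(empty), 0)
})
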