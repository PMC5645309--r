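lin_frags <- function(n, chrom = "chr") {
  data.frame(chrom = chrom, start = seq(0L, by = 250L, length.out = n),
             end = seq(250L, by = 250L, length.out = n), index = 0:(n - 1L),
             mappable = TRUE)
}

test_that("window sums slide over mappable fragments", {
  expect_equal(window_statistics(c(1, 2, 3, 4), 3), c(6, 9))
  expect_equal(window_statistics(c(5, 1, 7), 1), c(5, 1, 7))
  expect_error(window_statistics(c(1, 2), 3), "fewer than w")
})

test_that("permutation-invariant inputs yield no significant windows", {
  thr <- permutation_threshold(rep(4, 50), caller_params(seed = 3))
  expect_identical(thr$threshold, Inf)
  expect_true(all(thr$table$fdr_hat >= 1))
})

test_that("the streaming caller matches the naive oracle bit-for-bit", {
  # fixed 60-fragment background with one elevated run
  set.seed(606)
  x <- rpois(60, 3)
  x[25:28] <- x[25:28] + c(35, 42, 38, 31)
  p <- caller_params(w = 3, iterations = 1000, fdr = 0.01, fdr_prob = 0.05,
                     seed = 77)
  thr <- permutation_threshold(x, p)
  oracle <- naive_caller(x, 3, 1000, 0.01, 0.05, seed = 77)
  expect_identical(thr$table$candidate, oracle$candidates)
  expect_identical(thr$table$mean_perm_ge, oracle$mean_perm_ge)
  expect_identical(thr$table$fdr_hat, oracle$fdr_hat)
  expect_identical(thr$threshold, oracle$threshold)

  iv <- call_significant(x, thr$threshold, 3, lin_frags(60))
  expect_equal(nrow(iv), length(oracle$intervals))
  for (j in seq_len(nrow(iv))) {
    expect_equal(iv$first[j], oracle$intervals[[j]]$first)
    expect_equal(iv$last[j], oracle$intervals[[j]]$last)
    expect_equal(iv$peak[j], oracle$intervals[[j]]$peak)
    expect_equal(classify_category(x, iv$first[j], iv$last[j],
                                   thr$threshold, 3),
                 oracle$categories[j])
  }
})

test_that("limiting parameters call every window above the candidate floor", {
  set.seed(12)
  x <- rpois(40, 6)
  p <- caller_params(w = 3, iterations = 50, fdr = 0.999, fdr_prob = 1,
                     seed = 5)
  thr <- permutation_threshold(x, p)
  W <- window_statistics(x, 3)
  expect_equal(thr$threshold, min(W))
  iv <- call_significant(x, thr$threshold, 3, lin_frags(40))
  expect_equal(nrow(iv), 1L)  # everything merges into one interval
  expect_equal(iv$first, 1L)
  expect_equal(iv$last, 40L)
})

test_that("significant windows merge when overlapping or adjacent", {
  x <- numeric(30)
  x[10:14] <- 50          # two overlapping significant windows
  iv <- call_significant(x, 100, 3, lin_frags(30))
  expect_equal(nrow(iv), 1L)
  expect_equal(c(iv$first, iv$last), c(9L, 15L))

  x2 <- numeric(30); x2[5] <- 200; x2[20] <- 200
  iv2 <- call_significant(x2, 150, 3, lin_frags(30))
  expect_equal(nrow(iv2), 2L)
  expect_equal(iv2$last - iv2$first + 1L, c(3L, 3L) + 2L)

  expect_equal(nrow(call_significant(x2, 1e5, 3, lin_frags(30))), 0L)
})

test_that("robustness categories follow the removal and averaging rules", {
  x <- c(0, 0, 10, 100, 10, 0, 0)
  # members 3..5, T = 25: zeroing the top leaves 20 < 25, averaging the top
  # to its flanking fragments gives 30 >= 25
  expect_equal(classify_category(x, 3L, 5L, 25, 3), 2L)
  x2 <- c(0, 0, 40, 40, 40, 0, 0)
  expect_equal(classify_category(x2, 3L, 5L, 25, 3), 1L)
  x3 <- c(0, 0, 0, 100, 0, 0, 0)
  expect_equal(classify_category(x3, 3L, 5L, 90, 3), 3L)
  # ties for the top fragment break to the lowest index
  x4 <- c(0, 0, 60, 60, 0, 0, 0)
  expect_equal(classify_category(x4, 3L, 5L, 25, 3), 1L)
})

test_that("raising the threshold never adds intervals and categories are monotone", {
  set.seed(88)
  x <- rpois(50, 3); x[20:24] <- x[20:24] + 30
  frags <- lin_frags(50)
  iv_lo <- call_significant(x, 60, 3, frags)
  iv_hi <- call_significant(x, 90, 3, frags)
  expect_gte(nrow(iv_lo), nrow(iv_hi))
  # every high-threshold interval is contained in a low-threshold one
  for (j in seq_len(nrow(iv_hi)))
    expect_true(any(iv_lo$first <= iv_hi$first[j] & iv_lo$last >= iv_hi$last[j]))
  if (nrow(iv_hi)) {
    c_hi <- classify_category(x, iv_hi$first[1], iv_hi$last[1], 90, 3)
    c_lo <- classify_category(x, iv_hi$first[1], iv_hi$last[1], 60, 3)
    expect_lte(c_lo, c_hi + 1L)
  }
})

test_that("calling is deterministic in the seed and regions are independent", {
  set.seed(41)
  toy <- make_toy_genome(n_chrom = 1, chrom_len = 250000L, seed = 21)
  bait <- toy_bait(toy, "P1", toy$tss[["P1"]])
  fr <- toy$map$fragments
  x <- rpois(nrow(fr), 3)
  # spike the central three fragments of each planted locus
  pl <- unlist(lapply(toy$truth$planted, function(p) p$rows[3:5]),
               use.names = FALSE)
  x[pl] <- x[pl] + 80
  cc <- fourcmap:::new_fragment_counts("P1", "rep1", x, toy$map)
  regions <- list(whole = list(chrom = fr$chrom[1]),
                  domain = list(chrom = fr$chrom[1],
                                start = toy$domain$start,
                                end = toy$domain$end))
  p <- caller_params(iterations = 200, seed = 13)
  a <- call_bait(cc, bait, regions, p)
  b <- call_bait(cc, bait, regions, p)
  expect_identical(summary(a), summary(b))
  expect_equal(unname(a$seeds), c(13L, 14L))
  # planted fragments are called in both region modes
  for (rg in names(regions)) {
    iv <- a$intervals[[rg]]
    expect_gt(nrow(iv), 0)
    covered <- vapply(pl, function(r)
      any(iv$start < fr$end[r] & iv$end > fr$start[r]), logical(1))
    expect_true(all(covered))
  }
  expect_error(call_bait(cc, bait, list(a = list(chrom = "x"),
                                        a = list(chrom = "x")), p),
               "uniquely named")
})

test_that("unmappable fragments are excluded from windows entirely", {
  toy <- make_toy_genome(n_chrom = 1, chrom_len = 150000L, seed = 22)
  fr <- toy$map$fragments
  bait <- toy_bait(toy, "P1", toy$tss[["P1"]])
  x <- numeric(nrow(fr))
  mp <- which(fr$mappable)
  # an isolated spike on three mappable fragments that straddle an
  # unmappable gap still forms one window
  run <- NULL
  for (i in seq_len(length(mp) - 2)) {
    if (mp[i + 2] - mp[i] > 2) { run <- mp[i:(i + 2)]; break }
  }
  skip_if(is.null(run))
  x[run] <- 100
  cc <- fourcmap:::new_fragment_counts("P1", "rep1", x, toy$map)
  calls <- call_bait(cc, bait, list(whole = list(chrom = fr$chrom[1])),
                     caller_params(iterations = 100, seed = 2))
  iv <- calls$intervals$whole
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$peak, 300)
})
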