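toy_small <- function(seed = 5) {
  make_toy_genome(n_chrom = 2, chrom_len = c(200000L, 60000L), seed = seed)
}

test_that("the toy genome is deterministic in its seed", {
  a <- toy_small(5)
  b <- toy_small(5)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$map$fragments, b$map$fragments)
  expect_identical(a$tracks, b$tracks)
  c <- toy_small(6)
  expect_false(identical(as.character(a$genome), as.character(c$genome)))
})

test_that("fragment count matches the binomial site-density expectation", {
  toy <- toy_small(8)
  fr <- toy$map$fragments
  n1 <- sum(fr$chrom == names(toy$genome)[1])
  expected <- 200000 / 250
  expect_lt(abs(n1 - expected), 3 * sqrt(expected) + 0.016 * expected)
  # every internal fragment boundary coincides with a motif occurrence
  s <- as.character(toy$genome[[1]])
  internal <- fr[fr$chrom == names(toy$genome)[1] & fr$index > 0, ]
  expect_true(all(substr(rep(s, nrow(internal)), internal$start + 1,
                         internal$start + 4) == "GATC"))
})

test_that("planted clusters appear as co-binding of the configured TF numbers", {
  toy <- toy_small(9)
  covers <- function(tf, chrom, pos) {
    tr <- toy$tracks$tf[[tf]]
    any(tr$chrom == chrom & tr$start <= pos & tr$end > pos)
  }
  tfs <- names(toy$tracks$tf)
  # each planted locus: the six designated TF tracks all overlap its midpoint
  for (p in toy$truth$planted)
    expect_true(all(vapply(tfs[1:6], covers, logical(1),
                           chrom = toy$domain$chrom, pos = p$mid)))
  # 5-TF decoy: exactly the designated five, not the sixth
  d5 <- (toy$truth$decoy5[["start"]] + toy$truth$decoy5[["end"]]) %/% 2
  expect_true(all(vapply(tfs[1:5], covers, logical(1),
                         chrom = toy$domain$chrom, pos = d5)))
  expect_false(covers(tfs[6], toy$domain$chrom, d5))
  expect_error(make_toy_genome(site_density = 0.9), "infeasible site_density")
  expect_error(make_toy_genome(chrom_len = 10000L), ">= 200 fragments")
})

test_that("simulated libraries are seed-reproducible and conserve read composition", {
  toy <- toy_small(5)
  bait <- toy_bait(toy, "P1", toy$tss[["P1"]])
  model <- contact_model(domain = toy$domain,
                         planted = data.frame(row = toy$truth$planted_rows,
                                              gamma = 20))
  spec <- library_spec(5000, seed = 44)
  a <- simulate_4c_library(toy, bait, model, spec)
  b <- simulate_4c_library(toy, bait, model, spec)
  expect_identical(a$pairs, b$pairs)
  expect_identical(a$truth$captured, b$truth$captured)
  expect_equal(sum(a$truth$captured) + a$truth$n_self + a$truth$n_uncut,
               5000)
  # FASTQ bytes are identical too
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  g1 <- withr::local_tempfile(); g2 <- withr::local_tempfile()
  write_pairs_fastq(a$pairs, f1, f2)
  write_pairs_fastq(b$pairs, g1, g2)
  expect_identical(readLines(f1), readLines(g1))
  expect_identical(readLines(f2), readLines(g2))
})

test_that("degenerate self-ligation fraction sends every read to the bait fragment", {
  toy <- toy_small(5)
  bait <- toy_bait(toy, "P1", toy$tss[["P1"]])
  model <- contact_model(domain = toy$domain)
  sim <- simulate_4c_library(toy, bait, model,
                             library_spec(400, p_self = 1, p_uncut = 0,
                                          seed = 3))
  expect_equal(sim$truth$n_self, 400)
  expect_equal(sum(sim$truth$captured), 0)
  # and those reads genuinely carry the bait fragment sequence
  dm <- demultiplex(sim$pairs, list(bait))
  tr <- trim_and_filter(dm$assigned$P1, bait)
  loci <- align_exact(tr$reads$seq, toy$genome)
  cc <- count_per_fragment(loci, toy$map)
  fr <- toy$map$fragments
  bait_row <- which(fr$chrom == bait$chrom & fr$start <= bait$start &
                      fr$end > bait$start)
  expect_equal(cc$counts[bait_row], nrow(tr$reads))
})

test_that("planted fragments follow the multinomial contact weights", {
  toy <- toy_small(5)
  bait <- toy_bait(toy, "P1", toy$tss[["P1"]])
  pl <- toy$truth$planted_rows[8]          # a central planted fragment
  model <- contact_model(domain = toy$domain, frag_noise_sd = 0,
                         planted = data.frame(row = pl, gamma = 50))
  spec <- library_spec(50000, p_self = 0, p_uncut = 0, seed = 91)
  sim <- simulate_4c_library(toy, bait, model, spec)
  w <- sim$truth$weights
  p <- w / sum(w)
  exp_counts <- 50000 * p
  sd_counts <- sqrt(50000 * p * (1 - p))
  # observed counts within 4 sigma of the multinomial expectation
  check <- which(exp_counts > 5)
  expect_true(all(abs(sim$truth$captured[check] - exp_counts[check]) <=
                    4 * sd_counts[check] + 1))
  # the planted fragment dominates each non-planted neighbour
  expect_gt(exp_counts[pl], max(exp_counts[c(pl - 6, pl + 6)]))
  expect_gt(sim$truth$captured[pl], sim$truth$captured[pl - 6])
})

test_that("control libraries are sparse uniform noise", {
  toy <- toy_small(5)
  bait <- toy_bait(toy, "P1", toy$tss[["P1"]])
  model <- contact_model(domain = toy$domain)
  sim <- simulate_4c_library(toy, bait, model,
                             library_spec(3000, seed = 2, is_control = TRUE),
                             label = "control")
  hit <- which(sim$truth$captured > 0)
  expect_lte(length(hit), ceiling(0.015 * nrow(toy$map$fragments)))
  expect_gt(length(hit), 2)
})

test_that("toy tracks are written as plain-text artefacts", {
  toy <- toy_small(5)
  dir <- withr::local_tempdir()
  files <- write_toy_tracks(toy, dir)
  expect_true(all(file.exists(files)))
  fa <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_identical(as.character(fa), as.character(toy$genome))
  truth <- read.table(file.path(dir, "truth.tsv"), header = TRUE)
  expect_equal(nrow(truth), 5L)
})
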