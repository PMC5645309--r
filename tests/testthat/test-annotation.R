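iv_df <- function(start, end, category = 1L, chrom = "chr16") {
  data.frame(chrom = rep_len(chrom, length(start)), start = start, end = end,
             category = rep_len(category, length(start)))
}

test_that("replicate overlap keeps category-1/2 intersections with colour classes", {
  out <- intersect_replicates(iv_df(100, 200, 1L), iv_df(150, 250, 1L))
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$start, out$end), c(150, 200))
  expect_equal(out$colour, "red")

  mixed <- intersect_replicates(iv_df(100, 200, 1L), iv_df(150, 250, 2L))
  expect_equal(mixed$colour, "orange")

  # category-3 intervals are discarded before overlapping
  expect_equal(nrow(intersect_replicates(iv_df(100, 200, 3L),
                                         iv_df(150, 250, 1L))), 0L)
  # disjoint intervals don't overlap
  expect_equal(nrow(intersect_replicates(iv_df(100, 200, 1L),
                                         iv_df(200, 300, 1L))), 0L)
  # symmetry up to parent labels
  a <- iv_df(c(100, 500), c(220, 640), c(1L, 2L))
  b <- iv_df(c(180, 600), c(300, 900), c(2L, 1L))
  ab <- intersect_replicates(a, b)
  ba <- intersect_replicates(b, a)
  expect_equal(ab[c("chrom", "start", "end", "colour")],
               ba[c("chrom", "start", "end", "colour")])
})

test_that("domain counts use the interval midpoint", {
  dom <- list(chrom = "chr16", start = 1000, end = 2000)
  iv <- iv_df(c(1100, 1700, 2500), c(1200, 2150, 2600))
  expect_equal(count_domain(iv, dom), c(inside = 2L, outside = 1L))
  # straddling interval with midpoint inside counts inside
  expect_equal(count_domain(iv_df(950, 1100, 1L), dom),
               c(inside = 1L, outside = 0L))
  expect_equal(count_domain(iv_df(integer(0), integer(0), integer(0)), dom),
               c(inside = 0L, outside = 0L))
})

test_that("gene overlap honours the 2 kb promoter window on both strands", {
  genes <- data.frame(name = c("plus", "minus"), chrom = "chr16",
                      strand = c("+", "-"),
                      txStart = c(10000L, 50000L), txEnd = c(14000L, 54000L))
  hit_genes <- function(s, e)
    gene_overlap(iv_df(s, e), genes)$gene
  expect_equal(hit_genes(11000, 11001), "plus")         # 1 bp inside the body
  # plus strand: promoter covers [txStart - 2000, txStart)
  expect_equal(hit_genes(7990, 8002), "plus")           # base 1999 bp upstream
  expect_equal(hit_genes(7990, 8001), "plus")           # base exactly 2000 bp
  expect_equal(length(hit_genes(7990, 8000)), 0L)       # 2001 bp: outside
  # minus strand: upstream extends to higher coordinates
  expect_equal(hit_genes(55990, 56000), "minus")        # within [54000, 56000)
  expect_equal(length(hit_genes(56000, 56010)), 0L)
  # mirror check by reflecting coordinates around the genome midpoint
  L <- 64000L
  genes_r <- data.frame(name = "plusr", chrom = "chr16", strand = "+",
                        txStart = L - 54000L, txEnd = L - 50000L)
  for (span in list(c(55990, 56000), c(56000, 56010), c(54100, 54200))) {
    fwd <- nrow(gene_overlap(iv_df(span[1], span[2]), genes[2, ]))
    refl <- nrow(gene_overlap(iv_df(L - span[2], L - span[1]), genes_r))
    expect_equal(fwd, refl)
  }
  # an interval may hit several genes
  both <- gene_overlap(iv_df(9000, 52000), genes)
  expect_equal(sort(both$gene), c("minus", "plus"))
})

test_that("TF clusters require distinct-TF multiplicity at the same location", {
  mk <- function(...) {
    spans <- list(...)
    data.frame(chrom = "chr16",
               start = vapply(spans, `[`, numeric(1), 1),
               end = vapply(spans, `[`, numeric(1), 2))
  }
  six <- stats::setNames(lapply(1:6, function(i) mk(c(1000, 1400))),
                         paste0("tf", 1:6))
  cl <- find_tf_clusters(six)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_tfs, 6L)
  expect_equal(c(cl$start, cl$end), c(1000, 1400))

  five <- six[1:5]
  expect_equal(nrow(find_tf_clusters(five)), 0L)

  # six TFs overlapping only pairwise in a chain: max multiplicity 2
  chain <- stats::setNames(lapply(0:5, function(i)
    mk(c(1000 + i * 300, 1400 + i * 300))), paste0("tf", 1:6))
  expect_equal(nrow(find_tf_clusters(chain)), 0L)

  expect_error(find_tf_clusters(stats::setNames(six, rep("tf1", 6))),
               "uniquely named")

  # randomised fixtures against the per-base sweep oracle
  set.seed(99)
  for (rep in 1:8) {
    peaks <- stats::setNames(lapply(1:7, function(i) {
      st <- sample(0:4500, 5)
      data.frame(chrom = "chr16", start = st, end = st + sample(100:400, 5,
                                                                replace = TRUE))
    }), paste0("tf", 1:7))
    for (mt in c(3L, 5L)) {
      cl <- find_tf_clusters(peaks, min_tfs = mt)
      cores <- naive_tf_cores(peaks, mt)
      expect_equal(nrow(cl), nrow(cores))
      if (nrow(cl)) {
        expect_equal(cl$core_start, cores$start)
        expect_equal(cl$core_end, cores$end)
        expect_true(all(cl$n_tfs >= mt))
      }
    }
  }
})

test_that("enhancer candidates respect the 2 kb proximity rule", {
  cl <- data.frame(chrom = "chr16", start = 10000L, end = 10500L,
                   core_start = 10000L, core_end = 10500L,
                   n_tfs = 6L, members = "a,b,c,d,e,f")
  cand_at <- function(iv_start, iv_end) {
    call_enhancer_candidates(cl, list(P1 = iv_df(iv_start, iv_end)))
  }
  expect_equal(nrow(cand_at(10200, 10300)$candidates), 1L)   # overlap
  expect_equal(cand_at(10200, 10300)$candidates$distance, 0)
  expect_equal(nrow(cand_at(12500, 12600)$candidates), 1L)   # gap 2000
  expect_equal(cand_at(12500, 12600)$candidates$distance, 2000)
  expect_equal(nrow(cand_at(12501, 12600)$candidates), 0L)   # gap 2001
  # upstream side
  expect_equal(nrow(cand_at(7900, 8000)$candidates), 1L)
  expect_equal(nrow(cand_at(7900, 7999)$candidates), 0L)

  # a cluster near intervals of two baits: one candidate, two supports
  two <- call_enhancer_candidates(cl, list(P1 = iv_df(10600, 10700),
                                           p24 = iv_df(9000, 9990)))
  expect_equal(nrow(two$candidates), 1L)
  expect_equal(nrow(two$supports), 2L)
  expect_equal(two$candidates$baits, "P1,p24")

  # randomised double-loop oracle over both emission criteria
  set.seed(123)
  for (rep in 1:8) {
    k <- 6
    cls <- data.frame(chrom = "chr16",
                      start = sample(0:50000, k), n_tfs = 6L,
                      members = "x")
    cls$end <- cls$start + 400L
    cls$core_start <- cls$start; cls$core_end <- cls$end
    ivs <- iv_df(sample(0:50000, 5), integer(5))
    ivs$end <- ivs$start + sample(500:3000, 5)
    got <- call_enhancer_candidates(cls, list(P1 = ivs))$candidates
    want <- vapply(seq_len(k), function(i)
      any(vapply(seq_len(nrow(ivs)), function(j)
        naive_gap(cls$start[i], cls$end[i], ivs$start[j], ivs$end[j]) <= 2000,
        logical(1))), logical(1))
    expect_equal(sort(got$start), sort(cls$start[want]))
  }
})

test_that("candidates are named by signed kb distance from the TSS", {
  expect_equal(name_by_tss_distance(100000 + 24300, 100000, "+"), "+24")
  expect_equal(name_by_tss_distance(500000 + 371000, 500000, "-"), "-371")
  expect_equal(name_by_tss_distance(100000, 100000, "+"), "+0")
  expect_equal(name_by_tss_distance(100000 - 58490, 100000, "+"), "-58")
})

test_that("cohesin/CTCF status and CNE overlap are literal span overlaps", {
  cand <- data.frame(chrom = "chr16", start = 1000L, end = 1500L)
  rad <- data.frame(chrom = "chr16", start = 1400L, end = 1600L)
  ctcf_hit <- data.frame(chrom = "chr16", start = 900L, end = 1100L)
  ctcf_miss <- data.frame(chrom = "chr16", start = 1500L, end = 1700L)
  expect_true(cohesin_ctcf_status(cand, rad, ctcf_miss))
  expect_false(cohesin_ctcf_status(cand, rad, ctcf_hit))
  none <- data.frame(chrom = "chr16", start = 5000L, end = 5100L)
  expect_false(cohesin_ctcf_status(cand, none, ctcf_miss))
  expect_true(cne_overlap(cand, rad))
  expect_false(cne_overlap(cand, none))
})
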