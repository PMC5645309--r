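# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths.

# naive O(n*m) motif scan: 0-based occurrence starts
naive_motif_starts <- function(seqstr, motif) {
  n <- nchar(seqstr); m <- nchar(motif)
  hits <- integer(0)
  for (i in seq_len(n - m + 1L))
    if (substr(seqstr, i, i + m - 1L) == motif) hits <- c(hits, i - 1L)
  hits
}

# naive digestion: fragment starts/ends from motif starts
naive_digest <- function(seqstr, motif) {
  cuts <- naive_motif_starts(seqstr, motif)
  cuts <- cuts[cuts > 0L]
  starts <- c(0L, cuts)
  data.frame(start = starts, end = c(cuts, nchar(seqstr)))
}

# exhaustive k-mer occurrence count on both strands
revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
naive_kmer_count <- function(kmer, seqs) {
  tot <- 0L
  for (s in seqs)
    tot <- tot + length(naive_motif_starts(s, kmer)) +
      length(naive_motif_starts(s, revcomp_chr(kmer)))
  tot
}

# independent naive permutation-FDR caller, same RNG stream contract as the
# package (set.seed then one sample.int per iteration)
naive_window_sums <- function(x, w) {
  vapply(seq_len(length(x) - w + 1L), function(i) sum(x[i:(i + w - 1L)]),
         numeric(1))
}
naive_caller <- function(x, w, iterations, fdr, fdr_prob, seed) {
  W <- naive_window_sums(x, w)
  nW <- length(W)
  np <- (1 - fdr_prob) * nW
  k <- if (abs(np - round(np)) < 1e-9) max(1L, as.integer(round(np)))
       else floor(np) + 1L
  floor_q <- sort(W)[max(1L, k)]
  cand <- sort(unique(W[W >= floor_q]))
  n_obs_ge <- vapply(cand, function(t) sum(W >= t), numeric(1))
  perm_tot <- numeric(length(cand))
  set.seed(seed)
  for (it in seq_len(iterations)) {
    Wp <- naive_window_sums(x[sample.int(length(x))], w)
    perm_tot <- perm_tot + vapply(cand, function(t) sum(Wp >= t), numeric(1))
  }
  fdr_hat <- (perm_tot / iterations) / n_obs_ge
  ok <- fdr_hat < fdr
  thr <- if (any(ok)) cand[which(ok)[1L]] else Inf
  sig <- which(W >= thr)
  intervals <- list()
  if (length(sig)) {
    run_start <- sig[1L]; run_end <- sig[1L]
    flush <- function(a, b) {
      members <- a:(b + w - 1L)
      list(first = a, last = b + w - 1L, peak = max(W[a:b]))
    }
    for (s in sig[-1L]) {
      if (s - run_end > w) {
        intervals[[length(intervals) + 1L]] <- flush(run_start, run_end)
        run_start <- s
      }
      run_end <- s
    }
    intervals[[length(intervals) + 1L]] <- flush(run_start, run_end)
  }
  cats <- vapply(intervals, function(iv) {
    members <- iv$first:iv$last
    m <- members[which.max(x[members])]
    test_mod <- function(val) {
      y <- x; y[m] <- val
      any(naive_window_sums(y[members], w) >= thr)
    }
    if (test_mod(0)) return(1L)
    fl <- c(if (m > 1L) x[m - 1L], if (m < length(x)) x[m + 1L])
    if (test_mod(mean(fl))) return(2L)
    3L
  }, integer(1))
  list(threshold = thr, candidates = cand,
       mean_perm_ge = perm_tot / iterations, fdr_hat = fdr_hat,
       intervals = intervals, categories = cats)
}

# per-base distinct-TF multiplicity (sweep by explicit base loop, small coords)
naive_tf_cores <- function(peaks, min_tfs, lo = 0L, hi = 5000L) {
  mult <- integer(hi - lo)
  for (tf in names(peaks)) {
    covered <- logical(hi - lo)
    p <- peaks[[tf]]
    for (i in seq_len(nrow(p))) {
      a <- max(p$start[i], lo); b <- min(p$end[i], hi)
      if (b > a) covered[(a - lo + 1L):(b - lo)] <- TRUE
    }
    mult <- mult + covered
  }
  in_core <- mult >= min_tfs
  r <- rle(in_core)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = lo + starts[r$values] - 1L, end = lo + ends[r$values])
}

# gap in bp between two half-open intervals (0 when touching or overlapping)
naive_gap <- function(s1, e1, s2, e2) max(0L, s2 - e1, s1 - e2)

# a small deterministic read-pair fixture builder
make_pairs <- function(seq1, seq2, qual1 = NULL, qual2 = NULL) {
  if (is.null(qual1)) qual1 <- strrep("I", nchar(seq1))
  if (is.null(qual2)) qual2 <- strrep("I", nchar(seq2))
  fourcmap::read_pairs(sprintf("r%03d", seq_along(seq1)),
                       seq1, qual1, seq2, qual2)
}

# shared small scenario (cached per test run) for tests that only need a
# modest library
small_scenario_result <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      scn <- fourcmap::standard_scenario(seed = 7L, n_reads = 2e4)
      cache <<- fourcmap::analyse_scenario(scn)
    }
    cache
  }
})
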