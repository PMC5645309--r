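#' Replicate-reproducible significant interactions
#'
#' Overlaps the significant intervals of two replicates (same bait, same
#' region). Category-3 (single-fragment-driven) intervals are discarded
#' before overlapping; a rep1 and a rep2 interval reproducible by >= 1 bp
#' overlap are reported as their intersection span. Colour is
#' \code{"red"} iff both parents are category 1 (the most robust class),
#' \code{"orange"} otherwise.
#'
#' @param calls1,calls2 Interval data.frames (chrom, start, end, category)
#'   from the two replicates.
#' @return data.frame: chrom, start, end, colour, cat1, cat2, parent spans.
#' @export
intersect_replicates <- function(calls1, calls2) {
  a <- calls1[calls1$category != 3L, , drop = FALSE]
  b <- calls2[calls2$category != 3L, , drop = FALSE]
  out <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                    colour = character(0), cat1 = integer(0), cat2 = integer(0),
                    start1 = integer(0), end1 = integer(0),
                    start2 = integer(0), end2 = integer(0))
  if (nrow(a) == 0L || nrow(b) == 0L) return(out)
  ga <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start + 1L, a$end))
  gb <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start + 1L, b$end))
  hits <- GenomicRanges::findOverlaps(ga, gb)
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  if (length(i) == 0L) return(out)
  data.frame(chrom = a$chrom[i],
             start = pmax(a$start[i], b$start[j]),
             end = pmin(a$end[i], b$end[j]),
             colour = ifelse(a$category[i] == 1L & b$category[j] == 1L,
                             "red", "orange"),
             cat1 = a$category[i], cat2 = b$category[j],
             start1 = a$start[i], end1 = a$end[i],
             start2 = b$start[j], end2 = b$end[j])
}

#' Count intervals inside and outside a domain
#'
#' An interval is inside iff its midpoint lies within the domain
#' (half-open), so a boundary-straddling interval is counted exactly once.
#'
#' @param intervals data.frame with chrom, start, end.
#' @param domain list or data.frame row with chrom, start, end.
#' @return Named integer vector \code{c(inside=, outside=)}; sums to
#'   \code{nrow(intervals)}.
#' @export
count_domain <- function(intervals, domain) {
  if (nrow(intervals) == 0L) return(c(inside = 0L, outside = 0L))
  mid <- (intervals$start + intervals$end) %/% 2
  inside <- intervals$chrom == domain$chrom &
    mid >= domain$start & mid < domain$end
  c(inside = sum(inside), outside = sum(!inside))
}

#' Overlap intervals with gene bodies and promoters
#'
#' A hit is an interval overlapping the union of a gene body and its
#' promoter window, the \code{promoter_ext} bp immediately 5' of the TSS on
#' the gene's strand (higher coordinates for minus-strand genes). All hits
#' are reported; an interval may hit several genes.
#'
#' @param intervals data.frame with chrom, start, end.
#' @param genes data.frame with name, chrom, strand (\code{"+"}/\code{"-"}),
#'   txStart, txEnd (0-based half-open).
#' @param promoter_ext Promoter extension in bp (default 2000).
#' @return data.frame: interval row, gene name, interval and gene spans.
#' @export
gene_overlap <- function(intervals, genes, promoter_ext = 2000) {
  ext_start <- ifelse(genes$strand == "+", genes$txStart - promoter_ext,
                      genes$txStart)
  ext_end <- ifelse(genes$strand == "+", genes$txEnd,
                    genes$txEnd + promoter_ext)
  hits <- do.call(rbind, lapply(seq_len(nrow(genes)), function(g) {
    ov <- intervals$chrom == genes$chrom[g] &
      intervals$start < ext_end[g] & intervals$end > ext_start[g]
    if (!any(ov)) return(NULL)
    data.frame(interval = which(ov), gene = genes$name[g],
               chrom = genes$chrom[g],
               int_start = intervals$start[ov], int_end = intervals$end[ov],
               gene_start = genes$txStart[g], gene_end = genes$txEnd[g])
  }))
  if (is.null(hits))
    hits <- data.frame(interval = integer(0), gene = character(0),
                       chrom = character(0), int_start = integer(0),
                       int_end = integer(0), gene_start = integer(0),
                       gene_end = integer(0))
  hits
}

#' Find transcription-factor co-binding clusters
#'
#' Computes coverage by distinct-TF multiplicity (each TF's peaks are first
#' reduced, so one TF contributes at most 1 anywhere) and takes maximal runs
#' with multiplicity \code{>= min_tfs} as cluster cores. Each core is
#' extended to the union span of the peaks contributing to it; the member
#' list is the distinct TFs with a peak overlapping the core.
#'
#' @param peaks Named list (one element per TF; duplicate names are an
#'   error) of peak data.frames with chrom, start, end (0-based half-open).
#' @param min_tfs Minimum number of distinct co-bound TFs (default 6).
#' @param merge_slop Optional bp slop: peaks are widened by
#'   \code{merge_slop/2} on each side before computing multiplicity
#'   (default 0 — "same location" means literal base-pair co-coverage).
#' @return data.frame of clusters: chrom, start, end (extended span),
#'   core_start, core_end, n_tfs, members (comma-separated TF names).
#' @export
find_tf_clusters <- function(peaks, min_tfs = 6, merge_slop = 0) {
  if (is.null(names(peaks)) || anyDuplicated(names(peaks)))
    stop("peak tracks must be uniquely named by TF")
  grl <- lapply(names(peaks), function(tf) {
    p <- peaks[[tf]]
    gr <- GenomicRanges::GRanges(p$chrom,
                                 IRanges::IRanges(p$start + 1L, p$end))
    if (merge_slop > 0)
      gr <- GenomicRanges::resize(gr,
                                  GenomicRanges::width(gr) + merge_slop,
                                  fix = "center")
    gr <- GenomicRanges::reduce(gr)
    S4Vectors::mcols(gr)$tf <- rep(tf, length(gr))
    gr
  })
  all_peaks <- suppressWarnings(do.call(c, grl))
  if (length(all_peaks) == 0L)
    return(empty_clusters())
  cov <- GenomicRanges::coverage(all_peaks)
  cores <- GenomicRanges::GRanges(IRanges::slice(cov, lower = min_tfs,
                                                 rangesOnly = TRUE))
  if (length(cores) == 0L) return(empty_clusters())
  hits <- GenomicRanges::findOverlaps(cores, all_peaks)
  do.call(rbind, lapply(seq_along(cores), function(k) {
    contrib <- all_peaks[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == k]]
    members <- sort(unique(S4Vectors::mcols(contrib)$tf))
    data.frame(chrom = as.character(GenomicRanges::seqnames(cores)[k]),
               start = min(GenomicRanges::start(contrib)) - 1L,
               end = max(GenomicRanges::end(contrib)),
               core_start = GenomicRanges::start(cores)[k] - 1L,
               core_end = GenomicRanges::end(cores)[k],
               n_tfs = length(members),
               members = paste(members, collapse = ","))
  }))
}

empty_clusters <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             core_start = integer(0), core_end = integer(0),
             n_tfs = integer(0), members = character(0))
}

# gap in bp between two half-open spans on the same chrom; 0 when they touch
# or overlap
span_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s2 - e1, s1 - e2))
}

#' Call enhancer candidates from TF clusters near significant interactions
#'
#' A cluster becomes a candidate iff a replicate-reproducible significant
#' interaction lies directly at it or within \code{max_dist} bp of its span
#' (gap between spans; overlap means distance 0). Every supporting
#' (bait, interval) pair is recorded so per-bait connectivity is queryable.
#'
#' @param clusters data.frame from [find_tf_clusters()].
#' @param intervals_by_bait Named list (by bait) of reproducible-interval
#'   data.frames (chrom, start, end).
#' @param max_dist Maximum gap in bp (default 2000).
#' @return List: \code{$candidates} (one row per emitted cluster, with
#'   distance and supporting baits) and \code{$supports} (one row per
#'   supporting bait-interval pair).
#' @export
call_enhancer_candidates <- function(clusters, intervals_by_bait,
                                     max_dist = 2000) {
  supports <- do.call(rbind, lapply(names(intervals_by_bait), function(bn) {
    iv <- intervals_by_bait[[bn]]
    do.call(rbind, lapply(seq_len(nrow(clusters)), function(k) {
      same <- iv$chrom == clusters$chrom[k]
      if (!any(same)) return(NULL)
      gap <- span_gap(clusters$start[k], clusters$end[k],
                      iv$start[same], iv$end[same])
      hit <- gap <= max_dist
      if (!any(hit)) return(NULL)
      data.frame(cluster = k, bait = bn,
                 int_start = iv$start[same][hit], int_end = iv$end[same][hit],
                 distance = gap[hit])
    }))
  }))
  if (is.null(supports))
    supports <- data.frame(cluster = integer(0), bait = character(0),
                           int_start = integer(0), int_end = integer(0),
                           distance = integer(0))
  emitted <- sort(unique(supports$cluster))
  candidates <- clusters[emitted, , drop = FALSE]
  candidates$distance <- vapply(emitted, function(k)
    min(supports$distance[supports$cluster == k]), numeric(1))
  candidates$baits <- vapply(emitted, function(k)
    paste(sort(unique(supports$bait[supports$cluster == k])), collapse = ","),
    character(1))
  rownames(candidates) <- NULL
  list(candidates = candidates, supports = supports)
}

#' Name a candidate by its distance from a TSS
#'
#' Signed distance from the reference TSS to the cluster midpoint, in the
#' gene's transcription direction (positive = downstream), rounded to the
#' nearest kb: e.g. \code{"-371"}, \code{"+24"}.
#'
#' @param mid Cluster midpoint (bp); for a candidate row use
#'   \code{(start + end) \%/\% 2}.
#' @param tss TSS position (bp).
#' @param strand Gene strand, \code{"+"} or \code{"-"}.
#' @return Character label, sign always shown.
#' @export
name_by_tss_distance <- function(mid, tss, strand = "+") {
  d <- if (strand == "+") mid - tss else tss - mid
  sprintf("%+d", round(d / 1000))
}

#' Cohesin-without-CTCF status of a candidate
#'
#' TRUE iff at least one Rad21 (cohesin) peak overlaps the cluster span and
#' no CTCF peak does — the signature of CTCF-independent cohesin occupancy
#' at enhancer loops.
#'
#' @param candidate data.frame row(s) with chrom, start, end.
#' @param rad21,ctcf Peak data.frames (chrom, start, end).
#' @return Logical vector.
#' @export
cohesin_ctcf_status <- function(candidate, rad21, ctcf) {
  ov <- function(peaks, k) {
    any(peaks$chrom == candidate$chrom[k] &
          peaks$start < candidate$end[k] & peaks$end > candidate$start[k])
  }
  vapply(seq_len(nrow(candidate)), function(k)
    ov(rad21, k) && !ov(ctcf, k), logical(1))
}

#' Overlap with a conserved non-coding element track
#' @param candidate data.frame row(s) with chrom, start, end.
#' @param cne CNE data.frame (chrom, start, end).
#' @return Logical vector.
#' @export
cne_overlap <- function(candidate, cne) {
  vapply(seq_len(nrow(candidate)), function(k)
    any(cne$chrom == candidate$chrom[k] &
          cne$start < candidate$end[k] & cne$end > candidate$start[k]),
    logical(1))
}
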