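#' Exact-match unique alignment of trimmed reads
#'
#' A deliberately simple aligner for toy genomes: a read aligns iff it (or
#' its reverse complement) occurs exactly once in the genome across both
#' strands; reads with zero or multiple occurrences are unaligned. The
#' reported position is the read's 5'-most aligned base (leftmost genomic
#' base on the plus strand, rightmost on the minus strand). Real-data runs
#' use an external aligner and enter the pipeline via pre-aligned loci.
#'
#' @param seqs Character vector of read sequences (length >= 30 each).
#' @param genome Named \code{DNAStringSet} (or character) genome.
#' @return data.frame with one row per read: \code{chrom}, \code{pos}
#'   (0-based 5' base), \code{strand}; \code{NA} rows for unaligned reads.
#' @export
align_exact <- function(seqs, genome) {
  genome <- as_dna_set(genome)
  u <- unique(seqs)
  w <- nchar(u)
  anchor <- min(w)
  hits <- data.frame(chrom = rep(NA_character_, length(u)),
                     pos = rep(NA_integer_, length(u)),
                     strand = rep(NA_character_, length(u)),
                     stringsAsFactors = FALSE)
  n_hit <- integer(length(u))
  # anchor on a fixed-width prefix (one PDict per strand), then verify the
  # full-length read at each candidate site
  for (strand in c("+", "-")) {
    q <- if (strand == "+") u
         else as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(u)))
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(substr(q, 1L, anchor)))
    for (ci in seq_along(genome)) {
      chromseq <- genome[[ci]]
      clen <- length(chromseq)
      m <- Biostrings::matchPDict(pd, chromseq)
      starts <- Biostrings::startIndex(m)
      for (k in which(lengths(starts) > 0L)) {
        for (s1 in starts[[k]]) {
          e1 <- s1 + w[k] - 1L
          if (e1 > clen) next
          if (w[k] > anchor &&
              as.character(Biostrings::subseq(chromseq, s1, e1)) != q[k]) next
          n_hit[k] <- n_hit[k] + 1L
          if (n_hit[k] == 1L) {
            hits$chrom[k] <- names(genome)[ci]
            hits$pos[k] <- if (strand == "+") s1 - 1L else e1 - 1L
            hits$strand[k] <- strand
          }
        }
      }
    }
  }
  hits[n_hit != 1L, ] <- list(NA_character_, NA_integer_, NA_character_)
  out <- hits[match(seqs, u), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-fragment read counts for one bait library
#'
#' Assigns each aligned locus to the primary-enzyme fragment containing its
#' 5'-most aligned base (half-open containment) and tallies counts over the
#' whole fragment map. Unaligned loci (NA rows) are tallied but not counted.
#'
#' @param loci data.frame from [align_exact()] (columns chrom, pos, strand).
#' @param map A \code{"fragment_map"}.
#' @param bait Bait name label.
#' @param library Library label (\code{"rep1"}, \code{"rep2"}, \code{"control"}).
#' @return A \code{"fragment_counts"} object: per-fragment counts aligned
#'   row-for-row with \code{map$fragments}, plus totals.
#' @export
count_per_fragment <- function(loci, map, bait = "bait", library = "rep1") {
  fr <- map$fragments
  counts <- numeric(nrow(fr))
  ok <- !is.na(loci$chrom)
  if (any(ok)) {
    for (ch in unique(loci$chrom[ok])) {
      sel <- ok & loci$chrom == ch
      rows <- which(fr$chrom == ch)
      if (length(rows) == 0L) stop("locus on chrom absent from map: ", ch)
      i <- findInterval(loci$pos[sel], fr$start[rows])
      tab <- tabulate(i, nbins = length(rows))
      counts[rows] <- counts[rows] + tab
    }
  }
  new_fragment_counts(bait, library, counts, map,
                      total_assigned = sum(ok), n_unaligned = sum(!ok))
}

new_fragment_counts <- function(bait, library, counts, map,
                                total_assigned = sum(counts),
                                n_unaligned = 0L, total_retained = NULL,
                                filter_report = NULL) {
  structure(list(bait = bait, library = library, counts = counts, map = map,
                 total_assigned = total_assigned, n_unaligned = n_unaligned,
                 total_retained = total_retained, filter_report = filter_report),
            class = "fragment_counts")
}

#' @export
print.fragment_counts <- function(x, ...) {
  cat(sprintf("<fragment_counts> bait=%s library=%s; %d fragments; %g reads on map%s\n",
              x$bait, x$library, length(x$counts), sum(x$counts),
              if (!is.null(x$filter_report)) " (filtered)" else ""))
  invisible(x)
}

#' Apply the three 4C artefact filters
#'
#' Zeroes, in order: (1) the bait fragment itself (self-ligated reads),
#' (2) the two fragments index-adjacent to the bait fragment (uncut reads),
#' (3) every fragment with at least 1 read in the non-ligated control
#' library. All other counts are unchanged. The removed totals per rule are
#' recorded in \code{$filter_report} and satisfy
#' removed + retained = raw total exactly.
#'
#' @param counts A \code{"fragment_counts"} for one bait library.
#' @param bait The [bait_spec()] whose fragment defines self-ligation/uncut.
#' @param control A \code{"fragment_counts"} for the control (non-ligated)
#'   library on the same fragment map, or \code{NULL} to skip rule 3.
#' @return The filtered \code{"fragment_counts"} with
#'   \code{$total_retained} and \code{$filter_report} set.
#' @export
apply_filters <- function(counts, bait, control = NULL) {
  fr <- counts$map$fragments
  if (!is.null(control) && !identical(control$map$fragments[c("chrom", "start", "end")],
                                      fr[c("chrom", "start", "end")]))
    stop("counts and control are on different fragment maps")
  x <- counts$counts
  raw_total <- sum(x)
  bait_row <- which(fr$chrom == bait$chrom & fr$start <= bait$start &
                      fr$end > bait$start)
  if (length(bait_row) != 1L) stop("bait fragment not found in map")
  removed_self <- x[bait_row]
  x[bait_row] <- 0
  adj <- which(fr$chrom == fr$chrom[bait_row] &
                 abs(fr$index - fr$index[bait_row]) == 1L)
  removed_uncut <- sum(x[adj])
  x[adj] <- 0
  if (!is.null(control)) {
    hit <- control$counts >= 1
    removed_control <- sum(x[hit])
    x[hit] <- 0
  } else {
    removed_control <- 0
  }
  report <- c(self_ligated = removed_self, uncut = removed_uncut,
              control_hit = removed_control, retained = sum(x),
              raw_total = raw_total)
  new_fragment_counts(counts$bait, counts$library, x, counts$map,
                      total_assigned = counts$total_assigned,
                      n_unaligned = counts$n_unaligned,
                      total_retained = sum(x), filter_report = report)
}

#' Write per-fragment counts as TSV
#'
#' Columns: chrom, start, end, frag_index, count.
#' @param counts A \code{"fragment_counts"}.
#' @param path Output file.
#' @export
write_counts_tsv <- function(counts, path) {
  fr <- counts$map$fragments
  utils::write.table(
    data.frame(chrom = fr$chrom, start = fr$start, end = fr$end,
               frag_index = fr$index, count = counts$counts),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
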