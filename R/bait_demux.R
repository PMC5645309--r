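#' Bait (viewpoint) specification
#'
#' A 4C bait is defined by its primer pair and its genomic fragment. The
#' forward primer reads from inside the bait fragment across the primary
#' digestion site into the captured fragment, so it must end with (and
#' include) the primary enzyme motif; demultiplexing matches it exactly.
#'
#' @param name Bait name, unique within a run (e.g. \code{"P1"}, \code{"+24"}).
#' @param fwd_primer Forward primer sequence, ending with the primary motif.
#' @param rev_primer Reverse primer sequence.
#' @param chrom,start,end Genomic span (0-based half-open) of the bait fragment.
#' @param primary_motif Motif of the primary enzyme (default \code{"GATC"}).
#' @param secondary_enzyme Optional [enzyme()] used for circularisation
#'   (metadata only; quantification is on primary fragments).
#' @return An object of class \code{"bait_spec"}.
#' @export
bait_spec <- function(name, fwd_primer, rev_primer, chrom, start, end,
                      primary_motif = "GATC", secondary_enzyme = NULL) {
  fwd_primer <- toupper(fwd_primer); rev_primer <- toupper(rev_primer)
  if (!endsWith(fwd_primer, primary_motif))
    stop("fwd_primer of bait '", name, "' must end with the primary motif ",
         primary_motif)
  stopifnot(start >= 0, end > start)
  structure(list(name = name, fwd_primer = fwd_primer, rev_primer = rev_primer,
                 chrom = chrom, start = as.integer(start), end = as.integer(end),
                 primary_motif = primary_motif,
                 secondary_enzyme = secondary_enzyme),
            class = "bait_spec")
}

#' @export
print.bait_spec <- function(x, ...) {
  cat(sprintf("<bait_spec> %s %s:%d-%d fwd=%s rev=%s\n", x$name, x$chrom,
              x$start, x$end, x$fwd_primer, x$rev_primer))
  invisible(x)
}

#' Paired-end read container
#'
#' A light in-memory container for read pairs: parallel character vectors of
#' ids, mate sequences and Phred+33 quality strings.
#'
#' @param id,seq1,qual1,seq2,qual2 Parallel character vectors.
#' @return An object of class \code{"read_pairs"}.
#' @export
read_pairs <- function(id, seq1, qual1, seq2, qual2) {
  n <- length(id)
  stopifnot(length(seq1) == n, length(qual1) == n,
            length(seq2) == n, length(qual2) == n,
            all(nchar(seq1) == nchar(qual1)), all(nchar(seq2) == nchar(qual2)))
  structure(list(id = id, seq1 = seq1, qual1 = qual1,
                 seq2 = seq2, qual2 = qual2), class = "read_pairs")
}

#' @export
length.read_pairs <- function(x) length(x$id)

#' @export
print.read_pairs <- function(x, ...) {
  cat(sprintf("<read_pairs> %d pairs\n", length(x)))
  invisible(x)
}

subset_pairs <- function(x, i) {
  read_pairs(x$id[i], x$seq1[i], x$qual1[i], x$seq2[i], x$qual2[i])
}

validate_bait_primers <- function(baits) {
  nm <- vapply(baits, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("bait names must be unique")
  fwd <- vapply(baits, `[[`, "", "fwd_primer")
  if (anyDuplicated(fwd)) stop("two baits share an identical fwd_primer")
  prim <- c(fwd, vapply(baits, `[[`, "", "rev_primer"))
  for (i in seq_along(prim)) for (j in seq_along(prim)) {
    if (i != j && prim[i] != prim[j] && startsWith(prim[j], prim[i]))
      stop("bait primers must be mutually non-prefix: '", prim[i],
           "' is a prefix of '", prim[j], "'")
  }
  invisible(baits)
}

#' Demultiplex read pairs by bait primers
#'
#' A pair is assigned to a bait iff one mate begins exactly (0 mismatches)
#' with the bait's forward primer and the other mate begins exactly with its
#' reverse primer. Mate roles are normalised on output so that mate1 always
#' carries the forward primer (and hence the captured-fragment sequence after
#' the digestion site). Pairs matching no bait in either orientation are
#' returned unassigned; every input pair lands in exactly one output stream.
#'
#' @param pairs A [read_pairs()] object.
#' @param baits List of [bait_spec()] objects; primers are validated to be
#'   mutually non-prefix.
#' @return List with \code{$assigned} (named list of \code{read_pairs} per
#'   bait), \code{$unassigned} (\code{read_pairs}) and \code{$tally}
#'   (named integer vector summing to \code{length(pairs)}).
#' @export
demultiplex <- function(pairs, baits) {
  validate_bait_primers(baits)
  n <- length(pairs)
  taken <- logical(n)
  assigned <- list()
  tally <- integer(0)
  for (b in baits) {
    fwd1 <- startsWith(pairs$seq1, b$fwd_primer) & startsWith(pairs$seq2, b$rev_primer)
    fwd2 <- startsWith(pairs$seq2, b$fwd_primer) & startsWith(pairs$seq1, b$rev_primer)
    hit1 <- fwd1 & !taken
    hit2 <- fwd2 & !taken & !hit1
    taken <- taken | hit1 | hit2
    keep <- read_pairs(
      c(pairs$id[hit1], pairs$id[hit2]),
      c(pairs$seq1[hit1], pairs$seq2[hit2]),
      c(pairs$qual1[hit1], pairs$qual2[hit2]),
      c(pairs$seq2[hit1], pairs$seq1[hit2]),
      c(pairs$qual2[hit1], pairs$qual1[hit2]))
    assigned[[b$name]] <- keep
    tally[b$name] <- length(keep)
  }
  unassigned <- subset_pairs(pairs, !taken)
  tally["unassigned"] <- length(unassigned)
  list(assigned = assigned, unassigned = unassigned, tally = tally)
}

#' Trim assigned read pairs and filter by length
#'
#' For pairs already assigned to a bait (mate1 normalised to carry the
#' forward primer): removes the primer prefix up to but excluding the primary
#' digestion-site motif, so the retained read starts with the motif at the
#' ligation junction; trims the longest 3' suffix whose bases all have Phred
#' quality below \code{qual_min}; rejects reads shorter than \code{len_min}
#' after trimming. Only the trimmed captured mate proceeds to alignment; the
#' reverse mate served demultiplexing only.
#'
#' @param pairs [read_pairs()] assigned to \code{bait}.
#' @param bait The [bait_spec()].
#' @param qual_min Minimum Phred quality retained at the 3' end (default 20).
#' @param len_min Minimum retained read length in bp (default 30).
#' @return List with \code{$reads} (data.frame \code{id}, \code{seq},
#'   \code{qual}) and \code{$n_rejected}.
#' @export
trim_and_filter <- function(pairs, bait, qual_min = 20, len_min = 30) {
  drop <- nchar(bait$fwd_primer) - nchar(bait$primary_motif)
  seq <- substring(pairs$seq1, drop + 1L)
  qual <- substring(pairs$qual1, drop + 1L)
  keep_len <- quality_keep_length(qual, qual_min)
  seq <- substr(seq, 1L, keep_len)
  qual <- substr(qual, 1L, keep_len)
  ok <- keep_len >= len_min
  list(reads = data.frame(id = pairs$id[ok], seq = seq[ok], qual = qual[ok],
                          stringsAsFactors = FALSE),
       n_rejected = sum(!ok))
}

# length of each read after removing the longest all-below-threshold 3' suffix
quality_keep_length <- function(qual, qual_min) {
  thr <- as.raw(qual_min + 33L)
  vapply(qual, function(q) {
    r <- charToRaw(q)
    ok <- which(r >= thr)
    if (length(ok) == 0L) 0L else ok[length(ok)]
  }, integer(1), USE.NAMES = FALSE)
}

#' Read / write paired FASTQ
#'
#' @param path1,path2 FASTQ files for mate 1 and mate 2.
#' @return A [read_pairs()] object.
#' @export
read_pairs_fastq <- function(path1, path2) {
  # suppressed: Biostrings drops the (empty) mcols with a warning
  r1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path1))
  r2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path2))
  id1 <- sub("/1$", "", sub(" .*", "", names(r1)))
  id2 <- sub("/2$", "", sub(" .*", "", names(r2)))
  if (!identical(id1, id2)) stop("mate files are not in matching order")
  read_pairs(id1,
             unname(as.character(r1)),
             unname(as.character(Biostrings::quality(r1))),
             unname(as.character(r2)),
             unname(as.character(Biostrings::quality(r2))))
}

#' @param pairs A [read_pairs()] object.
#' @rdname read_pairs_fastq
#' @export
write_pairs_fastq <- function(pairs, path1, path2) {
  write_fastq_one(pairs$seq1, pairs$qual1, paste0(pairs$id, "/1"), path1)
  write_fastq_one(pairs$seq2, pairs$qual2, paste0(pairs$id, "/2"), path2)
  invisible(c(path1, path2))
}

write_fastq_one <- function(seq, qual, id, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seq),
    Biostrings::PhredQuality(Biostrings::BStringSet(qual)))
  names(x) <- id
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}
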