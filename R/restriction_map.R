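#' Restriction enzyme definition
#'
#' A restriction enzyme is described by its name and its unambiguous DNA
#' recognition motif. The primary enzyme of a 4C-seq experiment (typically a
#' 4-cutter such as DpnII, motif \code{GATC}) defines the fragment map on
#' which all quantification happens; the secondary enzyme (e.g. BfaI or MseI)
#' only shapes the amplicon structure and is carried as metadata.
#'
#' @param name Short enzyme name, e.g. \code{"DpnII"}.
#' @param motif Recognition motif over \code{A,C,G,T}, length >= 4.
#' @return An object of class \code{"enzyme"}.
#' @examples
#' enzyme("DpnII", "GATC")
#' @export
enzyme <- function(name, motif) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  motif <- toupper(motif)
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) < 4L ||
      grepl("[^ACGT]", motif)) {
    stop("enzyme motif must be a DNA string over {A,C,G,T} of length >= 4")
  }
  structure(list(name = name, motif = motif), class = "enzyme")
}

#' @export
print.enzyme <- function(x, ...) {
  cat(sprintf("<enzyme> %s (%s)\n", x$name, x$motif))
  invisible(x)
}

#' DpnII, the canonical 4C-seq primary 4-cutter
#' @rdname enzyme
#' @export
dpnii <- function() enzyme("DpnII", "GATC")

new_fragment_map <- function(enzyme, frags) {
  structure(list(enzyme = enzyme, fragments = frags), class = "fragment_map")
}

#' In-silico restriction digestion of a genome
#'
#' Cuts every chromosome at each occurrence of the enzyme motif (cut position
#' = motif start, so each internal fragment begins with the motif) and returns
#' the resulting ordered, non-overlapping fragment map tiling each chromosome
#' exactly. A chromosome without any motif occurrence yields a single fragment.
#' All fragments start out flagged mappable; see [flag_mappability()].
#'
#' @param genome A named \code{\link[Biostrings]{DNAStringSet}} (or named
#'   character vector of uppercase DNA sequences).
#' @param enzyme An [enzyme()]; defaults to DpnII.
#' @return A \code{"fragment_map"}: list with \code{$enzyme} and
#'   \code{$fragments}, a data.frame with columns \code{chrom}, \code{start}
#'   (0-based inclusive), \code{end} (exclusive), \code{index} (0-based
#'   ordinal per chromosome) and \code{mappable}.
#' @examples
#' gen <- Biostrings::DNAStringSet(c(chrTest = "AAGATCAA"))
#' digest_genome(gen)$fragments
#' @export
digest_genome <- function(genome, enzyme = dpnii()) {
  genome <- as_dna_set(genome)
  if (is.null(names(genome)) || anyDuplicated(names(genome)) || any(!nzchar(names(genome))))
    stop("genome sequences must have unique non-empty names")
  frags <- lapply(seq_along(genome), function(i) {
    len <- Biostrings::width(genome)[i]
    if (len == 0L) stop("empty contig: ", names(genome)[i])
    hits <- Biostrings::start(Biostrings::matchPattern(enzyme$motif, genome[[i]]))
    cuts <- sort(unique(hits)) - 1L          # 0-based cut positions
    cuts <- cuts[cuts > 0L]                  # a cut at 0 adds no boundary
    starts <- c(0L, cuts)
    data.frame(chrom = names(genome)[i],
               start = starts,
               end = c(cuts, len),
               index = seq_along(starts) - 1L,
               mappable = TRUE,
               stringsAsFactors = FALSE)
  })
  new_fragment_map(enzyme, do.call(rbind, frags))
}

#' @export
print.fragment_map <- function(x, ...) {
  cat(sprintf("<fragment_map> %s; %d fragments on %d sequence(s); %d mappable\n",
              x$enzyme$name, nrow(x$fragments),
              length(unique(x$fragments$chrom)), sum(x$fragments$mappable)))
  invisible(x)
}

#' Flag fragment mappability by fragment-end k-mer uniqueness
#'
#' 4C reads anchor at a cut site and extend into the captured fragment, so a
#' fragment is only quantifiable if the \code{read_len}-bp sequence at its
#' cut-site end maps uniquely. Mappability is modelled intrinsically: a
#' fragment is mappable iff its leading \code{read_len}-mer (the end adjacent
#' to the upstream cut site) occurs exactly once in the genome across both
#' strands. Fragments shorter than \code{read_len} are unmappable.
#'
#' @param map A \code{"fragment_map"}.
#' @param genome The genome the map was digested from.
#' @param read_len Read anchor length in bp (>= 1).
#' @return The map with the \code{mappable} column recomputed.
#' @export
flag_mappability <- function(map, genome, read_len) {
  stopifnot(inherits(map, "fragment_map"), read_len >= 1L)
  genome <- as_dna_set(genome)
  fr <- map$fragments
  long <- (fr$end - fr$start) >= read_len
  mappable <- logical(nrow(fr))
  if (any(long)) {
    idx <- which(long)
    kmers <- Biostrings::DNAStringSet(vapply(idx, function(i) {
      as.character(Biostrings::subseq(genome[[fr$chrom[i]]],
                                      start = fr$start[i] + 1L,
                                      width = read_len))
    }, character(1)))
    n_fwd <- genome_occurrences(kmers, genome)
    n_rev <- genome_occurrences(Biostrings::reverseComplement(kmers), genome)
    mappable[idx] <- (n_fwd + n_rev) == 1L
  }
  map$fragments$mappable <- mappable
  map
}

# total occurrence count of each query on the forward strand of the genome;
# queries of equal width are batched through a PDict
genome_occurrences <- function(queries, genome) {
  n <- integer(length(queries))
  w <- Biostrings::width(queries)
  for (wd in unique(w)) {
    sel <- which(w == wd)
    pd <- Biostrings::PDict(queries[sel])
    tot <- integer(length(sel))
    for (i in seq_along(genome))
      tot <- tot + Biostrings::countPDict(pd, genome[[i]])
    n[sel] <- tot
  }
  n
}

#' Locate the fragment containing a genomic position
#'
#' @param map A \code{"fragment_map"}.
#' @param chrom Chromosome name.
#' @param pos 0-based position(s); \code{0 <= pos < chrom length}.
#' @return The matching row(s) of \code{map$fragments} (half-open containment:
#'   \code{start <= pos < end}).
#' @export
locate_fragment <- function(map, chrom, pos) {
  fr <- map$fragments[map$fragments$chrom == chrom, , drop = FALSE]
  if (nrow(fr) == 0L) stop("unknown chrom: ", chrom)
  if (any(pos < 0L) || any(pos >= fr$end[nrow(fr)]))
    stop("position out of range for ", chrom)
  fr[findInterval(pos, fr$start), , drop = FALSE]
}

#' Write a fragment map as BED
#'
#' Columns: chrom, start, end, name = per-chrom fragment index, score =
#' 0/1 mappability flag, strand ".".
#'
#' @param map A \code{"fragment_map"}.
#' @param path Output file.
#' @export
write_fragment_bed <- function(map, path) {
  fr <- map$fragments
  bed <- data.frame(fr$chrom, fr$start, fr$end,
                    paste0("frag_", fr$index), as.integer(fr$mappable), ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

as_dna_set <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  Biostrings::DNAStringSet(genome)
}

fragments_gr <- function(map) {
  fr <- map$fragments
  GenomicRanges::GRanges(fr$chrom,
                         IRanges::IRanges(fr$start + 1L, fr$end),
                         index = fr$index, mappable = fr$mappable)
}
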