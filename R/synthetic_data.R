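#' Cis contact model for the 4C library simulator
#'
#' Captured-fragment weights follow the standard empirical shape of cis 4C
#' profiles: a truncated power-law distance decay on fragment midpoints,
#' attenuated across the domain boundary, with a flat background and
#' planted high-contact fragments:
#' \deqn{w_j = \epsilon + \gamma_j \beta^{cross(j)} (1 + |mid_j - mid_{bait}|/s)^{-\alpha}}
#' where \eqn{\gamma_j} is the planted weight (1 for unplanted fragments)
#' and \eqn{cross(j) = 1} iff fragment j lies outside the domain containing
#' the bait. Fragments on other chromosomes receive a small uniform trans
#' weight.
#'
#' @param domain list(chrom, start, end): the domain containing the bait.
#' @param decay_scale Decay scale s in bp.
#' @param decay_exponent Positive decay exponent alpha.
#' @param background Flat per-fragment background weight epsilon.
#' @param boundary_attenuation Multiplier beta in (0, 1] applied beyond the
#'   domain boundary.
#' @param planted data.frame(row, gamma): planted fragment rows (row numbers
#'   into \code{map$fragments}) and their weights gamma > 1.
#' @param trans_background Per-fragment weight on non-bait chromosomes.
#' @param frag_noise_sd Lognormal sdlog of per-fragment efficiency noise
#'   multiplying the weight of every unplanted cis fragment (drawn
#'   independently per library). 4C per-fragment counts are strongly
#'   overdispersed relative to Poisson (fragment length, GC and ligation
#'   efficiency vary); without this the smooth decay envelope would be an
#'   unrealistically clean signal. Planted weights are left exact: they are
#'   the controlled ground truth.
#' @return An object of class \code{"contact_model"}.
#' @export
contact_model <- function(domain, decay_scale = 100000, decay_exponent = 1,
                          background = 2e-3, boundary_attenuation = 0.2,
                          planted = data.frame(row = integer(0),
                                               gamma = numeric(0)),
                          trans_background = 1e-4, frag_noise_sd = 0.45) {
  stopifnot(decay_scale > 0, decay_exponent > 0, background >= 0,
            boundary_attenuation > 0, boundary_attenuation <= 1,
            all(planted$gamma > 1), frag_noise_sd >= 0)
  structure(list(domain = domain, decay_scale = decay_scale,
                 decay_exponent = decay_exponent, background = background,
                 boundary_attenuation = boundary_attenuation,
                 planted = planted, trans_background = trans_background,
                 frag_noise_sd = frag_noise_sd),
            class = "contact_model")
}

#' Library specification for the 4C simulator
#'
#' @param n_reads Number of read pairs.
#' @param p_self Fraction of self-ligated reads (bait fragment religated to
#'   itself).
#' @param p_uncut Fraction of uncut reads (read-through into a fragment
#'   adjacent to the bait).
#' @param read_len Read length in bp.
#' @param seed Integer seed; the library is byte-reproducible from it.
#' @param is_control Simulate the non-ligated control: captured fragments
#'   drawn uniformly from a sparse random subset instead of the contact
#'   model.
#' @param control_sparsity Fraction of fragments in the control subset.
#' @return An object of class \code{"library_spec"}.
#' @export
library_spec <- function(n_reads, p_self = 0.05, p_uncut = 0.05,
                         read_len = 100, seed = 1L, is_control = FALSE,
                         control_sparsity = 0.015) {
  stopifnot(n_reads > 0, p_self >= 0, p_uncut >= 0, p_self + p_uncut <= 1,
            read_len >= 50)
  structure(list(n_reads = as.integer(n_reads), p_self = p_self,
                 p_uncut = p_uncut, read_len = as.integer(read_len),
                 seed = as.integer(seed), is_control = is_control,
                 control_sparsity = control_sparsity),
            class = "library_spec")
}

toy_tf_names <- function() {
  c("Scl", "Lmo2", "Gata2", "Fli1", "Erg", "Ldb1", "Meis1", "Pu1")
}

#' Generate a toy genome with annotation tracks and planted ground truth
#'
#' Builds a deterministic (seeded) random genome whose primary-enzyme sites
#' occur at density \code{site_density}, digests it, flags mappability, and
#' embeds: a two-promoter gene on the first chromosome (P1 the active
#' promoter convention, P2 downstream), a domain interval containing both
#' promoters, five planted enhancer loci (each a run of seven consecutive
#' mappable fragments) carrying 6-TF co-binding clusters, a 5-TF decoy
#' cluster, a distant 6-TF decoy on the second chromosome, Rad21/CTCF peak
#' tracks (some planted enhancers carry Rad21 without CTCF), and a CNE
#' track. All planted locations are returned as ground truth.
#'
#' @param n_chrom Number of chromosomes (>= 1; the first carries the gene
#'   and domain, others provide trans background).
#' @param chrom_len Chromosome length(s) in bp, recycled to \code{n_chrom}.
#' @param site_density Primary-enzyme site density per bp (must give >= 200
#'   fragments on the first chromosome).
#' @param seed Integer seed.
#' @param enzyme Primary [enzyme()] (default DpnII).
#' @param read_len_map Anchor length for mappability flagging (default 50).
#' @return A \code{"toy_genome"}: list with \code{$genome}
#'   (DNAStringSet), \code{$map} (mappability-flagged fragment map),
#'   \code{$genes}, \code{$tss} (named positions), \code{$domain},
#'   \code{$tracks} (named list: \code{tf} = per-TF peak list,
#'   \code{rad21}, \code{ctcf}, \code{cne}), and \code{$truth} (planted
#'   enhancer rows/spans, decoy spans, domain).
#' @export
make_toy_genome <- function(n_chrom = 2, chrom_len = c(500000L, 120000L),
                            site_density = 1 / 250, seed = 1L,
                            enzyme = dpnii(), read_len_map = 50L) {
  if (site_density <= 0 || site_density > 1 / (2 * nchar(enzyme$motif)))
    stop("infeasible site_density")
  chrom_len <- as.integer(rep_len(chrom_len, n_chrom))
  if (chrom_len[1] * site_density < 200)
    stop("first chromosome too short for >= 200 fragments at this site_density")
  set.seed(seed)
  chroms <- paste0("chrS", LETTERS[seq_len(n_chrom)])
  seqs <- vapply(chrom_len, random_digestible_sequence, character(1),
                 site_density = site_density, motif = enzyme$motif)
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms
  map <- flag_mappability(digest_genome(genome, enzyme), genome, read_len_map)

  len1 <- chrom_len[1]
  tss <- c(P1 = as.integer(round(0.48 * len1)),
           P2 = as.integer(round(0.60 * len1)))
  gene_end <- as.integer(round(0.64 * len1))
  genes <- data.frame(
    name = c("tgtA-P1", "tgtA-P2", "bysA", if (n_chrom > 1) "bysB"),
    chrom = c(chroms[1], chroms[1], chroms[1],
              if (n_chrom > 1) chroms[2]),
    strand = "+",
    txStart = c(tss[["P1"]], tss[["P2"]], as.integer(round(0.85 * len1)),
                if (n_chrom > 1) as.integer(round(0.3 * chrom_len[2]))),
    txEnd = c(gene_end, gene_end, as.integer(round(0.87 * len1)),
              if (n_chrom > 1) as.integer(round(0.32 * chrom_len[2]))),
    stringsAsFactors = FALSE)
  domain <- list(chrom = chroms[1], start = as.integer(round(0.30 * len1)),
                 end = as.integer(round(0.70 * len1)))

  # planted enhancer loci: runs of seven consecutive mappable fragments
  # (long enough that blacklisting any single member still leaves a full
  # calling window of intact planted fragments)
  enh_frac <- c(0.34, 0.37, 0.40, 0.56, 0.62)
  fr <- map$fragments
  mp1 <- which(fr$chrom == chroms[1] & fr$mappable)
  planted <- lapply(enh_frac, function(f) {
    target <- f * len1
    ctr <- which.min(abs((fr$start[mp1] + fr$end[mp1]) / 2 - target))
    ctr <- min(max(ctr, 4L), length(mp1) - 3L)
    rows <- mp1[(ctr - 3L):(ctr + 3L)]
    list(rows = rows, span = c(min(fr$start[rows]), max(fr$end[rows])),
         mid = (min(fr$start[rows]) + max(fr$end[rows])) %/% 2)
  })
  enh_labels <- vapply(planted, function(p)
    name_by_tss_distance(p$mid, tss[["P1"]], "+"), character(1))
  names(planted) <- enh_labels

  tfs <- toy_tf_names()
  cluster_peaks <- function(chrom, mid, tf_set) {
    do.call(rbind, lapply(tf_set, function(tf) {
      jit <- sample.int(80L, 2L)
      data.frame(tf = tf, chrom = chrom,
                 start = as.integer(mid - 150L - jit[1]),
                 end = as.integer(mid + 150L + jit[2]))
    }))
  }
  planted_cl <- do.call(rbind, lapply(planted, function(p)
    cluster_peaks(chroms[1], p$mid, tfs[1:6])))
  decoy5_mid <- as.integer(round(0.80 * len1))       # outside the domain
  decoy5 <- cluster_peaks(chroms[1], decoy5_mid, tfs[1:5])
  decoy6 <- if (n_chrom > 1)
    cluster_peaks(chroms[2], as.integer(round(0.5 * chrom_len[2])), tfs[1:6])
  scatter <- do.call(rbind, lapply(tfs, function(tf) {
    ch <- sample(chroms, 25L, replace = TRUE)
    st <- vapply(ch, function(c2)
      sample.int(chrom_len[match(c2, chroms)] - 400L, 1L), integer(1))
    data.frame(tf = tf, chrom = ch, start = st, end = st + 250L)
  }))
  all_tf <- rbind(planted_cl, decoy5, decoy6, scatter)
  tf_tracks <- lapply(tfs, function(tf)
    all_tf[all_tf$tf == tf, c("chrom", "start", "end"), drop = FALSE])
  names(tf_tracks) <- tfs

  peak_at <- function(mid, chrom = chroms[1], half = 200L)
    data.frame(chrom = chrom, start = as.integer(mid - half),
               end = as.integer(mid + half))
  rad21 <- rbind(peak_at(planted[[1]]$mid), peak_at(planted[[2]]$mid),
                 peak_at(planted[[4]]$mid),
                 peak_at(domain$start), peak_at(domain$end),
                 peak_at(tss[["P1"]] + 2000L))
  ctcf <- rbind(peak_at(domain$start), peak_at(domain$end),
                peak_at(planted[[4]]$mid), peak_at(tss[["P1"]] + 2000L))
  cne <- rbind(peak_at(planted[[2]]$mid, half = 300L),
               peak_at(planted[[5]]$mid, half = 300L),
               peak_at(as.integer(round(0.25 * len1)), half = 300L))

  truth <- list(
    planted = planted,
    planted_rows = unlist(lapply(planted, `[[`, "rows"), use.names = FALSE),
    cluster_spans = do.call(rbind, lapply(seq_along(planted), function(i)
      data.frame(label = enh_labels[i], chrom = chroms[1],
                 start = planted[[i]]$mid - 230L,
                 end = planted[[i]]$mid + 230L))),
    decoy5 = c(start = decoy5_mid - 230L, end = decoy5_mid + 230L),
    decoy6_chrom = if (n_chrom > 1) chroms[2] else NA_character_,
    domain = domain)

  structure(list(genome = genome, map = map, genes = genes, tss = tss,
                 domain = domain,
                 tracks = list(tf = tf_tracks, rad21 = rad21, ctcf = ctcf,
                               cne = cne),
                 truth = truth, seed = seed,
                 params = list(n_chrom = n_chrom, chrom_len = chrom_len,
                               site_density = site_density,
                               read_len_map = read_len_map)),
            class = "toy_genome")
}

#' @export
print.toy_genome <- function(x, ...) {
  cat(sprintf("<toy_genome> %d chrom(s), %s bp; %d fragments; %d planted enhancer loci\n",
              length(x$genome), paste(Biostrings::width(x$genome), collapse = "+"),
              nrow(x$map$fragments), length(x$truth$planted)))
  invisible(x)
}

# random DNA of length len whose only motif occurrences are planted sites at
# ~site_density per bp (motif occurrences arising by chance are scrubbed by
# letter replacement until none remain)
random_digestible_sequence <- function(len, site_density, motif) {
  mlen <- nchar(motif)
  sites0 <- which(stats::runif(len - mlen) < site_density)  # 1-based starts
  if (length(sites0) > 1L)
    sites0 <- sites0[c(TRUE, diff(sites0) > mlen)]
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  mchars <- strsplit(motif, "")[[1]]
  for (s in sites0) chars[s:(s + mlen - 1L)] <- mchars
  repeat {
    seqstr <- paste(chars, collapse = "")
    occ <- Biostrings::start(Biostrings::matchPattern(
      motif, Biostrings::DNAString(seqstr)))
    extra <- setdiff(occ, sites0)
    if (length(extra) == 0L) return(seqstr)
    # flip one interior base of each chance occurrence
    chars[extra + 2L] <- ifelse(chars[extra + 2L] == "A", "C", "A")
  }
}

#' Derive a bait specification from a toy genome position
#'
#' Selects the fragment containing \code{pos} (it must be an internal,
#' sufficiently long fragment so that primers exist) and derives a 20-bp
#' forward primer ending with the primary digestion site at the fragment's
#' downstream boundary, plus a 20-bp reverse primer from the fragment start.
#'
#' @param toy A \code{"toy_genome"}.
#' @param name Bait name.
#' @param pos 0-based position on the first chromosome (e.g. a TSS).
#' @return A [bait_spec()].
#' @export
toy_bait <- function(toy, name, pos) {
  fr <- toy$map$fragments
  chrom <- names(toy$genome)[1]
  rows <- which(fr$chrom == chrom)
  cand <- rows[findInterval(pos, fr$start[rows])]
  # walk to the nearest internal fragment long enough for primer design
  while (fr$index[cand] < 1L || (fr$end[cand] - fr$start[cand]) < 40L)
    cand <- cand + 1L
  s <- fr$start[cand]; e <- fr$end[cand]
  chromseq <- toy$genome[[chrom]]
  primer16 <- as.character(Biostrings::subseq(chromseq, e - 15L, e))
  motif <- toy$map$enzyme$motif
  bait_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::subseq(chromseq, s + 1L, e)))
  bait_spec(name, fwd_primer = paste0(primer16, motif),
            rev_primer = substr(bait_rc, 1L, 20L),
            chrom = chrom, start = s, end = e, primary_motif = motif)
}

#' Simulate one 4C-seq library
#'
#' Draws each read pair as: with probability \code{p_self} a self-ligation
#' (captured fragment = the bait fragment), with \code{p_uncut} an uncut
#' read-through (captured fragment = a fragment index-adjacent to the
#' bait), otherwise a captured fragment drawn from the [contact_model()]
#' weights (or, for a control library, uniformly from a sparse random
#' fragment subset). The forward mate carries the bait forward primer
#' through the primary digestion site followed by the captured fragment
#' sequence; the reverse mate carries the reverse primer. Mates are emitted
#' in random order (the demultiplexer re-normalises them). Base qualities
#' are constant high.
#'
#' @param toy A \code{"toy_genome"} (or list with \code{$genome},
#'   \code{$map}).
#' @param bait A [bait_spec()] inside \code{model$domain}.
#' @param model A [contact_model()].
#' @param spec A [library_spec()].
#' @param label Library label carried into read ids.
#' @return List: \code{$pairs} ([read_pairs()]), \code{$truth} with the true
#'   per-fragment captured-count vector and the self/uncut tallies
#'   (conservation: \code{sum(captured) + n_self + n_uncut == n_reads}).
#' @export
simulate_4c_library <- function(toy, bait, model, spec, label = "rep1") {
  set.seed(spec$seed)
  genome <- toy$genome
  fr <- toy$map$fragments
  nfr <- nrow(fr)
  bait_row <- which(fr$chrom == bait$chrom & fr$start <= bait$start &
                      fr$end > bait$start)
  stopifnot(length(bait_row) == 1L)
  bait_mid <- (fr$start[bait_row] + fr$end[bait_row]) / 2
  if (bait_mid < model$domain$start || bait_mid >= model$domain$end ||
      bait$chrom != model$domain$chrom)
    stop("bait fragment must lie inside the contact-model domain")
  adj <- which(fr$chrom == fr$chrom[bait_row] &
                 abs(fr$index - fr$index[bait_row]) == 1L)

  if (spec$is_control) {
    w <- numeric(nfr)
    eligible <- setdiff(which(fr$index > 0L), c(bait_row, adj))
    sub <- sample(eligible, max(1L, ceiling(spec$control_sparsity * nfr)))
    w[sub] <- 1
  } else {
    w <- rep(model$trans_background, nfr)
    cis <- which(fr$chrom == bait$chrom)
    mid <- (fr$start[cis] + fr$end[cis]) / 2
    gamma <- rep(1, length(cis))
    pl <- match(model$planted$row, cis)
    gamma[pl[!is.na(pl)]] <- model$planted$gamma[!is.na(pl)]
    cross <- as.numeric(mid < model$domain$start | mid >= model$domain$end)
    decay <- model$boundary_attenuation^cross *
      (1 + abs(mid - bait_mid) / model$decay_scale)^(-model$decay_exponent)
    eta <- stats::rlnorm(length(cis), -model$frag_noise_sd^2 / 2,
                         model$frag_noise_sd)
    eta[gamma > 1] <- 1             # planted weights stay exact
    w[cis] <- model$background + gamma * eta * decay
    w[fr$index == 0L] <- 0          # no upstream cut site: cannot ligate
    w[c(bait_row, adj)] <- 0        # handled by p_self / p_uncut
  }

  kind <- rmultinom(1, spec$n_reads,
                    c(self = spec$p_self, uncut = spec$p_uncut,
                      captured = 1 - spec$p_self - spec$p_uncut))[, 1]
  captured <- rmultinom(1, kind[["captured"]], w)[, 1]
  n_uncut_side <- rmultinom(1, kind[["uncut"]], c(1, 1))[, 1]

  src_rows <- c(rep.int(seq_len(nfr), captured),
                rep.int(bait_row, kind[["self"]]),
                rep.int(adj[1], n_uncut_side[1]),
                rep.int(adj[2], n_uncut_side[2]))
  src_rows <- src_rows[sample.int(length(src_rows))]

  primer16 <- substr(bait$fwd_primer, 1L,
                     nchar(bait$fwd_primer) - nchar(bait$primary_motif))
  insert_len <- spec$read_len - nchar(primer16)
  used <- sort(unique(src_rows))
  frag_prefix <- vapply(used, function(r) {
    as.character(Biostrings::subseq(
      genome[[fr$chrom[r]]], fr$start[r] + 1L,
      min(fr$end[r], fr$start[r] + insert_len)))
  }, character(1))
  seq1 <- paste0(primer16, frag_prefix[match(src_rows, used)])
  bait_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::subseq(genome[[bait$chrom]], bait$start + 1L, bait$end)))
  mate2 <- substr(paste0(bait$rev_primer,
                         substr(bait_rc, 21L, nchar(bait_rc)),
                         strrep("A", spec$read_len)), 1L, spec$read_len)
  n <- length(src_rows)
  seq2 <- rep(mate2, n)
  qual1 <- strrep("I", nchar(seq1))
  qual2 <- rep(strrep("I", spec$read_len), n)
  swap <- stats::runif(n) < 0.5
  pairs <- read_pairs(
    id = sprintf("%s_%s_r%06d", bait$name, label, seq_len(n)),
    seq1 = ifelse(swap, seq2, seq1),
    qual1 = ifelse(swap, qual2, qual1),
    seq2 = ifelse(swap, seq1, seq2),
    qual2 = ifelse(swap, qual1, qual2))
  list(pairs = pairs,
       truth = list(captured = captured, n_self = kind[["self"]],
                    n_uncut = kind[["uncut"]], bait_row = bait_row,
                    adj_rows = adj, weights = w))
}

#' The standard synthetic scenario
#'
#' The package's reference study conditions: a 500 kb main chromosome plus a
#' 120 kb trans chromosome, one bait at the active P1 promoter, five planted
#' enhancer loci (gamma = 20 on each of seven consecutive mappable
#' fragments) inside the domain, two replicate libraries of 2e5 reads and a
#' sparse non-ligated control, the standard caller parameters (w = 3,
#' 1000 iterations, fdr = 0.01, fdr_prob = 0.05) and a 25 kb
#' viewpoint-proximal exclusion zone.
#'
#' @param seed Integer master seed; library seeds are derived from it.
#' @param n_reads Reads per replicate (default 2e5).
#' @param gamma Planted contact weight (default 20).
#' @param null Set \code{TRUE} for a null scenario: no planted weights
#'   (gamma dropped), everything else identical.
#' @return List: \code{$toy}, \code{$bait}, \code{$model},
#'   \code{$lib_specs} (rep1, rep2, control), \code{$regions},
#'   \code{$params} ([caller_params()]), \code{$exclude_bp} (the
#'   viewpoint-proximal exclusion radius used when calling).
#' @export
standard_scenario <- function(seed = 1L, n_reads = 2e5, gamma = 20,
                              null = FALSE) {
  toy <- make_toy_genome(seed = seed)
  bait <- toy_bait(toy, "P1", toy$tss[["P1"]])
  planted <- if (null) data.frame(row = integer(0), gamma = numeric(0))
             else data.frame(row = toy$truth$planted_rows, gamma = gamma)
  model <- contact_model(domain = toy$domain, planted = planted)
  lib_specs <- list(
    rep1 = library_spec(n_reads, seed = seed + 101L),
    rep2 = library_spec(n_reads, seed = seed + 202L),
    control = library_spec(max(2e4, n_reads %/% 10), seed = seed + 303L,
                           is_control = TRUE))
  regions <- list(
    whole = list(chrom = toy$domain$chrom),
    domain = list(chrom = toy$domain$chrom, start = toy$domain$start,
                  end = toy$domain$end))
  list(toy = toy, bait = bait, model = model, lib_specs = lib_specs,
       regions = regions, params = caller_params(seed = seed),
       exclude_bp = 25000)
}

#' Write toy-genome annotation tracks to a directory
#'
#' Emits the genome FASTA, fragment-map BED, per-TF / Rad21 / CTCF / CNE
#' peak BEDs, gene-model TSV, domain BED and ground-truth TSV.
#'
#' @param toy A \code{"toy_genome"}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_toy_tracks <- function(toy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  p <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(toy$genome, p); files <- c(files, p)
  p <- file.path(dir, "fragments.bed")
  write_fragment_bed(toy$map, p); files <- c(files, p)
  write_bed3 <- function(df, path) {
    utils::write.table(df[, c("chrom", "start", "end")], path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    path
  }
  for (tf in names(toy$tracks$tf))
    files <- c(files, write_bed3(toy$tracks$tf[[tf]],
                                 file.path(dir, paste0("tf_", tf, ".bed"))))
  files <- c(files, write_bed3(toy$tracks$rad21, file.path(dir, "rad21.bed")),
             write_bed3(toy$tracks$ctcf, file.path(dir, "ctcf.bed")),
             write_bed3(toy$tracks$cne, file.path(dir, "cne.bed")),
             write_bed3(data.frame(chrom = toy$domain$chrom,
                                   start = toy$domain$start,
                                   end = toy$domain$end),
                        file.path(dir, "domain.bed")))
  p <- file.path(dir, "genes.tsv")
  utils::write.table(toy$genes, p, sep = "\t", quote = FALSE,
                     row.names = FALSE); files <- c(files, p)
  p <- file.path(dir, "truth.tsv")
  utils::write.table(toy$truth$cluster_spans, p, sep = "\t", quote = FALSE,
                     row.names = FALSE); files <- c(files, p)
  invisible(files)
}
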