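#' Reads-per-million normalisation
#'
#' Scales each per-fragment count by \code{1e6 / total}, where the
#' denominator is the retained (post-filter) read total of the library, so
#' replicate profiles are comparable after blacklist differences. When every
#' retained read lies on the map the normalised values sum to exactly 1e6.
#'
#' @param counts A \code{"fragment_counts"} (normally filtered).
#' @return The \code{"fragment_counts"} with real-valued RPM counts.
#' @export
rpm_normalize <- function(counts) {
  total <- if (!is.null(counts$total_retained)) counts$total_retained
           else sum(counts$counts)
  if (total <= 0) stop("cannot RPM-normalise a library with zero retained reads")
  counts$counts <- counts$counts * 1e6 / total
  counts$rpm <- TRUE
  counts
}

#' Running-window sum contact profile
#'
#' The displayed 4C contact profile: at each fragment, the sum of the
#' (normalised) counts of \code{k} successive fragments centred on it,
#' computed per chromosome. At chromosome edges the window is truncated to
#' the available fragments. With \code{mean = TRUE} the sum is divided by
#' the effective window size.
#'
#' @param counts A \code{"fragment_counts"} (typically RPM-normalised).
#' @param k Odd window size in fragments (default 9).
#' @param mean Divide by the effective window size (default \code{FALSE}:
#'   the displayed quantity is the windowed sum).
#' @return A \code{"smoothed_profile"}: data.frame chrom, start, end, index,
#'   value, with \code{k} as attribute.
#' @export
running_window_sum <- function(counts, k = 9, mean = FALSE) {
  stopifnot(k >= 1, k %% 2 == 1)
  fr <- counts$map$fragments
  half <- (k - 1L) %/% 2L
  value <- numeric(nrow(fr))
  for (ch in unique(fr$chrom)) {
    rows <- which(fr$chrom == ch)
    x <- counts$counts[rows]
    n <- length(x)
    cs <- c(0, cumsum(x))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    v <- cs[hi + 1L] - cs[lo]
    if (mean) v <- v / (hi - lo + 1L)
    value[rows] <- v
  }
  structure(data.frame(chrom = fr$chrom, start = fr$start, end = fr$end,
                       index = fr$index, value = value),
            k = k, bait = counts$bait, library = counts$library,
            class = c("smoothed_profile", "data.frame"))
}

#' Cumulative read-distance curve
#'
#' For one chromosome, orders fragments by genomic coordinate and reports
#' the cumulative percentage of the chromosome's reads at each fragment
#' midpoint, with the bait position annotated — the read-distribution
#' diagnostic showing how tightly contacts concentrate around the viewpoint.
#'
#' @param counts A \code{"fragment_counts"}.
#' @param bait The [bait_spec()] (position marker).
#' @param chrom Chromosome to summarise (default: the bait's).
#' @return data.frame (pos = fragment midpoint, cum_pct), with
#'   \code{bait_pos} attribute; cum_pct is monotone 0..100 ending at 100.
#' @export
cumulative_distance_curve <- function(counts, bait, chrom = bait$chrom) {
  fr <- counts$map$fragments
  rows <- which(fr$chrom == chrom)
  x <- counts$counts[rows]
  tot <- sum(x)
  if (tot <= 0) stop("no reads on ", chrom)
  ord <- order(fr$start[rows])
  mid <- (fr$start[rows] + fr$end[rows]) %/% 2
  structure(data.frame(pos = mid[ord], cum_pct = 100 * cumsum(x[ord]) / tot),
            bait_pos = (bait$start + bait$end) %/% 2,
            class = c("cumulative_curve", "data.frame"))
}

#' Write a smoothed profile as bedGraph
#' @param profile A \code{"smoothed_profile"}.
#' @param path Output file.
#' @export
write_profile_bedgraph <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s_%s_k%d\"",
                     attr(profile, "bait"), attr(profile, "library"),
                     attr(profile, "k")), con)
  utils::write.table(profile[, c("chrom", "start", "end", "value")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Minimal contact-profile plot
#'
#' Unstyled base-graphics rendering of a smoothed profile for one
#' chromosome, with the bait position marked.
#'
#' @param x A \code{"smoothed_profile"}.
#' @param chrom Chromosome to draw (default: first).
#' @param bait Optional [bait_spec()] to mark.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.smoothed_profile <- function(x, chrom = x$chrom[1], bait = NULL, ...) {
  sel <- x$chrom == chrom
  graphics::plot((x$start[sel] + x$end[sel]) / 2, x$value[sel], type = "h",
                 xlab = paste0(chrom, " position (bp)"),
                 ylab = sprintf("RPM %d-fragment sum", attr(x, "k")), ...)
  if (!is.null(bait)) graphics::abline(v = (bait$start + bait$end) / 2,
                                       col = "red", lty = 2)
  invisible(x)
}
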