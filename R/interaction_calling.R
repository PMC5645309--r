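#' Parameters for permutation-FDR interaction calling
#'
#' Defaults are the standard 4C settings: sliding window of 3 fragments,
#' 1000 permutations, FDR < 0.01, with candidate thresholds restricted to
#' the top fifth percentile (\code{fdr_prob = 0.05}) of observed window
#' sums. Only mappable fragments enter the statistic.
#'
#' @param w Odd window size in fragments (default 3).
#' @param iterations Number of permutations (default 1000).
#' @param fdr FDR cutoff (default 0.01).
#' @param fdr_prob Candidate thresholds are observed window sums at or above
#'   the \code{1 - fdr_prob} quantile (default 0.05).
#' @param seed Integer seed for the permutation stream.
#' @return An object of class \code{"caller_params"}.
#' @export
caller_params <- function(w = 3, iterations = 1000, fdr = 0.01,
                          fdr_prob = 0.05, seed = 1L) {
  stopifnot(w >= 1, w %% 2 == 1, iterations >= 1,
            fdr > 0, fdr < 1, fdr_prob > 0, fdr_prob <= 1)
  structure(list(w = as.integer(w), iterations = as.integer(iterations),
                 fdr = fdr, fdr_prob = fdr_prob, seed = as.integer(seed)),
            class = "caller_params")
}

#' Sliding window sums over mappable fragments
#'
#' \code{W_i = sum(x[i..i+w-1])} sliding by one in mappable-index space:
#' \code{x} must already be the count vector of the region's mappable
#' fragments in genomic order (unmappable fragments are excluded entirely,
#' making their neighbours window-adjacent).
#'
#' @param x Numeric count vector over the mappable fragments of a region.
#' @param w Window size.
#' @return Numeric vector of length \code{length(x) - w + 1}.
#' @export
window_statistics <- function(x, w) {
  n <- length(x)
  if (n < w) stop("region has fewer than w mappable fragments")
  cs <- c(0, cumsum(x))
  cs[(w + 1L):(n + 1L)] - cs[1:(n - w + 1L)]
}

#' Permutation-FDR significance threshold
#'
#' Candidate thresholds are the distinct observed window sums at or above
#' the \code{1 - fdr_prob} empirical quantile of all observed window sums.
#' For each candidate \code{T}, the estimated FDR is the mean number of
#' permuted windows \code{>= T} (each permutation uniformly shuffles the
#' per-fragment count multiset across the region's mappable fragments)
#' divided by the number of observed windows \code{>= T}. The returned
#' threshold is the smallest candidate with estimated FDR below \code{fdr};
#' \code{Inf} (no significant interactions) if none qualifies.
#'
#' @param x Counts over the region's mappable fragments, genomic order.
#' @param params A [caller_params()].
#' @return List: \code{threshold} (numeric, \code{Inf} if none),
#'   \code{table} (data.frame candidate / n_obs_ge / mean_perm_ge / fdr_hat),
#'   \code{window_sums} (observed), \code{params}.
#' @export
permutation_threshold <- function(x, params = caller_params()) {
  W <- window_statistics(x, params$w)
  floor_q <- stats::quantile(W, probs = 1 - params$fdr_prob, type = 1,
                             names = FALSE)
  cand <- sort(unique(W[W >= floor_q]))
  n_obs_ge <- vapply(cand, function(t) sum(W >= t), numeric(1))
  perm_ge <- numeric(length(cand))
  n <- length(x)
  set.seed(params$seed)
  for (it in seq_len(params$iterations)) {
    Wp <- sort(window_statistics(x[sample.int(n)], params$w))
    perm_ge <- perm_ge +
      (length(Wp) - findInterval(cand, Wp, left.open = TRUE))
  }
  mean_perm_ge <- perm_ge / params$iterations
  fdr_hat <- mean_perm_ge / n_obs_ge
  ok <- fdr_hat < params$fdr
  list(threshold = if (any(ok)) cand[which(ok)[1L]] else Inf,
       table = data.frame(candidate = cand, n_obs_ge = n_obs_ge,
                          mean_perm_ge = mean_perm_ge, fdr_hat = fdr_hat),
       window_sums = W, params = params)
}

#' Call significant intervals at a threshold
#'
#' Marks windows with sum \code{>= threshold} and merges overlapping or
#' adjacent significant windows (in mappable-index space) into intervals.
#' Each interval's genomic extent is the union of its member fragments'
#' spans and its peak statistic the maximum member window sum.
#'
#' @param x Counts over the region's mappable fragments, genomic order.
#' @param threshold Threshold from [permutation_threshold()].
#' @param w Window size.
#' @param frags data.frame of the region's mappable fragments (rows parallel
#'   to \code{x}; columns chrom, start, end, index).
#' @return data.frame of intervals: chrom, start, end, first/last member
#'   positions (in the region's mappable-index space), peak, threshold.
#' @export
call_significant <- function(x, threshold, w, frags) {
  W <- window_statistics(x, w)
  sig <- which(W >= threshold)
  out <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                    first = integer(0), last = integer(0),
                    peak = numeric(0), threshold = numeric(0))
  if (length(sig) == 0L) return(out)
  # merge runs of windows whose member fragments overlap or are adjacent:
  # window i covers fragments i..i+w-1, so break when the next significant
  # window starts beyond current_end + 1
  run_id <- cumsum(c(1L, diff(sig) > w))
  for (r in unique(run_id)) {
    ws <- sig[run_id == r]
    first <- ws[1L]
    last <- ws[length(ws)] + w - 1L
    out <- rbind(out, data.frame(
      chrom = frags$chrom[first],
      start = min(frags$start[first:last]),
      end = max(frags$end[first:last]),
      first = first, last = last,
      peak = max(W[ws]), threshold = threshold))
  }
  out
}

#' Robustness category of a called interval
#'
#' Let \code{m} be the member fragment with the highest count (ties broken
#' by lowest index). Category 1: some member window still reaches the
#' threshold with \code{m}'s count set to 0. Category 2 (otherwise): some
#' member window reaches the threshold with \code{m}'s count replaced by the
#' mean of its two flanking mappable fragments' counts. Category 3: neither.
#'
#' @param x Counts over the region's mappable fragments.
#' @param first,last Member positions of the interval in \code{x}.
#' @param threshold,w Calling threshold and window size.
#' @return Integer 1, 2 or 3.
#' @export
classify_category <- function(x, first, last, threshold, w) {
  members <- first:last
  m <- members[which.max(x[members])]
  modified_hits <- function(val) {
    y <- x
    y[m] <- val
    any(window_statistics(y[members], w) >= threshold)
  }
  if (modified_hits(0)) return(1L)
  flanks <- c(if (m > 1L) x[m - 1L], if (m < length(x)) x[m + 1L])
  if (modified_hits(mean(flanks))) return(2L)
  3L
}

#' Call significant interactions for one bait over configured regions
#'
#' Runs the threshold / call / classify chain independently per region.
#' A region is either a whole chromosome or a genomic interval; only
#' mappable fragments inside it enter the statistic, and windows containing
#' the bait fragment or its index-adjacent neighbours are excluded (those
#' fragments were zeroed by the upstream filters; excluding them here guards
#' against misconfiguration). \code{exclude_bp} optionally widens the
#' excluded zone to all fragments whose midpoint lies within that distance
#' of the bait: the viewpoint-proximal profile is dominated by smooth
#' distance decay, which the exchangeable-counts permutation null cannot
#' model, so proximal windows would otherwise always be flagged. Each
#' region gets its own recorded seed (\code{params$seed + region ordinal}).
#'
#' @param counts A filtered \code{"fragment_counts"} for one bait library.
#' @param bait The [bait_spec()].
#' @param regions Named list of regions: each \code{list(chrom=, start=, end=)}
#'   (start/end optional: whole chromosome).
#' @param params A [caller_params()].
#' @param exclude_bp Radius in bp of the viewpoint-proximal exclusion zone
#'   (default 0: only the bait fragment and its index-adjacent neighbours
#'   are excluded).
#' @return A \code{"fourc_calls"} object: per-region interval data.frames
#'   (with \code{category} and \code{region} columns), threshold tables and
#'   the seeds used.
#' @export
call_bait <- function(counts, bait, regions, params = caller_params(),
                      exclude_bp = 0) {
  if (anyDuplicated(names(regions)) || is.null(names(regions)))
    stop("regions must be uniquely named")
  fr <- counts$map$fragments
  bait_row <- which(fr$chrom == bait$chrom & fr$start <= bait$start &
                      fr$end > bait$start)
  bait_mid <- (fr$start[bait_row] + fr$end[bait_row]) / 2
  excluded <- which(fr$chrom == fr$chrom[bait_row] &
                      (abs(fr$index - fr$index[bait_row]) <= 1L |
                         abs((fr$start + fr$end) / 2 - bait_mid) <= exclude_bp))
  out <- list()
  tables <- list()
  seeds <- integer(0)
  for (i in seq_along(regions)) {
    rg <- regions[[i]]
    rows <- which(fr$chrom == rg$chrom & fr$mappable)
    if (!is.null(rg$start))
      rows <- rows[fr$start[rows] >= rg$start & fr$end[rows] <= rg$end]
    rows <- setdiff(rows, excluded)
    rp <- params
    rp$seed <- params$seed + i - 1L
    seeds[names(regions)[i]] <- rp$seed
    thr <- permutation_threshold(counts$counts[rows], rp)
    iv <- call_significant(counts$counts[rows], thr$threshold, params$w,
                           fr[rows, , drop = FALSE])
    iv$category <- if (nrow(iv)) vapply(seq_len(nrow(iv)), function(j) {
      classify_category(counts$counts[rows], iv$first[j], iv$last[j],
                        thr$threshold, params$w)
    }, integer(1)) else integer(0)
    iv$region <- rep(names(regions)[i], nrow(iv))
    out[[names(regions)[i]]] <- iv
    tables[[names(regions)[i]]] <- thr$table
  }
  structure(list(bait = counts$bait, library = counts$library,
                 intervals = out, tables = tables, params = params,
                 seeds = seeds),
            class = "fourc_calls")
}

#' @export
print.fourc_calls <- function(x, ...) {
  cat(sprintf("<fourc_calls> bait=%s library=%s\n", x$bait, x$library))
  for (nm in names(x$intervals)) {
    iv <- x$intervals[[nm]]
    cat(sprintf("  region %-12s %3d significant interval(s)", nm, nrow(iv)))
    if (nrow(iv))
      cat(sprintf("  [categories: %s]",
                  paste(table(factor(iv$category, 1:3)), collapse = "/")))
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.fourc_calls <- function(object, ...) {
  do.call(rbind, lapply(object$intervals, function(iv)
    iv[, c("region", "chrom", "start", "end", "peak", "threshold", "category")]))
}

#' Write called intervals as BED9
#'
#' name = category, score = peak statistic scaled to 0-1000 within the set,
#' itemRgb red (255,0,0) for red-class intervals, orange (255,165,0)
#' otherwise. The red class (category 1 reproducible in both replicates) is
#' assigned downstream by [intersect_replicates()]; for single-replicate
#' calls everything is orange.
#'
#' @param intervals data.frame with chrom, start, end, category and
#'   optionally colour.
#' @param path Output file.
#' @param peak Column used for the score (default \code{"peak"}).
#' @export
write_calls_bed <- function(intervals, path, peak = "peak") {
  iv <- intervals
  score <- if (nrow(iv) && max(iv[[peak]]) > 0)
    as.integer(round(1000 * iv[[peak]] / max(iv[[peak]]))) else integer(nrow(iv))
  rgb <- if ("colour" %in% names(iv))
    ifelse(iv$colour == "red", "255,0,0", "255,165,0") else rep("255,165,0", nrow(iv))
  bed <- data.frame(iv$chrom, iv$start, iv$end,
                    paste0("cat", iv$category), score, ".",
                    iv$start, iv$end, rgb)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
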