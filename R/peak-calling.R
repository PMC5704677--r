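# Promoter (peak) identification from pooled CTSS signal: gap-based
# clustering, valley decomposition of composite clusters (a documented,
# simplified stand-in for decomposition-based peak identification),
# permissive/robust tiering, per-sample quantification.

#' Cluster CTSS positions into candidate promoter intervals
#'
#' Same-chromosome, same-strand positions whose successive gaps are at
#' most `max_gap` merge into one interval `[min, max + 1)`. Opposite
#' strands are never merged, even at identical coordinates.
#'
#' @param pooled Pooled [ctss_profile()].
#' @param max_gap Maximum allowed gap (bp) between successive CTSSs.
#' @return `data.table` with columns `chrom`, `start`, `end`, `strand`.
#' @export
cluster_ctss <- function(pooled, max_gap = 20) {
  p <- as.data.table(pooled)[count > 0]
  if (nrow(p) == 0L) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), strand = character()))
  }
  setorder(p, chrom, strand, pos)
  p[, new_cluster := c(TRUE, diff(pos) > max_gap), by = .(chrom, strand)]
  p[, cluster := cumsum(new_cluster), by = .(chrom, strand)]
  out <- p[, .(start = min(pos), end = max(pos) + 1L),
           by = .(chrom, strand, cluster)]
  out[, cluster := NULL]
  setcolorder(out, c("chrom", "start", "end", "strand"))
  setorder(out, chrom, start, strand)
  out[]
}

.gaussian_smooth <- function(x, sd) {
  if (sd <= 0) return(x)
  half <- max(1L, ceiling(4 * sd))
  k <- stats::dnorm(seq(-half, half), sd = sd)
  k <- k / sum(k)
  n <- length(x)
  padded <- c(rep(0, half), x, rep(0, half))
  vapply(seq_len(n), function(i) {
    sum(padded[i:(i + 2L * half)] * k)
  }, numeric(1))
}

# indices of strict local maxima of s, plateaus resolved to their centre
.local_maxima <- function(s) {
  n <- length(s)
  if (n == 1L) return(1L)
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  out <- integer()
  for (j in seq_len(k)) {
    left_ok <- j == 1L || r$values[j - 1L] < r$values[j]
    right_ok <- j == k || r$values[j + 1L] < r$values[j]
    if (left_ok && right_ok) {
      out <- c(out, as.integer(floor((starts[j] + ends[j]) / 2)))
    }
  }
  out
}

#' Decompose a composite cluster at smoothed-signal valleys
#'
#' The pooled per-base signal over the interval is Gaussian-smoothed
#' (`smooth_sd`); between each pair of adjacent local maxima separated by
#' at least `min_subpeak_gap` bp, the interval is split at the minimum of
#' the smoothed signal when that minimum is below `valley_fraction`
#' times the smaller of the two flanking maxima. Splitting never creates
#' overlapping sub-intervals and the union of CTSS positions over the
#' sub-intervals equals the parent's (signal conservation). This is a
#' simplified, parameterised substitute for decomposition-based peak
#' identification; see the package vignette for its rationale.
#'
#' @param interval One-row data.frame (`chrom`, `start`, `end`, `strand`).
#' @param pooled Pooled [ctss_profile()].
#' @param smooth_sd Gaussian smoothing SD in bp.
#' @param valley_fraction Valley depth threshold relative to flanking maxima.
#' @param min_subpeak_gap Minimum distance (bp) between maxima to split.
#' @return `data.table` of sub-intervals (same columns as the input),
#'   trimmed to their extreme CTSS positions.
#' @export
decompose_cluster <- function(interval, pooled, smooth_sd = 5,
                              valley_fraction = 0.1, min_subpeak_gap = 10) {
  p <- as.data.table(pooled)[chrom == interval$chrom &
                               strand == interval$strand &
                               pos >= interval$start & pos < interval$end]
  if (nrow(p) == 0L) return(data.table(chrom = character(),
                                       start = integer(), end = integer(),
                                       strand = character()))
  span <- interval$end - interval$start
  x <- numeric(span)
  x[p$pos - interval$start + 1L] <- p$count
  s <- .gaussian_smooth(x, smooth_sd)
  maxima <- .local_maxima(s)
  cuts <- integer()  # last index (1-based, within span) of each left part
  if (length(maxima) >= 2L) {
    for (j in seq_len(length(maxima) - 1L)) {
      m1 <- maxima[j]; m2 <- maxima[j + 1L]
      if (m2 - m1 < max(min_subpeak_gap, 2L)) next
      valley_idx <- m1 + which.min(s[(m1 + 1L):(m2 - 1L)])
      if (s[valley_idx] < valley_fraction * min(s[m1], s[m2])) {
        cuts <- c(cuts, valley_idx)
      }
    }
  }
  bounds <- c(0L, cuts, span)  # positions <= bound belong left
  out <- list()
  for (j in seq_len(length(bounds) - 1L)) {
    lo <- interval$start + bounds[j]        # genomic, inclusive
    hi <- interval$start + bounds[j + 1L]   # genomic, exclusive
    pp <- p[pos >= lo & pos < hi]
    if (nrow(pp) == 0L) next
    out[[length(out) + 1L]] <- data.table(chrom = interval$chrom,
                                          start = min(pp$pos),
                                          end = max(pp$pos) + 1L,
                                          strand = interval$strand)
  }
  rbindlist(out)
}

#' Call permissive and robust peaks from decomposed intervals
#'
#' A sub-interval becomes a *permissive* peak iff some sample has a
#' single CTSS position inside it with count >= `permissive_min`; it is
#' additionally *robust* iff some sample has a single position with
#' count >= `robust_min` whose tags-per-million in that same sample is
#' >= `robust_tpm`. Peaks are trimmed to `[min, max + 1)` of their CTSS
#' positions (pooled over samples) and named canonically.
#'
#' @param intervals Sub-intervals (`chrom`, `start`, `end`, `strand`).
#' @param libraries List of [sample_library()] objects.
#' @param permissive_min Minimum single-position count for the
#'   permissive tier (default 3).
#' @param robust_min Minimum single-position count for the robust tier
#'   (default 10).
#' @param robust_tpm Minimum tags-per-million at that same position in
#'   the same sample (default 1).
#' @return `data.table` with columns `chrom`, `start`, `end`, `strand`,
#'   `name`, `tier` (`"permissive"` or `"robust"`; every robust peak is
#'   also permissive — `tier` records the highest tier attained).
#' @export
call_peaks <- function(intervals, libraries, permissive_min = 3,
                       robust_min = 10, robust_tpm = 1) {
  empty <- data.table(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      name = character(), tier = character())
  iv <- as.data.table(intervals)
  if (nrow(iv) == 0L) return(empty)
  iv <- copy(iv)[, iv_id := .I]
  per_sample <- rbindlist(lapply(libraries, function(l) {
    ct <- as.data.table(l$ctss)
    if (nrow(ct) == 0L) return(NULL)
    ct <- copy(ct)[, `:=`(sample_id = l$sample_id,
                          tpm = tags_per_million(count, l$total_tags))]
    ct
  }))
  out <- list()
  for (i in seq_len(nrow(iv))) {
    hits <- per_sample[chrom == iv$chrom[i] & strand == iv$strand[i] &
                         pos >= iv$start[i] & pos < iv$end[i]]
    if (nrow(hits) == 0L) next
    permissive <- any(hits$count >= permissive_min)
    robust <- any(hits$count >= robust_min & hits$tpm >= robust_tpm)
    if (!permissive && !robust) next
    lo <- min(hits$pos); hi <- max(hits$pos) + 1L
    out[[length(out) + 1L]] <- data.table(
      chrom = iv$chrom[i], start = lo, end = hi, strand = iv$strand[i],
      name = cage_name(iv$chrom[i], lo, hi, iv$strand[i]),
      tier = if (robust) "robust" else "permissive")
  }
  res <- rbindlist(out)
  if (nrow(res) == 0L) return(empty)
  setorder(res, chrom, start, strand)
  res[]
}

#' Full clustering + decomposition + calling convenience wrapper
#'
#' @param libraries List of [sample_library()] objects.
#' @param max_gap,smooth_sd,valley_fraction,min_subpeak_gap See
#'   [cluster_ctss()] and [decompose_cluster()].
#' @param permissive_min,robust_min,robust_tpm See [call_peaks()].
#' @return Peak table as from [call_peaks()].
#' @export
identify_peaks <- function(libraries, max_gap = 20, smooth_sd = 5,
                           valley_fraction = 0.1, min_subpeak_gap = 10,
                           permissive_min = 3, robust_min = 10,
                           robust_tpm = 1) {
  pooled <- pool_samples(libraries)
  clusters <- cluster_ctss(pooled, max_gap = max_gap)
  subs <- rbindlist(lapply(seq_len(nrow(clusters)), function(i) {
    decompose_cluster(clusters[i], pooled, smooth_sd = smooth_sd,
                      valley_fraction = valley_fraction,
                      min_subpeak_gap = min_subpeak_gap)
  }))
  call_peaks(subs, libraries, permissive_min = permissive_min,
             robust_min = robust_min, robust_tpm = robust_tpm)
}

#' Quantify per-sample peak expression
#'
#' @param peaks Peak table ([call_peaks()]).
#' @param libraries List of [sample_library()] objects.
#' @return List with elements `counts` and `tpm`: peak x sample matrices
#'   (rownames = peak names).
#' @export
quantify_peak_expression <- function(peaks, libraries) {
  pk <- as.data.table(peaks)
  samples <- vapply(libraries, `[[`, character(1), "sample_id")
  counts <- matrix(0, nrow = nrow(pk), ncol = length(libraries),
                   dimnames = list(pk$name, samples))
  tpm <- counts
  for (j in seq_along(libraries)) {
    l <- libraries[[j]]
    ct <- as.data.table(l$ctss)
    if (nrow(ct) == 0L || nrow(pk) == 0L) next
    for (i in seq_len(nrow(pk))) {
      v <- ct[chrom == pk$chrom[i] & strand == pk$strand[i] &
                pos >= pk$start[i] & pos < pk$end[i], sum(count)]
      counts[i, j] <- v
    }
    tpm[, j] <- tags_per_million(counts[, j], l$total_tags)
  }
  list(counts = counts, tpm = tpm)
}

#' Fraction of each sample's tags falling inside peaks
#'
#' @param libraries List of [sample_library()] objects.
#' @param peaks Peak table.
#' @return Named numeric vector of fractions in `[0, 1]`.
#' @export
fraction_tags_in_peaks <- function(libraries, peaks) {
  pk <- as.data.table(peaks)
  vapply(libraries, function(l) {
    if (l$total_tags == 0L) return(NA_real_)
    if (nrow(pk) == 0L) return(0)
    ct <- as.data.table(l$ctss)
    inside <- 0
    for (i in seq_len(nrow(pk))) {
      inside <- inside + ct[chrom == pk$chrom[i] & strand == pk$strand[i] &
                              pos >= pk$start[i] & pos < pk$end[i],
                            sum(count)]
    }
    inside / l$total_tags
  }, numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(vapply(libraries, `[[`, character(1), "sample_id"))
}
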