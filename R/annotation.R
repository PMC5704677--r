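# Peak-to-gene association, genomic feature classification, TATA scan,
# CpG island detection, promoter architecture (sharp/TATA vs broad/CpG).

# IRanges-backed overlap of two half-open interval tables; returns index
# pairs (query i, subject j). Strand handling is the caller's business.
.overlap_pairs <- function(q_start, q_end, s_start, s_end) {
  if (length(q_start) == 0L || length(s_start) == 0L) {
    return(data.table(q = integer(), s = integer()))
  }
  q <- IRanges::IRanges(start = q_start + 1L, end = q_end)   # to 1-based closed
  s <- IRanges::IRanges(start = s_start + 1L, end = s_end)
  hits <- IRanges::findOverlaps(q, s)
  data.table(q = S4Vectors::queryHits(hits), s = S4Vectors::subjectHits(hits))
}

#' Associate peaks with gene models via the 1 kb TSS window rule
#'
#' A peak is associated with a gene model iff they are on the same
#' strand and the peak interval intersects the 1 kb window centred on
#' the gene's 5' end, `[tss - window_half, tss + window_half)`. All
#' qualifying (peak, transcript) pairs are reported, per source set.
#'
#' @param peaks Peak table (`chrom`, `start`, `end`, `strand`, `name`).
#' @param models Gene model table ([read_gene_models()]), possibly
#'   concatenated over several `source_set`s.
#' @param window_half Half-width of the TSS window (default 500 bp).
#' @return `data.table` with columns `peak`, `source_set`, `gene_id`,
#'   `transcript_id`, `distance` (signed bp from the peak 5' end to the
#'   gene TSS in transcript orientation; positive = downstream).
#' @export
associate_peaks_to_genes <- function(peaks, models, window_half = 500) {
  pk <- as.data.table(peaks)
  gm <- as.data.table(models)
  empty <- data.table(peak = character(), source_set = character(),
                      gene_id = character(), transcript_id = character(),
                      distance = integer())
  if (nrow(pk) == 0L || nrow(gm) == 0L) return(empty)
  out <- list()
  for (key in unique(paste(gm$chrom, gm$strand))) {
    parts <- strsplit(key, " ", fixed = TRUE)[[1]]
    g <- gm[chrom == parts[1] & strand == parts[2]]
    p <- pk[chrom == parts[1] & strand == parts[2]]
    if (nrow(p) == 0L) next
    hits <- .overlap_pairs(p$start, p$end,
                           g$tss - window_half, g$tss + window_half)
    if (nrow(hits) == 0L) next
    p5 <- ifelse(p$strand[hits$q] == "+", p$start[hits$q],
                 p$end[hits$q] - 1L)
    d <- ifelse(g$strand[hits$s] == "+", p5 - g$tss[hits$s],
                g$tss[hits$s] - p5)
    out[[length(out) + 1L]] <- data.table(
      peak = p$name[hits$q], source_set = g$source_set[hits$s],
      gene_id = g$gene_id[hits$s], transcript_id = g$transcript_id[hits$s],
      distance = as.integer(d))
  }
  res <- rbindlist(out)
  if (nrow(res) == 0L) return(empty)
  setorder(res, peak, source_set, gene_id, transcript_id)
  res[]
}

#' Breakdown of peaks by number of annotation sets hit
#'
#' @param associations Output of [associate_peaks_to_genes()].
#' @param peaks Peak table (defines the universe, including bin 0).
#' @param source_sets Character vector of all loaded set labels.
#' @return Named integer vector, bins `"0"` .. `"<n_sets>"`, summing to
#'   `nrow(peaks)`.
#' @export
annotation_breakdown <- function(associations, peaks, source_sets) {
  a <- as.data.table(associations)
  pk <- as.data.table(peaks)
  n_sets <- length(source_sets)
  hit <- a[source_set %in% source_sets,
           .(n = uniqueN(source_set)), by = peak]
  counts <- integer(n_sets + 1L)
  names(counts) <- as.character(0:n_sets)
  n_by_peak <- hit$n[match(pk$name, hit$peak)]
  n_by_peak[is.na(n_by_peak)] <- 0L
  tab <- table(factor(n_by_peak, levels = 0:n_sets))
  counts[] <- as.integer(tab)
  counts
}

#' Classify peaks into genomic feature classes
#'
#' Fixed precedence: promoter > 5UTR > exon > intron > TTS > CpG-island
#' > repeat > intergenic. Gene-relative classes (promoter, 5UTR, exon,
#' intron, TTS) require matching strand; CpG islands and repeats are
#' strandless. The promoter window is strand-oriented
#' (`promoter_window[1]` bp upstream to `promoter_window[2]` bp
#' downstream of the TSS); the TTS window extends `tts_window` bp on
#' both sides of the 3' end.
#'
#' @param peaks Peak table.
#' @param models Gene model table.
#' @param cpg Optional CpG island BED table (`chrom`, `start`, `end`).
#' @param repeats Optional repeat BED table.
#' @param promoter_window `c(upstream, downstream)` in bp, default
#'   `c(1000, 500)`.
#' @param tts_window Half-window around the 3' end (default 500).
#' @return Character vector of classes, parallel to `peaks` rows.
#' @export
classify_genomic_feature <- function(peaks, models, cpg = NULL,
                                     repeats = NULL,
                                     promoter_window = c(1000, 500),
                                     tts_window = 500) {
  pk <- as.data.table(peaks)
  gm <- as.data.table(models)
  n <- nrow(pk)
  if (n == 0L) return(character())
  cls <- rep("intergenic", n)

  overlaps_any <- function(regions, stranded) {
    hit <- logical(n)
    if (is.null(regions) || nrow(regions) == 0L) return(hit)
    rg <- as.data.table(regions)
    for (i in seq_len(n)) {
      sel <- rg$chrom == pk$chrom[i] &
        rg$start < pk$end[i] & rg$end > pk$start[i]
      if (stranded) sel <- sel & rg$strand == pk$strand[i]
      hit[i] <- any(sel)
    }
    hit
  }

  if (nrow(gm) > 0L) {
    up <- promoter_window[1]; down <- promoter_window[2]
    prom <- gm[, .(chrom, strand,
                   start = ifelse(strand == "+", tss - up, tss - down + 1L),
                   end = ifelse(strand == "+", tss + down, tss + up + 1L))]
    tts_pos <- ifelse(gm$strand == "+", gm$tx_end - 1L, gm$tx_start)
    tts <- data.table(chrom = gm$chrom, strand = gm$strand,
                      start = tts_pos - tts_window,
                      end = tts_pos + tts_window + 1L)
    utr5 <- gm[!is.na(cds_start),
               .(chrom, strand,
                 start = ifelse(strand == "+", tx_start, cds_end),
                 end = ifelse(strand == "+", cds_start, tx_end))]
    utr5 <- utr5[end > start]
    exons <- gm[, .(start = unlist(exon_starts), end = unlist(exon_ends)),
                by = .(chrom, strand, transcript_id)]
    tx <- gm[, .(chrom, strand, start = tx_start, end = tx_end)]

    is_prom <- overlaps_any(prom, TRUE)
    is_utr5 <- overlaps_any(utr5, TRUE)
    is_exon <- overlaps_any(exons, TRUE)
    is_tx <- overlaps_any(tx, TRUE)
    is_tts <- overlaps_any(tts, TRUE)
  } else {
    is_prom <- is_utr5 <- is_exon <- is_tx <- is_tts <- logical(n)
  }
  is_cpg <- overlaps_any(cpg, FALSE)
  is_rep <- overlaps_any(repeats, FALSE)

  cls[is_rep] <- "repeat"
  cls[is_cpg] <- "CpG-island"
  cls[is_tts] <- "TTS"
  cls[is_tx & !is_exon] <- "intron"
  cls[is_exon] <- "exon"
  cls[is_utr5] <- "5UTR"
  cls[is_prom] <- "promoter"
  cls
}

# sequence string -> integer codes 1..4 for A,C,G,T (others NA)
.seq_codes <- function(seq_char) {
  match(strsplit(seq_char, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
}

#' Scan for a TATA-box motif around peak 5' boundaries
#'
#' For each peak, a strand-oriented window from `window[1]` (negative =
#' upstream) to `window[2]` bp around the peak's 5' boundary is
#' extracted from the genome and scanned with the PWM on the peak
#' strand. Log-odds scores use a uniform 0.25 background with a 0.01
#' pseudocount. The best-scoring offset at or above `log_odds_min`
#' (default: 60% of the maximal attainable score) is reported; ties go
#' to the offset closest to the anchor. Windows extending beyond the
#' chromosome are truncated with a warning.
#'
#' @param peaks Peak table.
#' @param genome A `Biostrings::DNAStringSet` (names = chromosomes).
#' @param pwm 4 x width frequency matrix, rows A/C/G/T ([read_pwm()]).
#' @param window `c(upstream, downstream)` offsets, default `c(-500, 200)`.
#' @param log_odds_min Score threshold; `NULL` for the 60%-of-max default.
#' @return `data.table` with columns `peak`, `has_tata`, `offset` (bp of
#'   the motif start relative to the anchor; negative = upstream; `NA`
#'   when no hit) and `score`.
#' @export
scan_tata_motif <- function(peaks, genome, pwm, window = c(-500, 200),
                            log_odds_min = NULL) {
  pk <- as.data.table(peaks)
  lod <- log2((pwm + 0.01) / colSums(pwm + 0.01)[col(pwm)] / 0.25)
  w <- ncol(lod)
  max_score <- sum(apply(lod, 2, max))
  if (is.null(log_odds_min)) log_odds_min <- 0.6 * max_score
  truncated <- FALSE
  res <- lapply(seq_len(nrow(pk)), function(i) {
    chrom <- pk$chrom[i]
    len <- Biostrings::width(genome[chrom])
    if (pk$strand[i] == "+") {
      anchor <- pk$start[i]
      lo <- anchor + window[1]; hi <- anchor + window[2]  # genomic, half-open
      clo <- max(lo, 0L); chi <- min(hi, len)
      seq <- as.character(Biostrings::subseq(genome[[chrom]], clo + 1L, chi))
      offsets <- seq.int(clo - anchor, by = 1L,
                         length.out = max(chi - clo - w + 1L, 0L))
    } else {
      anchor <- pk$end[i] - 1L
      lo <- anchor - window[2] + 1L; hi <- anchor - window[1] + 1L
      clo <- max(lo, 0L); chi <- min(hi, len)
      seq <- as.character(Biostrings::reverseComplement(
        Biostrings::subseq(genome[[chrom]], clo + 1L, chi)))
      offsets <- seq.int(anchor - chi + 1L, by = 1L,
                         length.out = max(chi - clo - w + 1L, 0L))
    }
    if (clo > lo || chi < hi) truncated <<- TRUE
    if (length(offsets) == 0L) {
      return(data.table(peak = pk$name[i], has_tata = FALSE,
                        offset = NA_integer_, score = NA_real_))
    }
    codes <- .seq_codes(seq)
    scores <- vapply(seq_along(offsets), function(k) {
      idx <- codes[k:(k + w - 1L)]
      if (anyNA(idx)) return(-Inf)
      sum(lod[cbind(idx, seq_len(w))])
    }, numeric(1))
    ok <- scores >= log_odds_min
    if (!any(ok)) {
      return(data.table(peak = pk$name[i], has_tata = FALSE,
                        offset = NA_integer_, score = max(scores)))
    }
    best <- which(ok & scores == max(scores[ok]))
    best <- best[which.min(abs(offsets[best]))]
    data.table(peak = pk$name[i], has_tata = TRUE,
               offset = as.integer(offsets[best]), score = scores[best])
  })
  if (truncated) {
    warning("scan window truncated at chromosome boundary for some peaks",
            call. = FALSE)
  }
  rbindlist(res)
}

#' Detect CpG islands with Gardiner-Garden-style criteria
#'
#' Slides a `min_len` window one bp at a time and marks windows with GC
#' fraction >= `min_gc` and observed/expected CpG >= `min_obs_exp`
#' (obs/exp = n_CpG * L / (n_C * n_G)); overlapping qualifying windows
#' are merged into maximal islands.
#'
#' @param genome A `Biostrings::DNAStringSet`.
#' @param min_len Window length (default 200).
#' @param min_gc Minimum GC fraction (inclusive).
#' @param min_obs_exp Minimum observed/expected CpG ratio (inclusive).
#' @return `data.table` with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @export
detect_cpg_islands <- function(genome, min_len = 200, min_gc = 0.5,
                               min_obs_exp = 0.6) {
  out <- list()
  for (chrom in names(genome)) {
    s <- as.character(genome[[chrom]])
    n <- nchar(s)
    if (n < min_len) next
    codes <- .seq_codes(s)
    isC <- as.integer(codes == 2L & !is.na(codes))
    isG <- as.integer(codes == 3L & !is.na(codes))
    isCpG <- as.integer(isC[-n] == 1L & isG[-1] == 1L)
    cC <- c(0L, cumsum(isC)); cG <- c(0L, cumsum(isG))
    cCpG <- c(0L, cumsum(isCpG), 0L)  # length n+1; window CpGs below
    starts <- seq_len(n - min_len + 1L)
    nc <- cC[starts + min_len] - cC[starts]
    ng <- cG[starts + min_len] - cG[starts]
    # CpG dinucleotides fully inside [start, start+min_len)
    ncpg <- cCpG[pmin(starts + min_len - 1L, n)] - cCpG[starts]
    gc <- (nc + ng) / min_len
    obs_exp <- ifelse(nc * ng > 0, ncpg * min_len / (nc * ng), 0)
    ok <- gc >= min_gc & obs_exp >= min_obs_exp
    if (!any(ok)) next
    r <- rle(ok)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1L
    for (j in which(r$values)) {
      out[[length(out) + 1L]] <- data.table(
        chrom = chrom,
        start = starts[starts_idx[j]] - 1L,
        end = starts[ends_idx[j]] - 1L + min_len)
    }
  }
  res <- rbindlist(out)
  if (nrow(res) == 0L) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer()))
  }
  setorder(res, chrom, start)
  res[]
}

#' Classify promoter architecture (TATA/CpG) and compare widths
#'
#' Combines TATA-scan hits and CpG-island overlap into the classes
#' `TATA-only`, `CpG-only`, `both`, `neither`, and reports a Welch
#' two-sample t statistic comparing TATA-only vs CpG-only peak widths.
#'
#' @param peaks Peak table.
#' @param tata_hits Output of [scan_tata_motif()].
#' @param cpg CpG island table (`chrom`, `start`, `end`).
#' @return List with `classes` (`data.table`: `peak`, `has_tata`,
#'   `has_cpg`, `arch_class`, `width`) and `width_test` (list: `t`,
#'   `df`, `p_value`, `widths_tata_only`, `widths_cpg_only`; `t` is
#'   negative when TATA-only peaks are narrower).
#' @export
classify_promoter_architecture <- function(peaks, tata_hits, cpg) {
  pk <- as.data.table(peaks)
  th <- as.data.table(tata_hits)
  has_tata <- th$has_tata[match(pk$name, th$peak)]
  has_tata[is.na(has_tata)] <- FALSE
  cpg <- as.data.table(cpg)
  has_cpg <- vapply(seq_len(nrow(pk)), function(i) {
    nrow(cpg) > 0L && any(cpg$chrom == pk$chrom[i] &
                            cpg$start < pk$end[i] & cpg$end > pk$start[i])
  }, logical(1))
  arch <- ifelse(has_tata & has_cpg, "both",
                 ifelse(has_tata, "TATA-only",
                        ifelse(has_cpg, "CpG-only", "neither")))
  classes <- data.table(peak = pk$name, has_tata = has_tata,
                        has_cpg = has_cpg, arch_class = arch,
                        width = pk$end - pk$start)
  wt <- classes[arch_class == "TATA-only", width]
  wc <- classes[arch_class == "CpG-only", width]
  width_test <- list(t = NA_real_, df = NA_real_, p_value = NA_real_,
                     widths_tata_only = wt, widths_cpg_only = wc)
  if (length(wt) >= 2L && length(wc) >= 2L) {
    tt <- tryCatch(stats::t.test(wt, wc),   # Welch by default
                   error = function(e) NULL) # both groups constant
    if (!is.null(tt)) {
      width_test$t <- unname(tt$statistic)
      width_test$df <- unname(tt$parameter)
      width_test$p_value <- tt$p.value
    }
  }
  list(classes = classes, width_test = width_test)
}
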