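# Independent brute-force oracles. These deliberately share no code
# with the implementation: per-base loops, O(n*m) scans, direct
# enumeration.

# map one base through one chain, walking blocks base by base
oracle_map_base <- function(ch, p) {
  t0 <- ch$t_start; q0 <- ch$q_start
  for (k in seq_len(nrow(ch$blocks))) {
    sz <- ch$blocks$size[k]
    if (p >= t0 && p < t0 + sz) {
      q <- q0 + (p - t0)
      if (ch$q_strand == "-") q <- ch$q_size - 1L - q
      return(q)
    }
    t0 <- t0 + sz + ch$blocks$dt[k]
    q0 <- q0 + sz + ch$blocks$dq[k]
  }
  NA_integer_
}

# full brute-force interval projection (chain choice by descending score)
oracle_project <- function(chrom, s, e, strand, chains, min_match = 0.95) {
  scores <- vapply(chains, `[[`, numeric(1), "score")
  for (ci in order(scores, decreasing = TRUE)) {
    ch <- chains[[ci]]
    if (ch$t_name != chrom) next
    mp <- vapply(s:(e - 1), function(p) oracle_map_base(ch, p), integer(1))
    if (sum(!is.na(mp)) / (e - s) >= min_match && any(!is.na(mp))) {
      d_strand <- if (ch$q_strand == "-") setdiff(c("+", "-"), strand)
        else strand
      return(list(chrom = ch$q_name, start = min(mp, na.rm = TRUE),
                  end = max(mp, na.rm = TRUE) + 1L, strand = d_strand))
    }
  }
  NULL
}

# O(n*m) stranded overlap of peaks against TSS windows
oracle_associate <- function(peaks, models, window_half = 500) {
  hits <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(models))) {
      if (peaks$chrom[i] != models$chrom[j]) next
      if (peaks$strand[i] != models$strand[j]) next
      w_lo <- models$tss[j] - window_half
      w_hi <- models$tss[j] + window_half
      if (peaks$start[i] < w_hi && peaks$end[i] > w_lo) {
        hits[[length(hits) + 1L]] <- data.frame(
          peak = peaks$name[i], transcript_id = models$transcript_id[j])
      }
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(peak = character(), transcript_id = character())
}

# brute sliding-window CpG island detector on a plain string
oracle_cpg <- function(seq_char, min_len = 200, min_gc = 0.5,
                       min_obs_exp = 0.6) {
  chars <- strsplit(seq_char, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < min_len) return(data.frame(start = integer(), end = integer()))
  ok <- logical(n - min_len + 1)
  for (s in seq_len(n - min_len + 1)) {
    win <- chars[s:(s + min_len - 1)]
    nc <- sum(win == "C"); ng <- sum(win == "G")
    ncpg <- sum(win[-min_len] == "C" & win[-1] == "G")
    gc <- (nc + ng) / min_len
    oe <- if (nc * ng > 0) ncpg * min_len / (nc * ng) else 0
    ok[s] <- gc >= min_gc && oe >= min_obs_exp
  }
  if (!any(ok)) return(data.frame(start = integer(), end = integer()))
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  out <- data.frame(start = integer(), end = integer())
  for (j in which(r$values)) {
    out <- rbind(out, data.frame(start = starts[j] - 1L,
                                 end = ends[j] - 1L + min_len))
  }
  out
}
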