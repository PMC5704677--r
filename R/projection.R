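# Cross-assembly interval projection through UCSC chains (liftOver-style
# block-walk), chain inversion, expression filtering, and 50 bp boundary
# matching of projected peaks against destination peaks.

#' Project stranded intervals through chain maps
#'
#' Each interval is walked through candidate chains on its chromosome in
#' decreasing score order; it maps through the first chain on whose
#' aligned blocks at least `min_match` of its bases land. The projected
#' interval is `[min, max + 1)` of the mapped destination bases; when
#' the chain's query strand is `"-"`, destination coordinates are
#' converted to the plus strand and the interval strand is flipped.
#'
#' @param intervals Table with columns `chrom`, `start`, `end`, `strand`
#'   (and optionally `name`, carried through).
#' @param chains List of [chain_map()] objects.
#' @param min_match Minimum fraction of bases that must map (default
#'   0.95, the liftOver default).
#' @return `data.table` with the input columns plus `status`
#'   (`"mapped"`, `"partial"` or `"no chain"`), `dest_chrom`,
#'   `dest_start`, `dest_end`, `dest_strand`, `chain_id`,
#'   `mapped_fraction`.
#' @export
project_intervals <- function(intervals, chains, min_match = 0.95) {
  iv <- as.data.table(intervals)
  n <- nrow(iv)
  res <- data.table(status = rep("no chain", n),
                    dest_chrom = NA_character_, dest_start = NA_integer_,
                    dest_end = NA_integer_, dest_strand = NA_character_,
                    chain_id = NA_integer_, mapped_fraction = 0)
  if (n == 0L) return(cbind(iv, res))
  scores <- vapply(chains, `[[`, numeric(1), "score")
  ord <- order(scores, decreasing = TRUE)
  for (i in seq_len(n)) {
    a <- iv$start[i]; b <- iv$end[i]
    touched <- FALSE
    for (ci in ord) {
      ch <- chains[[ci]]
      if (ch$t_name != iv$chrom[i]) next
      if (ch$t_end <= a || ch$t_start >= b) next
      touched <- TRUE
      blk <- ch$blocks
      t0 <- ch$t_start; q0 <- ch$q_start
      mapped <- 0L; qlo <- NA_integer_; qhi <- NA_integer_
      for (k in seq_len(nrow(blk))) {
        sz <- blk$size[k]
        o_lo <- max(a, t0); o_hi <- min(b, t0 + sz)
        if (o_hi > o_lo) {
          mapped <- mapped + (o_hi - o_lo)
          m_lo <- q0 + (o_lo - t0); m_hi <- q0 + (o_hi - t0)
          qlo <- if (is.na(qlo)) m_lo else min(qlo, m_lo)
          qhi <- if (is.na(qhi)) m_hi else max(qhi, m_hi)
        }
        t0 <- t0 + sz + blk$dt[k]
        q0 <- q0 + sz + blk$dq[k]
        if (t0 >= b) break
      }
      frac <- mapped / (b - a)
      if (frac >= min_match && mapped > 0L) {
        if (ch$q_strand == "+") {
          d_start <- qlo; d_end <- qhi; d_strand <- iv$strand[i]
        } else {
          d_start <- ch$q_size - qhi; d_end <- ch$q_size - qlo
          d_strand <- if (iv$strand[i] == "+") "-" else "+"
        }
        res[i, `:=`(status = "mapped", dest_chrom = ch$q_name,
                    dest_start = as.integer(d_start),
                    dest_end = as.integer(d_end),
                    dest_strand = d_strand, chain_id = ch$id,
                    mapped_fraction = frac)]
        break
      } else if (frac > res$mapped_fraction[i]) {
        res[i, mapped_fraction := frac]
      }
    }
    if (res$status[i] != "mapped" && touched) res[i, status := "partial"]
  }
  cbind(iv, res)
}

#' Invert a chain map (swap source and destination assemblies)
#'
#' Projection through `invert_chain(ch)` undoes projection through `ch`
#' for fully aligned intervals, including chains whose query strand is
#' `"-"`.
#'
#' @param ch A [chain_map()].
#' @return A [chain_map()] in the opposite direction.
#' @export
invert_chain <- function(ch) {
  b <- ch$blocks
  k <- nrow(b)
  if (ch$q_strand == "+") {
    blocks <- data.table(size = b$size, dt = b$dq, dq = b$dt)
    chain_map(score = ch$score,
              t_name = ch$q_name, t_size = ch$q_size,
              t_start = ch$q_start, t_end = ch$q_end,
              q_name = ch$t_name, q_size = ch$t_size, q_strand = "+",
              q_start = ch$t_start, q_end = ch$t_end,
              id = ch$id, blocks = blocks)
  } else {
    rev_idx <- rev(seq_len(k))
    # gap after new block i is the gap between old blocks (k-i) and (k-i+1)
    new_dt <- c(rev(b$dq[-k]), 0L)
    new_dq <- c(rev(b$dt[-k]), 0L)
    blocks <- data.table(size = b$size[rev_idx], dt = new_dt, dq = new_dq)
    chain_map(score = ch$score,
              t_name = ch$q_name, t_size = ch$q_size,
              t_start = ch$q_size - ch$q_end,
              t_end = ch$q_size - ch$q_start,
              q_name = ch$t_name, q_size = ch$t_size, q_strand = "-",
              q_start = ch$t_size - ch$t_end,
              q_end = ch$t_size - ch$t_start,
              id = ch$id, blocks = blocks)
  }
}

#' Filter a peak set to those expressed in matching samples
#'
#' Keeps peaks whose expression is at least `min_tpm` (and nonzero) in
#' at least one of the matching samples.
#'
#' @param peaks Peak table with a `name` column.
#' @param expression Matrix (rownames = peak names, colnames = samples).
#' @param matching_samples Columns to inspect; unknown labels error.
#' @param min_tpm Expression threshold (default 1).
#' @return Subset of `peaks`.
#' @export
filter_expressed <- function(peaks, expression, matching_samples,
                             min_tpm = 1) {
  missing <- setdiff(matching_samples, colnames(expression))
  if (length(missing)) {
    stop("unknown sample label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pk <- as.data.table(peaks)
  sub <- expression[, matching_samples, drop = FALSE]
  keep_names <- rownames(sub)[apply(sub, 1L, function(x) {
    any(x >= min_tpm & x > 0)
  })]
  pk[name %in% keep_names]
}

#' Match projected peaks to destination peaks (50 bp boundary rule)
#'
#' A projected source peak matches a destination peak iff they are on
#' the same chromosome and strand and both boundary shifts satisfy
#' `|dest.start - proj.start| <= max_dist` and
#' `|dest.end - proj.end| <= max_dist`. Among several candidates the one
#' minimising `|d_start| + |d_end|` wins; ties go to the leftmost
#' destination start.
#'
#' @param projected Output of [project_intervals()] run on source peaks
#'   (must contain a `name` column for the source peak).
#' @param dest_peaks Destination peak table.
#' @param max_dist Boundary tolerance in bp (default 50).
#' @return `data.table` with columns `source_peak`, `dest_chrom`,
#'   `dest_start`, `dest_end`, `dest_strand`, `dest_peak` (`NA` when
#'   unmatched), `d_start`, `d_end`.
#' @export
match_projected_peaks <- function(projected, dest_peaks, max_dist = 50) {
  pr <- as.data.table(projected)[status == "mapped"]
  dp <- as.data.table(dest_peaks)
  empty <- data.table(source_peak = character(), dest_chrom = character(),
                      dest_start = integer(), dest_end = integer(),
                      dest_strand = character(), dest_peak = character(),
                      d_start = integer(), d_end = integer())
  if (nrow(pr) == 0L) return(empty)
  res <- lapply(seq_len(nrow(pr)), function(i) {
    cand <- dp[chrom == pr$dest_chrom[i] & strand == pr$dest_strand[i]]
    row <- data.table(source_peak = pr$name[i],
                      dest_chrom = pr$dest_chrom[i],
                      dest_start = pr$dest_start[i],
                      dest_end = pr$dest_end[i],
                      dest_strand = pr$dest_strand[i],
                      dest_peak = NA_character_,
                      d_start = NA_integer_, d_end = NA_integer_)
    if (nrow(cand) == 0L) return(row)
    ds <- abs(cand$start - pr$dest_start[i])
    de <- abs(cand$end - pr$dest_end[i])
    ok <- ds <= max_dist & de <= max_dist
    if (!any(ok)) return(row)
    cand <- cand[ok]; ds <- ds[ok]; de <- de[ok]
    o <- order(ds + de, cand$start)
    row$dest_peak <- cand$name[o[1]]
    row$d_start <- as.integer(ds[o[1]])
    row$d_end <- as.integer(de[o[1]])
    row
  })
  rbindlist(res)
}
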