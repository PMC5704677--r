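# Shared fixture builders. Everything is constructed in code; no data
# files ship with the tests.

# quick CTSS profile from parallel vectors
prof <- function(chrom, pos, strand, count) {
  ctss_profile(chrom, pos, strand, count)
}

# a library whose total_tags is padded to `total` by a far-away filler
# position (so single-position tpm values can be dialled exactly)
lib_with_total <- function(sample_id, chrom, pos, strand, count, total) {
  filler <- total - sum(count)
  stopifnot(filler >= 0)
  if (filler > 0) {
    chrom <- c(chrom, "chrFill")
    pos <- c(pos, 0L)
    strand <- c(strand, "+")
    count <- c(count, filler)
  }
  sample_library(sample_id, prof(chrom, pos, strand, count))
}

# one-chain helper
one_chain <- function(blocks, t_name = "src", q_name = "dst",
                      t_size = 10000L, q_size = NULL, t_start = 0L,
                      q_start = 0L, q_strand = "+", score = 100,
                      id = 1L) {
  blocks <- as.data.frame(blocks)
  t_span <- sum(blocks$size) + sum(blocks$dt)
  q_span <- sum(blocks$size) + sum(blocks$dq)
  if (is.null(q_size)) q_size <- q_start + q_span
  chain_map(score = score, t_name = t_name, t_size = t_size,
            t_start = t_start, t_end = t_start + t_span,
            q_name = q_name, q_size = q_size, q_strand = q_strand,
            q_start = q_start, q_end = q_start + q_span,
            id = id, blocks = blocks)
}

# small simulated world used by several files (kept light)
small_config <- function(seed = 11, n_promoters = 10L, ...) {
  simulation_config(seed = seed, n_chroms = 2L, chrom_length = 15000L,
                    n_promoters = n_promoters, n_samples = 4L,
                    n_replicate_groups = 2L,
                    mean_expression = list(meanlog = log(150), sdlog = 1),
                    ...)
}
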