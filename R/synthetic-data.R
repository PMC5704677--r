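# Seeded synthetic fixtures: a pair of related toy genomes linked by a
# chain (indels + an optional strand flip), gene models with distinct
# transcription vs coding starts, sharp (TATA) and broad (CpG) promoters,
# replicate CTSS libraries with negative-binomial noise, a "reference
# species" peak set with expression, and engineered rescue candidates.
# Everything downstream of one seed is deterministic.

#' Simulation configuration
#'
#' Defaults describe the world the package's tests assume: two 50 kb
#' chromosomes, 40 promoters (half sharp, half broad), 6 samples in 2
#' replicate groups, log-normal promoter means with negative-binomial
#' replicate noise, sparse uniform background, and a destination genome
#' derived from the source by scattered small indels plus one
#' reverse-complemented chromosome.
#'
#' @param seed Integer RNG seed.
#' @param n_chroms,chrom_length Number and length (bp) of source
#'   chromosomes.
#' @param n_promoters Total promoters, spread across chromosomes.
#' @param fraction_sharp Fraction of sharp (TATA) promoters; the rest
#'   are broad (CpG).
#' @param n_samples,n_replicate_groups Destination CAGE samples and the
#'   number of replicate groups ("cell types") they split into.
#' @param mean_expression List `meanlog`, `sdlog`: log-normal
#'   distribution of per-promoter mean tag counts.
#' @param group_sdlog SD (log scale) of per-group expression
#'   multipliers (cell-type effects).
#' @param dispersion Negative-binomial size parameter for replicate
#'   noise. The default (40) is calibrated so that promoter-level
#'   Spearman correlation between replicates sits around 0.97, the
#'   reproducibility level reported for real CAGE replicates.
#' @param noise_rate Background tag rate per bp per sample.
#' @param chain_edit_rate Indel density (events per bp) between the two
#'   genomes.
#' @param frac_orf_like Fraction of genes whose transcription start
#'   equals the coding start.
#' @param frac_unannotated Fraction of destination genes whose true-TSS
#'   models are omitted from the destination annotation sets (rescue
#'   candidates); they keep a displaced ORF-like "predicted" model.
#' @param frac_source_unexpressed Fraction of source peaks expressed
#'   only in a non-matching sample (exercises the expression filter).
#' @param read_length Simulated read length (bp).
#' @param tata_distance Distance (bp) from the sharp-promoter TSS mode
#'   to the planted TATA motif start (default 35, within the 30-35 bp
#'   upstream preference window).
#' @param sharp_sd,broad_sd Positional SD (bp) of tags for the two
#'   promoter shapes.
#' @param sharp_halfspan,broad_halfspan Truncation half-width (bp) of
#'   the two shapes.
#' @param flip_chrom Index of the chromosome whose destination copy is
#'   reverse-complemented (0 = none).
#' @param source_sets Labels of the pseudo annotation sets.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_chroms = 2L,
                              chrom_length = 50000L, n_promoters = 40L,
                              fraction_sharp = 0.5, n_samples = 6L,
                              n_replicate_groups = 2L,
                              mean_expression = list(meanlog = log(300),
                                                     sdlog = 1.2),
                              group_sdlog = 0.8, dispersion = 40,
                              noise_rate = 1e-4, chain_edit_rate = 5e-4,
                              frac_orf_like = 0.3,
                              frac_unannotated = 0.15,
                              frac_source_unexpressed = 0.1,
                              read_length = 25L, tata_distance = 35L,
                              sharp_sd = 2, broad_sd = 25,
                              sharp_halfspan = 5L, broad_halfspan = 75L,
                              flip_chrom = 2L,
                              source_sets = c("ensembl", "refseq",
                                              "augustus")) {
  cfg <- as.list(environment())
  fracs <- c(fraction_sharp, frac_orf_like, frac_unannotated,
             frac_source_unexpressed)
  if (any(fracs < 0 | fracs > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (noise_rate < 0 || chain_edit_rate < 0 || dispersion <= 0 ||
      group_sdlog < 0) {
    stop("rates must be non-negative and dispersion positive",
         call. = FALSE)
  }
  if (n_samples < 1L || n_replicate_groups < 1L ||
      n_replicate_groups > n_samples) {
    stop("need 1 <= n_replicate_groups <= n_samples", call. = FALSE)
  }
  if (n_promoters < 1L || n_chroms < 1L || chrom_length < 5000L) {
    stop("need >= 1 promoter and chromosomes of >= 5000 bp",
         call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

.TATA_MOTIF <- "TATAAATA"

.sample_seq <- function(n, probs) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

.revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# exact-count sampling of a logical flag over n items
.flag_exact <- function(n, frac) {
  k <- round(frac * n)
  out <- logical(n)
  if (k > 0L) out[sample.int(n, k)] <- TRUE
  out
}

# Full deterministic build of the simulated world. All public generator
# entry points delegate here so that the same config yields the same
# world regardless of which piece is requested.
.cage_world <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  L <- config$chrom_length
  nC <- config$n_chroms
  src_chroms <- paste0("schr", seq_len(nC))
  dst_chroms <- paste0("dchr", seq_len(nC))
  margin <- 2000L

  # ---- promoter / gene plan --------------------------------------------
  per_chrom <- diff(round(seq(0, config$n_promoters, length.out = nC + 1)))
  plan <- list()
  for (ci in seq_len(nC)) {
    k <- per_chrom[ci]
    if (k == 0L) next
    slot <- (L - 2L * margin) / k
    jitter_amp <- max(0, min(500, slot / 4))
    tss <- as.integer(round(margin + (seq_len(k) - 0.5) * slot +
                              stats::runif(k, -jitter_amp, jitter_amp)))
    plan[[ci]] <- data.table(chrom_idx = ci, src_chrom = src_chroms[ci],
                             src_tss = tss)
  }
  prom <- rbindlist(plan)
  n <- nrow(prom)
  prom[, `:=`(
    id = sprintf("g%03d", seq_len(n)),
    strand = sample(c("+", "-"), n, replace = TRUE),
    sharp = .flag_exact(n, config$fraction_sharp),
    mean_tags = stats::rlnorm(n, config$mean_expression$meanlog,
                              config$mean_expression$sdlog),
    orf_like = .flag_exact(n, config$frac_orf_like),
    rescue_candidate = .flag_exact(n, config$frac_unannotated),
    src_unexpressed = .flag_exact(n, config$frac_source_unexpressed),
    gene_length = pmin(15000L, pmax(2000L, as.integer(round(
      stats::rlnorm(n, log(8000), 0.4)))))
  )]
  group_factors <- matrix(stats::rlnorm(n * config$n_replicate_groups,
                                        0, config$group_sdlog),
                          nrow = n)

  # set membership (shared across species); first set holds every gene
  sets <- config$source_sets
  membership <- matrix(TRUE, nrow = n, ncol = length(sets),
                       dimnames = list(prom$id, sets))
  if (length(sets) >= 2L) {
    for (j in 2:length(sets)) {
      membership[, j] <- stats::runif(n) < stats::runif(1, 0.6, 0.9)
    }
  }

  # ---- source genome with planted TATA / CpG ---------------------------
  base_probs <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  cpg_probs <- c(A = 0.15, C = 0.35, G = 0.35, T = 0.15)
  src_seq <- character(nC)
  cpg_src <- list()
  motif_len <- nchar(.TATA_MOTIF)
  for (ci in seq_len(nC)) {
    chars <- strsplit(.sample_seq(L, base_probs), "", fixed = TRUE)[[1]]
    pp <- prom[chrom_idx == ci]
    for (i in seq_len(nrow(pp))) {
      t <- pp$src_tss[i]
      if (pp$sharp[i]) {
        if (pp$strand[i] == "+") {
          at <- t - config$tata_distance            # motif start, 0-based
          chars[(at + 1):(at + motif_len)] <-
            strsplit(.TATA_MOTIF, "", fixed = TRUE)[[1]]
        } else {
          at <- t + config$tata_distance            # 5'-most base on '-'
          rc <- strsplit(.revcomp_chr(.TATA_MOTIF), "", fixed = TRUE)[[1]]
          chars[(at - motif_len + 2):(at + 1)] <- rc
        }
      } else {
        island <- c(max(0L, t - 150L), min(L, t + 150L))
        seg <- .sample_seq(island[2] - island[1], cpg_probs)
        chars[(island[1] + 1):island[2]] <-
          strsplit(seg, "", fixed = TRUE)[[1]]
        cpg_src[[length(cpg_src) + 1L]] <-
          data.table(chrom = src_chroms[ci], start = island[1],
                     end = island[2], chrom_idx = ci)
      }
    }
    src_seq[ci] <- paste(chars, collapse = "")
  }
  cpg_src <- if (length(cpg_src)) rbindlist(cpg_src) else
    data.table(chrom = character(), start = integer(), end = integer(),
               chrom_idx = integer())

  # ---- edits, destination genome, chains -------------------------------
  events <- vector("list", nC)   # per chrom: pos, size, type
  dest_seq <- character(nC)
  dest_len <- integer(nC)
  chains <- list()
  for (ci in seq_len(nC)) {
    n_ev <- stats::rpois(1, L * config$chain_edit_rate)
    ev <- data.table(pos = integer(), size = integer(), type = character())
    if (n_ev > 0L) {
      cand <- sort(sample.int(L - 400L, n_ev) + 200L)
      # keep events clear of TSS neighbourhoods and of each other
      tss_here <- prom[chrom_idx == ci, src_tss]
      ok <- vapply(cand, function(p) {
        all(abs(p - tss_here) > 200L)
      }, logical(1))
      cand <- cand[ok]
      if (length(cand) > 1L) {
        keep <- c(TRUE, diff(cand) >= 300L)
        cand <- cand[keep]
      }
      if (length(cand) > 0L) {
        ev <- data.table(pos = cand,
                         size = sample.int(10L, length(cand),
                                           replace = TRUE),
                         type = sample(c("del", "ins"), length(cand),
                                       replace = TRUE))
      }
    }
    events[[ci]] <- ev
    # build edited sequence + chain blocks
    pieces <- character()
    sizes <- integer(); dts <- integer(); dqs <- integer()
    t_cur <- 0L
    src <- src_seq[ci]
    for (i in seq_len(nrow(ev))) {
      blk <- ev$pos[i] - t_cur
      pieces <- c(pieces, substr(src, t_cur + 1L, ev$pos[i]))
      if (ev$type[i] == "del") {
        sizes <- c(sizes, blk); dts <- c(dts, ev$size[i]); dqs <- c(dqs, 0L)
        t_cur <- ev$pos[i] + ev$size[i]
      } else {
        sizes <- c(sizes, blk); dts <- c(dts, 0L); dqs <- c(dqs, ev$size[i])
        pieces <- c(pieces, .sample_seq(ev$size[i], base_probs))
        t_cur <- ev$pos[i]
      }
    }
    pieces <- c(pieces, substr(src, t_cur + 1L, L))
    sizes <- c(sizes, L - t_cur); dts <- c(dts, 0L); dqs <- c(dqs, 0L)
    if (sum(sizes) == 0L) {
      stop("chain edit rate leaves zero aligned bases on ",
           src_chroms[ci], call. = FALSE)
    }
    edited <- paste(pieces, collapse = "")
    Ld <- nchar(edited)
    dest_len[ci] <- Ld
    flipped <- ci == config$flip_chrom
    dest_seq[ci] <- if (flipped) .revcomp_chr(edited) else edited
    chains[[ci]] <- chain_map(
      score = 1000 * (nC - ci + 1), t_name = src_chroms[ci], t_size = L,
      t_start = 0L, t_end = L, q_name = dst_chroms[ci], q_size = Ld,
      q_strand = if (flipped) "-" else "+", q_start = 0L, q_end = Ld,
      id = ci, blocks = data.table(size = sizes, dt = dts, dq = dqs))
  }

  # ---- coordinate maps --------------------------------------------------
  map_pos <- function(ci, p, clamp = c("none", "up", "down")) {
    clamp <- match.arg(clamp)
    ev <- events[[ci]]
    del <- ev[type == "del"]
    ins <- ev[type == "ins"]
    in_del <- function(x) {
      nrow(del) > 0L && any(x >= del$pos & x < del$pos + del$size)
    }
    if (in_del(p)) {
      if (clamp == "none") return(NA_integer_)
      step <- if (clamp == "up") 1L else -1L
      while (in_del(p)) p <- p + step
    }
    shift <- 0L
    if (nrow(ins)) shift <- shift + sum(ins$size[ins$pos <= p])
    if (nrow(del)) shift <- shift - sum(del$size[del$pos + del$size <= p])
    p + shift
  }
  # edited-orientation -> final dest plus-strand
  flip_pos <- function(ci, p) {
    if (ci == config$flip_chrom) dest_len[ci] - 1L - p else p
  }
  flip_interval <- function(ci, s, e) {
    if (ci == config$flip_chrom) c(dest_len[ci] - e, dest_len[ci] - s)
    else c(s, e)
  }
  dest_pos <- function(ci, p, clamp = "up") {
    flip_pos(ci, map_pos(ci, p, clamp))
  }
  dest_interval <- function(ci, s, e) {
    s2 <- map_pos(ci, s, "up")
    e2 <- map_pos(ci, e - 1L, "down") + 1L
    flip_interval(ci, s2, e2)
  }
  dest_strand <- function(ci, strand) {
    if (ci == config$flip_chrom) c(`+` = "-", `-` = "+")[[strand]]
    else strand
  }

  prom[, dst_chrom := dst_chroms[chrom_idx]]
  prom[, dst_tss := vapply(seq_len(.N), function(i)
    dest_pos(chrom_idx[i], src_tss[i]), integer(1))]
  prom[, dst_strand := vapply(seq_len(.N), function(i)
    dest_strand(chrom_idx[i], strand[i]), character(1))]

  # ---- gene models ------------------------------------------------------
  gene_span <- function(tss, strand, len, L_chrom) {
    if (strand == "+") c(tss, min(tss + len, L_chrom))
    else c(max(0L, tss - len + 1L), tss + 1L)
  }
  cds_offset <- as.integer(round(stats::runif(n, 150, 600)))
  src_models <- list()
  dst_models <- list()
  for (i in seq_len(n)) {
    sp <- gene_span(prom$src_tss[i], prom$strand[i], prom$gene_length[i], L)
    off <- if (prom$orf_like[i]) 0L else cds_offset[i]
    if (prom$strand[i] == "+") {
      cds <- c(sp[1] + off, sp[2] - 200L)
    } else {
      cds <- c(sp[1] + 200L, sp[2] - off)
    }
    src_models[[i]] <- data.table(
      chrom = prom$src_chrom[i], tx_start = sp[1], tx_end = sp[2],
      strand = prom$strand[i], gene_id = paste0("S", prom$id[i]),
      transcript_id = paste0("S", prom$id[i], ".t1"),
      cds_start = cds[1], cds_end = cds[2],
      tss = prom$src_tss[i], source_set = NA_character_,
      exon_starts = list(sp[1]), exon_ends = list(sp[2]))
    ci <- prom$chrom_idx[i]
    dsp <- dest_interval(ci, sp[1], sp[2])
    dcds <- dest_interval(ci, cds[1], cds[2])
    dst_models[[i]] <- data.table(
      chrom = prom$dst_chrom[i], tx_start = dsp[1], tx_end = dsp[2],
      strand = prom$dst_strand[i], gene_id = paste0("D", prom$id[i]),
      transcript_id = paste0("D", prom$id[i], ".t1"),
      cds_start = dcds[1], cds_end = dcds[2],
      tss = prom$dst_tss[i], source_set = NA_character_,
      exon_starts = list(dsp[1]), exon_ends = list(dsp[2]))
  }
  src_models <- rbindlist(src_models)
  dst_models <- rbindlist(dst_models)

  per_set <- function(models, set_j, drop_candidates) {
    keep <- membership[, set_j]
    if (drop_candidates) keep <- keep & !prom$rescue_candidate
    m <- models[keep]
    m[, source_set := sets[set_j]]
    m
  }
  src_annotation <- rbindlist(lapply(seq_along(sets), function(j)
    per_set(copy(src_models), j, FALSE)))
  dst_annotation <- rbindlist(lapply(seq_along(sets), function(j)
    per_set(copy(dst_models), j, TRUE)))

  # displaced ORF-like "predicted" models for rescue candidates: the gene
  # exists near the peak (within 10 kb) but its annotated TSS is the ORF
  # start, > 1 kb downstream, so the peak cannot associate with it
  displacement <- as.integer(round(stats::runif(n, 2000, 6000)))
  pred_rows <- which(prom$rescue_candidate)
  dst_predicted <- rbindlist(lapply(pred_rows, function(i) {
    ci <- prom$chrom_idx[i]
    Ld <- dest_len[ci]
    if (prom$dst_strand[i] == "+") {
      s <- min(prom$dst_tss[i] + displacement[i], Ld - 1000L)
      e <- min(s + prom$gene_length[i], Ld)
    } else {
      e <- max(prom$dst_tss[i] - displacement[i] + 1L, 1000L)
      s <- max(e - prom$gene_length[i], 0L)
    }
    data.table(chrom = prom$dst_chrom[i], tx_start = s, tx_end = e,
               strand = prom$dst_strand[i],
               gene_id = paste0("D", prom$id[i]),
               transcript_id = paste0("D", prom$id[i], ".orf"),
               cds_start = if (prom$dst_strand[i] == "+") s else s + 100L,
               cds_end = if (prom$dst_strand[i] == "+") e - 100L else e,
               tss = if (prom$dst_strand[i] == "+") s else e - 1L,
               source_set = "predicted",
               exon_starts = list(s), exon_ends = list(e))
  }))
  if (nrow(dst_predicted) == 0L) {
    dst_predicted <- dst_annotation[0]
  }

  orthology <- data.table(source_gene = paste0("S", prom$id),
                          dest_gene = paste0("D", prom$id))

  # CpG islands on the destination
  cpg_dst <- if (nrow(cpg_src)) {
    rbindlist(lapply(seq_len(nrow(cpg_src)), function(i) {
      ci <- cpg_src$chrom_idx[i]
      iv <- dest_interval(ci, cpg_src$start[i], cpg_src$end[i])
      data.table(chrom = dst_chroms[ci], start = iv[1], end = iv[2])
    }))
  } else data.table(chrom = character(), start = integer(),
                    end = integer())

  # ---- TATA frequency matrix -------------------------------------------
  consensus <- strsplit(.TATA_MOTIF, "", fixed = TRUE)[[1]]
  pwm <- matrix(0.04, nrow = 4, ncol = motif_len,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(motif_len)) pwm[consensus[j], j] <- 0.88

  # ---- source ("reference species") peak set ---------------------------
  src_peak_halfwidth <- ifelse(prom$sharp, 2L, 25L)
  src_peaks <- data.table(
    chrom = prom$src_chrom,
    start = prom$src_tss - src_peak_halfwidth,
    end = prom$src_tss + src_peak_halfwidth + 1L,
    strand = prom$strand)
  src_peaks[, name := cage_name(chrom, start, end, strand)]
  groups <- paste0("grp", seq_len(config$n_replicate_groups))
  ref_cols <- c(paste0(groups, "_ref"), "other_ref")
  src_expr <- matrix(0, nrow = n, ncol = length(ref_cols),
                     dimnames = list(src_peaks$name, ref_cols))
  for (i in seq_len(n)) {
    tpm_like <- prom$mean_tags[i]
    if (prom$src_unexpressed[i]) {
      src_expr[i, "other_ref"] <- tpm_like
    } else {
      src_expr[i, seq_along(groups)] <- tpm_like *
        group_factors[i, seq_along(groups)]
    }
  }

  # ---- CTSS / SAM simulation on the destination ------------------------
  sample_group <- rep(seq_len(config$n_replicate_groups),
                      length.out = config$n_samples)
  sample_group <- sort(sample_group)
  sample_ids <- unlist(lapply(seq_len(config$n_replicate_groups),
                              function(g) {
    paste0("grp", g, "_rep", seq_len(sum(sample_group == g)))
  }))
  rl <- config$read_length
  profiles <- list()
  sam_lines <- list()
  truth_tags <- list()
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", dst_chroms, dest_len))
  for (s in seq_len(config$n_samples)) {
    g <- sample_group[s]
    tag_chrom <- character(); tag_pos <- integer(); tag_strand <- character()
    for (i in seq_len(n)) {
      mu <- prom$mean_tags[i] * group_factors[i, g]
      ntags <- stats::rnbinom(1, size = config$dispersion, mu = mu)
      if (ntags == 0L) next
      sd_i <- if (prom$sharp[i]) config$sharp_sd else config$broad_sd
      half <- if (prom$sharp[i]) config$sharp_halfspan else
        config$broad_halfspan
      off <- as.integer(round(stats::rnorm(ntags, 0, sd_i)))
      off <- pmin(pmax(off, -half), half)
      tag_chrom <- c(tag_chrom, rep(prom$dst_chrom[i], ntags))
      tag_pos <- c(tag_pos, prom$dst_tss[i] + off)
      tag_strand <- c(tag_strand, rep(prom$dst_strand[i], ntags))
    }
    # uniform background
    total_len <- sum(dest_len)
    nbg <- stats::rpois(1, total_len * config$noise_rate)
    if (nbg > 0L) {
      ci <- sample.int(nC, nbg, replace = TRUE, prob = dest_len / total_len)
      bgpos <- as.integer(rl + floor(stats::runif(nbg) *
                                       (dest_len[ci] - 2L * rl)))
      tag_chrom <- c(tag_chrom, dst_chroms[ci])
      tag_pos <- c(tag_pos, bgpos)
      tag_strand <- c(tag_strand, sample(c("+", "-"), nbg, replace = TRUE))
    }
    if (length(tag_pos) == 0L) {
      stop("sample ", sample_ids[s], " has zero library size; raise ",
           "mean_expression or noise_rate", call. = FALSE)
    }
    ord <- order(tag_chrom, tag_pos, tag_strand)
    tag_chrom <- tag_chrom[ord]; tag_pos <- tag_pos[ord]
    tag_strand <- tag_strand[ord]
    profiles[[sample_ids[s]]] <- ctss_profile(tag_chrom, tag_pos,
                                              tag_strand,
                                              rep(1L, length(tag_pos)))
    flag <- ifelse(tag_strand == "+", 0L, 16L)
    pos1 <- ifelse(tag_strand == "+", tag_pos + 1L, tag_pos - rl + 2L)
    good <- sprintf("%s_r%06d\t%d\t%s\t%d\t30\t%dM\t*\t0\t0\t*\t*\tNM:i:0",
                    sample_ids[s], seq_along(tag_pos), flag, tag_chrom,
                    pos1, rl)
    # records that must be discarded by the quality filters
    bad <- c(
      sprintf("%s_badq\t0\t%s\t101\t15\t%dM\t*\t0\t0\t*\t*\tNM:i:0",
              sample_ids[s], dst_chroms[1], rl),
      sprintf("%s_badf\t256\t%s\t201\t30\t%dM\t*\t0\t0\t*\t*\tNM:i:0",
              sample_ids[s], dst_chroms[1], rl),
      sprintf("%s_badnm\t0\t%s\t301\t30\t%dM\t*\t0\t0\t*\t*\tNM:i:6",
              sample_ids[s], dst_chroms[1], rl))
    sam_lines[[sample_ids[s]]] <- c(header, good, bad)
    truth_tags[[sample_ids[s]]] <- length(tag_pos)
  }

  list(config = config,
       src_chroms = src_chroms, dst_chroms = dst_chroms,
       source_seq = Biostrings::DNAStringSet(
         stats::setNames(src_seq, src_chroms)),
       dest_seq = Biostrings::DNAStringSet(
         stats::setNames(dest_seq, dst_chroms)),
       dest_len = dest_len,
       chains = chains, events = events,
       promoters = prom[], group_factors = group_factors,
       src_models = src_annotation, dst_models = dst_annotation,
       dst_predicted = dst_predicted,
       orthology = orthology,
       cpg_src = cpg_src[, .(chrom, start, end)], cpg_dst = cpg_dst,
       pwm = pwm,
       src_peaks = src_peaks, src_expr = src_expr,
       sample_ids = sample_ids, sample_group = sample_group,
       profiles = profiles, sam_lines = sam_lines,
       n_tags = unlist(truth_tags))
}

#' Generate the toy genome pair, chain and orthology table
#'
#' @param config A [simulation_config()].
#' @return List with `source` and `dest` (`DNAStringSet`s), `chains`
#'   (list of [chain_map()]), `orthology` and the per-chromosome edit
#'   tables (`events`).
#' @export
generate_genome_pair <- function(config) {
  w <- .cage_world(config)
  list(source = w$source_seq, dest = w$dest_seq, chains = w$chains,
       orthology = w$orthology, events = w$events)
}

#' Generate gene models, CpG islands, TATA PWM and the reference peak set
#'
#' @param config A [simulation_config()].
#' @return List: `source_models` / `dest_models` (annotation tables over
#'   all pseudo sets; rescue-candidate genes are absent from every
#'   destination set), `dest_predicted` (displaced ORF-like models of
#'   the candidates), `cpg_source` / `cpg_dest`, `pwm`, `source_peaks`,
#'   `source_expression`, `promoters` (the ground-truth plan).
#' @export
generate_gene_models <- function(config) {
  w <- .cage_world(config)
  list(source_models = w$src_models, dest_models = w$dst_models,
       dest_predicted = w$dst_predicted, cpg_source = w$cpg_src,
       cpg_dest = w$cpg_dst, pwm = w$pwm, source_peaks = w$src_peaks,
       source_expression = w$src_expr, promoters = w$promoters)
}

#' Simulate replicate CTSS profiles and the matching SAM streams
#'
#' @param config A [simulation_config()].
#' @return List: `libraries` (list of [sample_library()]), `sam_lines`
#'   (per sample, SAM text lines whose quality-filtered CTSS equals the
#'   library profile), `sample_groups`, `truth` (promoter plan).
#' @export
simulate_ctss_profiles <- function(config) {
  w <- .cage_world(config)
  libraries <- lapply(w$sample_ids, function(sid) {
    sample_library(sid, w$profiles[[sid]])
  })
  names(libraries) <- w$sample_ids
  list(libraries = libraries, sam_lines = w$sam_lines,
       sample_groups = stats::setNames(w$sample_group, w$sample_ids),
       truth = w$promoters)
}

#' Write the full fixture bundle to a directory
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list of all written paths plus the in-memory
#'   world pieces.
#' @export
make_cage_fixtures <- function(config, dir) {
  w <- .cage_world(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(w$source_seq, p("source.fa"))
  Biostrings::writeXStringSet(w$dest_seq, p("dest.fa"))
  write_chain_file(w$chains, p("src_to_dest.chain"))
  utils::write.table(w$orthology, p("orthology.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  for (set in unique(w$src_models$source_set)) {
    write_gene_models(w$src_models[w$src_models$source_set == set, ],
                      p(sprintf("source_genes_%s.bed", set)))
    write_gene_models(w$dst_models[w$dst_models$source_set == set, ],
                      p(sprintf("dest_genes_%s.bed", set)))
  }
  if (nrow(w$dst_predicted)) {
    write_gene_models(w$dst_predicted, p("dest_genes_predicted.bed"))
  }
  write_bed(w$cpg_src, p("cpg_islands_source.bed"))
  write_bed(w$cpg_dst, p("cpg_islands_dest.bed"))
  write_pwm(w$pwm, p("tata.pwm"))
  src_pk <- data.table(chrom = w$src_peaks$chrom,
                       start = w$src_peaks$start, end = w$src_peaks$end,
                       name = w$src_peaks$name, score = 0L,
                       strand = w$src_peaks$strand)
  write_bed(src_pk, p("source_peaks.bed"))
  write_expression_matrix(w$src_expr, p("source_expression.tsv"))
  for (sid in w$sample_ids) {
    write_ctss_bed(w$profiles[[sid]], p(sprintf("ctss_%s.bed", sid)))
    writeLines(w$sam_lines[[sid]], p(sprintf("%s.sam", sid)))
  }
  truth <- list(
    promoters = as.data.frame(w$promoters),
    sample_groups = as.list(stats::setNames(w$sample_group, w$sample_ids)),
    seed = config$seed)
  jsonlite::write_json(truth, p("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(list(dir = dir, world = w)))
}
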