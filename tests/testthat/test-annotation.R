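test_that("association follows the 1 kb centred window, same strand", {
  models <- data.frame(chrom = "c1", tx_start = 1000L, tx_end = 6000L,
                       strand = "+", gene_id = "g1",
                       transcript_id = "g1.t1", cds_start = 1200L,
                       cds_end = 5800L, tss = 1000L,
                       source_set = "ensembl")
  pk <- function(start, end, strand = "+") {
    data.frame(chrom = "c1", start = start, end = end, strand = strand,
               name = cage_name("c1", start, end, strand))
  }
  # window is [500, 1500): peak [490,510) overlaps
  expect_equal(nrow(associate_peaks_to_genes(pk(490L, 510L), models)), 1L)
  # peak [1500,1520) misses (half-open boundary)
  expect_equal(nrow(associate_peaks_to_genes(pk(1500L, 1520L), models)), 0L)
  # peak ending exactly at the window start misses; one bp later hits
  expect_equal(nrow(associate_peaks_to_genes(pk(480L, 500L), models)), 0L)
  expect_equal(nrow(associate_peaks_to_genes(pk(480L, 501L), models)), 1L)
  # opposite strand never associates
  expect_equal(nrow(associate_peaks_to_genes(pk(990L, 1010L, "-"),
                                             models)), 0L)
  # signed distance: peak 5' end at 990 on '+' -> -10
  a <- associate_peaks_to_genes(pk(990L, 1010L), models)
  expect_equal(a$distance, -10L)
})

test_that("association sweep matches the brute-force oracle", {
  set.seed(5)
  models <- data.frame(
    chrom = sample(c("c1", "c2"), 8, TRUE),
    strand = sample(c("+", "-"), 8, TRUE),
    tss = sample(500:5000, 8), gene_id = paste0("g", 1:8),
    transcript_id = paste0("g", 1:8, ".t1"), source_set = "ensembl")
  models$tx_start <- models$tss - 100L   # only tss matters here
  models$tx_end <- models$tss + 100L
  # dense boundary sweep: a 20 bp peak sliding across one gene's window
  tss <- 2000L
  m1 <- data.frame(chrom = "c1", strand = "+", tss = tss,
                   tx_start = tss, tx_end = tss + 3000L, gene_id = "g",
                   transcript_id = "g.t1", source_set = "s")
  for (off in seq(-560, 560, by = 7)) {
    p <- data.frame(chrom = "c1", start = tss + off,
                    end = tss + off + 20L, strand = "+",
                    name = "pk")
    got <- nrow(associate_peaks_to_genes(p, m1)) == 1L
    want <- (tss + off) < (tss + 500L) && (tss + off + 20L) > (tss - 500L)
    expect_equal(got, want, info = paste("offset", off))
  }
  # random instances against the O(n*m) oracle
  for (rep in 1:5) {
    n <- 30
    peaks <- data.frame(chrom = sample(c("c1", "c2"), n, TRUE),
                        start = sample(0:5500, n),
                        strand = sample(c("+", "-"), n, TRUE))
    peaks$end <- peaks$start + sample(1:200, n, TRUE)
    peaks$name <- paste0("p", seq_len(n))
    got <- associate_peaks_to_genes(peaks, models)
    want <- oracle_associate(peaks, models)
    key <- function(d) sort(paste(d$peak, d$transcript_id))
    expect_equal(key(got), key(want))
  }
})

test_that("annotation breakdown bins by distinct sets and conserves peaks", {
  peaks <- data.frame(name = c("p1", "p2", "p3"))
  assoc <- data.frame(
    peak = c("p1", "p1", "p1", "p3"),
    source_set = c("ensembl", "refseq", "ensembl", "est"),
    gene_id = c("a", "a", "b", "c"),
    transcript_id = c("a.1", "a.1", "b.1", "c.1"), distance = 0L)
  bins <- annotation_breakdown(assoc, peaks,
                               c("ensembl", "refseq", "est"))
  expect_equal(unname(bins), c(1L, 1L, 1L, 0L))  # p2 in bin 0, p1 bin 2
  expect_equal(sum(bins), nrow(peaks))
  expect_equal(names(bins), c("0", "1", "2", "3"))
})

test_that("genomic classification follows the fixed precedence", {
  models <- data.frame(chrom = "c1", tx_start = 5000L, tx_end = 15000L,
                       strand = "+", gene_id = "g",
                       transcript_id = "g.t1", cds_start = 6000L,
                       cds_end = 14000L, tss = 5000L, source_set = "s")
  models$exon_starts <- I(list(c(5000L, 9000L)))
  models$exon_ends <- I(list(c(7000L, 15000L)))
  cpg <- data.frame(chrom = "c1", start = 20000L, end = 21000L)
  reps <- data.frame(chrom = "c1", start = c(20500L, 30000L),
                     end = c(20600L, 30100L))
  pk <- function(start, end, strand = "+") {
    data.frame(chrom = "c1", start = start, end = end, strand = strand,
               name = "x")
  }
  cls <- function(p) classify_genomic_feature(p, models, cpg, reps)
  expect_equal(cls(pk(4900L, 4950L)), "promoter")   # within 1 kb upstream
  expect_equal(cls(pk(5400L, 5450L)), "promoter")   # within 500 bp downstream
  expect_equal(cls(pk(5700L, 5750L)), "5UTR")       # past promoter window, before CDS
  expect_equal(cls(pk(9500L, 9550L)), "exon")
  expect_equal(cls(pk(8000L, 8050L)), "intron")
  expect_equal(cls(pk(15100L, 15150L)), "TTS")
  expect_equal(cls(pk(20000L, 20050L)), "CpG-island")
  expect_equal(cls(pk(20500L, 20550L)), "CpG-island") # CpG beats repeat
  expect_equal(cls(pk(30000L, 30050L)), "repeat")
  expect_equal(cls(pk(40000L, 40050L)), "intergenic")
  # gene-relative classes are strand-specific
  expect_equal(cls(pk(9500L, 9550L, "-")), "intergenic")
})

test_that("TATA scan finds planted motifs, respects strand and threshold", {
  set.seed(2)
  bg <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE,
                     prob = c(0.2, 0.3, 0.3, 0.2)), collapse = "")
  # plant consensus so the motif starts 30 bp upstream of position 1500
  s <- bg
  substr(s, 1500 - 30 + 1, 1500 - 30 + 8) <- "TATAAATA"
  genome <- Biostrings::DNAStringSet(c(chrA = s))
  pwm <- matrix(0.04, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  cons <- strsplit("TATAAATA", "")[[1]]
  for (j in 1:8) pwm[cons[j], j] <- 0.88
  pk <- data.frame(chrom = "chrA", start = 1500L, end = 1511L,
                   strand = "+", name = "p1")
  hit <- scan_tata_motif(pk, genome, pwm)
  expect_true(hit$has_tata)
  expect_equal(hit$offset, -30L)

  # strand symmetry: reverse-complement everything
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  genome_m <- Biostrings::DNAStringSet(c(chrA = rc))
  pk_m <- data.frame(chrom = "chrA", start = 3000L - 1511L,
                     end = 3000L - 1500L, strand = "-", name = "p1m")
  hit_m <- scan_tata_motif(pk_m, genome_m, pwm)
  expect_equal(hit_m$offset, hit$offset)
  expect_equal(hit_m$score, hit$score)

  # GC-rich sequence under a stringent threshold: no hit
  gc <- paste(rep("GC", 600), collapse = "")
  genome_gc <- Biostrings::DNAStringSet(c(chrB = gc))
  # window extends past the chromosome start -> truncated, with warning
  pk_gc <- data.frame(chrom = "chrB", start = 300L, end = 311L,
                      strand = "+", name = "p2")
  expect_warning(
    hit_gc <- scan_tata_motif(pk_gc, genome_gc, pwm),
    "truncated")
  expect_false(hit_gc$has_tata)
})

test_that("CpG island detection matches the brute-force window oracle", {
  set.seed(8)
  # alternating CG: maximal island
  s1 <- paste(rep("CG", 100), collapse = "")
  g1 <- Biostrings::DNAStringSet(c(c1 = s1))
  isl <- detect_cpg_islands(g1)
  expect_equal(nrow(isl), 1L)
  expect_equal(c(isl$start, isl$end), c(0L, 200L))
  # pure AT: nothing
  g2 <- Biostrings::DNAStringSet(c(c1 = paste(rep("AT", 100),
                                              collapse = "")))
  expect_equal(nrow(detect_cpg_islands(g2)), 0L)
  # random mixed sequence vs oracle (includes boundary windows)
  for (rep in 1:3) {
    s <- paste(sample(c("A", "C", "G", "T"), 800, TRUE,
                      prob = c(0.22, 0.28, 0.28, 0.22)), collapse = "")
    got <- detect_cpg_islands(Biostrings::DNAStringSet(c(cx = s)),
                              min_len = 100)
    want <- oracle_cpg(s, min_len = 100)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
  # GC exactly at the threshold is included (>=)
  s <- paste(c(rep("CGAT", 50)), collapse = "")  # GC = 0.5, obs/exp high
  got <- detect_cpg_islands(Biostrings::DNAStringSet(c(cy = s)),
                            min_len = 200)
  want <- oracle_cpg(s, min_len = 200)
  expect_equal(got$start, want$start)
  expect_gte(nrow(got), 1L)
})

test_that("architecture classes combine the two booleans; widths tested", {
  peaks <- data.frame(chrom = "c1",
                      start = c(100L, 300L, 500L, 700L, 900L, 1100L),
                      end = c(110L, 312L, 600L, 820L, 910L, 1210L),
                      strand = "+",
                      name = paste0("p", 1:6))
  tata <- data.frame(peak = paste0("p", 1:6),
                     has_tata = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
                     offset = NA_integer_, score = NA_real_)
  cpg <- data.frame(chrom = "c1", start = c(495L, 695L, 1095L),
                    end = c(610L, 830L, 1215L))
  arch <- classify_promoter_architecture(peaks, tata, cpg)
  expect_equal(arch$classes$arch_class,
               c("TATA-only", "TATA-only", "CpG-only", "CpG-only",
                 "TATA-only", "CpG-only"))
  # TATA-only widths {10,12,10}, CpG-only {100,120,110}: Welch t by hand
  wt <- c(10, 12, 10); wc <- c(100, 120, 110)
  t_hand <- (mean(wt) - mean(wc)) /
    sqrt(var(wt) / 3 + var(wc) / 3)
  expect_equal(arch$width_test$t, t_hand)
  expect_lt(arch$width_test$t, 0)
})
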