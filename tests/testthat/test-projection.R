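test_that("identity chain is a fixpoint; deletions shift coordinates", {
  ident <- one_chain(data.frame(size = 5000L, dt = 0L, dq = 0L))
  iv <- data.frame(chrom = "src", start = 100L, end = 150L, strand = "+",
                   name = "a")
  r <- project_intervals(iv, list(ident))
  expect_equal(r$status, "mapped")
  expect_equal(c(r$dest_start, r$dest_end), c(100L, 150L))
  expect_equal(r$dest_strand, "+")

  # 10 bp deleted from the destination upstream of the interval:
  # all destination coordinates shift by -10
  del <- one_chain(data.frame(size = c(500L, 4500L), dt = c(10L, 0L),
                              dq = c(0L, 0L)))
  iv <- data.frame(chrom = "src", start = 600L, end = 660L, strand = "-",
                   name = "b")
  r <- project_intervals(iv, list(del))
  expect_equal(c(r$dest_start, r$dest_end), c(590L, 650L))
  expect_equal(r$dest_strand, "-")
})

test_that("min_match gates partially aligned intervals", {
  # interval with 40% of bases in the chain gap -> unmapped("partial")
  ch <- one_chain(data.frame(size = c(100L, 100L), dt = c(40L, 0L),
                             dq = c(0L, 0L)))
  iv <- data.frame(chrom = "src", start = 60L, end = 160L, strand = "+",
                   name = "a")
  r <- project_intervals(iv, list(ch))
  expect_equal(r$status, "partial")
  expect_equal(r$mapped_fraction, 0.6)
  # the same interval passes with a permissive min_match
  r2 <- project_intervals(iv, list(ch), min_match = 0.5)
  expect_equal(r2$status, "mapped")
  # interval on a chromosome with no chain at all
  iv2 <- data.frame(chrom = "none", start = 0L, end = 10L, strand = "+",
                    name = "b")
  expect_equal(project_intervals(iv2, list(ch))$status, "no chain")
})

test_that("projection agrees with the per-base brute-force mapper", {
  set.seed(42)
  cfg <- simulation_config(seed = 5, n_promoters = 10,
                           chrom_length = 15000L, chain_edit_rate = 2e-3)
  chains <- generate_genome_pair(cfg)$chains
  # the fixture contains indels on both chromosomes and a strand flip
  expect_true(any(vapply(chains, function(c) nrow(c$blocks) > 1,
                         logical(1))))
  expect_true(any(vapply(chains, `[[`, character(1), "q_strand") == "-"))
  n <- 400
  iv <- data.frame(chrom = sample(c("schr1", "schr2"), n, TRUE),
                   start = sample(0:14800, n, TRUE),
                   strand = sample(c("+", "-"), n, TRUE))
  iv$end <- iv$start + sample(5:120, n, TRUE)
  iv$name <- paste0("i", seq_len(n))
  res <- project_intervals(iv, chains)
  for (i in seq_len(n)) {
    want <- oracle_project(iv$chrom[i], iv$start[i], iv$end[i],
                           iv$strand[i], chains)
    if (is.null(want)) {
      expect_true(res$status[i] != "mapped", info = paste("row", i))
    } else {
      expect_equal(res$status[i], "mapped", info = paste("row", i))
      expect_equal(res$dest_chrom[i], want$chrom)
      expect_equal(res$dest_start[i], want$start)
      expect_equal(res$dest_end[i], want$end)
      expect_equal(res$dest_strand[i], want$strand)
    }
  }
  # monotonicity within one chain: projected starts preserve order
  on1 <- res[res$status == "mapped" & res$chain_id == 1 &
               res$dest_strand == res$strand, ]
  o <- order(on1$start)
  expect_true(all(diff(on1$dest_start[o]) >= 0))
})

test_that("round trip through the inverted chain restores fully
           aligned intervals (both strands)", {
  set.seed(42)
  cfg <- simulation_config(seed = 5, n_promoters = 10,
                           chrom_length = 15000L, chain_edit_rate = 2e-3)
  chains <- generate_genome_pair(cfg)$chains
  inv <- lapply(chains, invert_chain)
  n <- 200
  iv <- data.frame(chrom = sample(c("schr1", "schr2"), n, TRUE),
                   start = sample(0:14800, n, TRUE),
                   strand = sample(c("+", "-"), n, TRUE))
  iv$end <- iv$start + sample(5:80, n, TRUE)
  iv$name <- paste0("i", seq_len(n))
  res <- project_intervals(iv, chains)
  # fully aligned = every base maps and the image is gap-free
  full <- res[res$status == "mapped" & res$mapped_fraction == 1 &
                (res$dest_end - res$dest_start) == (res$end - res$start), ]
  expect_gt(nrow(full), 50)
  back <- project_intervals(
    data.frame(chrom = full$dest_chrom, start = full$dest_start,
               end = full$dest_end, strand = full$dest_strand,
               name = full$name), inv)
  expect_true(all(back$status == "mapped"))
  expect_equal(back$dest_chrom, full$chrom)
  expect_equal(back$dest_start, full$start)
  expect_equal(back$dest_end, full$end)
  expect_equal(back$dest_strand, full$strand)
})

test_that("expression filter keeps matching-sample signal only", {
  peaks <- data.frame(chrom = "c", start = c(0L, 10L, 20L),
                      end = c(5L, 15L, 25L), strand = "+",
                      name = c("p1", "p2", "p3"))
  expr <- matrix(c(5, 0, 0,
                   0, 7, 0,
                   0, 0, 0.5), 3, 3, byrow = TRUE,
                 dimnames = list(c("p1", "p2", "p3"),
                                 c("match1", "other", "match2")))
  kept <- filter_expressed(peaks, expr, c("match1", "match2"))
  expect_equal(kept$name, "p1")                 # p2 only in non-matching
  kept0 <- filter_expressed(peaks, expr, c("match1", "match2"),
                            min_tpm = 0)
  expect_equal(kept0$name, c("p1", "p3"))       # any nonzero signal
  expect_error(filter_expressed(peaks, expr, "missing"), "unknown sample")
})

test_that("50 bp matching requires both boundaries within threshold", {
  dest <- data.frame(chrom = "d", start = 1000L, end = 1100L,
                     strand = "+", name = "dp", tier = "robust")
  mk_proj <- function(ds, de) {
    data.frame(chrom = "s", start = 1L, end = 2L, strand = "+",
               name = "sp", status = "mapped", dest_chrom = "d",
               dest_start = 1000L + ds, dest_end = 1100L + de,
               dest_strand = "+", chain_id = 1L, mapped_fraction = 1)
  }
  # sweep both deltas; enumeration oracle is the condition itself
  for (ds in seq(-60L, 60L, by = 12L)) {
    for (de in seq(-60L, 60L, by = 12L)) {
      m <- match_projected_peaks(mk_proj(ds, de), dest)
      expect_equal(!is.na(m$dest_peak), abs(ds) <= 50 && abs(de) <= 50,
                   info = paste(ds, de))
    }
  }
  # boundary case: exactly 50/50 matches; 51 does not
  expect_false(is.na(match_projected_peaks(mk_proj(50L, -50L),
                                           dest)$dest_peak))
  expect_true(is.na(match_projected_peaks(mk_proj(51L, 0L),
                                          dest)$dest_peak))
  # among multiple candidates the closer one wins; ties -> leftmost
  dest2 <- data.frame(chrom = "d", start = c(1000L, 1010L),
                      end = c(1100L, 1110L), strand = "+",
                      name = c("near", "far"), tier = "robust")
  m <- match_projected_peaks(mk_proj(0L, 0L), dest2)
  expect_equal(m$dest_peak, "near")
  dest3 <- data.frame(chrom = "d", start = c(990L, 1010L),
                      end = c(1090L, 1110L), strand = "+",
                      name = c("left", "right"), tier = "robust")
  m <- match_projected_peaks(mk_proj(0L, 0L), dest3)
  expect_equal(m$dest_peak, "left")
  # strand must agree
  destm <- transform(dest, strand = "-")
  expect_true(is.na(match_projected_peaks(mk_proj(0L, 0L),
                                          destm)$dest_peak))
})
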