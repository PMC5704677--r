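# CTSS quantification: alignment records -> single-base 5'-end profiles,
# tags-per-million scaling, pooling across samples.

#' Read alignment records from a SAM text file
#'
#' Minimal SAM parser covering what CTSS extraction needs: flag, chrom,
#' 0-based start, reference end (from the CIGAR), MAPQ, strand (flag bit
#' 0x10) and the `NM` edit-distance tag when present.
#'
#' @param path Path to a SAM text file.
#' @return `data.table` with columns `qname`, `flag`, `chrom`, `start`,
#'   `end`, `strand`, `mapq`, `nm` (`NA` when the tag is absent).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  empty <- data.table(qname = character(), flag = integer(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      mapq = integer(), nm = integer())
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 11L)) {
    stop("malformed SAM line ", which(lengths(fields) < 11L)[1L],
         " in ", path, call. = FALSE)
  }
  flag <- vapply(fields, function(f) as.integer(f[2]), integer(1))
  pos1 <- vapply(fields, function(f) as.integer(f[4]), integer(1))
  cigar <- vapply(fields, `[`, character(1), 6L)
  ref_len <- vapply(cigar, cigar_reference_length, integer(1),
                    USE.NAMES = FALSE)
  nm <- vapply(fields, function(f) {
    tags <- f[-(1:11)]
    hit <- tags[startsWith(tags, "NM:i:")]
    if (length(hit)) as.integer(sub("NM:i:", "", hit[1])) else NA_integer_
  }, integer(1))
  data.table(qname = vapply(fields, `[`, character(1), 1L),
             flag = flag,
             chrom = vapply(fields, `[`, character(1), 3L),
             start = pos1 - 1L,
             end = pos1 - 1L + ref_len,
             strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
             mapq = vapply(fields, function(f) as.integer(f[5]), integer(1)),
             nm = nm)
}

#' Reference-consuming length of a CIGAR string
#' @param cigar A CIGAR string (`"*"` gives 0).
#' @return Number of reference bases consumed (M/D/N/=/X operations).
#' @export
cigar_reference_length <- function(cigar) {
  if (cigar == "*") return(0L)
  ops <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (length(toks) == 0L) stop("malformed CIGAR: ", cigar, call. = FALSE)
  lens <- as.integer(sub("[MIDNSHP=X]$", "", toks))
  kinds <- sub("^[0-9]+", "", toks)
  sum(lens[kinds %in% c("M", "D", "N", "=", "X")])
}

#' Extract a CTSS profile from alignment records
#'
#' Each retained record contributes one tag at the position of its 5'
#' end: `start` on `"+"`, `end - 1` on `"-"`. Records are dropped when
#' (i) unmapped (flag 0x4), (ii) any bit of `exclude_flags` is set
#' (default 768 = secondary + QC-fail, the `samtools view -F 768`
#' semantics), (iii) `mapq < min_mapq` (the `-q` semantics: keep
#' `>= min_mapq`), or (iv) sequence identity `1 - NM/aligned_length`
#' falls below `min_identity`. Records without an `NM` tag pass the
#' identity filter with a one-time warning; records with an unknown
#' strand are skipped with a warning.
#'
#' @param records Alignment table as from [read_sam()] (or a path to a
#'   SAM file), with columns `chrom`, `start`, `end`, `strand`, `mapq`,
#'   `flag` and optionally `nm`.
#' @param min_mapq Minimum mapping quality (kept if `mapq >= min_mapq`).
#' @param exclude_flags SAM flag bits that exclude a record.
#' @param min_identity Minimum sequence identity in `[0, 1]`.
#' @return A [ctss_profile()].
#' @examples
#' aln <- data.frame(chrom = "chr1", start = 100L, end = 125L,
#'                   strand = "+", mapq = 30L, flag = 0L, nm = 0L)
#' extract_ctss_from_alignments(aln)
#' @export
extract_ctss_from_alignments <- function(records, min_mapq = 20,
                                         exclude_flags = 768L,
                                         min_identity = 0.85) {
  if (is.character(records) && length(records) == 1L) {
    records <- read_sam(records)
  }
  r <- as.data.table(records)
  if (!"nm" %in% names(r)) r[, nm := NA_integer_]
  if (!"flag" %in% names(r)) r[, flag := 0L]
  bad_strand <- !r$strand %in% c("+", "-")
  if (any(bad_strand)) {
    warning(sum(bad_strand), " record(s) with unknown strand skipped",
            call. = FALSE)
    r <- r[!bad_strand]
  }
  keep <- bitwAnd(r$flag, 4L) == 0L &
    bitwAnd(r$flag, as.integer(exclude_flags)) == 0L &
    r$mapq >= min_mapq
  no_nm <- is.na(r$nm)
  if (any(no_nm & keep)) {
    warning("records without NM tag pass the identity filter (",
            sum(no_nm & keep), " record(s))", call. = FALSE)
  }
  identity_ok <- no_nm | (1 - r$nm / pmax(r$end - r$start, 1L)) >= min_identity
  keep <- keep & identity_ok
  r <- r[keep]
  if (nrow(r) == 0L) return(ctss_profile())
  pos <- ifelse(r$strand == "+", r$start, r$end - 1L)
  ctss_profile(r$chrom, pos, r$strand, rep(1L, nrow(r)))
}

#' Tags per million
#'
#' @param count Tag count(s).
#' @param total_tags Library total (uniquely mapped tags); must be > 0.
#' @return `count * 1e6 / total_tags`.
#' @examples
#' tags_per_million(10, 1e7)  # 1.0, the robust-threshold boundary
#' @export
tags_per_million <- function(count, total_tags) {
  if (any(total_tags <= 0)) stop("total_tags must be > 0", call. = FALSE)
  count * 1e6 / total_tags
}

#' Bundle a sample's CTSS profile with its identifier and library size
#'
#' @param sample_id Sample label.
#' @param ctss A [ctss_profile()].
#' @return A list of class `cage_library` with elements `sample_id`,
#'   `ctss` and `total_tags` (the sum of all counts).
#' @export
sample_library <- function(sample_id, ctss) {
  structure(list(sample_id = sample_id, ctss = ctss,
                 total_tags = sum(ctss$count)),
            class = "cage_library")
}

#' Pool CTSS profiles across samples
#'
#' Position-wise sum of counts, per strand; strands are never merged.
#'
#' @param libraries List of [sample_library()] objects (at least one).
#' @return Pooled [ctss_profile()].
#' @export
pool_samples <- function(libraries) {
  stopifnot(length(libraries) >= 1L)
  all <- rbindlist(lapply(libraries, function(l) as.data.table(l$ctss)))
  ctss_profile(all$chrom, all$pos, all$strand, all$count)
}
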