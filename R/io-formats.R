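# On-disk formats: BED6 CTSS, BED12 gene models, UCSC chain, expression
# matrices, orthology tables, PWM text. All coordinates are 0-based
# half-open (BED convention) throughout the package.

#' @import data.table
NULL

.datatable.aware <- TRUE

#' Canonical CAGE name string for a stranded interval
#'
#' Builds the `"chrom:start..end,strand"` identifier used for CTSSs and
#' peaks. This exact dialect (two dots, comma before the strand) is the
#' external contract for interoperability with FANTOM-style files.
#'
#' @param chrom Chromosome names.
#' @param start 0-based start positions.
#' @param end End positions (half-open).
#' @param strand `"+"` or `"-"`.
#' @return Character vector of names.
#' @examples
#' cage_name("chr1", 100, 101, "+")
#' @export
cage_name <- function(chrom, start, end, strand) {
  paste0(chrom, ":", start, "..", end, ",", strand)
}

.check_strand <- function(strand) {
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    stop("invalid strand symbol(s): ",
         paste(unique(strand[bad]), collapse = ", "), call. = FALSE)
  }
  invisible(strand)
}

#' Construct a CTSS profile
#'
#' A CTSS profile is the single-base 5'-end signal of one sample (or a
#' pool): a table with one row per (chrom, pos, strand) carrying a tag
#' count. Duplicate positions are summed; rows are sorted by
#' (chrom, pos, strand) and zero-count rows dropped.
#'
#' @param chrom,pos,strand,count Parallel vectors; `pos` is 0-based.
#' @return A `data.table` of class `ctss_profile` with columns
#'   `chrom`, `pos`, `strand`, `count`.
#' @export
ctss_profile <- function(chrom = character(), pos = integer(),
                         strand = character(), count = integer()) {
  .check_strand(strand)
  if (any(count < 0)) stop("negative CTSS count", call. = FALSE)
  dt <- data.table(chrom = as.character(chrom), pos = as.integer(pos),
                   strand = as.character(strand), count = as.numeric(count))
  dt <- dt[count > 0, .(count = sum(count)), by = .(chrom, pos, strand)]
  setorder(dt, chrom, pos, strand)
  setattr(dt, "class", c("ctss_profile", class(dt)))
  dt[]
}

#' Read a CTSS BED6 file
#'
#' Expects the single-base dialect: `end == start + 1`, column 5 an
#' integer tag count, column 4 the canonical name string.
#'
#' @param path Path to a BED6 file (may be empty).
#' @return A [ctss_profile()].
#' @export
read_ctss_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(ctss_profile())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop("malformed BED6 line ", which(nf < 6L)[1L], " in ", path,
         call. = FALSE)
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  count <- suppressWarnings(as.integer(m[, 5]))
  bad <- is.na(start) | is.na(end) | is.na(count)
  if (any(bad)) {
    stop("malformed BED6 line ", which(bad)[1L], " in ", path, call. = FALSE)
  }
  if (any(end != start + 1L)) {
    stop("CTSS record with end != start+1 at line ",
         which(end != start + 1L)[1L], " in ", path, call. = FALSE)
  }
  .check_strand(m[, 6])
  ctss_profile(m[, 1], start, m[, 6], count)
}

#' Write a CTSS profile as canonical BED6
#'
#' Rows with zero counts are dropped; names are regenerated with
#' [cage_name()], so `write_ctss_bed(read_ctss_bed(f), g)` is
#' byte-identical to a canonical `f`.
#'
#' @param profile A [ctss_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ctss_bed <- function(profile, path) {
  p <- as.data.table(profile)[count > 0]
  setorder(p, chrom, pos, strand)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", p$chrom, p$pos, p$pos + 1L,
                   cage_name(p$chrom, p$pos, p$pos + 1L, p$strand),
                   as.integer(round(p$count)), p$strand)
  writeLines(lines, path)
  invisible(path)
}

# ---- generic BED6 (peaks, CpG islands, repeats) -------------------------

#' Read a plain BED file (3-6 columns)
#'
#' @param path Path to a BED file.
#' @return `data.table` with columns `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  if (length(lines) == 0L) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- min(lengths(fields), 6L)
  if (n < 3L) stop("BED line with fewer than 3 fields in ", path,
                   call. = FALSE)
  m <- matrix(unlist(lapply(fields, `[`, seq_len(n))), ncol = n, byrow = TRUE)
  dt <- as.data.table(m)
  setnames(dt, cols[seq_len(n)])
  dt[, `:=`(start = as.integer(start), end = as.integer(end))]
  if ("score" %in% names(dt)) dt[, score := as.numeric(score)]
  dt[]
}

#' Write a BED file from a table with chrom/start/end (+ name, score, strand)
#' @param x A data.frame with at least `chrom`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- as.data.table(x)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  lines <- do.call(paste, c(unname(as.list(x[, cols, with = FALSE])),
                            sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# ---- UCSC chain ---------------------------------------------------------

#' Construct a chain map
#'
#' A chain describes a colinear pairwise alignment between a *target*
#' (source assembly for projection) and a *query* (destination assembly)
#' as ordered blocks of `(size, dt, dq)`: `size` aligned bases, then `dt`
#' unaligned target bases and `dq` unaligned query bases. Query
#' coordinates are given on `q_strand`; for `"-"` they count from the
#' reverse-complemented sequence, as in the UCSC format.
#'
#' @param score Chain score (numeric).
#' @param t_name,t_size,t_start,t_end Target sequence name/length/span.
#' @param q_name,q_size,q_strand,q_start,q_end Query side; strand `"+"/"-"`.
#' @param id Integer chain id.
#' @param blocks `data.frame` with columns `size`, `dt`, `dq` (last row
#'   must have `dt == dq == 0`).
#' @return A list of class `chain_map`.
#' @export
chain_map <- function(score, t_name, t_size, t_start, t_end,
                      q_name, q_size, q_strand, q_start, q_end, id, blocks) {
  blocks <- as.data.table(blocks)
  stopifnot(all(c("size", "dt", "dq") %in% names(blocks)))
  if (any(blocks$size < 0) || any(blocks$dt < 0) || any(blocks$dq < 0)) {
    stop("negative block size or gap in chain ", id, call. = FALSE)
  }
  if (!q_strand %in% c("+", "-")) {
    stop("unknown strand symbol '", q_strand, "' in chain ", id,
         call. = FALSE)
  }
  if (sum(blocks$size) + sum(blocks$dt) != t_end - t_start) {
    stop("chain ", id, ": target span does not reconcile with blocks",
         call. = FALSE)
  }
  if (sum(blocks$size) + sum(blocks$dq) != q_end - q_start) {
    stop("chain ", id, ": query span does not reconcile with blocks",
         call. = FALSE)
  }
  structure(list(score = score, t_name = t_name, t_size = as.integer(t_size),
                 t_start = as.integer(t_start), t_end = as.integer(t_end),
                 q_name = q_name, q_size = as.integer(q_size),
                 q_strand = q_strand, q_start = as.integer(q_start),
                 q_end = as.integer(q_end), id = as.integer(id),
                 blocks = blocks[]),
            class = "chain_map")
}

#' Parse a UCSC chain file
#'
#' @param path Path to a chain file (plain text or gzip).
#' @return List of [chain_map()] objects, in file order.
#' @export
parse_chain_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  chains <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(lines[i])) { i <- i + 1L; next }
    if (!startsWith(lines[i], "chain")) {
      stop("expected chain header at line ", i, " of ", path, call. = FALSE)
    }
    h <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(h) != 13L) {
      stop("malformed chain header at line ", i, " of ", path, call. = FALSE)
    }
    if (h[5] != "+") {
      stop("unknown target strand '", h[5], "' at line ", i, " of ", path,
           call. = FALSE)
    }
    i <- i + 1L
    sizes <- integer(); dts <- integer(); dqs <- integer()
    repeat {
      if (i > n || !nzchar(lines[i])) {
        stop("truncated chain (missing terminal block) near line ", i,
             " of ", path, call. = FALSE)
      }
      b <- suppressWarnings(as.integer(strsplit(lines[i], "[ \t]+")[[1]]))
      if (anyNA(b)) stop("malformed block line ", i, " of ", path,
                         call. = FALSE)
      if (length(b) == 1L) {
        sizes <- c(sizes, b); dts <- c(dts, 0L); dqs <- c(dqs, 0L)
        i <- i + 1L
        break
      } else if (length(b) == 3L) {
        sizes <- c(sizes, b[1]); dts <- c(dts, b[2]); dqs <- c(dqs, b[3])
        i <- i + 1L
      } else {
        stop("malformed block line ", i, " of ", path, call. = FALSE)
      }
    }
    chains[[length(chains) + 1L]] <- chain_map(
      score = as.numeric(h[2]),
      t_name = h[3], t_size = as.integer(h[4]),
      t_start = as.integer(h[6]), t_end = as.integer(h[7]),
      q_name = h[8], q_size = as.integer(h[9]), q_strand = h[10],
      q_start = as.integer(h[11]), q_end = as.integer(h[12]),
      id = as.integer(h[13]),
      blocks = data.table(size = sizes, dt = dts, dq = dqs))
  }
  chains
}

#' Write chains in UCSC chain format
#' @param chains List of [chain_map()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain_file <- function(chains, path) {
  out <- character()
  for (ch in chains) {
    out <- c(out, sprintf("chain %s %s %d + %d %d %s %d %s %d %d %d",
                          format(ch$score, scientific = FALSE),
                          ch$t_name, ch$t_size, ch$t_start, ch$t_end,
                          ch$q_name, ch$q_size, ch$q_strand,
                          ch$q_start, ch$q_end, ch$id))
    b <- ch$blocks
    k <- nrow(b)
    if (k > 1L) {
      out <- c(out, sprintf("%d\t%d\t%d", b$size[-k], b$dt[-k], b$dq[-k]))
    }
    out <- c(out, sprintf("%d", b$size[k]), "")
  }
  writeLines(out, path)
  invisible(path)
}

# ---- BED12 gene models --------------------------------------------------

#' Read gene models from a BED12 file
#'
#' The name field is parsed as `"gene_id|transcript_id"` when it contains
#' a pipe, otherwise gene and transcript id are both the name.
#' `thickStart`/`thickEnd` carry the coding span; `thickStart == thickEnd`
#' marks a non-coding record (CDS columns are `NA`).
#'
#' @param path Path to a BED12 file.
#' @param source_set Label of the annotation set (e.g. `"ensembl"`).
#' @return `data.table` with columns `chrom`, `tx_start`, `tx_end`,
#'   `strand`, `gene_id`, `transcript_id`, `cds_start`, `cds_end`, `tss`
#'   (5' end: `tx_start` on `"+"`, `tx_end - 1` on `"-"`), `source_set`,
#'   and list-columns `exon_starts`/`exon_ends` (absolute, half-open).
#' @export
read_gene_models <- function(path, source_set = "genes") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  empty <- data.table(chrom = character(), tx_start = integer(),
                      tx_end = integer(), strand = character(),
                      gene_id = character(), transcript_id = character(),
                      cds_start = integer(), cds_end = integer(),
                      tss = integer(), source_set = character(),
                      exon_starts = list(), exon_ends = list())
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 12L)) {
    stop("BED12 line with fewer than 12 fields in ", path, call. = FALSE)
  }
  recs <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    tx_start <- as.integer(f[2]); tx_end <- as.integer(f[3])
    thick_s <- as.integer(f[7]); thick_e <- as.integer(f[8])
    n_blocks <- as.integer(f[10])
    sizes <- as.integer(strsplit(f[11], ",", fixed = TRUE)[[1]])
    starts <- as.integer(strsplit(f[12], ",", fixed = TRUE)[[1]])
    if (length(sizes) != n_blocks || length(starts) != n_blocks) {
      stop("blockSizes/blockStarts inconsistent at line ", i, " of ", path,
           call. = FALSE)
    }
    ex_s <- tx_start + starts
    ex_e <- ex_s + sizes
    if (starts[1] != 0L || ex_e[n_blocks] != tx_end || any(ex_e > tx_end)) {
      stop("blocks inconsistent with transcript span at line ", i, " of ",
           path, call. = FALSE)
    }
    strand <- f[6]
    .check_strand(strand)
    name <- f[4]
    if (grepl("|", name, fixed = TRUE)) {
      parts <- strsplit(name, "|", fixed = TRUE)[[1]]
      gene_id <- parts[1]; transcript_id <- parts[2]
    } else {
      gene_id <- name; transcript_id <- name
    }
    coding <- thick_e > thick_s
    list(chrom = f[1], tx_start = tx_start, tx_end = tx_end, strand = strand,
         gene_id = gene_id, transcript_id = transcript_id,
         cds_start = if (coding) thick_s else NA_integer_,
         cds_end = if (coding) thick_e else NA_integer_,
         tss = if (strand == "+") tx_start else tx_end - 1L,
         source_set = source_set,
         exon_starts = list(ex_s), exon_ends = list(ex_e))
  })
  rbindlist(recs)
}

#' Write gene models as BED12
#' @param models Table as returned by [read_gene_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  m <- as.data.table(models)
  lines <- vapply(seq_len(nrow(m)), function(i) {
    ex_s <- m$exon_starts[[i]]; ex_e <- m$exon_ends[[i]]
    sizes <- ex_e - ex_s
    starts <- ex_s - m$tx_start[i]
    name <- if (m$gene_id[i] == m$transcript_id[i]) m$gene_id[i] else
      paste0(m$gene_id[i], "|", m$transcript_id[i])
    thick_s <- if (is.na(m$cds_start[i])) m$tx_start[i] else m$cds_start[i]
    thick_e <- if (is.na(m$cds_start[i])) m$tx_start[i] else m$cds_end[i]
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            m$chrom[i], m$tx_start[i], m$tx_end[i], name, m$strand[i],
            thick_s, thick_e, length(sizes),
            paste0(paste(sizes, collapse = ","), ","),
            paste0(paste(starts, collapse = ","), ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- expression matrices, orthology, PWM --------------------------------

#' Read a tab-separated expression matrix (rows = peaks, cols = samples)
#' @param path Path to a TSV with a header line and row names in column 1.
#' @return Numeric matrix with peak names as rownames.
#' @export
read_expression_matrix <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- dt[[1]]
  storage.mode(m) <- "numeric"
  m
}

#' Write an expression matrix as TSV
#' @param m Numeric matrix with rownames.
#' @param path Output path.
#' @param id_col Header of the first (row name) column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, id_col = "peak") {
  header <- paste(c(id_col, colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format(m[i, ], trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an orthology table (source_gene_id TAB dest_gene_id)
#' @param path Path to a two-column TSV (no header).
#' @return `data.table` with columns `source_gene`, `dest_gene`.
#' @export
read_orthology <- function(path) {
  dt <- fread(path, sep = "\t", header = FALSE,
              colClasses = list(character = 1:2))
  setnames(dt, c("source_gene", "dest_gene"))
  dt[]
}

#' Read a position-weight (frequency) matrix
#'
#' Four tab-separated rows labelled A, C, G, T; columns are motif
#' positions with base frequencies.
#'
#' @param path Path to the PWM text file.
#' @return 4 x width numeric matrix, rows `A`, `C`, `G`, `T`.
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bases <- vapply(parts, `[`, character(1), 1L)
  if (!setequal(bases, c("A", "C", "G", "T"))) {
    stop("PWM must have rows labelled A, C, G, T", call. = FALSE)
  }
  vals <- lapply(parts, function(p) as.numeric(p[-1]))
  m <- do.call(rbind, vals)
  rownames(m) <- bases
  m[c("A", "C", "G", "T"), , drop = FALSE]
}

#' Write a position-frequency matrix
#' @param pwm 4 x width matrix with rows A, C, G, T.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(pwm, path) {
  lines <- vapply(c("A", "C", "G", "T"), function(b) {
    paste(c(b, format(pwm[b, ], trim = TRUE)), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
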